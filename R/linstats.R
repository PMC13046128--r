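# Linear statistics on cell counts and normalised distances.

#' One-way analysis of variance across groups
#'
#' Classical fixed-effects one-way ANOVA: between-group mean square over
#' within-group mean square with `(k - 1, N - k)` degrees of freedom. Used
#' for per-animal cell counts across genotypes.
#'
#' @param groups list of numeric vectors, one per group; at least two groups
#'   with at least two values each and positive within-group variance.
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("each group needs at least two values", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), times = n))
  within <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (within <= 0) {
    stop("zero within-group variance: F undefined", call. = FALSE)
  }
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab[["F value"]][1], df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
       p_value = tab[["Pr(>F)"]][1])
}

#' Nested one-way ANOVA with animals nested in genotype
#'
#' Tests the genotype effect against the animal-within-genotype stratum:
#' `F = MS_genotype / MS_animal(genotype)` with
#' `(k - 1, sum(a_i - 1))` degrees of freedom, where `a_i` is the number of
#' animals in genotype `i`. Sums of squares are sequential (genotype entered
#' first), which is unambiguous for this single-factor nested layout and
#' weights animal means by their cell counts in unbalanced designs. Used
#' for per-cell normalised distances, where cells are pseudo-replicates
#' within an animal.
#'
#' @param values numeric vector of per-cell values.
#' @param genotype,animal vectors (coerced to factor) labelling each value;
#'   every animal must belong to exactly one genotype and every genotype
#'   must contribute at least two animals.
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
nested_anova <- function(values, genotype, animal) {
  if (length(values) != length(genotype) || length(values) != length(animal)) {
    stop("values, genotype and animal must have equal length", call. = FALSE)
  }
  g <- factor(genotype)
  a <- factor(paste(genotype, animal, sep = ":"))
  if (nlevels(g) < 2L) stop("need at least two genotypes", call. = FALSE)
  animals_per_g <- tapply(a, g, function(x) length(unique(x)))
  if (any(animals_per_g < 2L)) {
    stop("every genotype needs at least two animals", call. = FALSE)
  }
  map <- tapply(as.character(g), a, function(x) length(unique(x)))
  if (any(map != 1L)) stop("an animal maps to several genotypes", call. = FALSE)
  fit <- stats::aov(values ~ g + g:a)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  ig <- match("g", rn); ia <- match("g:a", rn)
  if (is.na(ig) || is.na(ia)) stop("nested decomposition failed", call. = FALSE)
  msg <- tab[ig, "Mean Sq"]; msa <- tab[ia, "Mean Sq"]
  df1 <- tab[ig, "Df"]; df2 <- tab[ia, "Df"]
  if (!is.finite(msa) || msa <= 0) {
    stop("zero animal-within-genotype variance: F undefined", call. = FALSE)
  }
  Fval <- msg / msa
  list(F = Fval, df1 = df1, df2 = df2,
       p_value = stats::pf(Fval, df1, df2, lower.tail = FALSE))
}
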