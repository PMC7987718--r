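# Two-choice oviposition preference scoring and its statistical contracts.

#' Oviposition preference index
#'
#' `(eggs_a - eggs_b) / (eggs_a + eggs_b)`, with side A the
#' pheromone-treated oviposition zone: +1.0 means every egg on the
#' pheromone side, -1.0 every egg on the control side. Females that laid
#' no eggs have an undefined index (`NA`).
#'
#' @param eggs_a,eggs_b Non-negative egg counts (vectorized).
#' @return Index in `[-1, 1]` or `NA`.
#' @export
oviposition_index <- function(eggs_a, eggs_b) {
  stopifnot(all(eggs_a >= 0, na.rm = TRUE), all(eggs_b >= 0, na.rm = TRUE))
  tot <- eggs_a + eggs_b
  ifelse(is.na(tot) | tot == 0, NA_real_, (eggs_a - eggs_b) / tot)
}

#' Two-tailed Wilcoxon signed-rank test against no preference
#'
#' Tests whether preference indices differ from `mu` (default 0, no
#' preference). Zero differences are dropped; the exact null distribution
#' is used for up to 25 nonzero differences without ties, otherwise the
#' normal approximation with continuity correction.
#'
#' @param x Preference indices (NA allowed, dropped).
#' @param mu Null location.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A list with `V` (signed-rank statistic), `p` (two-sided),
#'   `n_used` (nonzero differences) and `exact`.
#' @export
ovi_signed_rank <- function(x, mu = 0, exact_max = 25) {
  d <- x[!is.na(x)] - mu
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    warning("all differences zero; signed-rank test undefined")
    return(list(V = NA_real_, p = NA_real_, n_used = 0L, exact = NA))
  }
  exact <- n <= exact_max && !any(duplicated(abs(nz)))
  res <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = exact,
                                             correct = TRUE))
  list(V = unname(res$statistic), p = res$p.value, n_used = n,
       exact = exact)
}

#' Quasibinomial GLM for oviposition preference across genotypes
#'
#' Fits `cbind(eggs_a, eggs_b) ~ genotype` with a quasibinomial error
#' distribution (logit link, IRLS) and tests the genotype term with an
#' F test using the Pearson-based dispersion estimate. Females with zero
#' total eggs carry no information and are dropped; complete separation
#' (a genotype with pooled proportion 0 or 1) is flagged.
#'
#' @param eggs `data.frame(genotype, eggs_a, eggs_b)`, one row per female.
#' @return A list with `fit` (the glm object), `dispersion`, `F`, `df1`,
#'   `df2`, `p` and `proportions` (`data.frame(genotype, prop_a)` of
#'   fitted per-genotype side-A proportions).
#' @export
preference_glm <- function(eggs) {
  check_columns(eggs, c("genotype", "eggs_a", "eggs_b"), "egg table")
  d <- eggs[eggs$eggs_a + eggs$eggs_b > 0, , drop = FALSE]
  d$genotype <- factor(d$genotype)
  if (nlevels(d$genotype) < 2L) stop("need >= 2 genotypes")
  pooled <- tapply(d$eggs_a, d$genotype, sum) /
    tapply(d$eggs_a + d$eggs_b, d$genotype, sum)
  if (any(pooled %in% c(0, 1))) {
    warning("complete separation: genotype(s) with pooled proportion 0 or 1")
  }
  fit <- stats::glm(cbind(eggs_a, eggs_b) ~ genotype,
                    family = stats::quasibinomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 50))
  dispersion <- sum(stats::residuals(fit, type = "pearson")^2) /
    stats::df.residual(fit)
  an <- stats::anova(fit, test = "F")
  nd <- data.frame(genotype = levels(d$genotype))
  props <- data.frame(genotype = nd$genotype,
                      prop_a = stats::predict(fit, newdata = nd,
                                              type = "response"))
  list(fit = fit, dispersion = dispersion,
       F = an["genotype", "F"], df1 = an["genotype", "Df"],
       df2 = stats::df.residual(fit), p = an["genotype", "Pr(>F)"],
       proportions = props)
}

#' Negative-binomial GLM for total fecundity across genotypes
#'
#' Fits `total eggs ~ genotype` with a negative-binomial error
#' distribution (log link, dispersion estimated by maximum likelihood) and
#' tests the genotype term with a chi-squared likelihood-ratio test
#' against the intercept-only model. Zero-variance groups are flagged.
#'
#' @param eggs `data.frame(genotype, eggs_a, eggs_b)`, one row per female.
#' @return A list with `fit`, `theta` (estimated NB size), `chisq`, `df`,
#'   `p` and `means` (`data.frame(genotype, mean_eggs)` of fitted group
#'   means).
#' @export
fecundity_glm <- function(eggs) {
  check_columns(eggs, c("genotype", "eggs_a", "eggs_b"), "egg table")
  d <- data.frame(genotype = factor(eggs$genotype),
                  total = eggs$eggs_a + eggs$eggs_b)
  if (nlevels(d$genotype) < 2L) stop("need >= 2 genotypes")
  vars <- tapply(d$total, d$genotype, stats::var)
  if (any(!is.na(vars) & vars == 0)) {
    warning("zero-variance group(s); negative-binomial fit may be unstable")
  }
  fit <- MASS::glm.nb(total ~ genotype, data = d)
  fit0 <- MASS::glm.nb(total ~ 1, data = d)
  an <- stats::anova(fit0, fit)
  nd <- data.frame(genotype = levels(d$genotype))
  means <- data.frame(genotype = nd$genotype,
                      mean_eggs = stats::predict(fit, newdata = nd,
                                                 type = "response"))
  list(fit = fit, theta = fit$theta,
       chisq = an$`LR stat.`[2], df = an$`   df`[2] %||% (nlevels(d$genotype) - 1L),
       p = an$`Pr(Chi)`[2], means = means)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a
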