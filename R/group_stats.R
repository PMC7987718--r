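# Group-level statistics: mean density curves, KS, Kaplan-Meier/log-rank,
# one-way ANOVA + pairwise t tests, Kruskal-Wallis + Mann-Whitney U, Holm.
#
# These are thin, contract-enforcing wrappers over the standard machinery
# (stats::density, ks.test, aov/t.test, kruskal.test/wilcox.test, p.adjust,
# survival::survfit/survdiff) so that downstream reports carry one
# consistent shape; the tests validate them against enumeration and hand
# oracles.

#' Mean of per-individual kernel density curves
#'
#' Estimates one Gaussian KDE per individual (rule-of-thumb bandwidth, the
#' `density()` default) on a common 512-point grid spanning the pooled data
#' range plus `cut` bandwidths on each side, then averages the curves
#' pointwise across individuals with a normal-approximation 95% CI.
#'
#' @param samples List of numeric vectors, one per individual. Individuals
#'   with fewer than two finite values are excluded with a warning.
#' @param n_grid Number of grid points.
#' @param cut Grid extension beyond the data range, in units of the
#'   largest individual bandwidth.
#' @return A list with `curve` (`data.frame(grid, density, ci_low,
#'   ci_high)`) and `n_individuals`.
#' @export
mean_density <- function(samples, n_grid = 512, cut = 3) {
  stopifnot(is.list(samples))
  samples <- lapply(samples, function(x) x[is.finite(x)])
  ok <- vapply(samples, function(x) length(x) >= 2L, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " individual(s) with fewer than 2 finite samples ",
            "excluded from the mean density")
  }
  samples <- samples[ok]
  if (length(samples) == 0L) stop("no individual with >= 2 finite samples")
  bws <- vapply(samples, stats::bw.nrd0, numeric(1))
  lo <- min(unlist(samples)) - cut * max(bws)
  hi <- max(unlist(samples)) + cut * max(bws)
  dens <- vapply(seq_along(samples), function(i) {
    stats::density(samples[[i]], bw = bws[i], from = lo, to = hi,
                   n = n_grid)$y
  }, numeric(n_grid))
  grid <- seq(lo, hi, length.out = n_grid)
  m <- rowMeans(dens)
  k <- length(samples)
  se <- if (k > 1L) apply(dens, 1, stats::sd) / sqrt(k) else rep(NA_real_,
                                                                 n_grid)
  z <- stats::qnorm(0.975)
  list(curve = data.frame(grid = grid, density = m,
                          ci_low = m - z * se, ci_high = m + z * se),
       n_individuals = k)
}

#' Two-sample two-sided Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute ECDF difference; the p-value comes
#' from `ks.test()` with default settings (exact at small sample sizes
#' without ties, asymptotic otherwise).
#'
#' @param x,y Nonempty numeric samples.
#' @return A list with `D` and `p`.
#' @export
ks_2sample <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Kaplan-Meier copulation curves and log-rank test
#'
#' Product-limit estimator per group with Greenwood-based 95% CIs
#' (`survfit` defaults), a global log-rank test across groups, and pairwise
#' log-rank tests with Holm adjustment. Subjects with missing event times
#' or times beyond the horizon are censored at the horizon (the standard
#' handling of non-copulators in a fixed-length assay).
#'
#' @param time_min Time to event (copulation), minutes. `NA` = no event.
#' @param event Logical/0-1 event indicator.
#' @param group Group (genotype) factor; every level must have >= 1
#'   subject.
#' @param horizon_min Assay horizon, minutes.
#' @return A list with `curves` (`data.frame(group, time, n_risk, n_event,
#'   surv, ci_low, ci_high)`), `chisq`, `df`, `p` and `pairwise`
#'   (`data.frame(group1, group2, chisq, p, p_adj)`, `NULL` for two
#'   groups or fewer... present for >= 3 groups).
#' @export
km_logrank <- function(time_min, event, group, horizon_min = 60) {
  check_scalar(horizon_min, "horizon_min", lower = 1e-9)
  if (!is.factor(group)) group <- factor(group)
  if (any(table(group) == 0L)) stop("every group must have >= 1 subject")
  event <- as.integer(as.logical(event))
  time_min <- as.numeric(time_min)
  event[is.na(time_min) | time_min > horizon_min] <- 0L
  time_min[is.na(time_min)] <- horizon_min
  time_min <- pmin(time_min, horizon_min)
  if (any(time_min <= 0)) stop("event times must be positive")

  d <- data.frame(time = time_min, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sm <- summary(sf, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(group)[1], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv,
                       ci_low = sm$lower, ci_high = sm$upper)

  k <- nlevels(group)
  chisq <- 0
  p <- 1
  if (k >= 2L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(chisq, df = k - 1L, lower.tail = FALSE)
  }
  pairwise <- NULL
  if (k >= 2L) {
    prs <- utils::combn(levels(group), 2L)
    pw <- apply(prs, 2L, function(pr) {
      dd <- d[d$group %in% pr, , drop = FALSE]
      dd$group <- droplevels(dd$group)
      s2 <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = dd)
      c(chisq = unname(s2$chisq),
        p = stats::pchisq(unname(s2$chisq), df = 1L, lower.tail = FALSE))
    })
    pairwise <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                           chisq = pw["chisq", ], p = pw["p", ],
                           p_adj = holm_adjust(pw["p", ]))
  }
  list(curves = curves, chisq = chisq, df = k - 1L, p = p,
       pairwise = pairwise)
}

#' One-way ANOVA with Holm-adjusted pairwise pooled t tests
#'
#' Standard one-way decomposition via `aov()`, followed by two-sided
#' pooled-variance t tests for every group pair, all pairwise p-values
#' Holm-adjusted. Degenerate (zero residual variance) data are flagged
#' with a warning.
#'
#' @param values Numeric response.
#' @param group Group factor (>= 2 levels, each with >= 2 values).
#' @return A list with `F`, `df1`, `df2`, `p` and `pairwise`
#'   (`data.frame(group1, group2, t, p, p_adj)`).
#' @export
anova_pairwise_t <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  if (any(table(group) < 2L)) stop("every group needs >= 2 values")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  if (tab["Residuals", "Sum Sq"] < 1e-12) {
    warning("residual variance is (numerically) zero; F is unreliable")
  }
  prs <- utils::combn(levels(group), 2L)
  pw <- apply(prs, 2L, function(pr) {
    tt <- stats::t.test(values[group == pr[1]], values[group == pr[2]],
                        var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  list(F = tab["group", "F value"], df1 = tab["group", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["group", "Pr(>F)"],
       pairwise = data.frame(group1 = prs[1, ], group2 = prs[2, ],
                             t = pw["t", ], p = pw["p", ],
                             p_adj = holm_adjust(pw["p", ])))
}

#' Kruskal-Wallis test with Holm-adjusted pairwise Mann-Whitney U tests
#'
#' Rank-based H with tie correction (`kruskal.test`), then a two-sided
#' Mann-Whitney U test per group pair (`wilcox.test`, exact at small n
#' without ties), all pairwise p-values Holm-adjusted. All-tied data leave
#' H undefined and are flagged.
#'
#' @param values Numeric response.
#' @param group Group factor (>= 2 levels).
#' @return A list with `H`, `df`, `p` and `pairwise`
#'   (`data.frame(group1, group2, U, p, p_adj)`).
#' @export
kruskal_mwu <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  if (length(unique(values)) == 1L) {
    warning("all values tied; H undefined")
    return(list(H = NA_real_, df = nlevels(group) - 1L, p = NA_real_,
                pairwise = NULL))
  }
  kt <- stats::kruskal.test(values, group)
  prs <- utils::combn(levels(group), 2L)
  pw <- apply(prs, 2L, function(pr) {
    wt <- suppressWarnings(
      stats::wilcox.test(values[group == pr[1]], values[group == pr[2]],
                         alternative = "two.sided"))
    c(U = unname(wt$statistic), p = wt$p.value)
  })
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value,
       pairwise = data.frame(group1 = prs[1, ], group2 = prs[2, ],
                             U = pw["U", ], p = pw["p", ],
                             p_adj = holm_adjust(pw["p", ])))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down Holm adjustment with monotonicity enforcement, capped at 1
#' (`p.adjust(method = "holm")`). Adjustment is applied within one family
#' of comparisons; callers group p-values per metric.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}
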