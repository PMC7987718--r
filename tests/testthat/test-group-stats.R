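# Group statistics against enumeration and hand-arithmetic oracles.

# Hand log-rank for two groups: observed-minus-expected with
# hypergeometric variance, accumulated over distinct event times.
logrank_oracle_2g <- function(time, event, group) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2L)
  ts <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == levels(g)[1])
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

test_that("mean density averages individual KDEs and integrates to one", {
  set.seed(50)
  one <- list(rnorm(40))
  md <- mean_density(one)
  d <- density(one[[1]])  # same rule-of-thumb bandwidth, own grid
  ref <- approx(d$x, d$y, xout = md$curve$grid, rule = 2)$y
  expect_equal(md$curve$density, ref, tolerance = 1e-6)
  expect_lt(abs(pracma::trapz(md$curve$grid, md$curve$density) - 1), 1e-3)
  # two identical individuals: zero-width CI
  two <- mean_density(list(one[[1]], one[[1]]))
  expect_equal(two$curve$ci_low, two$curve$ci_high)
  expect_lt(abs(pracma::trapz(two$curve$grid, two$curve$density) - 1), 1e-3)
  expect_warning(mean_density(list(rnorm(10), 3)), "excluded")
})

test_that("KS statistic hits its bounds and matches small-n enumeration", {
  expect_equal(ks_2sample(1:5, 1:5)$D, 0)
  expect_equal(ks_2sample(1:5, 11:15)$D, 1)  # disjoint supports
  expect_error(ks_2sample(numeric(0), 1:3), "nonempty")
  # exact p by enumerating all assignments of pooled ranks (n = m = 5)
  set.seed(51)
  x <- rnorm(5); y <- rnorm(5, 1)
  obs <- ks_2sample(x, y)
  pool <- c(x, y)
  ks_stat <- function(a, b) {
    e <- sort(unique(pool))
    max(abs(ecdf(a)(e) - ecdf(b)(e)))
  }
  ds <- apply(combn(10, 5), 2, function(ix) ks_stat(pool[ix], pool[-ix]))
  p_enum <- mean(ds >= obs$D - 1e-12)
  expect_equal(obs$p, p_enum, tolerance = 1e-10)
})

test_that("KM with no censoring equals one minus the event-time ECDF", {
  times <- c(5, 8, 8, 12, 20, 33)
  r <- km_logrank(times, rep(1, 6), rep("g", 6), horizon_min = 60)
  cu <- r$curves[r$curves$n_event > 0, ]
  expect_equal(cu$surv, 1 - ecdf(times)(cu$time))
})

test_that("log-rank matches hand observed-minus-expected arithmetic", {
  # identical groups: chi-squared exactly zero
  tm <- c(3, 7, 11, 3, 7, 11)
  gr <- rep(c("a", "b"), each = 3)
  r0 <- km_logrank(tm, rep(1, 6), gr)
  expect_equal(r0$chisq, 0, tolerance = 1e-12)
  # toy two-group data with censoring
  tm2 <- c(2, 4, 9, 30, 3, 6, 60, 60)
  ev2 <- c(1, 1, 1, 0, 1, 1, 0, 0)
  gr2 <- rep(c("a", "b"), each = 4)
  r2 <- km_logrank(tm2, ev2, gr2)
  expect_equal(r2$chisq, logrank_oracle_2g(pmin(tm2, 60), ev2, gr2),
               tolerance = 1e-10)
  # three groups: df and a pairwise table with Holm adjustment
  tm3 <- c(tm2, 5, 15, 25, 60)
  ev3 <- c(ev2, 1, 1, 1, 0)
  gr3 <- c(gr2, rep("c", 4))
  r3 <- km_logrank(tm3, ev3, gr3)
  expect_equal(r3$df, 2)
  expect_equal(nrow(r3$pairwise), 3)
  expect_equal(r3$pairwise$p_adj, holm_adjust(r3$pairwise$p))
  expect_error(km_logrank(tm2, ev2, factor(gr2, levels = c("a", "b", "z"))),
               ">= 1 subject")
})

test_that("one-way ANOVA matches manual sums of squares and F = t^2", {
  # two groups: F equals the squared pooled t statistic
  set.seed(52)
  v <- c(rnorm(6), rnorm(6, 1))
  g <- rep(c("a", "b"), each = 6)
  r <- anova_pairwise_t(v, g)
  expect_equal(r$F, unname(r$pairwise$t^2), tolerance = 1e-10)
  expect_equal(r$p, r$pairwise$p, tolerance = 1e-10)
  # toy 3 x 5 table against brute-force sum-of-squares arithmetic
  vals <- c(4, 5, 6, 5, 5,  7, 8, 9, 8, 8,  4, 4, 5, 6, 6)
  grp <- rep(c("a", "b", "c"), each = 5)
  r3 <- anova_pairwise_t(vals, grp)
  gm <- mean(vals)
  ss_b <- sum(5 * (tapply(vals, grp, mean) - gm)^2)
  ss_w <- sum((vals - ave(vals, grp))^2)
  F_hand <- (ss_b / 2) / (ss_w / 12)
  expect_equal(r3$F, F_hand, tolerance = 1e-12)
  expect_equal(r3$p, pf(F_hand, 2, 12, lower.tail = FALSE))
  # identical groups: F = 0, p = 1
  rid <- anova_pairwise_t(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(rid$F, 0)
  expect_equal(rid$p, 1)
})

test_that("Kruskal-Wallis/Mann-Whitney match enumeration and rank laws", {
  # U for {1,2} vs {3,4}: all four pooled values in one order, U = 0,
  # exact two-sided p = 2/6
  r <- kruskal_mwu(c(1, 2, 3, 4), rep(c("a", "b"), each = 2))
  expect_equal(r$pairwise$U, 0)
  expect_equal(r$pairwise$p, 2 / 6, tolerance = 1e-12)
  # H is invariant under monotone transformation
  set.seed(53)
  v <- runif(18); g <- rep(c("a", "b", "c"), 6)
  expect_equal(kruskal_mwu(v, g)$H, kruskal_mwu(exp(v), g)$H)
  # identical group compositions: H = 0, p = 1
  rid <- kruskal_mwu(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(rid$H, 0)
  expect_equal(rid$p, 1)
  expect_warning(kruskal_mwu(rep(1, 6), rep(c("a", "b"), 3)), "tied")
})

test_that("Holm adjustment reproduces the step-down hand computation", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  # literal step-down for four p-values: sort, multiply by (m - i + 1),
  # enforce monotonicity, cap at 1
  p <- c(0.04, 0.001, 0.3, 0.02)
  o <- order(p)
  stepdown <- pmin(1, cummax(sort(p) * (4:1)))
  expect_equal(holm_adjust(p)[o], stepdown)
  expect_true(all(holm_adjust(p) >= p))
  expect_equal(order(holm_adjust(p)), order(p))
})
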