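# Synthetic generators: determinism, schedule fidelity, planted statistics.

test_that("all generators are seed-deterministic and leave the RNG alone", {
  set.seed(999)
  before <- .Random.seed
  cp <- courtship_sim_params(duration_s = 10, seed = 7,
                             bout_schedule = data.frame(
                               behavior = "wing_extension",
                               start_s = 2, end_s = 4, wing = "both"))
  expect_identical(sim_courtship_pair(cp), sim_courtship_pair(cp))
  ca <- calcium_sim_params(noise_sd = 2, drift_slope = 0.01, seed = 7)
  expect_identical(sim_calcium(ca), sim_calcium(ca))
  eg <- egg_sim_params(seed = 7)
  expect_identical(sim_egg_counts(eg), sim_egg_counts(eg))
  cn <- connectome_sim_params(planted_fractions = c(a = 0.2), seed = 7)
  expect_identical(sim_connectome(cn), sim_connectome(cn))
  expect_identical(.Random.seed, before)
})

test_that("ground-truth labels mirror the bout schedule exactly", {
  p <- courtship_sim_params(
    duration_s = 20, seed = 3,
    bout_schedule = data.frame(behavior = "wing_extension",
                               start_s = 4, end_s = 8, wing = "left"))
  sim <- sim_courtship_pair(p)
  # frames 100..199 at 25 fps
  expect_identical(which(sim$labels$wing_extension) - 1L, 100:199)
  expect_false(any(sim$labels$approaching))
  expect_identical(as.character(sim$truth$wing_state[101:200]),
                   rep("unilateral_left", 100))
})

test_that("contradictory bout schedules are rejected", {
  bad <- data.frame(behavior = c("wing_extension", "wing_extension"),
                    start_s = c(1, 2), end_s = c(3, 4),
                    wing = c("left", "right"))
  expect_error(courtship_sim_params(duration_s = 10, bout_schedule = bad),
               "schedule conflict")
  expect_error(courtship_sim_params(
    duration_s = 10,
    bout_schedule = data.frame(behavior = "approaching",
                               start_s = 1, end_s = 20)),
    "start_s < end_s <= duration_s")
  expect_error(courtship_sim_params(wing_rest_level = 0.3),
               "unambiguous")
})

test_that("with no pursuit the male faces the female at chance", {
  fracs <- vapply(1:20, function(s) {
    p <- courtship_sim_params(duration_s = 60, pursuit_gain = 0, seed = s)
    sim <- sim_courtship_pair(p)
    fe <- pair_features(sim$poses)
    mean(fe$facing_angle < pi / 2, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.08)
})

test_that("flies stay inside the arena", {
  p <- courtship_sim_params(duration_s = 120, seed = 11, pursuit_gain = 0)
  sim <- sim_courtship_pair(p)
  r <- sqrt(sim$poses$x_mm^2 + sim$poses$y_mm^2)
  expect_true(all(r <= p$arena_diameter_mm / 2 + 1e-9))
})

test_that("null calcium parameters give a constant trace at f0", {
  cs <- sim_calcium(calcium_sim_params(amplitude = 0, noise_sd = 0,
                                       drift_slope = 0, f0 = 80))
  expect_equal(cs$trace$f, rep(80, nrow(cs$trace)))
})

test_that("stimulus onsets are spaced at the inter-stimulus interval", {
  cs <- sim_calcium(calcium_sim_params(n_stimuli = 4, isi_s = 20,
                                       first_onset_s = 10))
  expect_equal(cs$protocol$onsets_s, c(10, 30, 50, 70))
})

test_that("the calcium kernel peaks at exactly the planted amplitude", {
  # analytic peak: t* = tau_r * log((tau_r + tau_d) / tau_r)
  tr <- 0.8; td <- 2.5
  tstar <- tr * log((tr + td) / tr)
  expect_equal(calcium_kernel(tstar, tr, td), 1)
  expect_true(all(calcium_kernel(seq(0, 30, 0.01), tr, td) <= 1))
  cs <- sim_calcium(calcium_sim_params(amplitude = 0.5, noise_sd = 0,
                                       fps = 100))
  d <- dff(cs$trace$time_s, cs$trace$f, cs$protocol$onsets_s[1])
  expect_equal(max(d$dff), 0.5, tolerance = 0.01)
})

test_that("egg-count generator respects planted preference", {
  all_a <- sim_egg_counts(egg_sim_params(preference_p = 1, n_females = 20,
                                         seed = 5))
  idx <- oviposition_index(all_a$eggs_a, all_a$eggs_b)
  expect_true(all(idx[!is.na(idx)] == 1))
  big <- sim_egg_counts(egg_sim_params(preference_p = 0.5, n_females = 200,
                                       seed = 6))
  expect_lt(abs(mean(oviposition_index(big$eggs_a, big$eggs_b),
                     na.rm = TRUE)), 0.1)
  none <- sim_egg_counts(egg_sim_params(mean_total_eggs = 0, seed = 7))
  expect_true(all(none$eggs_a + none$eggs_b == 0))
})

test_that("connectome generator plants recoverable budget fractions", {
  cn <- sim_connectome(connectome_sim_params(
    planted_fractions = c("oviEN-like" = 0.155),
    total_input_synapses = 10000, seed = 8))
  b <- input_budget(cn$synapses, "1000")
  expect_lt(abs(b$fraction[b$partner == "oviEN-like"] - 0.155), 0.02)
  one <- sim_connectome(connectome_sim_params(
    planted_fractions = c(solo = 1), total_input_synapses = 500, seed = 9))
  b1 <- input_budget(one$synapses, "1000")
  expect_equal(b1$fraction, 1)
  expect_error(connectome_sim_params(planted_fractions = c(a = 0.7, b = 0.4)),
               "sum to at most 1")
})
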