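# Courtship classification rules, bouts and per-male summaries.

make_labels <- function(n, true_at = integer(0), behavior = "approaching",
                        cop_from = NA) {
  lab <- data.frame(frame = seq_len(n) - 1L, fly = "male",
                    approaching = FALSE, facing = FALSE, contact = FALSE,
                    circling = FALSE, turning = FALSE,
                    wing_extension = FALSE, copulation = FALSE)
  lab[[behavior]][true_at + 1L] <- TRUE
  if (!is.na(cop_from)) lab$copulation[lab$frame >= cop_from] <- TRUE
  lab
}

test_that("copulation masking truncates at onset and is idempotent", {
  lab <- make_labels(1000, cop_from = 500)
  m <- mask_copulation(lab)
  expect_equal(nrow(m), 500)
  expect_equal(attr(m, "copulation_frame"), 500L)
  expect_equal(nrow(mask_copulation(m)), 500)
  no_cop <- make_labels(100)
  expect_equal(nrow(mask_copulation(no_cop)), 100)
  expect_true(is.na(attr(mask_copulation(no_cop), "copulation_frame")))
})

test_that("initiation rule matches its brute-force window scan", {
  fps <- 25
  # 75 consecutive positives starting at frame 100 -> initiation at 100
  lab <- make_labels(1000, true_at = 100:174)
  expect_identical(detect_initiation(lab, fps), 100L)
  expect_identical(brute_initiation(lab$approaching, fps), 100L)
  # 74 positives max in any 150-frame window -> no initiation
  lab74 <- make_labels(1000, true_at = 100:173)
  expect_true(is.na(detect_initiation(lab74, fps)))
  expect_true(is.na(brute_initiation(lab74$approaching, fps)))
  # all-false labels
  expect_true(is.na(detect_initiation(make_labels(500), fps)))
  # facing alone cannot initiate
  labf <- make_labels(1000, true_at = 100:300, behavior = "facing")
  expect_true(is.na(detect_initiation(labf, fps)))
  # random series against the oracle
  set.seed(10)
  for (i in 1:25) {
    x <- runif(2000) < runif(1, 0.1, 0.6)
    lab <- make_labels(2000, true_at = which(x) - 1L)
    expect_identical(detect_initiation(lab, fps),
                     brute_initiation(x, fps))
  }
})

test_that("short recordings are evaluated on available frames with a flag", {
  lab <- make_labels(100, true_at = 10:90)
  expect_warning(init <- detect_initiation(lab, 25),
                 "shorter than one initiation window")
  expect_identical(init, 10L)
})

test_that("wing-state rules reproduce the hand-derived cases", {
  # both wings at 0.30: bilateral only
  ws <- classify_wing_states(feature_row(0.30, 0.30))
  expect_true(ws$bilateral); expect_false(ws$unilateral)
  # (0.70, 0.10), female left, extended wing is the left one: ipsilateral
  ws <- classify_wing_states(feature_row(0.70, 0.10, "left"))
  expect_true(ws$unilateral); expect_true(ws$ipsilateral)
  expect_false(ws$contralateral)
  # same wings, female right: crossed -> contralateral
  ws <- classify_wing_states(feature_row(0.70, 0.10, "right"))
  expect_true(ws$unilateral); expect_true(ws$contralateral)
  expect_false(ws$ipsilateral)
  # thresholds are strict: exactly at threshold is not extension
  ws <- classify_wing_states(feature_row(0.26, 0.26))
  expect_false(ws$bilateral)
  ws <- classify_wing_states(feature_row(0.61, 0.10))
  expect_false(ws$unilateral)
  # on-axis female: neither ipsi nor contra
  ws <- classify_wing_states(feature_row(0.70, 0.10, "on-axis"))
  expect_false(ws$ipsilateral); expect_false(ws$contralateral)
  # missing wing: all four flags missing
  ws <- classify_wing_states(feature_row(NA, 0.70))
  expect_true(all(is.na(ws)))
})

test_that("bilateral and unilateral are mutually exclusive everywhere", {
  grid <- expand.grid(wl = seq(0, 1, 0.05), wr = seq(0, 1, 0.05))
  ws <- classify_wing_states(feature_row(grid$wl, grid$wr))
  expect_false(any(ws$bilateral & ws$unilateral))
})

test_that("bout extraction is an exact run-length round trip", {
  b <- bouts_from_series(c(F, F, T, T, T, F, F), fps = 25)
  expect_equal(b$start_frame, 2)
  expect_equal(b$end_frame, 5)
  expect_equal(b$duration_s, 3 / 25)
  expect_equal(nrow(bouts_from_series(rep(FALSE, 10), 25)), 0)
  # NA breaks a run
  b2 <- bouts_from_series(c(T, T, NA, T), fps = 1)
  expect_equal(nrow(b2), 2)
  # round trip on random series
  set.seed(20)
  for (i in 1:10) {
    x <- runif(500) < 0.3
    b <- bouts_from_series(x, fps = 25)
    rec <- rep(FALSE, 500)
    for (j in seq_len(nrow(b))) {
      rec[(b$start_frame[j] + 1):(b$end_frame[j])] <- TRUE
    }
    expect_identical(rec, x)
  }
})

test_that("wing choice index follows its formula and bounds", {
  expect_equal(wing_choice_index(30, 10), 0.5)
  expect_equal(wing_choice_index(0, 10), -1)
  expect_true(is.na(wing_choice_index(0, 0)))
})

test_that("courtship summary recovers schedule-planted quantities", {
  fps <- 25
  sched <- make_recovery_schedule(duration_s = 40)
  p <- courtship_sim_params(duration_s = 40, bout_schedule = sched,
                            seed = 31)
  sim <- sim_courtship_pair(p)
  fe <- pair_features(sim$poses)
  s <- courtship_summary(fe, sim$labels, fps)
  n_frames <- 40 * fps
  init <- round(sched$start_s[1] * fps)
  expect_equal(s$latency_to_court_min, init / fps / 60)
  # planted courtship index: scheduled frames / courtship-period frames
  court_frames <- n_frames - init
  on_frames <- length(schedule_frames(sched, fps, n_frames))
  expect_equal(s$courtship_index_pct, 100 * on_frames / court_frames,
               tolerance = 1e-10)
  # planted bilateral bouts: one "both" bout scheduled -> rate bouts/min
  n_both <- sum(sched$wing == "both", na.rm = TRUE)
  expect_equal(s$bilateral_bout_rate, n_both / (court_frames / fps / 60))
  expect_false(s$copulated)
})

test_that("six bilateral bouts over a two-minute courtship give rate 3/min", {
  fps <- 25
  starts <- 2 + (0:5) * 10
  sched <- data.frame(behavior = "wing_extension", start_s = starts,
                      end_s = starts + 5, wing = "both")
  p <- courtship_sim_params(duration_s = 122, bout_schedule = sched,
                            seed = 32, wing_noise_sd = 0)
  sim <- sim_courtship_pair(p)
  fe <- pair_features(sim$poses)
  s <- courtship_summary(fe, sim$labels, fps)
  # initiation at frame 50 -> courtship period 120 s
  expect_equal(s$latency_to_court_min, 2 / 60)
  expect_equal(s$bilateral_bout_rate, 3)
  expect_equal(s$bilateral_bout_len_s, 5)
})

test_that("non-initiating males are flagged with missing metrics", {
  p <- courtship_sim_params(duration_s = 20, seed = 33)  # empty schedule
  sim <- sim_courtship_pair(p)
  fe <- pair_features(sim$poses)
  s <- courtship_summary(fe, sim$labels, 25)
  expect_false(s$initiated)
  expect_true(is.na(s$courtship_index_pct))
  expect_true(is.na(s$latency_to_court_min))
})

test_that("copulation truncates the courtship period and is reported", {
  fps <- 25
  sched <- data.frame(behavior = "approaching", start_s = 1, end_s = 8)
  p <- courtship_sim_params(duration_s = 30, bout_schedule = sched,
                            copulation_start_s = 15, seed = 34)
  sim <- sim_courtship_pair(p)
  fe <- pair_features(sim$poses)
  s <- courtship_summary(fe, sim$labels, fps)
  expect_true(s$copulated)
  expect_equal(s$copulation_latency_min, 15 / 60)
  # index denominators stop at copulation: frames 25..374
  expect_equal(s$courtship_index_pct, 100 * (7 * fps) / (14 * fps))
})

test_that("position heatmap conserves counts and mirrors with the wings", {
  fe <- data.frame(rel_x = c(rep(2.5, 5), 12), rel_y = c(rep(0.5, 5), 0))
  hm <- relative_position_heatmap(fe, flag = rep(TRUE, 6),
                                  xlim = c(-10, 10), ylim = c(-10, 10),
                                  bin_mm = 1)
  expect_equal(sum(hm$counts), 5)       # one out-of-range point
  expect_equal(hm$overflow, 1)
  expect_equal(hm$n_flagged, 6)
  expect_equal(max(hm$counts), 5)       # all five in a single cell
  expect_equal(hm$counts[13, 11], 5L)   # cell [2,3) x [0,1)
  # empty flag set: all-zero grid
  hm0 <- relative_position_heatmap(fe, flag = rep(FALSE, 6))
  expect_true(all(hm0$counts == 0))
  # mirroring rel_y together with swapping wings leaves the grid mirrored
  set.seed(40)
  fe2 <- data.frame(rel_x = runif(300, -9, 9), rel_y = runif(300, -9, 9))
  flag <- runif(300) < 0.5
  h1 <- relative_position_heatmap(fe2, flag)
  fe2m <- fe2; fe2m$rel_y <- -fe2m$rel_y
  h2 <- relative_position_heatmap(fe2m, flag)
  expect_equal(h2$counts, h1$counts[, ncol(h1$counts):1])
})
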