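# Shared fixture builders. Everything is generated in code; no files.

# A non-overlapping bout schedule: one long approaching bout (so the
# initiation rule fires at its first frame) followed by wing-extension
# bouts of known wing assignment separated by gaps.
make_recovery_schedule <- function(duration_s,
                                   first_start_s = 4,
                                   approach_len_s = 4,
                                   n_wing_bouts = 4,
                                   bout_len_s = 2,
                                   gap_s = 1.5) {
  wings <- rep(c("both", "left", "right"), length.out = n_wing_bouts)
  wing_starts <- first_start_s + approach_len_s + gap_s +
    (seq_len(n_wing_bouts) - 1) * (bout_len_s + gap_s)
  sched <- data.frame(
    behavior = c("approaching", rep("wing_extension", n_wing_bouts)),
    start_s = c(first_start_s, wing_starts),
    end_s = c(first_start_s + approach_len_s, wing_starts + bout_len_s),
    wing = c(NA, wings))
  stopifnot(max(sched$end_s) <= duration_s)
  sched
}

# Frames (0-based) covered by a schedule row at a given fps.
schedule_frames <- function(sched, fps, n_frames) {
  unique(sort(unlist(lapply(seq_len(nrow(sched)), function(i) {
    f0 <- max(0L, round(sched$start_s[i] * fps))
    f1 <- min(n_frames, round(sched$end_s[i] * fps))
    if (f1 <= f0) integer(0) else seq.int(f0, f1 - 1L)
  }))))
}

# Brute-force initiation oracle: every window sum evaluated explicitly
# (embed builds the full n x w window matrix), then the first positive
# frame inside the earliest qualifying window. Independent of the cumsum
# path in detect_initiation().
brute_initiation <- function(x, fps, window_s = 6, required_s = 3) {
  n <- length(x)
  w <- round(window_s * fps)
  need <- round(required_s * fps)
  if (n < w) w <- n
  # embed row i holds x[i .. i+w-1] (reversed); rowSums = window sums
  sums <- rowSums(stats::embed(as.numeric(x), w))
  starts <- seq_len(n - w + 1L)
  hit <- which(sums >= need)[1]
  if (is.na(hit)) return(NA_integer_)
  win <- seq.int(starts[hit], starts[hit] + w - 1L)
  win[which(x[win])[1]] - 1L  # 0-based frame
}

# Exhaustive truth-table oracle for the wing-state rules, written as
# literal per-case logic (independent of the vectorized implementation).
oracle_wing_state <- function(wl, wr, side, bmin = 0.26, umax = 0.61) {
  mn <- min(wl, wr); mx <- max(wl, wr)
  bilateral <- mn > bmin
  unilateral <- (mx > umax) && (mn < bmin)
  ipsi <- FALSE; contra <- FALSE
  if (side == "left") {
    if (wl > umax) ipsi <- TRUE
    if (wr > umax) contra <- TRUE
  } else if (side == "right") {
    if (wr > umax) ipsi <- TRUE
    if (wl > umax) contra <- TRUE
  }
  c(bilateral = bilateral, unilateral = unilateral,
    ipsilateral = ipsi, contralateral = contra)
}

# Feature-table row builder for classifier tests.
feature_row <- function(wing_l, wing_r, side = "left") {
  data.frame(wing_l = wing_l, wing_r = wing_r,
             min_wing_ang = pmin(wing_l, wing_r),
             max_wing_ang = pmax(wing_l, wing_r),
             other_side = side)
}
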