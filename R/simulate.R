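# Synthetic-data generators with planted ground truth.
#
# Every generator takes a parameter object built by a `*_sim_params()`
# constructor and draws all randomness under the seed stored in that object
# (via withr::with_seed, so the caller's RNG state is untouched). Identical
# parameter objects therefore give byte-identical output.

courtship_behaviors <- c("approaching", "facing", "contact", "circling",
                         "turning", "wing_extension")

#' Parameters for the two-fly courtship simulator
#'
#' Builds and validates the parameter set consumed by
#' [sim_courtship_pair()]. Defaults mirror the standard assay: 25 frames/s
#' video of a 20 mm diameter circular chamber. Wing-angle levels are chosen
#' so that the planted rest / extended states sit far outside the 0.26 and
#' 0.61 rad classification thresholds (rest < 0.26 < 0.61 < extended), which
#' makes planted wing states unambiguous at the default noise level.
#'
#' @param fps Video frame rate, frames/s.
#' @param duration_s Assay duration, s.
#' @param arena_diameter_mm Circular arena diameter, mm.
#' @param bout_schedule `data.frame` with columns `behavior` (one of
#'   approaching, facing, contact, circling, turning, wing_extension),
#'   `start_s`, `end_s` (half-open interval, s) and optionally `wing`
#'   ("left", "right" or "both"; only used for wing_extension bouts,
#'   default "left"). All bouts belong to the focal male.
#' @param wing_noise_sd Gaussian per-frame wing-angle noise, rad.
#' @param wing_rest_level,wing_extended_level Mean wing angle at rest and
#'   during extension, rad. Must satisfy
#'   `wing_rest_level < 0.26 < 0.61 < wing_extended_level`.
#' @param pursuit_gain Proportional heading-steering gain toward the female
#'   during scheduled bouts, 1/s. 0 disables pursuit.
#' @param heading_noise_sd Per-frame heading random-walk SD, rad.
#' @param speed_mm_s,female_speed_mm_s Forward walking speeds, mm/s.
#' @param copulation_start_s Onset of the single terminal copulation bout,
#'   s, or `NULL` for a pair that never copulates.
#' @param seed Integer RNG seed.
#' @return A validated list of class `"courtship_sim_params"`.
#' @export
courtship_sim_params <- function(fps = 25, duration_s = 60,
                                 arena_diameter_mm = 20,
                                 bout_schedule = NULL,
                                 wing_noise_sd = 0.03,
                                 wing_rest_level = 0.08,
                                 wing_extended_level = 0.80,
                                 pursuit_gain = 5,
                                 heading_noise_sd = 0.2,
                                 speed_mm_s = 5,
                                 female_speed_mm_s = 3,
                                 copulation_start_s = NULL,
                                 seed = 1L) {
  check_scalar(fps, "fps", lower = 1e-9)
  check_scalar(duration_s, "duration_s", lower = 1e-9)
  check_scalar(arena_diameter_mm, "arena_diameter_mm", lower = 4)
  check_scalar(wing_noise_sd, "wing_noise_sd", lower = 0)
  check_scalar(wing_rest_level, "wing_rest_level", lower = 0)
  check_scalar(wing_extended_level, "wing_extended_level", lower = 0)
  check_scalar(pursuit_gain, "pursuit_gain", lower = 0)
  check_scalar(heading_noise_sd, "heading_noise_sd", lower = 0)
  check_scalar(speed_mm_s, "speed_mm_s", lower = 0)
  check_scalar(female_speed_mm_s, "female_speed_mm_s", lower = 0)
  check_scalar(copulation_start_s, "copulation_start_s", lower = 0,
               allow_null = TRUE)
  check_scalar(seed, "seed")
  if (!(wing_rest_level < 0.26 && wing_extended_level > 0.61)) {
    stop("planted wing levels must satisfy wing_rest_level < 0.26 < 0.61 < ",
         "wing_extended_level so planted states are unambiguous",
         call. = FALSE)
  }
  if (is.null(bout_schedule)) {
    bout_schedule <- data.frame(behavior = character(0), start_s = numeric(0),
                                end_s = numeric(0), wing = character(0))
  }
  check_columns(bout_schedule, c("behavior", "start_s", "end_s"),
                "bout_schedule")
  if (is.null(bout_schedule$wing)) bout_schedule$wing <- "left"
  bout_schedule$wing[is.na(bout_schedule$wing)] <- "left"
  if (nrow(bout_schedule) > 0L) {
    bad <- !bout_schedule$behavior %in% courtship_behaviors
    if (any(bad)) {
      stop("unknown behavior(s) in bout_schedule: ",
           paste(unique(bout_schedule$behavior[bad]), collapse = ", "),
           call. = FALSE)
    }
    if (any(!bout_schedule$wing %in% c("left", "right", "both"))) {
      stop("bout_schedule$wing must be 'left', 'right' or 'both'",
           call. = FALSE)
    }
    if (any(bout_schedule$start_s < 0 | bout_schedule$end_s > duration_s |
            bout_schedule$end_s <= bout_schedule$start_s)) {
      stop("bouts must satisfy 0 <= start_s < end_s <= duration_s",
           call. = FALSE)
    }
    .check_schedule_conflicts(bout_schedule)
  }
  structure(list(fps = fps, duration_s = duration_s,
                 arena_diameter_mm = arena_diameter_mm,
                 bout_schedule = bout_schedule,
                 wing_noise_sd = wing_noise_sd,
                 wing_rest_level = wing_rest_level,
                 wing_extended_level = wing_extended_level,
                 pursuit_gain = pursuit_gain,
                 heading_noise_sd = heading_noise_sd,
                 speed_mm_s = speed_mm_s,
                 female_speed_mm_s = female_speed_mm_s,
                 copulation_start_s = copulation_start_s,
                 seed = as.integer(seed)),
            class = "courtship_sim_params")
}

# Overlapping bouts of the same behavior, or overlapping wing_extension
# bouts with different wing assignments, are contradictory.
.check_schedule_conflicts <- function(sched) {
  for (b in unique(sched$behavior)) {
    s <- sched[sched$behavior == b, , drop = FALSE]
    s <- s[order(s$start_s), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start_s[-1L] < s$end_s[-nrow(s)])) {
      stop(sprintf("schedule conflict: overlapping '%s' bouts", b),
           call. = FALSE)
    }
  }
  invisible(NULL)
}

# One confined step: advance from (x, y) by speed*dt along heading th;
# a step crossing the arena wall is reflected specularly (position folded
# across the wall normal, heading reflected), which preserves the uniform
# position x heading invariant measure of the confined walk.
.step_in_arena <- function(x, y, th, speed, dt, r_max) {
  nx <- x + speed * dt * cos(th)
  ny <- y + speed * dt * sin(th)
  r <- sqrt(nx^2 + ny^2)
  if (r > r_max) {
    ux <- nx / r
    uy <- ny / r
    nx <- nx - 2 * (r - r_max) * ux
    ny <- ny - 2 * (r - r_max) * uy
    vx <- cos(th); vy <- sin(th)
    dot <- vx * ux + vy * uy
    th <- atan2(vy - 2 * dot * uy, vx - 2 * dot * ux)
    # a long step can still land outside for extreme geometries; clamp
    r2 <- sqrt(nx^2 + ny^2)
    if (r2 > r_max) {
      nx <- nx * r_max / r2
      ny <- ny * r_max / r2
    }
  }
  c(nx, ny, th)
}

# Frames covered by a [start_s, end_s) bout at a given frame rate (0-based).
bout_frames <- function(start_s, end_s, fps, n_frames) {
  f0 <- round(start_s * fps)
  f1 <- round(end_s * fps)  # exclusive
  f0 <- max(0L, f0)
  f1 <- min(n_frames, f1)
  if (f1 <= f0) return(integer(0))
  seq.int(f0, f1 - 1L)
}

#' Simulate a two-fly courtship assay with planted ground truth
#'
#' Generates per-frame pose tables for a male/female pair plus the
#' ground-truth behavior-label table the schedule implies. The male's
#' heading follows a wrapped random walk, steered proportionally toward the
#' female during scheduled courtship bouts; both flies walk forward at
#' constant speed and are confined to the arena (a step that would leave
#' the arena is simply not taken, so heading statistics stay independent of
#' position). Wing angles sit at the rest level except during scheduled
#' wing-extension bouts, when the scheduled wing (or both) is raised to the
#' extended level; Gaussian noise is added throughout and angles are
#' clamped at 0. An optional single terminal copulation interval freezes
#' the pair in contact.
#'
#' @param params A [courtship_sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{poses}{`data.frame(frame, fly, x_mm, y_mm, theta_rad,
#'       wing_l_rad, wing_r_rad)`, one row per (frame, fly),
#'       `fly` in `{"male","female"}`.}
#'     \item{labels}{`data.frame(frame, fly, approaching, facing, contact,
#'       circling, turning, wing_extension, copulation)` for the male.}
#'     \item{truth}{list with `wing_state` (factor per frame:
#'       none/unilateral_left/unilateral_right/bilateral),
#'       `copulation_frame` (or `NA`) and the schedule.}
#'   }
#' @export
sim_courtship_pair <- function(params) {
  stopifnot(inherits(params, "courtship_sim_params"))
  withr::with_seed(params$seed, .sim_courtship_impl(params))
}

.sim_courtship_impl <- function(p) {
  n <- round(p$duration_s * p$fps)
  dt <- 1 / p$fps
  r_max <- p$arena_diameter_mm / 2 - 1  # keep centroids 1 mm off the wall

  # Ground-truth label matrix from the schedule.
  lab <- matrix(FALSE, nrow = n, ncol = length(courtship_behaviors),
                dimnames = list(NULL, courtship_behaviors))
  wing_state <- rep("none", n)
  sched <- p$bout_schedule
  for (i in seq_len(nrow(sched))) {
    fr <- bout_frames(sched$start_s[i], sched$end_s[i], p$fps, n)
    lab[fr + 1L, sched$behavior[i]] <- TRUE
    if (sched$behavior[i] == "wing_extension") {
      wing_state[fr + 1L] <- switch(sched$wing[i],
                                    left = "unilateral_left",
                                    right = "unilateral_right",
                                    both = "bilateral")
    }
  }
  cop_frame <- if (is.null(p$copulation_start_s)) NA_integer_ else
    min(n, round(p$copulation_start_s * p$fps))
  copulation <- if (is.na(cop_frame)) rep(FALSE, n) else
    seq_len(n) - 1L >= cop_frame
  active <- rowSums(lab) > 0 & !copulation

  # Trajectories. Heading noise is generated up front; the per-frame loop
  # only integrates positions and the pursuit term.
  noise_m <- stats::rnorm(n, 0, p$heading_noise_sd)
  noise_f <- stats::rnorm(n, 0, p$heading_noise_sd)
  mx <- my <- fx <- fy <- th_m <- th_f <- numeric(n)
  mx[1] <- -r_max / 2; my[1] <- 0; th_m[1] <- 0
  fx[1] <- r_max / 2; fy[1] <- 0; th_f[1] <- pi
  for (t in 2:n) {
    if (!is.na(cop_frame) && t - 1L >= cop_frame) {
      # Terminal copulation: pair frozen, male mounted just behind female.
      fx[t] <- fx[t - 1]; fy[t] <- fy[t - 1]; th_f[t] <- th_f[t - 1]
      th_m[t] <- th_f[t]
      mx[t] <- fx[t] - cos(th_f[t]); my[t] <- fy[t] - sin(th_f[t])
      next
    }
    sf <- .step_in_arena(fx[t - 1], fy[t - 1],
                         wrap_angle(th_f[t - 1] + noise_f[t]),
                         p$female_speed_mm_s, dt, r_max)
    fx[t] <- sf[1]; fy[t] <- sf[2]; th_f[t] <- sf[3]
    steer <- 0
    if (active[t] && p$pursuit_gain > 0) {
      bearing <- atan2(fy[t - 1] - my[t - 1], fx[t - 1] - mx[t - 1])
      steer <- p$pursuit_gain * wrap_angle(bearing - th_m[t - 1]) * dt
    }
    sm <- .step_in_arena(mx[t - 1], my[t - 1],
                         wrap_angle(th_m[t - 1] + steer + noise_m[t]),
                         p$speed_mm_s, dt, r_max)
    mx[t] <- sm[1]; my[t] <- sm[2]; th_m[t] <- sm[3]
  }

  # Wing angles around the planted levels.
  base_l <- ifelse(wing_state %in% c("unilateral_left", "bilateral"),
                   p$wing_extended_level, p$wing_rest_level)
  base_r <- ifelse(wing_state %in% c("unilateral_right", "bilateral"),
                   p$wing_extended_level, p$wing_rest_level)
  wl_m <- pmax(0, base_l + stats::rnorm(n, 0, p$wing_noise_sd))
  wr_m <- pmax(0, base_r + stats::rnorm(n, 0, p$wing_noise_sd))
  wl_f <- pmax(0, p$wing_rest_level + stats::rnorm(n, 0, p$wing_noise_sd))
  wr_f <- pmax(0, p$wing_rest_level + stats::rnorm(n, 0, p$wing_noise_sd))

  frame <- seq_len(n) - 1L
  poses <- data.frame(
    frame = c(frame, frame),
    fly = rep(c("male", "female"), each = n),
    x_mm = c(mx, fx), y_mm = c(my, fy),
    theta_rad = wrap_angle(c(th_m, th_f)),
    wing_l_rad = c(wl_m, wl_f), wing_r_rad = c(wr_m, wr_f))
  poses <- poses[order(poses$frame, poses$fly != "male"), ]
  rownames(poses) <- NULL

  labels <- data.frame(frame = frame, fly = "male", as.data.frame(lab),
                       copulation = copulation)
  list(poses = poses, labels = labels,
       truth = list(wing_state = factor(wing_state,
                      levels = c("none", "unilateral_left",
                                 "unilateral_right", "bilateral")),
                    copulation_frame = cop_frame,
                    schedule = sched))
}

#' Parameters for the calcium-trace simulator
#'
#' Defaults mirror the imaging protocol: 5.92 frames/s acquisition, four
#' optogenetic stimuli per fly at a 20 s inter-stimulus interval, 5 s
#' stimulus duration. The response kernel is a difference-of-exponentials
#' `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)` normalized to unit peak,
#' a standard GCaMP-like shape, so `amplitude` is the planted peak dF/F.
#'
#' @param fps Acquisition rate, frames/s.
#' @param n_stimuli Number of stimuli.
#' @param isi_s Inter-stimulus (onset-to-onset) interval, s.
#' @param stim_duration_s Stimulus duration, s.
#' @param amplitude Planted peak response, dF/F units.
#' @param tau_rise_s,tau_decay_s Kernel time constants, s.
#' @param noise_sd Gaussian noise SD, raw fluorescence units.
#' @param drift_slope Slow linear baseline drift, fluorescence units/s.
#' @param f0 Baseline fluorescence (arbitrary units, > 0).
#' @param first_onset_s Time of the first stimulus onset, s. The default
#'   (10 s) leaves a full 10 s pre-onset baseline window.
#' @param seed Integer RNG seed.
#' @return A validated list of class `"calcium_sim_params"`.
#' @export
calcium_sim_params <- function(fps = 5.92, n_stimuli = 4, isi_s = 20,
                               stim_duration_s = 5, amplitude = 0.5,
                               tau_rise_s = 0.8, tau_decay_s = 2.5,
                               noise_sd = 0, drift_slope = 0, f0 = 100,
                               first_onset_s = 10, seed = 1L) {
  check_scalar(fps, "fps", lower = 1e-9)
  check_scalar(n_stimuli, "n_stimuli", lower = 1)
  check_scalar(isi_s, "isi_s", lower = 1e-9)
  check_scalar(stim_duration_s, "stim_duration_s", lower = 1e-9)
  check_scalar(amplitude, "amplitude")
  check_scalar(tau_rise_s, "tau_rise_s", lower = 1e-9)
  check_scalar(tau_decay_s, "tau_decay_s", lower = 1e-9)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(drift_slope, "drift_slope")
  check_scalar(f0, "f0", lower = 1e-9)
  check_scalar(first_onset_s, "first_onset_s", lower = 0)
  check_scalar(seed, "seed")
  structure(list(fps = fps, n_stimuli = as.integer(n_stimuli), isi_s = isi_s,
                 stim_duration_s = stim_duration_s, amplitude = amplitude,
                 tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
                 noise_sd = noise_sd, drift_slope = drift_slope, f0 = f0,
                 first_onset_s = first_onset_s, seed = as.integer(seed)),
            class = "calcium_sim_params")
}

#' Difference-of-exponentials calcium response kernel (unit peak)
#'
#' `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)` for `t >= 0`, zero before,
#' scaled so its maximum is exactly 1. The analytic peak time is
#' `tau_rise * log((tau_rise + tau_decay) / tau_rise)`.
#'
#' @param t Time since stimulus onset, s (vectorized).
#' @param tau_rise_s,tau_decay_s Time constants, s.
#' @return Kernel values in `[0, 1]`.
#' @export
calcium_kernel <- function(t, tau_rise_s, tau_decay_s) {
  k <- ifelse(t < 0, 0, (1 - exp(-t / tau_rise_s)) * exp(-t / tau_decay_s))
  t_peak <- tau_rise_s * log((tau_rise_s + tau_decay_s) / tau_rise_s)
  k_peak <- (1 - exp(-t_peak / tau_rise_s)) * exp(-t_peak / tau_decay_s)
  k / k_peak
}

#' Simulate a stimulus-locked fluorescence recording
#'
#' `F(t) = f0 + drift_slope * t + amplitude * f0 * sum_i kernel(t - onset_i)
#' + noise`. Stimulus onsets are evenly spaced at `isi_s` starting at
#' `first_onset_s`; the recording extends one full inter-stimulus interval
#' past the last onset so every epoch is analyzable.
#'
#' @param params A [calcium_sim_params()] object.
#' @return A list with `trace` (`data.frame(time_s, f)`), `protocol`
#'   (onsets_s, duration_s, pulse_rate_hz, pulse_ms, isi_s) and
#'   `true_amplitude` (the planted peak dF/F).
#' @export
sim_calcium <- function(params) {
  stopifnot(inherits(params, "calcium_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    onsets <- p$first_onset_s + p$isi_s * (seq_len(p$n_stimuli) - 1L)
    duration <- onsets[length(onsets)] + p$isi_s
    time_s <- seq(0, duration, by = 1 / p$fps)
    resp <- rowSums(vapply(onsets, function(o) {
      calcium_kernel(time_s - o, p$tau_rise_s, p$tau_decay_s)
    }, numeric(length(time_s))))
    f <- p$f0 + p$drift_slope * time_s + p$amplitude * p$f0 * resp +
      stats::rnorm(length(time_s), 0, p$noise_sd)
    list(trace = data.frame(time_s = time_s, f = f),
         protocol = list(onsets_s = onsets, duration_s = p$stim_duration_s,
                         pulse_rate_hz = 40, pulse_ms = 10, isi_s = p$isi_s),
         true_amplitude = p$amplitude)
  })
}

#' Parameters for the two-choice egg-count simulator
#'
#' @param n_females Number of females.
#' @param mean_total_eggs Mean total eggs per female (negative-binomial
#'   mean).
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param preference_p Probability that any given egg is laid on side A
#'   (the pheromone side).
#' @param genotype Genotype label for the generated females.
#' @param seed Integer RNG seed.
#' @return A validated list of class `"egg_sim_params"`.
#' @export
egg_sim_params <- function(n_females = 25, mean_total_eggs = 30,
                           dispersion = 5, preference_p = 0.5,
                           genotype = "g1", seed = 1L) {
  check_scalar(n_females, "n_females", lower = 1)
  check_scalar(mean_total_eggs, "mean_total_eggs", lower = 0)
  check_scalar(dispersion, "dispersion", lower = 1e-9)
  check_scalar(preference_p, "preference_p", lower = 0, upper = 1)
  check_scalar(seed, "seed")
  structure(list(n_females = as.integer(n_females),
                 mean_total_eggs = mean_total_eggs, dispersion = dispersion,
                 preference_p = preference_p,
                 genotype = as.character(genotype),
                 seed = as.integer(seed)),
            class = "egg_sim_params")
}

#' Simulate a two-choice oviposition assay
#'
#' Per female, total eggs are negative binomial
#' (`mu = mean_total_eggs`, `size = dispersion`) and the side-A count is
#' binomial(total, `preference_p`).
#'
#' @param params An [egg_sim_params()] object.
#' @return `data.frame(genotype, female_id, eggs_a, eggs_b)`.
#' @export
sim_egg_counts <- function(params) {
  stopifnot(inherits(params, "egg_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    total <- stats::rnbinom(p$n_females, size = p$dispersion,
                            mu = p$mean_total_eggs)
    eggs_a <- stats::rbinom(p$n_females, size = total, prob = p$preference_p)
    data.frame(genotype = p$genotype,
               female_id = sprintf("%s_%03d", p$genotype,
                                   seq_len(p$n_females)),
               eggs_a = eggs_a, eggs_b = total - eggs_a)
  })
}

#' Parameters for the synthetic connectome generator
#'
#' @param planted_fractions Named numeric vector: the expected fraction of
#'   the target's input budget contributed by each named partner. Must sum
#'   to at most 1; the remainder is spread over `n_background` anonymous
#'   background partners.
#' @param compartment_mix Named numeric vector (same names): fraction of
#'   each partner's synapses landing on the target's dendrite (the rest
#'   land on the axon). Defaults to 0.8 dendritic for every partner.
#' @param total_input_synapses Total input synapse count drawn for the
#'   target.
#' @param n_background Number of background partners sharing the remainder.
#' @param target_id Body id of the postsynaptic target.
#' @param seed Integer RNG seed.
#' @return A validated list of class `"connectome_sim_params"`.
#' @export
connectome_sim_params <- function(planted_fractions,
                                  compartment_mix = NULL,
                                  total_input_synapses = 10000,
                                  n_background = 20,
                                  target_id = "1000",
                                  seed = 1L) {
  if (is.null(names(planted_fractions)) ||
      any(!nzchar(names(planted_fractions)))) {
    stop("planted_fractions must be a named vector", call. = FALSE)
  }
  if (any(planted_fractions < 0) || sum(planted_fractions) > 1 + 1e-12) {
    stop("planted_fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  if (is.null(compartment_mix)) {
    compartment_mix <- stats::setNames(rep(0.8, length(planted_fractions)),
                                       names(planted_fractions))
  }
  if (!setequal(names(compartment_mix), names(planted_fractions)) ||
      any(compartment_mix < 0 | compartment_mix > 1)) {
    stop("compartment_mix must give a dendritic fraction in [0, 1] for ",
         "every planted partner", call. = FALSE)
  }
  compartment_mix <- compartment_mix[names(planted_fractions)]
  check_scalar(total_input_synapses, "total_input_synapses", lower = 1)
  check_scalar(n_background, "n_background", lower = 0)
  check_scalar(seed, "seed")
  structure(list(planted_fractions = planted_fractions,
                 compartment_mix = compartment_mix,
                 total_input_synapses = as.integer(total_input_synapses),
                 n_background = as.integer(n_background),
                 target_id = as.character(target_id),
                 seed = as.integer(seed)),
            class = "connectome_sim_params")
}

#' Simulate a synapse table with planted input-budget fractions
#'
#' Draws the target's `total_input_synapses` input synapses from a
#' multinomial over planted partners plus background partners, then splits
#' each partner's synapses between the target's dendritic and axonal
#' compartments according to `compartment_mix` (background partners use the
#' mean planted mix, or 0.8 if none). Presynaptic compartments are tagged
#' axonal (synapses leave via axons).
#'
#' @param params A [connectome_sim_params()] object.
#' @return A list with `synapses` (`data.frame(bodyid_pre, bodyid_post,
#'   compartment_pre, compartment_post, neuropil, weight)`), `meta`
#'   (`data.frame(bodyid, type_label, cluster)`) and `truth` (the planted
#'   fractions and compartment mix).
#' @export
sim_connectome <- function(params) {
  stopifnot(inherits(params, "connectome_sim_params"))
  p <- params
  withr::with_seed(p$seed, {
    planted <- p$planted_fractions
    rem <- max(0, 1 - sum(planted))
    nb <- if (rem > 0) p$n_background else 0L
    probs <- c(planted,
               if (nb > 0) stats::setNames(rep(rem / nb, nb),
                                           sprintf("bg_%03d", seq_len(nb))))
    counts <- as.integer(stats::rmultinom(1, p$total_input_synapses, probs))
    names(counts) <- names(probs)
    dmix <- c(p$compartment_mix,
              if (nb > 0) stats::setNames(
                rep(if (length(p$compartment_mix)) mean(p$compartment_mix)
                    else 0.8, nb),
                sprintf("bg_%03d", seq_len(nb))))
    dend <- stats::rbinom(length(counts), counts, dmix[names(counts)])
    axon <- counts - dend
    rows <- data.frame(bodyid_pre = rep(names(counts), 2L),
                       bodyid_post = p$target_id,
                       compartment_pre = "axon",
                       compartment_post = rep(c("dendrite", "axon"),
                                              each = length(counts)),
                       neuropil = "SMP",
                       weight = c(dend, axon))
    rows <- rows[rows$weight > 0, , drop = FALSE]
    rownames(rows) <- NULL
    meta <- data.frame(bodyid = c(p$target_id, names(counts)),
                       type_label = c("target", names(counts)),
                       cluster = c("target", names(counts)))
    list(synapses = rows, meta = meta,
         truth = list(fractions = planted, compartment_mix = p$compartment_mix,
                      total = p$total_input_synapses))
  })
}
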