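# Rule-based courtship classification and per-male summary statistics.

#' Drop all frames at or after copulation onset
#'
#' Copulating frames carry no courtship information, so the label table is
#' truncated at the first frame where the `copulation` column is TRUE. The
#' copulation frame is retained as the `"copulation_frame"` attribute
#' (NA when the pair never copulated). Idempotent.
#'
#' @param labels Behavior-label `data.frame` with `frame` and `copulation`
#'   columns.
#' @return The label table restricted to pre-copulation frames.
#' @export
mask_copulation <- function(labels) {
  check_columns(labels, c("frame", "copulation"), "label table")
  cop <- labels$frame[which(labels$copulation)[1]]
  if (is.na(cop) || length(cop) == 0L) {
    attr(labels, "copulation_frame") <- NA_integer_
    return(labels)
  }
  out <- labels[labels$frame < cop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "copulation_frame") <- as.integer(cop)
  out
}

#' Detect courtship initiation from behavior labels
#'
#' Courtship is initiated when the male exhibits any combination of the
#' courtship behaviors (excluding facing, by default) for a total of
#' `required_s` seconds over a sliding `window_s`-second window. Window
#' lengths are converted to frames with `round()` (ties to even). The
#' function returns the first positive frame inside the earliest
#' qualifying window, or `NA` if no window qualifies. Recordings shorter
#' than one window are evaluated over the available frames with a warning.
#'
#' @param labels Behavior-label table (`frame` column plus one logical
#'   column per behavior; `fly` and `copulation` are ignored).
#' @param fps Frame rate, frames/s.
#' @param window_s Sliding window length, s.
#' @param required_s Required cumulative behavior time in a window, s.
#' @param exclude Behaviors excluded from the initiation union.
#' @return Initiation frame id (same basis as `labels$frame`) or
#'   `NA_integer_`.
#' @export
detect_initiation <- function(labels, fps, window_s = 6, required_s = 3,
                              exclude = "facing") {
  check_scalar(fps, "fps", lower = 1e-9)
  if (!(required_s > 0 && required_s <= window_s)) {
    stop("must have 0 < required_s <= window_s", call. = FALSE)
  }
  beh <- setdiff(names(labels), c("frame", "fly", "copulation", exclude))
  if (length(beh) == 0L) stop("no behavior columns in label table")
  x <- rowSums(as.matrix(labels[, beh, drop = FALSE]), na.rm = TRUE) > 0
  n <- length(x)
  w <- round(window_s * fps)
  need <- round(required_s * fps)
  if (n < w) {
    warning("recording shorter than one initiation window; ",
            "evaluating over available frames")
    w <- n
  }
  if (n == 0L) return(NA_integer_)
  cs <- c(0, cumsum(x))
  starts <- seq_len(n - w + 1L)
  sums <- cs[starts + w] - cs[starts]
  hit <- which(sums >= need)[1]
  if (is.na(hit)) return(NA_integer_)
  in_win <- seq.int(hit, hit + w - 1L)
  first_pos <- in_win[which(x[in_win])[1]]
  as.integer(labels$frame[first_pos])
}

#' Classify per-frame wing-extension states
#'
#' Geometric wing-state rules (all inequalities strict):
#' \itemize{
#'   \item bilateral: both wings beyond 15 deg
#'     (`min_wing_ang > bilateral_min`);
#'   \item unilateral: one wing beyond 35 deg while the other is under
#'     15 deg (`max_wing_ang > unilateral_max` and
#'     `min_wing_ang < bilateral_min`);
#'   \item ipsilateral: the wing on the female's side of the male's body
#'     axis is beyond 35 deg (left wing > threshold while the female is
#'     left, or right wing while she is right);
#'   \item contralateral: the crossed cases.
#' }
#' Bilateral and unilateral are mutually exclusive by construction. Frames
#' with missing wing angles get all four flags missing; a female exactly on
#' the body axis counts as neither ipsi- nor contralateral.
#'
#' @param features Feature table from [pair_features()] (needs `wing_l`,
#'   `wing_r`, `min_wing_ang`, `max_wing_ang`, `other_side`).
#' @param bilateral_min Lesser-wing threshold, rad (15 deg).
#' @param unilateral_max Greater-wing threshold, rad (35 deg).
#' @return `data.frame(bilateral, unilateral, ipsilateral, contralateral)`
#'   of per-frame logicals, row-aligned with `features`.
#' @export
classify_wing_states <- function(features, bilateral_min = 0.26,
                                 unilateral_max = 0.61) {
  if (!(bilateral_min > 0 && bilateral_min < unilateral_max)) {
    stop("need 0 < bilateral_min < unilateral_max", call. = FALSE)
  }
  check_columns(features, c("wing_l", "wing_r", "min_wing_ang",
                            "max_wing_ang", "other_side"), "feature table")
  wl <- features$wing_l
  wr <- features$wing_r
  mn <- features$min_wing_ang
  mx <- features$max_wing_ang
  left <- !is.na(features$other_side) & features$other_side == "left"
  right <- !is.na(features$other_side) & features$other_side == "right"
  bilateral <- mn > bilateral_min
  unilateral <- mx > unilateral_max & mn < bilateral_min
  ipsilateral <- (wl > unilateral_max & left) | (wr > unilateral_max & right)
  contralateral <- (wl > unilateral_max & right) | (wr > unilateral_max & left)
  miss <- is.na(wl) | is.na(wr)
  out <- data.frame(bilateral = bilateral, unilateral = unilateral,
                    ipsilateral = ipsilateral, contralateral = contralateral)
  out[miss, ] <- NA
  out
}

#' Maximal runs of TRUE in a boolean series
#'
#' Run-length encodes the series and returns each maximal run of TRUE as a
#' bout with half-open frame interval `[start_frame, end_frame)`. Missing
#' values break a run.
#'
#' @param x Logical series (NA allowed).
#' @param fps Frame rate used to convert run lengths to seconds.
#' @param frames Frame ids aligned with `x`; defaults to 0-based indices.
#' @return `data.frame(start_frame, end_frame, duration_s)`, bouts disjoint
#'   and sorted.
#' @export
bouts_from_series <- function(x, fps, frames = seq_along(x) - 1L) {
  check_scalar(fps, "fps", lower = 1e-9)
  stopifnot(length(frames) == length(x))
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_frame = frames[starts[keep]],
             end_frame = frames[ends[keep]] + 1L,
             duration_s = r$lengths[keep] / fps)
}

#' Wing choice index
#'
#' Time the ipsilateral wing was extended minus time the contralateral wing
#' was extended, over the total time either was extended: +1 means the male
#' always sings with the wing nearest the female. Missing when no wing
#' extension occurred.
#'
#' @param t_ipsi,t_contra Total ipsi-/contralateral extension time, s
#'   (vectorized).
#' @return Index in `[-1, 1]`, or `NA` when both times are zero.
#' @export
wing_choice_index <- function(t_ipsi, t_contra) {
  stopifnot(all(t_ipsi >= 0, na.rm = TRUE), all(t_contra >= 0, na.rm = TRUE))
  tot <- t_ipsi + t_contra
  ifelse(is.na(tot) | tot == 0, NA_real_, (t_ipsi - t_contra) / tot)
}

#' Per-male courtship summary over the courtship period
#'
#' Masks copulation, detects initiation, and computes every summary metric
#' over the courtship period (post-initiation, pre-copulation frames):
#' latency to court, courtship index (percent of frames with any courtship
#' behavior, facing included), per-behavior indices, bilateral/unilateral
#' wing-extension indices and bilateral bout statistics, wing choice index,
#' mean facing angle, mean and minimum inter-fly distance, plus copulation
#' outcome. Males that never initiate get `NA` metrics and
#' `initiated = FALSE` so they can be excluded downstream.
#'
#' @param features Feature table from [pair_features()], frame-aligned
#'   with `labels`.
#' @param labels Behavior-label table (six behaviors + copulation).
#' @param fps Frame rate, frames/s.
#' @param window_s,required_s,exclude Initiation-rule parameters, see
#'   [detect_initiation()].
#' @param bilateral_min,unilateral_max Wing thresholds, see
#'   [classify_wing_states()].
#' @return One-row `data.frame` (see Details for columns).
#' @export
courtship_summary <- function(features, labels, fps,
                              window_s = 6, required_s = 3,
                              exclude = "facing",
                              bilateral_min = 0.26, unilateral_max = 0.61) {
  check_scalar(fps, "fps", lower = 1e-9)
  cop_all <- labels$frame[which(labels$copulation)[1]]
  copulated <- length(cop_all) == 1L && !is.na(cop_all)
  cop_latency <- if (copulated) cop_all / fps / 60 else NA_real_

  labs <- mask_copulation(labels)
  feats <- features[features$frame %in% labs$frame, , drop = FALSE]
  init <- detect_initiation(labs, fps, window_s, required_s, exclude)

  beh <- intersect(courtship_behaviors, names(labs))
  base <- data.frame(initiated = FALSE,
                     latency_to_court_min = NA_real_,
                     courtship_index_pct = NA_real_)
  for (b in beh) base[[paste0(b, "_index_pct")]] <- NA_real_
  base$bilateral_index_pct <- NA_real_
  base$bilateral_bout_rate <- NA_real_
  base$bilateral_bout_len_s <- NA_real_
  base$unilateral_index_pct <- NA_real_
  base$wing_choice_index <- NA_real_
  base$mean_facing_angle <- NA_real_
  base$mean_dist <- NA_real_
  base$min_dist <- NA_real_
  base$copulated <- copulated
  base$copulation_latency_min <- cop_latency
  if (is.na(init)) return(base)

  cl <- labs[labs$frame >= init, , drop = FALSE]
  fe <- feats[feats$frame >= init, , drop = FALSE]
  n_court <- nrow(cl)
  court_min <- n_court / fps / 60
  any_beh <- rowSums(as.matrix(cl[, beh, drop = FALSE]), na.rm = TRUE) > 0

  out <- base
  out$initiated <- TRUE
  out$latency_to_court_min <- init / fps / 60
  out$courtship_index_pct <- 100 * mean(any_beh)
  for (b in beh) out[[paste0(b, "_index_pct")]] <- 100 * mean(cl[[b]])

  ws <- classify_wing_states(fe, bilateral_min, unilateral_max)
  out$bilateral_index_pct <- 100 * mean(ws$bilateral, na.rm = TRUE)
  out$unilateral_index_pct <- 100 * mean(ws$unilateral, na.rm = TRUE)
  bl_bouts <- bouts_from_series(ws$bilateral, fps, frames = fe$frame)
  out$bilateral_bout_rate <- nrow(bl_bouts) / court_min
  out$bilateral_bout_len_s <- if (nrow(bl_bouts)) mean(bl_bouts$duration_s)
                              else NA_real_
  t_ipsi <- sum(ws$ipsilateral, na.rm = TRUE) / fps
  t_contra <- sum(ws$contralateral, na.rm = TRUE) / fps
  out$wing_choice_index <- wing_choice_index(t_ipsi, t_contra)
  out$mean_facing_angle <- mean(fe$facing_angle, na.rm = TRUE)
  out$mean_dist <- mean(fe$dist_to_other, na.rm = TRUE)
  out$min_dist <- suppressWarnings(min(fe$dist_to_other, na.rm = TRUE))
  if (!is.finite(out$min_dist)) out$min_dist <- NA_real_
  out
}

#' 2-D occurrence histogram of the female's egocentric position
#'
#' Bins the female's position in the male's egocentric frame (`rel_x`
#' forward, `rel_y` leftward) over the frames where `flag` is TRUE, as used
#' for the relative-position heatmaps during contralateral and ipsilateral
#' wing extension. Cells hold occurrence counts, not densities. Flagged
#' frames falling outside the grid (or with missing coordinates) are
#' accumulated in a single overflow count, so
#' `sum(counts) + overflow == number of flagged frames`.
#'
#' @param features Feature table from [pair_features()].
#' @param flag Per-frame logical selecting which frames to bin (row-aligned
#'   with `features`); NA counts as FALSE.
#' @param xlim,ylim Grid extents, mm.
#' @param bin_mm Square bin side, mm.
#' @return A list with `counts` (matrix, rows = `rel_x` bins, cols =
#'   `rel_y` bins), `overflow`, `n_flagged`, `x_breaks`, `y_breaks`.
#' @export
relative_position_heatmap <- function(features, flag,
                                      xlim = c(-10, 10), ylim = c(-10, 10),
                                      bin_mm = 1) {
  check_columns(features, c("rel_x", "rel_y"), "feature table")
  stopifnot(length(flag) == nrow(features))
  check_scalar(bin_mm, "bin_mm", lower = 1e-9)
  flag <- !is.na(flag) & flag
  xb <- seq(xlim[1], xlim[2], by = bin_mm)
  yb <- seq(ylim[1], ylim[2], by = bin_mm)
  nx <- length(xb) - 1L
  ny <- length(yb) - 1L
  counts <- matrix(0L, nrow = nx, ncol = ny)
  rx <- features$rel_x[flag]
  ry <- features$rel_y[flag]
  ix <- floor((rx - xlim[1]) / bin_mm) + 1L
  iy <- floor((ry - ylim[1]) / bin_mm) + 1L
  # points exactly on the upper edge belong to the last bin
  ix[!is.na(rx) & rx == xlim[2]] <- nx
  iy[!is.na(ry) & ry == ylim[2]] <- ny
  inside <- !is.na(ix) & !is.na(iy) & ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  for (k in which(inside)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  list(counts = counts, overflow = sum(!inside), n_flagged = sum(flag),
       x_breaks = xb, y_breaks = yb)
}
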