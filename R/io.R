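# CSV readers/writers for the pipeline's table dialects.
#
# All writers emit UTF-8 CSV with a header row, '.' decimal separator and
# floats at 6 significant digits, so a given table always serializes the
# same way. Readers validate the schema and report malformed rows by
# number.

.read_checked <- function(path, required, what, numeric_cols = required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, required, what)
  for (cc in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[cc]])) {
      suppressWarnings(v <- as.numeric(df[[cc]]))
      bad <- which(is.na(v) & !is.na(df[[cc]]) & nzchar(df[[cc]]))
      if (length(bad) > 0L) {
        stop(sprintf("%s: malformed value in column '%s' at row %d",
                     what, cc, bad[1]), call. = FALSE)
      }
      df[[cc]] <- v
    }
  }
  df
}

.write_csv6 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-fly pose table
#'
#' Reads `frame, fly, x_mm, y_mm, theta_rad, wing_l_rad, wing_r_rad` CSV as
#' written by [write_pose_table()] (or exported from a video tracker).
#' Coordinates are multiplied by `scale` — pass mm-per-pixel (e.g.
#' `20 / 1600` for a 20 mm arena imaged at 1600 px) when the tracker
#' exported pixels, or leave 1 for mm. Validates the schema, per-fly frame
#' monotonicity and (frame, fly) uniqueness.
#'
#' @param path CSV path.
#' @param scale Multiplicative scale applied to `x_mm`/`y_mm`.
#' @return Pose `data.frame` in mm/rad.
#' @export
read_pose_table <- function(path, scale = 1) {
  check_scalar(scale, "scale", lower = 1e-12)
  df <- .read_checked(path, c("frame", "fly", "x_mm", "y_mm", "theta_rad",
                              "wing_l_rad", "wing_r_rad"), "pose table",
                      numeric_cols = c("frame", "x_mm", "y_mm", "theta_rad",
                                       "wing_l_rad", "wing_r_rad"))
  if (anyDuplicated(df[, c("frame", "fly")])) {
    stop("pose table: duplicate (frame, fly) rows", call. = FALSE)
  }
  for (id in unique(df$fly)) {
    fr <- df$frame[df$fly == id]
    if (is.unsorted(fr, strictly = TRUE)) {
      stop("pose table: non-monotone frames for fly '", id, "'",
           call. = FALSE)
    }
  }
  df$x_mm <- df$x_mm * scale
  df$y_mm <- df$y_mm * scale
  df
}

#' @rdname read_pose_table
#' @param poses Pose table to write.
#' @export
write_pose_table <- function(poses, path) {
  check_columns(poses, c("frame", "fly", "x_mm", "y_mm", "theta_rad",
                         "wing_l_rad", "wing_r_rad"), "pose table")
  .write_csv6(poses, path)
}

#' Read or write a behavior-label table
#'
#' CSV with `frame`, `fly` and one 0/1 column per behavior (six courtship
#' behaviors plus `copulation`). Label columns are returned as logicals.
#'
#' @param path CSV path.
#' @return Label `data.frame`.
#' @export
read_behavior_labels <- function(path) {
  df <- .read_checked(path, c("frame", "fly"), "label table",
                      numeric_cols = "frame")
  lab_cols <- setdiff(names(df), c("frame", "fly"))
  if (length(lab_cols) == 0L) stop("label table has no behavior columns")
  for (cc in lab_cols) df[[cc]] <- as.logical(df[[cc]])
  df
}

#' @rdname read_behavior_labels
#' @param labels Label table to write (logical columns written as 0/1).
#' @export
write_behavior_labels <- function(labels, path) {
  check_columns(labels, c("frame", "fly"), "label table")
  lg <- vapply(labels, is.logical, logical(1))
  labels[lg] <- lapply(labels[lg], as.integer)
  .write_csv6(labels, path)
}

#' Read or write a fluorescence trace table
#'
#' CSV with `time_s` and `f` columns.
#'
#' @param path CSV path.
#' @return Trace `data.frame(time_s, f)`.
#' @export
read_trace <- function(path) {
  df <- .read_checked(path, c("time_s", "f"), "trace table")
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("trace table: time_s must be strictly increasing", call. = FALSE)
  }
  df
}

#' @rdname read_trace
#' @param trace Trace table to write.
#' @export
write_trace <- function(trace, path) {
  check_columns(trace, c("time_s", "f"), "trace table")
  .write_csv6(trace, path)
}

#' Read or write an egg-count table
#'
#' CSV with `genotype, female_id, eggs_a, eggs_b`; side A is the
#' pheromone-treated zone.
#'
#' @param path CSV path.
#' @return Egg-count `data.frame`.
#' @export
read_egg_counts <- function(path) {
  df <- .read_checked(path, c("genotype", "female_id", "eggs_a", "eggs_b"),
                      "egg table", numeric_cols = c("eggs_a", "eggs_b"))
  if (any(df$eggs_a < 0 | df$eggs_b < 0 |
          df$eggs_a != round(df$eggs_a) | df$eggs_b != round(df$eggs_b))) {
    stop("egg table: counts must be non-negative integers", call. = FALSE)
  }
  df
}

#' @rdname read_egg_counts
#' @param eggs Egg-count table to write.
#' @export
write_egg_counts <- function(eggs, path) {
  check_columns(eggs, c("genotype", "female_id", "eggs_a", "eggs_b"),
                "egg table")
  .write_csv6(eggs, path)
}

#' Read or write a synapse table
#'
#' CSV with `bodyid_pre, bodyid_post, compartment_post, neuropil, weight`
#' (optionally `compartment_pre`), the neuPrint-style edge-list schema.
#'
#' @param path CSV path.
#' @return Synapse `data.frame` (body ids as character).
#' @export
read_synapse_table <- function(path) {
  df <- .read_checked(path, c("bodyid_pre", "bodyid_post",
                              "compartment_post", "neuropil", "weight"),
                      "synapse table", numeric_cols = "weight")
  if (any(df$weight < 1 | df$weight != round(df$weight))) {
    stop("synapse table: weight must be a positive integer", call. = FALSE)
  }
  df$bodyid_pre <- as.character(df$bodyid_pre)
  df$bodyid_post <- as.character(df$bodyid_post)
  df
}

#' @rdname read_synapse_table
#' @param synapses Synapse table to write.
#' @export
write_synapse_table <- function(synapses, path) {
  check_columns(synapses, c("bodyid_pre", "bodyid_post", "compartment_post",
                            "neuropil", "weight"), "synapse table")
  .write_csv6(synapses, path)
}
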