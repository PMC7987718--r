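# Per-frame pairwise geometry from two-fly pose tracks.
#
# All operations are frame-local and vectorized; missing data propagate as
# NA and are excluded from downstream denominators.

#' Facing angle between a fly's heading and the line to the other fly
#'
#' The angle between the focal fly's heading vector and the displacement
#' from its centroid to the other fly's centroid, in `[0, pi]`. 0 means the
#' other fly is dead ahead, `pi` directly behind. Coincident centroids give
#' `NA` (undefined geometry), not an error.
#'
#' @param x,y Focal centroid, mm.
#' @param theta Focal heading, rad (counter-clockwise from +x).
#' @param other_x,other_y Other fly's centroid, mm.
#' @return Facing angle, rad, vectorized over frames.
#' @export
facing_angle <- function(x, y, theta, other_x, other_y) {
  dx <- other_x - x
  dy <- other_y - y
  d <- sqrt(dx^2 + dy^2)
  cosv <- (cos(theta) * dx + sin(theta) * dy) / d
  out <- acos(pmin(1, pmax(-1, cosv)))
  out[!is.na(d) & d == 0] <- NA_real_
  out
}

#' Centroid-to-centroid distance between the two flies
#'
#' @param x,y,other_x,other_y Centroids, mm.
#' @return Euclidean distance, mm.
#' @export
dist_to_other <- function(x, y, other_x, other_y) {
  sqrt((other_x - x)^2 + (other_y - y)^2)
}

#' Position of the other fly in the focal fly's egocentric frame
#'
#' Rotates the displacement to the other fly by minus the focal heading:
#' `rel_x` points along the heading (forward), `rel_y` to the focal fly's
#' left. `other_side` is "left"/"right" by the sign of `rel_y`, or
#' "on-axis" when `rel_y` is exactly 0 (including coincident centroids).
#'
#' @inheritParams facing_angle
#' @return `data.frame(rel_x, rel_y, other_side)`.
#' @export
egocentric_position <- function(x, y, theta, other_x, other_y) {
  dx <- other_x - x
  dy <- other_y - y
  rel_x <- cos(theta) * dx + sin(theta) * dy
  rel_y <- -sin(theta) * dx + cos(theta) * dy
  side <- rep(NA_character_, length(rel_y))
  ok <- !is.na(rel_y)
  side[ok] <- ifelse(rel_y[ok] > 0, "left",
                     ifelse(rel_y[ok] < 0, "right", "on-axis"))
  data.frame(rel_x = rel_x, rel_y = rel_y, other_side = side)
}

#' Lesser and greater wing angle of a fly
#'
#' Elementwise min/max of the left and right wing angles. If either wing is
#' missing on a frame, both extrema are missing for that frame.
#'
#' @param wing_l,wing_r Wing angles from the body axis, rad, >= 0.
#' @return `data.frame(min_wing_ang, max_wing_ang)`.
#' @export
wing_extrema <- function(wing_l, wing_r) {
  miss <- is.na(wing_l) | is.na(wing_r)
  mn <- pmin(wing_l, wing_r)
  mx <- pmax(wing_l, wing_r)
  mn[miss] <- NA_real_
  mx[miss] <- NA_real_
  data.frame(min_wing_ang = mn, max_wing_ang = mx)
}

#' Per-frame pairwise features for a focal fly
#'
#' Joins the focal and partner poses frame by frame and computes the
#' feature set consumed by the courtship classifiers: facing angle,
#' centroid distance, wing extrema, egocentric partner position and side.
#' Frames where the partner is missing yield missing pairwise features.
#'
#' @param poses Pose table as produced by [sim_courtship_pair()] /
#'   [read_pose_table()]: columns `frame, fly, x_mm, y_mm, theta_rad,
#'   wing_l_rad, wing_r_rad`.
#' @param focal,other Fly identifiers (defaults "male" and "female").
#' @return `data.frame(frame, facing_angle, dist_to_other, min_wing_ang,
#'   max_wing_ang, rel_x, rel_y, other_side, wing_l, wing_r)`, one row per
#'   focal frame, ordered by frame.
#' @export
pair_features <- function(poses, focal = "male", other = "female") {
  check_columns(poses, c("frame", "fly", "x_mm", "y_mm", "theta_rad",
                         "wing_l_rad", "wing_r_rad"), "pose table")
  foc <- poses[poses$fly == focal, , drop = FALSE]
  oth <- poses[poses$fly == other, , drop = FALSE]
  if (nrow(foc) == 0L) stop("no rows for focal fly '", focal, "'")
  foc <- foc[order(foc$frame), , drop = FALSE]
  idx <- match(foc$frame, oth$frame)
  ox <- oth$x_mm[idx]
  oy <- oth$y_mm[idx]
  ego <- egocentric_position(foc$x_mm, foc$y_mm, foc$theta_rad, ox, oy)
  wex <- wing_extrema(foc$wing_l_rad, foc$wing_r_rad)
  data.frame(frame = foc$frame,
             facing_angle = facing_angle(foc$x_mm, foc$y_mm, foc$theta_rad,
                                         ox, oy),
             dist_to_other = dist_to_other(foc$x_mm, foc$y_mm, ox, oy),
             wex, ego,
             wing_l = foc$wing_l_rad, wing_r = foc$wing_r_rad)
}
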