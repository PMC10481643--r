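# Rotational-bias scoring of pose-tracked head/torso/tail-base coordinates.

#' Impute, smooth and trim a pose track
#'
#' Missing coordinates are replaced by the nearest-in-time present value
#' (ties resolve to the earlier frame), each node coordinate series is then
#' smoothed with a Savitzky-Golay filter (polynomial degree 3, window length
#' 15 frames by default), and the first `drop_first` frames are dropped to
#' exclude unstable video capture at recording onset.
#'
#' @param track a [pose_track()]
#' @param poly_degree,window Savitzky-Golay filter settings; `window` must
#'   be odd and exceed `poly_degree`
#' @param drop_first frames removed from the start after smoothing
#' @return a `pose_track` of length `nrow(track) - drop_first` with no
#'   missing values
#' @export
preprocess_track <- function(track, poly_degree = 3L, window = 15L,
                             drop_first = 5L) {
  stopifnot(inherits(track, "pose_track"))
  n <- nrow(track)
  if (n <= window + drop_first)
    stop("track too short for the smoothing window plus dropped frames")
  if (window %% 2L == 0L) stop("window length must be odd")
  cols <- c("head_x", "head_y", "torso_x", "torso_y", "tail_x", "tail_y")
  out <- track
  for (cl in cols) {
    x <- track[[cl]]
    if (all(is.na(x))) stop("node series ", cl, " is entirely missing")
    x <- impute_nearest(x)
    out[[cl]] <- signal::sgolayfilt(x, p = poly_degree, n = window)
  }
  out <- out[(drop_first + 1L):n, , drop = FALSE]
  rownames(out) <- NULL
  pose_track(out, fps = attr(track, "fps"))
}

#' Frame-to-frame rotation angles from egocentric heading
#'
#' The egocentric head vector of each frame is `head - torso`; the heading
#' is that vector's planar angle against the positive x axis. The rotation
#' series is the wrapped frame-to-frame heading difference in
#' `(-180, 180]` degrees (so a heading step across the axis discontinuity,
#' e.g. 179 to -179 degrees, is reported as +2, not -358). Residual
#' artifacts -- physically impossible jumps beyond `artifact_thresh` and
#' frames with a degenerate (near zero-length) head-torso vector -- are
#' replaced by the nearest valid angle, and the series is finally smoothed
#' with a Gaussian filter.
#'
#' @param track a preprocessed [pose_track()] (see [preprocess_track()])
#' @param gaussian_sigma standard deviation (frames) of the Gaussian smoother
#' @param artifact_thresh absolute angle increment (degrees/frame) above
#'   which a value is treated as a tracking artifact
#' @return numeric vector of length `nrow(track) - 1` (degrees per frame,
#'   positive = counterclockwise in image coordinates)
#' @export
compute_rotation_series <- function(track, gaussian_sigma = 3,
                                    artifact_thresh = 90) {
  stopifnot(inherits(track, "pose_track"))
  hx <- track$head_x - track$torso_x
  hy <- track$head_y - track$torso_y
  len <- sqrt(hx^2 + hy^2)
  heading <- atan2(hy, hx) * 180 / pi
  heading[len < 1e-9] <- NA_real_
  d <- wrap_angle(diff(heading))
  d[abs(d) > artifact_thresh] <- NA_real_
  d <- impute_nearest(d)
  gaussian_smooth(d, gaussian_sigma)
}

#' Per-frame displacement of a tracked node
#'
#' Euclidean distance between a node's coordinates in consecutive frames,
#' computed on preprocessed (smoothed) coordinates. The tail-base node is
#' used by default for moving-state classification.
#'
#' @param track a preprocessed [pose_track()]
#' @param node one of `"tail"`, `"head"`, `"torso"`
#' @return numeric vector of length `nrow(track) - 1` (pixels per frame)
#' @export
node_displacement <- function(track, node = c("tail", "head", "torso")) {
  node <- match.arg(node)
  x <- track[[paste0(node, "_x")]]
  y <- track[[paste0(node, "_y")]]
  sqrt(diff(x)^2 + diff(y)^2)
}

#' Classify frames as moving or stationary
#'
#' A frame is moving iff its displacement exceeds `disp_thresh` pixels and
#' its absolute rotation angle exceeds `angle_thresh_low` degrees, or its
#' absolute rotation angle alone exceeds `angle_thresh_high` degrees (the
#' robust head-swing branch).
#'
#' @param angle_series rotation angles, degrees per frame
#' @param displacement_series node displacement, pixels per frame
#' @param disp_thresh,angle_thresh_low,angle_thresh_high thresholds
#' @return logical vector, `TRUE` for moving frames
#' @export
classify_moving <- function(angle_series, displacement_series,
                            disp_thresh = 0.4, angle_thresh_low = 0.5,
                            angle_thresh_high = 2) {
  if (length(angle_series) != length(displacement_series))
    stop("angle and displacement series must have equal length")
  (displacement_series > disp_thresh & abs(angle_series) > angle_thresh_low) |
    abs(angle_series) > angle_thresh_high
}

#' Rotation-bias score over moving frames
#'
#' Bias is the net signed rotation over moving frames normalized by the
#' total unsigned rotation over moving frames, a dimensionless score in
#' `[-1, 1]` (positive = counterclockwise in image coordinates). The net
#' rotation rate is the signed sum over moving frames divided by the
#' series duration in minutes.
#'
#' @param angle_series rotation angles, degrees per frame
#' @param moving_mask logical vector from [classify_moving()]
#' @param fps frames per second
#' @return list with `bias` (`NA` when no frame moves), `net_rotation_rate`
#'   (degrees/minute) and `n_moving`
#' @export
score_rotation_bias <- function(angle_series, moving_mask, fps = 15) {
  if (length(angle_series) != length(moving_mask))
    stop("angle series and moving mask must have equal length")
  mv <- angle_series[moving_mask]
  minutes <- length(angle_series) / fps / 60
  if (length(mv) == 0L)
    return(list(bias = NA_real_, net_rotation_rate = 0, n_moving = 0L))
  denom <- sum(abs(mv))
  list(bias = if (denom > 0) sum(mv) / denom else 0,
       net_rotation_rate = sum(mv) / minutes,
       n_moving = length(mv))
}

#' Full rotation-bias pipeline for one pose-tracked session
#'
#' Runs imputation, Savitzky-Golay smoothing and frame trimming, derives the
#' egocentric rotation-angle series and the tail-base displacement series,
#' classifies moving frames, and scores the rotational bias from moving
#' frames only.
#'
#' @param track a raw [pose_track()]
#' @param poly_degree,window,drop_first see [preprocess_track()]
#' @param gaussian_sigma see [compute_rotation_series()]
#' @param disp_thresh,angle_thresh_low,angle_thresh_high see
#'   [classify_moving()]
#' @return an object of class `rotation_result`: list with `angle_series`,
#'   `displacement_series`, `moving_mask`, `bias`, `net_rotation_rate`,
#'   `n_moving`, `fps`
#' @export
analyze_rotation <- function(track, poly_degree = 3L, window = 15L,
                             drop_first = 5L, gaussian_sigma = 3,
                             disp_thresh = 0.4, angle_thresh_low = 0.5,
                             angle_thresh_high = 2) {
  fps <- attr(track, "fps") %||% 15
  pp <- preprocess_track(track, poly_degree, window, drop_first)
  ang <- compute_rotation_series(pp, gaussian_sigma)
  disp <- node_displacement(pp, "tail")
  mv <- classify_moving(ang, disp, disp_thresh, angle_thresh_low,
                        angle_thresh_high)
  sc <- score_rotation_bias(ang, mv, fps)
  structure(
    list(angle_series = ang, displacement_series = disp, moving_mask = mv,
         bias = sc$bias, net_rotation_rate = sc$net_rotation_rate,
         n_moving = sc$n_moving, fps = fps),
    class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf(
    "<rotation_result> %d frames, %d moving; bias %.3f; net rate %.1f deg/min\n",
    length(x$angle_series), x$n_moving,
    if (is.na(x$bias)) NA_real_ else x$bias, x$net_rotation_rate))
  invisible(x)
}
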