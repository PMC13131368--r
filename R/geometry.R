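#' Euclidean distance between two points
#' @param p,q Length-2 numeric vectors (x, y) in pixels.
#' @return Non-negative distance in pixels.
#' @export
euclidean_distance <- function(p, q) {
  stopifnot(is.finite(p), is.finite(q))
  sqrt(sum((p - q)^2))
}

#' Ear angulation by the law of cosines
#'
#' The ear angle is measured at the ear attachment (base) landmark — the
#' hinge of ear rotation — between the ear tip and a supra-ocular
#' reference point (the same side's upper eyelid landmark in the
#' 10-keypoint schema). With leg lengths a = |base - tip|,
#' c = |base - eye_ref| and opposite side b = |tip - eye_ref|,
#' cos(theta) = (a^2 + c^2 - b^2) / (2 a c); the cosine is clamped to
#' [-1, 1] before the arccosine for numerical safety.
#'
#' @param ear_tip,ear_base,eye_ref Length-2 numeric points in pixels.
#' @param eps Degeneracy tolerance in pixels; pairwise distances at or
#'   below it raise an error. Default 1e-6.
#' @return Angle at the base vertex in degrees, in `[0, 180]`.
#' @export
#' @examples
#' ear_angle(c(1, 0), c(0, 0), c(0, 1)) # 90
ear_angle <- function(ear_tip, ear_base, eye_ref, eps = 1e-6) {
  a <- euclidean_distance(ear_base, ear_tip)
  c_ <- euclidean_distance(ear_base, eye_ref)
  b <- euclidean_distance(ear_tip, eye_ref)
  if (a <= eps) stop("degenerate geometry: ear_tip coincides with ear_base", call. = FALSE)
  if (c_ <= eps) stop("degenerate geometry: eye_ref coincides with ear_base", call. = FALSE)
  if (b <= eps) stop("degenerate geometry: ear_tip coincides with eye_ref", call. = FALSE)
  cosv <- (a^2 + c_^2 - b^2) / (2 * a * c_)
  cosv <- min(1, max(-1, cosv))
  acos(cosv) * 180 / pi
}

#' Classify ear posture from the ear angle
#'
#' Backward when the angle exceeds 90 degrees, frontward when it is at
#' or below 90 degrees.
#'
#' @param angle Ear angle in degrees, `[0, 180]`.
#' @return `"frontward"` or `"backward"`.
#' @export
classify_ear_position <- function(angle) {
  if (!is.finite(angle) || angle < 0 || angle > 180) {
    stop("angle must be in [0, 180] degrees", call. = FALSE)
  }
  if (angle > 90) "backward" else "frontward"
}

#' Pixel-to-centimeter calibration from the ear-tag fiducial
#'
#' The animal's ear tag has a known physical size; its pixel extent in
#' the image (the larger tag dimension) fixes the scale.
#'
#' @param tag_size_cm Physical tag size in cm, > 0.
#' @param tag_extent_px Tag extent in pixels, > 0.
#' @return A list of class `scale_calibration` with `tag_size_cm`,
#'   `tag_extent_px` and `cm_per_px`.
#' @export
scale_calibration <- function(tag_size_cm, tag_extent_px) {
  if (!is.finite(tag_size_cm) || tag_size_cm <= 0) {
    stop("tag_size_cm must be > 0", call. = FALSE)
  }
  if (!is.finite(tag_extent_px) || tag_extent_px <= 0) {
    stop("tag_extent_px must be > 0", call. = FALSE)
  }
  structure(
    list(
      tag_size_cm = tag_size_cm, tag_extent_px = tag_extent_px,
      cm_per_px = tag_size_cm / tag_extent_px
    ),
    class = "scale_calibration"
  )
}

#' Distance between two named keypoints, in centimeters
#'
#' Euclidean pixel distance between two labelled keypoints converted to
#' cm by the calibration. Used for eye opening (upper vs lower eyelid
#' landmark) and nostril distance (left vs right nostril). A keypoint
#' with visibility 0 yields `NA` (missing trait), not an error.
#'
#' @param frame A [kp_frame()].
#' @param label_a,label_b Keypoint labels.
#' @param cal A [scale_calibration()], or `NULL` to return the pixel
#'   distance unscaled (pixel-only mode).
#' @return Distance in cm (or pixels when `cal` is `NULL`); `NA_real_`
#'   when either keypoint is absent.
#' @export
paired_distance_cm <- function(frame, label_a, label_b, cal = NULL) {
  if (frame$visibility[label_a] == 0L || frame$visibility[label_b] == 0L) {
    return(NA_real_)
  }
  d_px <- euclidean_distance(frame$points[label_a, ], frame$points[label_b, ])
  if (is.null(cal)) {
    return(d_px)
  }
  if (!inherits(cal, "scale_calibration")) {
    stop("cal must be a scale_calibration (or NULL for pixel-only mode)", call. = FALSE)
  }
  d_px * cal$cm_per_px
}

# angle + posture for one side; NA when any of the three keypoints absent
side_ear_result <- function(frame, side, eps = 1e-6) {
  labs <- paste0(side, c("_ear_tip", "_ear_base", "_eye_top"))
  if (any(frame$visibility[labs] == 0L)) {
    return(list(angle = NA_real_, position = NA_character_))
  }
  ang <- ear_angle(
    frame$points[labs[1], ], frame$points[labs[2], ],
    frame$points[labs[3], ],
    eps = eps
  )
  list(angle = ang, position = classify_ear_position(ang))
}

#' Extract all per-frame facial phenotypes
#'
#' Composes ear angulation and posture (per side), eye opening (per
#' side) and nostril distance for one frame. Any trait whose required
#' keypoint is absent is reported as missing; a frame using occluded
#' (visibility 1) keypoints is flagged `low_confidence`.
#'
#' @param frame A [kp_frame()].
#' @param cal A [scale_calibration()] or `NULL` for pixel-only
#'   distances.
#' @param eps Degeneracy tolerance passed to [ear_angle()].
#' @return A one-row data.frame: frame_index, left/right ear angle and
#'   position, eye openings and nostril distance (cm), low_confidence.
#' @export
extract_frame_phenotypes <- function(frame, cal = NULL, eps = 1e-6) {
  left <- side_ear_result(frame, "left", eps)
  right <- side_ear_result(frame, "right", eps)
  data.frame(
    frame_index = frame$frame_index,
    left_ear_angle_deg = left$angle,
    left_ear_position = left$position,
    right_ear_angle_deg = right$angle,
    right_ear_position = right$position,
    eye_opening_left_cm = paired_distance_cm(frame, "left_eye_top", "left_eye_bottom", cal),
    eye_opening_right_cm = paired_distance_cm(frame, "right_eye_top", "right_eye_bottom", cal),
    nostril_distance_cm = paired_distance_cm(frame, "left_nostril", "right_nostril", cal),
    low_confidence = any(frame$visibility == 1L),
    stringsAsFactors = FALSE
  )
}

#' Per-frame phenotypes for a whole trajectory
#'
#' @param traj A [kp_trajectory()].
#' @param cal A [scale_calibration()] or `NULL`.
#' @return A data.frame with one row per frame (see
#'   [extract_frame_phenotypes()]).
#' @export
extract_trajectory_phenotypes <- function(traj, cal = NULL) {
  do.call(rbind, lapply(traj$frames, extract_frame_phenotypes, cal = cal))
}
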