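#' The canonical 10-keypoint calf-face schema
#'
#' Ordered keypoint labels for the calf face: ear tips and attachment
#' (base) points, upper and lower eyelid landmarks, and the two nostrils.
#' These ten landmarks are the minimal set supporting ear angulation,
#' eye opening and nostril distance.
#'
#' @param names Character vector of keypoint labels. Defaults to the
#'   canonical calf-face set.
#' @param skeleton Optional list of label pairs used for visualization.
#' @return An object of class `kp_schema` with elements `names` and
#'   `skeleton`.
#' @export
#' @examples
#' sch <- calf_face_schema()
#' sch$names
calf_face_schema <- function(names = c(
                               "left_ear_tip", "left_ear_base",
                               "right_ear_tip", "right_ear_base",
                               "left_eye_top", "left_eye_bottom",
                               "right_eye_top", "right_eye_bottom",
                               "left_nostril", "right_nostril"
                             ),
                             skeleton = list(
                               c("left_ear_tip", "left_ear_base"),
                               c("right_ear_tip", "right_ear_base"),
                               c("left_eye_top", "left_eye_bottom"),
                               c("right_eye_top", "right_eye_bottom"),
                               c("left_nostril", "right_nostril")
                             )) {
  names <- as.character(names)
  if (anyDuplicated(names)) {
    stop("keypoint labels must be unique", call. = FALSE)
  }
  if (length(names) < 1L) stop("schema needs at least one label", call. = FALSE)
  structure(list(names = names, skeleton = skeleton), class = "kp_schema")
}

#' Construct a single-frame keypoint record
#'
#' Holds one frame's named 2D keypoints in pixel coordinates (origin
#' top-left, y increasing downward, sub-pixel values allowed) together
#' with COCO-style visibility flags (0 absent, 1 occluded, 2 visible).
#'
#' @param frame_index Non-negative integer frame index.
#' @param points Numeric matrix with one row per keypoint and two columns
#'   (x, y) in pixels; row names are the keypoint labels.
#' @param visibility Named integer vector of visibility flags, same
#'   labels as `points`.
#' @param image_size Length-2 numeric `(width, height)` in pixels.
#' @param bbox Optional length-4 numeric `(x, y, width, height)` in pixels.
#' @param schema A `kp_schema`; every schema label must be present.
#' @return An object of class `kp_frame`.
#' @export
kp_frame <- function(frame_index, points, visibility, image_size,
                     bbox = NULL, schema = calf_face_schema()) {
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L) {
    stop("frame_index must be a non-negative integer", call. = FALSE)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have two columns (x, y)", call. = FALSE)
  missing_lab <- setdiff(schema$names, rownames(points))
  if (length(missing_lab)) {
    stop("points missing schema labels: ", paste(missing_lab, collapse = ", "),
      call. = FALSE
    )
  }
  points <- points[schema$names, , drop = FALSE]
  colnames(points) <- c("x", "y")
  visibility <- visibility[schema$names]
  if (anyNA(visibility)) {
    stop("visibility missing for some schema labels", call. = FALSE)
  }
  visibility <- as.integer(visibility)
  names(visibility) <- schema$names
  if (any(!visibility %in% 0:2)) {
    stop("visibility flags must be 0, 1 or 2", call. = FALSE)
  }
  vis <- visibility > 0L
  if (any(vis & !is.finite(points[, 1]))) {
    stop("non-finite coordinates for visible keypoints", call. = FALSE)
  }
  image_size <- as.numeric(image_size)
  if (length(image_size) != 2L || any(image_size <= 0)) {
    stop("image_size must be positive (width, height)", call. = FALSE)
  }
  if (!is.null(bbox)) {
    bbox <- as.numeric(bbox)
    if (length(bbox) != 4L) stop("bbox must be (x, y, width, height)", call. = FALSE)
  }
  structure(
    list(
      frame_index = frame_index, points = points, visibility = visibility,
      image_size = image_size, bbox = bbox, schema = schema
    ),
    class = "kp_frame"
  )
}

#' Construct a keypoint trajectory
#'
#' A time-ordered sequence of [kp_frame()] records for one animal and
#' one recording session at a known frame rate (default 1 frame per
#' second, matching frame-extracted farm video).
#'
#' @param animal_id,session_id Character identifiers.
#' @param frames List of `kp_frame` objects with strictly increasing
#'   `frame_index`.
#' @param frame_rate Frames per second, > 0. Default 1.
#' @return An object of class `kp_trajectory`.
#' @export
kp_trajectory <- function(animal_id, session_id, frames, frame_rate = 1) {
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be > 0", call. = FALSE)
  }
  if (!length(frames)) stop("trajectory needs at least one frame", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "kp_frame"))) {
    stop("frames must all be kp_frame objects", call. = FALSE)
  }
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (any(diff(idx) <= 0L)) {
    stop("frame_index must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      animal_id = as.character(animal_id),
      session_id = as.character(session_id),
      frame_rate = frame_rate, frames = frames
    ),
    class = "kp_trajectory"
  )
}

#' @export
print.kp_frame <- function(x, ...) {
  cat(
    "<kp_frame> index", x$frame_index, "|",
    sum(x$visibility == 2L), "visible /", length(x$visibility), "keypoints\n"
  )
  invisible(x)
}

#' @export
print.kp_trajectory <- function(x, ...) {
  cat(
    "<kp_trajectory>", x$animal_id, "/", x$session_id, "|",
    length(x$frames), "frames @", x$frame_rate, "fps\n"
  )
  invisible(x)
}
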