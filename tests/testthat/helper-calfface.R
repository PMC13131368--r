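# shared fixture builders; all data is generated in code

schema10 <- calf_face_schema()

# a frame from a named list of c(x, y) points; unlisted labels sit at the
# origin with visibility 0
make_frame <- function(points, visibility = NULL, frame_index = 0L,
                       image_size = c(640, 640), bbox = NULL) {
  pts <- matrix(0, nrow = length(schema10$names), ncol = 2,
                dimnames = list(schema10$names, c("x", "y")))
  vis <- stats::setNames(rep(0L, length(schema10$names)), schema10$names)
  for (lab in names(points)) {
    pts[lab, ] <- points[[lab]]
    vis[lab] <- 2L
  }
  if (!is.null(visibility)) vis[names(visibility)] <- visibility
  kp_frame(frame_index, pts, vis, image_size, bbox = bbox, schema = schema10)
}

# fully visible frame with all 10 keypoints at given jittered positions
make_full_frame <- function(seed = 1, frame_index = 0L, image_size = c(640, 640)) {
  set.seed(seed)
  pts <- matrix(runif(20, 100, 500), ncol = 2,
                dimnames = list(schema10$names, c("x", "y")))
  vis <- stats::setNames(rep(2L, 10), schema10$names)
  kp_frame(frame_index, pts, vis, image_size,
           bbox = c(90, 90, 420, 420), schema = schema10)
}

# independent angle oracle: vector dot product / arccos
angle_oracle_deg <- function(tip, base, eye) {
  u <- tip - base
  v <- eye - base
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}
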