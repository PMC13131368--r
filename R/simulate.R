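#' Parameters of the synthetic calf-head keypoint generator
#'
#' Defaults describe a plausible study calf: nostril distance 5.93 cm
#' and eye openings 2.75 / 2.76 cm (left / right), ears alternating
#' between a frontward posture near 60 degrees and a backward posture
#' near 120 degrees under a two-state Markov chain whose stationary
#' distribution puts about 64% of time frontward and whose switch rate
#' is about 0.196 per frame-pair (roughly 3.7 transitions per 20-frame
#' window). The ear tag is a 7.0 cm fiducial.
#'
#' @param scale_px_per_cm Pixels per centimeter, > 0. Default 12.
#' @param nostril_distance_cm True nostril separation in cm. Default 5.93.
#' @param eye_opening_cm Named `c(left = , right = )` eye openings in cm.
#' @param ear_front_angle_deg Mean ear angle in the frontward state,
#'   <= 90. Default 60.
#' @param ear_back_angle_deg Mean ear angle in the backward state,
#'   > 90. Default 120.
#' @param angle_jitter_sd_deg SD of per-frame Gaussian angle jitter.
#'   Default 5.
#' @param p_front_to_back,p_back_to_front Per-frame Markov transition
#'   probabilities. Defaults 0.153 and 0.274.
#' @param keypoint_noise_sd_px Isotropic Gaussian keypoint noise SD in
#'   pixels. Default 1.
#' @param tag_size_cm Physical ear-tag size in cm. Default 7.
#' @param n_frames Number of frames. Default 100.
#' @param frame_rate Frames per second. Default 1.
#' @param seed Integer RNG seed. Default 1.
#' @return A list of class `head_model_params`.
#' @export
head_model_params <- function(scale_px_per_cm = 12,
                              nostril_distance_cm = 5.93,
                              eye_opening_cm = c(left = 2.75, right = 2.76),
                              ear_front_angle_deg = 60,
                              ear_back_angle_deg = 120,
                              angle_jitter_sd_deg = 5,
                              p_front_to_back = 0.153,
                              p_back_to_front = 0.274,
                              keypoint_noise_sd_px = 1,
                              tag_size_cm = 7,
                              n_frames = 100L,
                              frame_rate = 1,
                              seed = 1L) {
  p <- list(
    scale_px_per_cm = scale_px_per_cm,
    nostril_distance_cm = nostril_distance_cm,
    eye_opening_cm = eye_opening_cm,
    ear_front_angle_deg = ear_front_angle_deg,
    ear_back_angle_deg = ear_back_angle_deg,
    angle_jitter_sd_deg = angle_jitter_sd_deg,
    p_front_to_back = p_front_to_back,
    p_back_to_front = p_back_to_front,
    keypoint_noise_sd_px = keypoint_noise_sd_px,
    tag_size_cm = tag_size_cm,
    n_frames = as.integer(n_frames),
    frame_rate = frame_rate,
    seed = as.integer(seed)
  )
  check_pos <- c(
    "scale_px_per_cm", "nostril_distance_cm", "tag_size_cm",
    "n_frames", "frame_rate"
  )
  for (nm in check_pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be > 0", call. = FALSE)
    }
  }
  if (any(!is.finite(p$eye_opening_cm)) || any(p$eye_opening_cm <= 0) ||
    !all(c("left", "right") %in% names(p$eye_opening_cm))) {
    stop("parameter 'eye_opening_cm' needs positive left and right entries",
      call. = FALSE
    )
  }
  for (nm in c("p_front_to_back", "p_back_to_front")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      stop("parameter '", nm, "' must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (!(p$ear_front_angle_deg <= 90 && 90 < p$ear_back_angle_deg)) {
    stop("parameter 'ear_front_angle_deg' must be <= 90 < 'ear_back_angle_deg'",
      call. = FALSE
    )
  }
  if (p$angle_jitter_sd_deg < 0 || p$keypoint_noise_sd_px < 0) {
    stop("parameter 'angle_jitter_sd_deg'/'keypoint_noise_sd_px' must be >= 0",
      call. = FALSE
    )
  }
  structure(p, class = "head_model_params")
}

# fixed head template in cm; origin between the eyes, y increases downward
# (image convention). Ears sit above/outside the eyes, nostrils below.
head_template_cm <- function(p) {
  half_nostril <- p$nostril_distance_cm / 2
  rbind(
    left_ear_base = c(-6, -1),
    right_ear_base = c(6, -1),
    left_eye_top = c(-4, 0),
    left_eye_bottom = c(-4, p$eye_opening_cm[["left"]]),
    right_eye_top = c(4, 0),
    right_eye_bottom = c(4, p$eye_opening_cm[["right"]]),
    left_nostril = c(-half_nostril, 8),
    right_nostril = c(half_nostril, 8)
  )
}

ear_length_cm <- 7 # base-to-tip length of the template ear

# place the ear tip so the (tip, base, eye_top) angle at the base equals
# `angle_deg`: rotate the unit base->eye vector by +/- the angle (left ear
# rotates clockwise in image coordinates, right counter-clockwise, so the
# tips point outward and mirror symmetry holds exactly).
ear_tip_cm <- function(base, eye_top, angle_deg, side) {
  u <- (eye_top - base) / sqrt(sum((eye_top - base)^2))
  th <- angle_deg * pi / 180 * if (side == "left") -1 else 1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  base + ear_length_cm * as.vector(rot %*% u)
}

# simulate a two-state chain; returns character vector of "front"/"back"
simulate_ear_chain <- function(n, p_fb, p_bf, init = "front") {
  states <- character(n)
  s <- init
  for (i in seq_len(n)) {
    states[i] <- s
    if (s == "front") {
      if (stats::runif(1) < p_fb) s <- "back"
    } else {
      if (stats::runif(1) < p_bf) s <- "front"
    }
  }
  states
}

#' Simulate a calf-head keypoint trajectory with known ground truth
#'
#' Stand-in for farm video that is not publicly deposited: emits
#' per-frame 10-keypoint calf-face records at the configured frame rate.
#' Each frame is built from a fixed head template in cm (nostrils
#' `nostril_distance_cm` apart, eyelid landmarks separated by the eye
#' openings, fixed ear bases, ear tips rotated about the bases so the
#' tip-base-eye angle equals the current posture state's mean angle plus
#' Gaussian jitter). Each ear follows its own two-state Markov chain.
#' The template is scaled to pixels, translated to the image center with
#' small global jitter, and perturbed with isotropic Gaussian keypoint
#' noise. The ear-tag fiducial extent is emitted as
#' `tag_size_cm * scale_px_per_cm` pixels.
#'
#' @param params A [head_model_params()].
#' @param animal_id,session_id Identifiers stored on the trajectory.
#' @param image_size Image `(width, height)` in pixels. Default 640x640.
#' @return A list: `trajectory` (a [kp_trajectory()]), `tag_extent_px`,
#'   and `truth` — per-frame true keypoints, true ear states and angles,
#'   true trait values in cm, and `params`.
#' @export
simulate_trajectory <- function(params = head_model_params(),
                                animal_id = "sim_calf",
                                session_id = "sim_session",
                                image_size = c(640, 640)) {
  stopifnot(inherits(params, "head_model_params"))
  old_seed <- set_local_seed(params$seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  n <- params$n_frames
  tmpl <- head_template_cm(params)
  states_left <- simulate_ear_chain(n, params$p_front_to_back, params$p_back_to_front)
  states_right <- simulate_ear_chain(n, params$p_front_to_back, params$p_back_to_front)
  angle_of <- function(state) {
    if (state == "front") params$ear_front_angle_deg else params$ear_back_angle_deg
  }
  schema <- calf_face_schema()
  center <- image_size / 2
  frames <- vector("list", n)
  true_angles <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("left", "right")))
  true_points <- vector("list", n)
  for (i in seq_len(n)) {
    ang_l <- angle_of(states_left[i]) + stats::rnorm(1, 0, params$angle_jitter_sd_deg)
    ang_r <- angle_of(states_right[i]) + stats::rnorm(1, 0, params$angle_jitter_sd_deg)
    ang_l <- min(180, max(0, ang_l))
    ang_r <- min(180, max(0, ang_r))
    true_angles[i, ] <- c(ang_l, ang_r)
    pts_cm <- rbind(
      tmpl,
      left_ear_tip = ear_tip_cm(
        tmpl["left_ear_base", ], tmpl["left_eye_top", ], ang_l, "left"
      ),
      right_ear_tip = ear_tip_cm(
        tmpl["right_ear_base", ], tmpl["right_eye_top", ], ang_r, "right"
      )
    )[schema$names, ]
    shift <- center + stats::rnorm(2, 0, 2) # global camera/head jitter, px
    pts_px <- pts_cm * params$scale_px_per_cm
    pts_px <- sweep(pts_px, 2, shift, `+`)
    true_points[[i]] <- pts_px
    noisy <- pts_px + matrix(
      stats::rnorm(2L * nrow(pts_px), 0, params$keypoint_noise_sd_px),
      ncol = 2
    )
    pad <- 5
    bbox <- c(
      min(noisy[, 1]) - pad, min(noisy[, 2]) - pad,
      diff(range(noisy[, 1])) + 2 * pad, diff(range(noisy[, 2])) + 2 * pad
    )
    frames[[i]] <- kp_frame(
      frame_index = i - 1L, points = noisy,
      visibility = stats::setNames(rep(2L, nrow(noisy)), rownames(noisy)),
      image_size = image_size, bbox = bbox, schema = schema
    )
  }
  traj <- kp_trajectory(animal_id, session_id, frames, params$frame_rate)
  tag_extent_px <- params$tag_size_cm * params$scale_px_per_cm

  pos_of <- function(states) ifelse(states == "front", "frontward", "backward")
  truth <- list(
    params = params,
    states = data.frame(
      frame_index = seq_len(n) - 1L,
      left = states_left, right = states_right,
      stringsAsFactors = FALSE
    ),
    angles = true_angles,
    points = true_points,
    positions = list(left = pos_of(states_left), right = pos_of(states_right)),
    traits = list(
      nostril_distance_cm = params$nostril_distance_cm,
      eye_opening_cm = params$eye_opening_cm
    )
  )
  list(trajectory = traj, tag_extent_px = tag_extent_px, truth = truth)
}

#' Corrupt a trajectory's keypoints
#'
#' Supplies the "predicted" side for OKS experiments: each visible
#' keypoint is displaced by isotropic Gaussian noise and dropped
#' (visibility set to 0) independently with `drop_prob`.
#'
#' @param traj A [kp_trajectory()].
#' @param displacement_sd_px Gaussian displacement SD in pixels, >= 0.
#' @param drop_prob Per-keypoint drop probability in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return A new [kp_trajectory()].
#' @export
corrupt_keypoints <- function(traj, displacement_sd_px, drop_prob = 0, seed = 1L) {
  stopifnot(inherits(traj, "kp_trajectory"))
  if (!is.finite(displacement_sd_px) || displacement_sd_px < 0) {
    stop("displacement_sd_px must be >= 0", call. = FALSE)
  }
  if (drop_prob < 0 || drop_prob > 1) {
    stop("drop_prob must be in [0, 1]", call. = FALSE)
  }
  old_seed <- set_local_seed(as.integer(seed))
  on.exit(restore_seed(old_seed), add = TRUE)
  frames <- lapply(traj$frames, function(f) {
    n <- nrow(f$points)
    pts <- f$points + matrix(stats::rnorm(2L * n, 0, displacement_sd_px), ncol = 2)
    vis <- f$visibility
    dropped <- vis > 0L & stats::runif(n) < drop_prob
    vis[dropped] <- 0L
    kp_frame(
      frame_index = f$frame_index, points = pts, visibility = vis,
      image_size = f$image_size, bbox = f$bbox, schema = f$schema
    )
  })
  kp_trajectory(traj$animal_id, traj$session_id, frames, traj$frame_rate)
}

# seed handling that restores the caller's RNG state
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
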