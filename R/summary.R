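#' Train/predict holdout counts
#'
#' Nearest-integer rounding of `total * train_fraction` for the training
#' count; the remainder is retained for prediction. With 6,702 images
#' and a 10% selection this gives 670 training and 6,032 prediction
#' images.
#'
#' @param total Total image count, > 0.
#' @param train_fraction Training proportion in (0, 1).
#' @return A named vector `c(train = , predict = )`.
#' @export
#' @examples
#' holdout_count(6702, 0.10)
holdout_count <- function(total, train_fraction) {
  if (!is.finite(total) || total <= 0) stop("total must be > 0", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  train <- round(total * train_fraction)
  c(train = train, predict = total - train)
}

#' Animal-grouped train/validation/test split
#'
#' Assigns whole animals to subsets so that image-count proportions
#' approximate the targets while no animal (and hence no image) spans
#' two subsets — preventing identity leakage between training and
#' evaluation. Animals are shuffled deterministically by the seed, then
#' assigned greedily to the subset with the largest remaining image
#' deficit.
#'
#' @param units A data.frame with columns `image_id` and `animal_id`.
#' @param fractions Named numeric proportions summing to 1, e.g.
#'   `c(train = 0.70, val = 0.15, test = 0.15)`.
#' @param seed Integer seed making the assignment reproducible.
#' @return A data.frame with columns `image_id`, `animal_id`, `subset`.
#' @export
group_split <- function(units,
                        fractions = c(train = 0.70, val = 0.15, test = 0.15),
                        seed = 1L) {
  stopifnot(
    is.data.frame(units),
    all(c("image_id", "animal_id") %in% names(units))
  )
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("subset fractions must sum to 1", call. = FALSE)
  }
  animals <- unique(as.character(units$animal_id))
  if (length(animals) < length(fractions)) {
    stop(
      "infeasible split: ", length(animals), " animals for ",
      length(fractions), " subsets",
      call. = FALSE
    )
  }
  old_seed <- set_local_seed(as.integer(seed))
  on.exit(restore_seed(old_seed), add = TRUE)
  animals <- sample(animals)
  n_img <- table(as.character(units$animal_id))[animals]
  total <- sum(n_img)
  target <- fractions * total
  assigned <- stats::setNames(numeric(length(fractions)), names(fractions))
  subset_of <- character(length(animals))
  names(subset_of) <- animals
  # seed each subset with one animal so none ends up empty, then greedily
  # fill the largest remaining deficit
  for (i in seq_along(animals)) {
    deficit <- target - assigned
    if (i <= length(fractions)) {
      empty <- names(assigned)[assigned == 0 & !names(assigned) %in% subset_of]
      pick <- if (length(empty)) {
        empty[which.max(deficit[empty])]
      } else {
        names(which.max(deficit))
      }
    } else {
      pick <- names(which.max(deficit))
    }
    subset_of[animals[i]] <- pick
    assigned[pick] <- assigned[pick] + n_img[[animals[i]]]
  }
  data.frame(
    image_id = units$image_id,
    animal_id = units$animal_id,
    subset = unname(subset_of[as.character(units$animal_id)]),
    stringsAsFactors = FALSE
  )
}

#' Descriptive summary of one trait
#'
#' Minimum, arithmetic mean, maximum, sample standard deviation (n - 1
#' denominator) and coefficient of variation `CV = 100 * sd / mean` (in
#' percent; `cv_display` rounds to the nearest integer for reporting).
#' CV is undefined (missing) for a non-positive mean.
#'
#' @param values Numeric values; `NA`s are dropped. At least two
#'   non-missing values are needed for the SD.
#' @param item Trait name for the row.
#' @return A one-row data.frame: item, minimum, mean, maximum, sd,
#'   cv_percent, cv_display.
#' @export
#' @examples
#' # CV reconstruction from summary-level mean and SD:
#' 100 * 0.82 / 5.93 # nostril distance -> ~14%
summarize_trait <- function(values, item = "trait") {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarize for '", item, "'", call. = FALSE)
  if (length(values) < 2L) {
    stop("need at least 2 values for the SD of '", item, "'", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  cv <- if (m > 0) 100 * s / m else NA_real_
  data.frame(
    item = item,
    minimum = min(values),
    mean = m,
    maximum = max(values),
    sd = s,
    cv_percent = cv,
    cv_display = if (is.na(cv)) NA_real_ else round(cv),
    stringsAsFactors = FALSE
  )
}

#' Coefficient of variation from a printed mean and SD
#'
#' Reconstructs the integer CV (%) reported in descriptive tables from
#' their mean and SD columns.
#'
#' @param mean,sd Summary-level mean (> 0) and SD (>= 0).
#' @return Integer percent, `round(100 * sd / mean)`.
#' @export
cv_from_mean_sd <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  round(100 * sd / mean)
}

#' Session-level phenotype record
#'
#' Aggregates the per-frame traits of one trajectory into one row:
#' mean distances in cm over defined frames, per-ear time budgets, and
#' pooled (both ears) per-window movement counts under the
#' 20-consecutive-frame rule.
#'
#' @param traj A [kp_trajectory()].
#' @param cal A [scale_calibration()] or `NULL` for pixel units.
#' @param min_window Minimum consecutive frames for movement windows.
#' @return A one-row data.frame.
#' @export
session_phenotypes <- function(traj, cal = NULL, min_window = 20L) {
  per_frame <- extract_trajectory_phenotypes(traj, cal)
  fr <- traj$frame_rate
  budget_l <- time_in_position(per_frame$left_ear_position, fr)
  budget_r <- time_in_position(per_frame$right_ear_position, fr)
  wins <- rbind(
    ear_window_stats(per_frame$left_ear_position, fr, min_window),
    ear_window_stats(per_frame$right_ear_position, fr, min_window)
  )
  data.frame(
    animal_id = traj$animal_id,
    session_id = traj$session_id,
    n_frames = length(traj$frames),
    nostril_distance_cm = mean(per_frame$nostril_distance_cm, na.rm = TRUE),
    eye_opening_left_cm = mean(per_frame$eye_opening_left_cm, na.rm = TRUE),
    eye_opening_right_cm = mean(per_frame$eye_opening_right_cm, na.rm = TRUE),
    time_front_left_s = budget_l$time_front,
    time_back_left_s = budget_l$time_back,
    time_front_right_s = budget_r$time_front,
    time_back_right_s = budget_r$time_back,
    ear_movement_count = if (nrow(wins)) mean(wins$n_transitions) else NA_real_,
    n_movement_windows = nrow(wins),
    stringsAsFactors = FALSE
  )
}

#' Descriptive trait summary across movement windows and frames
#'
#' Builds the six-row descriptive table of the extracted facial traits:
#' nostril distance, right and left eye opening (per frame, cm), time in
#' front and back position and ear movements (per qualifying 20-frame
#' window, both ears pooled).
#'
#' @param traj A [kp_trajectory()].
#' @param cal A [scale_calibration()] or `NULL`.
#' @param min_window Minimum consecutive frames per movement window.
#' @return A data.frame with one [summarize_trait()] row per trait.
#' @export
phenotype_summary <- function(traj, cal = NULL, min_window = 20L) {
  per_frame <- extract_trajectory_phenotypes(traj, cal)
  fr <- traj$frame_rate
  wins <- rbind(
    ear_window_stats(per_frame$left_ear_position, fr, min_window),
    ear_window_stats(per_frame$right_ear_position, fr, min_window)
  )
  rows <- list(
    summarize_trait(per_frame$nostril_distance_cm, "Nostril distance (cm)"),
    summarize_trait(per_frame$eye_opening_right_cm, "Eye right opening (cm)"),
    summarize_trait(per_frame$eye_opening_left_cm, "Eye left opening (cm)")
  )
  if (nrow(wins) >= 2L) {
    rows <- c(rows, list(
      summarize_trait(wins$time_front_s, "Time ear front position (s)"),
      summarize_trait(wins$time_back_s, "Time ear back position (s)"),
      summarize_trait(wins$n_transitions, "Ear movement (no. of times)")
    ))
  }
  do.call(rbind, rows)
}

#' Run the full phenotyping (and optional evaluation) pipeline
#'
#' Deterministic end-to-end driver: reads or simulates trajectories,
#' extracts per-frame and session phenotypes, writes `phenotypes.csv`
#' and `summary.csv` (and `eval_report.csv` in evaluation mode), plus a
#' plain-text run log recording inputs, settings and frame counts.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   `mode` ("phenotype", "evaluate" or "both"); `out_dir`; either
#'   `trajectories` (list of [kp_trajectory()]) or `input` (COCO JSON
#'   path, one trajectory per file); `tag_size_cm` and `tag_extent_px`
#'   for calibration (omit both for pixel-only traits); `min_window`
#'   (default 20); and for evaluation `pred_trajectories` (or
#'   `displacement_sd_px` + `seed` to corrupt the inputs) and `kappas`.
#' @return Invisibly, a list with `phenotypes`, `summary` and (when
#'   evaluated) `eval` — the objects written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- match.arg(config$mode %||% "phenotype", c("phenotype", "evaluate", "both"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  trajs <- config$trajectories
  if (is.null(trajs)) {
    if (is.null(config$input)) {
      stop("config must name 'trajectories' or 'input' before any computation",
        call. = FALSE
      )
    }
    paths <- config$input
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input files not found: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    trajs <- lapply(paths, function(p) {
      recs <- read_coco_keypoints(p)
      kp_trajectory(
        animal_id = tools::file_path_sans_ext(basename(p)),
        session_id = "s1",
        frames = lapply(recs, `[[`, "frame"),
        frame_rate = config$frame_rate %||% 1
      )
    })
  }
  cal <- NULL
  if (!is.null(config$tag_size_cm) && !is.null(config$tag_extent_px)) {
    cal <- scale_calibration(config$tag_size_cm, config$tag_extent_px)
  }
  min_window <- config$min_window %||% 20L

  result <- list()
  log_lines <- c(
    paste0("calfface run ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("mode: ", mode),
    paste0("trajectories: ", length(trajs)),
    paste0(
      "frames: ",
      paste(vapply(trajs, function(t) length(t$frames), integer(1)), collapse = ",")
    ),
    paste0("calibration: ", if (is.null(cal)) {
      "none (pixel units)"
    } else {
      sprintf("%.4f cm/px", cal$cm_per_px)
    }),
    paste0("min_window: ", min_window)
  )

  if (mode %in% c("phenotype", "both")) {
    phen <- do.call(rbind, lapply(trajs, session_phenotypes,
      cal = cal, min_window = min_window
    ))
    summ <- do.call(rbind, lapply(seq_along(trajs), function(i) {
      s <- phenotype_summary(trajs[[i]], cal = cal, min_window = min_window)
      s$animal_id <- trajs[[i]]$animal_id
      s$session_id <- trajs[[i]]$session_id
      s
    }))
    write_phenotype_table(phen, file.path(out_dir, "phenotypes.csv"))
    utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    result$phenotypes <- phen
    result$summary <- summ
    skipped <- sum(vapply(trajs, function(t) {
      pf <- extract_trajectory_phenotypes(t, cal)
      sum(!stats::complete.cases(pf[, c(
        "left_ear_position", "right_ear_position",
        "nostril_distance_cm"
      )]))
    }, numeric(1)))
    log_lines <- c(log_lines, paste0(
      "frames with missing traits (absent keypoints): ", skipped
    ))
  }

  if (mode %in% c("evaluate", "both")) {
    preds <- config$pred_trajectories
    if (is.null(preds)) {
      if (is.null(config$displacement_sd_px)) {
        stop("evaluation needs 'pred_trajectories' or 'displacement_sd_px'",
          call. = FALSE
        )
      }
      preds <- lapply(trajs, corrupt_keypoints,
        displacement_sd_px = config$displacement_sd_px,
        drop_prob = config$drop_prob %||% 0,
        seed = config$seed %||% 1L
      )
    }
    pairs <- unlist(lapply(seq_along(trajs), function(i) {
      lapply(seq_along(trajs[[i]]$frames), function(j) {
        list(pred = preds[[i]]$frames[[j]], truth = trajs[[i]]$frames[[j]])
      })
    }), recursive = FALSE)
    ev <- evaluate_keypoints(pairs, kappas = config$kappas %||% 0.05)
    write_eval_report(ev, file.path(out_dir, "eval_report.csv"))
    result$eval <- ev
    log_lines <- c(log_lines, sprintf(
      "evaluation: %d pairs, AP %.4f, AR %.4f, F1 %.4f",
      length(pairs), ev$ap_mean, ev$ar_mean, ev$f1
    ))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
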