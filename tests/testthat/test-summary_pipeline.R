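test_that("holdout counts round to the nearest image and always sum back", {
  expect_identical(holdout_count(6702, 0.10), c(train = 670, predict = 6032))
  expect_identical(holdout_count(10, 0.5), c(train = 5, predict = 5))
  set.seed(8)
  for (i in 1:100) {
    total <- sample(1:10000, 1)
    frac <- runif(1, 0.01, 0.99)
    h <- holdout_count(total, frac)
    expect_identical(unname(h["train"] + h["predict"]), as.numeric(total))
  }
  expect_error(holdout_count(0, 0.1), "> 0")
  expect_error(holdout_count(10, 1), "\\(0, 1\\)")
})

test_that("group_split keeps every animal in one subset at target proportions", {
  units <- data.frame(
    image_id = sprintf("img%03d", 1:100),
    animal_id = rep(sprintf("calf%02d", 1:10), each = 10)
  )
  sp <- group_split(units, c(train = 0.7, val = 0.15, test = 0.15), seed = 42)
  expect_identical(nrow(sp), 100L)
  expect_identical(anyDuplicated(sp$image_id), 0L)
  per_animal <- tapply(sp$subset, sp$animal_id, function(s) length(unique(s)))
  expect_true(all(per_animal == 1))
  counts <- table(sp$subset)
  expect_true(all(c("train", "val", "test") %in% names(counts)))
  # with 10 equal animals the feasible allocation nearest 70/15/15 is 7/1.5/1.5
  expect_equal(unname(counts[["train"]]), 70, tolerance = 10)
  expect_gte(counts[["val"]], 10)
  expect_gte(counts[["test"]], 10)
})

test_that("group_split is deterministic in the seed and checks feasibility", {
  units <- data.frame(
    image_id = as.character(1:60),
    animal_id = rep(letters[1:6], times = c(20, 15, 10, 8, 4, 3))
  )
  a <- group_split(units, seed = 7)
  b <- group_split(units, seed = 7)
  expect_identical(a, b)
  sp1 <- group_split(units, c(all = 1), seed = 1)
  expect_true(all(sp1$subset == "all"))
  expect_error(
    group_split(units[1:3, ], c(a = 0.25, b = 0.25, c = 0.25, d = 0.25)),
    "infeasible"
  )
  expect_error(group_split(units, c(train = 0.6, test = 0.2)), "sum to 1")
})

test_that("summarize_trait matches brute-force statistics before rounding", {
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(sample(2:200, 1), mean = runif(1, 1, 20), sd = runif(1, 0.1, 3))
    row <- summarize_trait(x, "t")
    expect_equal(row$minimum, min(x), tolerance = 1e-9)
    expect_equal(row$mean, sum(x) / length(x), tolerance = 1e-9)
    expect_equal(row$maximum, max(x), tolerance = 1e-9)
    expect_equal(row$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
      tolerance = 1e-9
    )
    if (row$mean > 0) {
      expect_equal(row$cv_percent, 100 * row$sd / row$mean, tolerance = 1e-9)
    }
    expect_true(row$minimum <= row$mean && row$mean <= row$maximum)
  }
  cst <- summarize_trait(rep(4.2, 10), "const")
  expect_equal(cst$sd, 0)
  expect_equal(cst$cv_percent, 0)
  neg <- summarize_trait(c(-2, 0, 2, 0), "zero-mean")
  expect_true(is.na(neg$cv_percent))
  expect_error(summarize_trait(numeric(0)), "no values")
  expect_error(summarize_trait(5), "at least 2")
})

test_that("integer CVs are reconstructed from summary-level mean and SD", {
  expect_identical(cv_from_mean_sd(5.93, 0.82), 14)
  expect_identical(cv_from_mean_sd(2.76, 0.40), 14)
  expect_identical(cv_from_mean_sd(5.43, 1.05), 19)
  expect_identical(cv_from_mean_sd(3.73, 0.79), 21)
})

test_that("session phenotypes aggregate frames, budgets and pooled windows", {
  sim <- simulate_trajectory(head_model_params(n_frames = 100, seed = 12))
  cal <- scale_calibration(7, sim$tag_extent_px)
  row <- session_phenotypes(sim$trajectory, cal)
  expect_identical(nrow(row), 1L)
  expect_identical(row$n_frames, 100L)
  expect_equal(row$time_front_left_s + row$time_back_left_s, 100)
  expect_identical(row$n_movement_windows, 10L) # 5 tumbling windows x 2 ears
  summ <- phenotype_summary(sim$trajectory, cal)
  expect_identical(summ$item, c(
    "Nostril distance (cm)", "Eye right opening (cm)", "Eye left opening (cm)",
    "Time ear front position (s)", "Time ear back position (s)",
    "Ear movement (no. of times)"
  ))
  tf <- summ[summ$item == "Time ear front position (s)", ]
  tb <- summ[summ$item == "Time ear back position (s)", ]
  expect_equal(tf$mean + tb$mean, 20) # per-window conservation at 1 fps
})

test_that("the pipeline writes deterministic tables and a run log", {
  sim <- simulate_trajectory(head_model_params(n_frames = 60, seed = 20))
  cfg <- list(
    mode = "both", trajectories = list(sim$trajectory),
    tag_size_cm = 7, tag_extent_px = sim$tag_extent_px,
    displacement_sd_px = 3, seed = 21
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg$out_dir <- d1
  r1 <- run_pipeline(cfg)
  cfg$out_dir <- d2
  r2 <- run_pipeline(cfg)
  for (f in c("phenotypes.csv", "summary.csv", "eval_report.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    )
  }
  expect_true(file.exists(file.path(d1, "run_log.txt")))
  expect_identical(nrow(r1$phenotypes), 1L)
  expect_identical(r1$phenotypes, r2$phenotypes)
  expect_true(r1$eval$ap_mean <= 1)
})

test_that("evaluate mode on identical predictions yields a perfect report", {
  sim <- simulate_trajectory(head_model_params(n_frames = 25, seed = 30))
  d <- withr::local_tempdir()
  res <- run_pipeline(list(
    mode = "evaluate", trajectories = list(sim$trajectory),
    pred_trajectories = list(sim$trajectory), out_dir = d
  ))
  expect_equal(res$eval$ap_mean, 1)
  expect_equal(res$eval$ar_mean, 1)
})

test_that("the pipeline reads COCO input files and validates configuration", {
  sim <- simulate_trajectory(head_model_params(n_frames = 30, seed = 33))
  jf <- withr::local_tempfile(fileext = ".json")
  write_coco_keypoints(sim$trajectory$frames, jf)
  d <- withr::local_tempdir()
  res <- run_pipeline(list(
    mode = "phenotype", input = jf, out_dir = d,
    tag_size_cm = 7, tag_extent_px = sim$tag_extent_px
  ))
  expect_equal(res$phenotypes$nostril_distance_cm, 5.93, tolerance = 0.05)
  expect_error(run_pipeline(list(mode = "phenotype", out_dir = d)), "trajectories")
  expect_error(
    run_pipeline(list(mode = "phenotype", input = "no_such.json", out_dir = d)),
    "not found"
  )
})
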