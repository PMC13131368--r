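test_that("OKS is 1 at zero displacement and matches the closed form", {
  truth <- make_full_frame(seed = 1)
  expect_equal(compute_oks(truth, truth)$oks, 1)

  # single visible keypoint: OKS = exp(-d^2 / (2 s^2 k^2))
  s2 <- 300 * 200
  k <- 0.05
  truth1 <- make_frame(list(left_nostril = c(100, 100)))
  for (d in c(0.5, 3, 10, 25)) {
    pred1 <- make_frame(list(left_nostril = c(100 + d, 100)))
    rec <- compute_oks(pred1, truth1, kappas = k, area = s2)
    expect_equal(rec$oks, exp(-d^2 / (2 * s2 * k^2)), tolerance = 1e-12)
    expect_identical(rec$n_visible, 1L)
  }
  # d^2 = 2 s^2 k^2 -> e^-1
  d <- sqrt(2 * s2 * k^2)
  pred1 <- make_frame(list(left_nostril = c(100 + d, 100)))
  expect_equal(compute_oks(pred1, truth1, kappas = k, area = s2)$oks,
    exp(-1),
    tolerance = 1e-9
  )
})

test_that("one perfect and one very distant keypoint average to 0.5", {
  truth <- make_frame(list(
    left_nostril = c(100, 100), right_nostril = c(150, 100)
  ))
  pred <- make_frame(list(
    left_nostril = c(100, 100), right_nostril = c(1e7, 1e7)
  ))
  expect_equal(compute_oks(pred, truth, area = 1e4)$oks, 0.5, tolerance = 1e-12)
})

test_that("keypoints absent in the truth are excluded from both sums", {
  truth <- make_frame(list(
    left_nostril = c(100, 100), right_nostril = c(150, 100)
  ))
  pred <- make_frame(list(
    left_nostril = c(100, 100), right_nostril = c(150, 100)
  ))
  # hide one truth keypoint and move its prediction far away: no effect
  truth$visibility[["right_nostril"]] <- 0L
  pred$points["right_nostril", ] <- c(5000, 5000)
  rec <- compute_oks(pred, truth, area = 1e4)
  expect_equal(rec$oks, 1)
  expect_identical(rec$n_visible, 1L)
  expect_true(is.na(rec$per_keypoint_terms[["right_nostril"]]))
})

test_that("OKS errors on zero visible keypoints and non-positive area", {
  truth <- make_full_frame()
  truth$visibility[] <- 0L
  pred <- make_full_frame()
  expect_error(compute_oks(pred, truth, area = 100), "no visible")
  expect_error(compute_oks(pred, make_full_frame(), area = 0), "positive")
})

test_that("OKS is invariant to joint translation and to uniform rescaling", {
  set.seed(42)
  for (rep in 1:200) {
    truth <- make_full_frame(seed = rep)
    pred <- corrupt_keypoints(
      kp_trajectory("a", "s", list(truth)), 4,
      seed = rep
    )$frames[[1]]
    base <- compute_oks(pred, truth)$oks
    # joint translation
    tr <- runif(2, -50, 50)
    t2 <- truth
    p2 <- pred
    t2$points <- sweep(t2$points, 2, tr, `+`)
    p2$points <- sweep(p2$points, 2, tr, `+`)
    t2$bbox[1:2] <- t2$bbox[1:2] + tr
    expect_equal(compute_oks(p2, t2)$oks, base, tolerance = 1e-12)
    # uniform rescale of coordinates and sqrt(area)
    lam <- runif(1, 0.2, 5)
    t3 <- truth
    p3 <- pred
    t3$points <- t3$points * lam
    p3$points <- p3$points * lam
    t3$bbox <- t3$bbox * lam
    expect_equal(compute_oks(p3, t3)$oks, base, tolerance = 1e-9)
  }
})

test_that("OKS strictly decreases as one keypoint's displacement grows", {
  truth <- make_full_frame(seed = 9)
  d <- seq(0, 40, by = 5)
  scores <- vapply(d, function(dd) {
    pred <- truth
    pred$points["left_ear_tip", 1] <- pred$points["left_ear_tip", 1] + dd
    compute_oks(pred, truth)$oks
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("threshold classification follows the within-threshold (>=) rule", {
  m <- classify_at_threshold(c(0.9, 0.8, 0.6), 0.75)
  expect_identical(m$tp, 2L)
  expect_identical(m$fp, 1L)
  expect_equal(m$precision, 2 / 3)

  expect_equal(classify_at_threshold(c(0.3, 0.6), 0)$precision, 1)
  # a score exactly at the threshold is a true positive
  expect_identical(classify_at_threshold(c(0.75, 0.5), 0.75)$tp, 1L)
  expect_error(classify_at_threshold(numeric(0), 0.5), "no OKS scores")
  expect_error(classify_at_threshold(0.5, 1.2), "\\[0, 1\\]")
})

test_that("precision is non-increasing in the threshold for a fixed score set", {
  set.seed(11)
  scores <- runif(200)
  prec <- vapply(
    seq(0, 1, by = 0.05),
    function(t) classify_at_threshold(scores, t)$precision, numeric(1)
  )
  expect_true(all(diff(prec) <= 1e-12))
})

test_that("evaluate matches brute-force enumeration per threshold", {
  sim <- simulate_trajectory(head_model_params(n_frames = 40, seed = 3))
  pred <- corrupt_keypoints(sim$trajectory, displacement_sd_px = 6, seed = 4)
  pairs <- lapply(seq_len(40), function(i) {
    list(pred = pred$frames[[i]], truth = sim$trajectory$frames[[i]])
  })
  ev <- evaluate_keypoints(pairs)
  scores <- vapply(pairs, function(p) compute_oks(p$pred, p$truth)$oks, numeric(1))
  expect_equal(ev$oks, scores)
  taus <- seq(0.5, 0.95, by = 0.05)
  for (i in seq_along(taus)) {
    expect_identical(ev$per_threshold$tp[i], sum(scores >= taus[i]))
    expect_equal(ev$per_threshold$precision[i], mean(scores >= taus[i]))
  }
  expect_equal(ev$ap_mean, mean(vapply(taus, function(t) mean(scores >= t), numeric(1))))
  expect_equal(ev$ap_at[["0.75"]], mean(scores >= 0.75))
  expect_equal(ev$f1, f1_score(ev$ap_mean, ev$ar_mean))
  # perfect predictions give a perfect sweep
  perfect <- lapply(sim$trajectory$frames, function(f) list(pred = f, truth = f))
  evp <- evaluate_keypoints(perfect)
  expect_equal(evp$ap_mean, 1)
  expect_equal(evp$ar_mean, 1)
  expect_equal(evp$f1, 1)
})

test_that("missed truth instances lower recall but not precision", {
  ev <- classify_at_threshold(c(0.9, 0.9, 0.9, 0.2), 0.5, n_truth = 8)
  expect_equal(ev$precision, 3 / 4)
  expect_equal(ev$recall, 3 / 8)
})

test_that("F1 is the harmonic mean with the 0/0 convention", {
  expect_equal(f1_score(0.958, 0.958), 0.958)
  expect_equal(f1_score(1, 0), 0)
  expect_equal(f1_score(0.5, 1), 2 / 3)
  expect_equal(f1_score(0, 0), 0)
  p <- runif(20)
  r <- runif(20)
  f <- mapply(f1_score, p, r)
  expect_true(all(f <= pmax(p, r) + 1e-12) && all(f >= 0))
})

test_that("the evaluation report CSV carries the sweep and the summary row", {
  sim <- simulate_trajectory(head_model_params(n_frames = 10, seed = 5))
  pairs <- lapply(sim$trajectory$frames, function(f) list(pred = f, truth = f))
  ev <- evaluate_keypoints(pairs)
  p <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(ev, p)
  tab <- utils::read.csv(p)
  expect_identical(nrow(tab), 11L) # 10 thresholds + summary
  expect_equal(tab$f1[11], 1)
})
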