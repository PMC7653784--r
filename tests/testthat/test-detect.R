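test_that("scaling selection reproduces the published worked examples", {
  d320 <- select_scaling(320, 227, 0.125)
  expect_equal(d320$operation, "down")
  expect_equal(d320$factor, 0.625)
  expect_equal(d320$scaled_particle, 200)

  d94 <- select_scaling(94, 227, 0.125)
  expect_equal(d94$operation, "up")
  expect_equal(d94$factor, 2.375)

  d221 <- select_scaling(221, 227, 0.125)
  expect_equal(d221$operation, "none")
  expect_equal(cryopickr:::round_half_up(221 * 1.125), 249)

  d188 <- select_scaling(188, 227, 0.125)
  expect_equal(d188$factor, 1.125)
  expect_equal(d188$scaled_particle, 212)

  expect_equal(select_scaling(227, 227, 0.125)$operation, "none")
})

test_that("scaling selection always respects the window bound", {
  set.seed(10)
  for (avg in sample(20:600, 40)) {
    d <- select_scaling(avg, 227, 0.125)
    if (d$operation != "none") {
      expect_lte(d$scaled_particle, 227)
      expect_equal(d$factor %% 0.125, 0)
    }
  }
})

test_that("rescale_and_pad sizes, pads to even, and is identity at 1", {
  m <- matrix(stats::runif(64 * 64), 64)
  up <- rescale_and_pad(m, tibble::tibble(operation = "up", factor = 1.125,
                                          scaled_particle = 0))
  expect_equal(dim(up), c(72, 72))  # 4096 -> 4608 at the same ratio
  odd <- rescale_and_pad(matrix(1, 50, 50), 1.06)  # 53 -> padded 54
  expect_equal(dim(odd), c(54, 54))
  expect_equal(odd[54, 1], 0)      # zero padding
  same <- rescale_and_pad(m, 1)
  expect_equal(same[seq_len(64), seq_len(64)], m)
})

test_that("sliding-window grids have the stated geometry and scores", {
  fit <- toy_fit()
  sim <- simulate_micrograph(width = 96, height = 64, n_particles = 2,
                             particle_size = 24, snr = 1, seed = 5)
  pre <- preprocess_chain(sim$pixels)
  sm <- sliding_window_scores(pre, fit, window = 32, stride = 16)
  expect_equal(dim(sm$scores), c((64 - 32) / 16 + 1, (96 - 32) / 16 + 1,
                                 4))
  expect_true(all(abs(apply(sm$scores, c(1, 2), sum) - 1) < 1e-6))
  # spot-check one position against a direct prediction
  p <- predict_patch(fit, pre[17:48, 33:64])
  expect_equal(sm$scores[2, 3, ], unname(p), tolerance = 1e-12)
  one <- sliding_window_scores(matrix(0.5, 32, 32), fit, 32, 8)
  expect_equal(dim(one$scores)[1:2], c(1, 1))
})

test_that("score-map cleaning thresholds, connects and drops big regions", {
  sm <- structure(list(
    scores = array(0, c(6, 6, 2)), x0 = seq(0, 40, by = 8),
    y0 = seq(0, 40, by = 8), window = 16, stride = 8,
    class_names = c("top_view", "background")), class = "cryo_score_map")
  expect_equal(nrow(clean_score_map(sm, "top_view")), 0)

  sm$scores[3, 4, 1] <- 0.9
  one <- clean_score_map(sm, "top_view")
  expect_equal(nrow(one), 1)
  expect_equal(one$score, 0.9)
  expect_equal(one$x, sm$x0[4])
  expect_equal(one$y, sm$y0[3])

  # a 30-cell smeared region is dropped with a 20-cell cutoff
  smear <- sm
  smear$scores[1:5, 1:6, 1] <- 0.8
  expect_equal(nrow(clean_score_map(smear, "top_view",
                                    max_region_area = 20)), 0)
  # never more candidates than above-threshold cells
  set.seed(6)
  rnd <- sm
  rnd$scores[, , 1] <- matrix(stats::runif(36), 6)
  out <- clean_score_map(rnd, "top_view", score_threshold = 0.5,
                         max_region_area = 100)
  expect_lte(nrow(out), sum(rnd$scores[, , 1] >= 0.5))
  expect_error(clean_score_map(sm, "nope"), "unknown class")
})

test_that("IoU matches its worked cases", {
  expect_equal(box_iou(0, 0, 10, 10, 0, 0, 10, 10), 1)
  expect_equal(box_iou(0, 0, 10, 10, 30, 30, 10, 10), 0)
  expect_equal(box_iou(0, 0, 10, 10, 5, 0, 10, 10), 1 / 3)
})

test_that("greedy NMS equals the quadratic reference on random instances", {
  expect_equal(nrow(nms(random_boxes(0))), 0)
  two <- tibble::tibble(x = c(0, 1), y = c(0, 1), w = 20, h = 20,
                        score = c(0.8, 0.7), label = "p")
  kept <- nms(two, 0.3)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.8)
  set.seed(12)
  for (i in 1:25) {
    cand <- random_boxes(50, labels = c("p", "q"))
    thr <- stats::runif(1, 0.1, 0.7)
    mine <- nms(cand, thr)
    ref <- naive_nms(cand, thr)
    expect_equal(mine[order(mine$label, mine$x, mine$y), ],
                 ref[order(ref$label, ref$x, ref$y), ])
    # output is a subset with pairwise IoU below the threshold per class
    for (cls in unique(mine$label)) {
      mm <- mine[mine$label == cls, ]
      if (nrow(mm) > 1)
        for (a in 1:(nrow(mm) - 1)) for (b in (a + 1):nrow(mm))
          expect_lt(box_iou(mm$x[a], mm$y[a], mm$w[a], mm$h[a],
                            mm$x[b], mm$y[b], mm$w[b], mm$h[b]), thr)
    }
  }
})

test_that("full picking achieves 0.9 precision and recall on synthetic data", {
  fit <- toy_fit()
  for (seed in 1:3) {
    sim <- simulate_micrograph(n_particles = 20, snr = 0.3, seed = 100 + seed)
    s1 <- stage1_pick(sim$pixels, particle_size = 24, shape = "disc")
    avg <- mean(2 * s1$detections$r)
    picks <- pick_particles(sim$pixels, fit, avg_particle = avg,
                            particle_classes = "top_view")
    met <- detection_metrics(match_picks(picks, sim$truth,
                                         match_radius = 12))
    expect_gte(met$precision, 0.9)
    expect_gte(met$recall, 0.9)
  }
})

test_that("a particle-free noise micrograph yields no picks", {
  fit <- toy_fit()
  sim <- simulate_micrograph(n_particles = 0, noise_sigma = 0.63, seed = 9)
  picks <- pick_particles(sim$pixels, fit, avg_particle = 24,
                          particle_classes = "top_view")
  expect_equal(nrow(picks), 0)
})

test_that("picked coordinates map back through the scale factor", {
  fit <- toy_fit()
  sim <- simulate_micrograph(n_particles = 20, snr = 0.3, seed = 101)
  picks <- pick_particles(sim$pixels, fit, avg_particle = 24,
                          particle_classes = "top_view")
  decision <- select_scaling(24, 32, 0.125)
  # re-applying the factor must land every center back on the scaled
  # sliding-window grid (origin window/2, step = stride)
  gx <- (picks$cx * decision$factor - 16) / 8
  gy <- (picks$cy * decision$factor - 16) / 8
  expect_true(all(abs(gx - round(gx)) < 1e-9))
  expect_true(all(abs(gy - round(gy)) < 1e-9))
})
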