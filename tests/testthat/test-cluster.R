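test_that("intensity clustering separates two-level images exactly", {
  sim <- simulate_micrograph(n_particles = 8, seed = 3, noise_sigma = 0)
  norm <- normalize_micrograph(sim$pixels)
  cl <- ibc_cluster(norm, 2)
  expect_identical(cl$mask, sim$clean > sim$background_level + 1e-9)
  # permuting pixel positions cannot change any assignment
  perm <- sample(length(norm))
  cl2 <- ibc_cluster(matrix(norm[perm], nrow(norm)), 2)
  expect_equal(sort(table(cl$labels)), sort(table(cl2$labels)))
  expect_error(ibc_cluster(matrix(0.5, 10, 10), 2), "distinct")
})

test_that("intensity clustering recovers particle pixels at SNR 0.3", {
  sim <- simulate_micrograph(n_particles = 20, snr = 0.3, seed = 1)
  pre <- preprocess_chain(sim$pixels,
                          preprocess_params(morph_radius = 2))
  mask <- ibc_cluster(pre, 2)$mask
  tm <- sim$clean > sim$background_level + 1e-9
  expect_gte(sum(mask & tm) / sum(tm), 0.9)
  jac <- vapply(seq_len(nrow(sim$truth)), function(i) {
    b <- sim$truth[i, ]
    t_ <- tm[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)]
    m_ <- mask[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)]
    sum(t_ & m_) / sum(t_ | m_)
  }, numeric(1))
  expect_true(all(jac >= 0.7))
})

test_that("superpixel clustering masks discs and rejects flat images", {
  sim <- simulate_micrograph(n_particles = 8, seed = 3, noise_sigma = 0)
  norm <- normalize_micrograph(sim$pixels)
  sp <- superpixel_cluster(norm, n_superpixels = 150, k = 2)
  tm <- sim$clean > sim$background_level + 1e-9
  jac <- vapply(seq_len(nrow(sim$truth)), function(i) {
    b <- sim$truth[i, ]
    t_ <- tm[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)]
    m_ <- sp$mask[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)]
    sum(t_ & m_) / sum(t_ | m_)
  }, numeric(1))
  expect_true(all(jac >= 0.7))
  expect_error(superpixel_cluster(matrix(0.5, 50, 50), 100, 2), "distinct")
  expect_error(superpixel_cluster(norm, n_superpixels = 1, k = 2),
               "at least k")
})

test_that("mask cleaning removes small and border objects, never adds", {
  m <- matrix(FALSE, 50, 50)
  m[10:19, 10:19] <- TRUE          # big interior component
  m[30, 30] <- TRUE                # 1-px speck
  m[31, 31] <- TRUE; m[32, 30] <- TRUE  # 3-px speck (8-connected)
  m[1:5, 40:45] <- TRUE            # touches border
  cleaned <- clean_mask(m, min_area = 10, border_margin = 1)
  expect_equal(sum(cleaned), 100)
  expect_identical(clean_mask(m, 0, 0), m)
  n0 <- max(cryopickr:::label_matrix_8(m))
  n1 <- max(cryopickr:::label_matrix_8(cleaned))
  expect_lte(n1, n0)
})

test_that("component labeling is 8-connected and conserves pixels", {
  m <- matrix(FALSE, 30, 30)
  m[5:9, 5:9] <- TRUE
  m[20:24, 20:24] <- TRUE
  comps <- label_components(m)
  expect_length(comps, 2)
  expect_equal(vapply(comps, function(c) c$area, numeric(1)), c(25, 25))
  expect_equal(sum(vapply(comps, function(c) c$area, numeric(1))), sum(m))
  expect_length(label_components(matrix(FALSE, 5, 5)), 0)
  # a diagonal chain is a single 8-connected component
  d <- matrix(FALSE, 10, 10)
  d[cbind(1:5, 1:5)] <- TRUE
  expect_length(label_components(d), 1)
  # centroid falls inside the bounding box
  for (cp in comps) {
    expect_gte(cp$centroid[["x"]], cp$offset[["x"]])
    expect_lte(cp$centroid[["x"]], cp$offset[["x"]] + ncol(cp$mask) - 1)
  }
})

test_that("contour perimeter matches an independent contour tracer", {
  shapes <- list(
    square = {m <- matrix(FALSE, 30, 30); m[10:19, 12:21] <- TRUE; m},
    disc = perfect_circle_mask(30, 30, 12, c(64, 64)),
    bar = {m <- matrix(FALSE, 30, 40); m[15, 5:24] <- TRUE; m})
  for (nm in names(shapes)) {
    comp <- label_components(shapes[[nm]])[[1]]
    expect_equal(comp$perimeter, ocontour_perimeter(shapes[[nm]]),
                 tolerance = 1e-9, info = nm)
  }
})

test_that("circle detection agrees with the full-grid accumulator", {
  mask <- perfect_circle_mask(50, 45, 20, c(100, 100))
  mine <- detect_circles(mask, 10, 30)
  oracle <- brute_cht(mask, 10, 30)
  expect_equal(nrow(mine), 1)
  expect_lte(abs(mine$r[1] - 20), 1)
  expect_lte(sqrt((mine$cx[1] - 50)^2 + (mine$cy[1] - 45)^2), 1)
  expect_lte(sqrt((mine$cx[1] - oracle$cx)^2 + (mine$cy[1] - oracle$cy)^2), 1)
  expect_lte(abs(mine$r[1] - oracle$r), 1)

  expect_equal(nrow(detect_circles(matrix(FALSE, 50, 50), 5, 15)), 0)

  two <- perfect_circle_mask(25, 25, 12, c(100, 100)) |
    perfect_circle_mask(72, 70, 12, c(100, 100))
  found <- detect_circles(two, 8, 16)
  expect_equal(nrow(found), 2)
})

test_that("Feret diameters match the all-pairs projection reference", {
  sq <- matrix(FALSE, 30, 30)
  sq[10:19, 12:21] <- TRUE
  comp <- label_components(sq)[[1]]
  f <- feret_diameters(comp)
  expect_equal(f$max_diameter, 10 * sqrt(2), tolerance = 0.03)
  expect_equal(f$min_diameter, 10, tolerance = 0.03)
  ref <- naive_feret(comp)
  expect_equal(f$max_diameter, ref$max_diameter, tolerance = 0.01)
  expect_equal(f$min_diameter, ref$min_diameter, tolerance = 0.01)

  line <- matrix(FALSE, 10, 30)
  line[5, 5:24] <- TRUE
  fl <- feret_diameters(label_components(line)[[1]])
  expect_equal(fl$max_diameter, 20, tolerance = 0.05)
  expect_equal(fl$min_diameter, 1, tolerance = 0.05)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  fs <- feret_diameters(label_components(single)[[1]])
  expect_equal(fs$max_diameter, 1)

  # rotation invariance within discretization error
  big <- matrix(FALSE, 80, 80)
  big[30:49, 25:44] <- TRUE
  rot <- EBImage::rotate(big * 1, 30) > 0.5
  f0 <- feret_diameters(label_components(big)[[1]])
  f30 <- feret_diameters(label_components(rot)[[1]])
  expect_lte(abs(f30$max_diameter - f0$max_diameter) / f0$max_diameter, 0.03)
})

test_that("fixed-size patch extraction applies the center and border rules", {
  m <- matrix(stats::runif(200 * 200), 200)
  det <- tibble::tibble(cx = c(100, 10), cy = c(100, 100))
  out <- extract_particles(m, det, 50)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 75)
  expect_equal(out$y, 75)
  expect_equal(dim(out$patch[[1]]), c(50, 50))
  expect_error(extract_particles(m, det, 500), "exceeds")
})

test_that("stage-1 recall reaches 0.9 on 20-disc micrographs at SNR 0.3", {
  for (seed in 1:3) {
    sim <- simulate_micrograph(n_particles = 20, snr = 0.3, seed = seed)
    s1 <- stage1_pick(sim$pixels, particle_size = 24, shape = "disc")
    matched <- vapply(seq_len(nrow(sim$truth)), function(i)
      any((s1$detections$cx - sim$truth$cx[i])^2 +
          (s1$detections$cy - sim$truth$cy[i])^2 <= 12^2), logical(1))
    expect_gte(mean(matched), 0.9)
  }
})
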