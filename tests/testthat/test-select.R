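test_that("circularity reproduces the analytic shape identities", {
  r <- 3.7
  expect_equal(circularity(2 * pi * r, pi * r^2), 1)
  s <- 9.1
  expect_equal(circularity(4 * s, s^2), 4 / pi)
  expect_error(circularity(10, 0), "positive")
  # rasterized disc: implementation value equals the independent tracer
  disc <- perfect_circle_mask(32, 32, 30 / 2, c(64, 64))
  comp <- label_components(disc)[[1]]
  expect_equal(circularity_component(comp),
               circularity(ocontour_perimeter(disc), sum(disc)),
               tolerance = 1e-9)
})

test_that("perfect circle masks have the advertised area and symmetry", {
  for (r in c(10, 15, 30)) {
    m <- perfect_circle_mask(40, 40, r, c(81, 81))
    expect_lte(abs(sum(m) - pi * r^2) / (pi * r^2), 0.03)
  }
  m1 <- perfect_circle_mask(2, 2, 1, c(5, 5))
  expect_equal(sum(m1), 5)  # plus-shape rasterization at radius 1
  m <- perfect_circle_mask(20, 20, 8, c(41, 41))
  expect_identical(m, cryopickr:::rotate90(m))
  expect_error(perfect_circle_mask(100, 10, 5, c(50, 50)), "outside")
})

test_that("top-view selection keeps clean discs, rejects deformed masks", {
  masks <- matrix(FALSE, 200, 200)
  for (cx in c(30, 90, 150)) masks <- masks |
    perfect_circle_mask(cx, 40, 15, c(200, 200))
  masks <- masks | perfect_circle_mask(30, 120, 15, c(200, 200))
  masks <- masks | perfect_circle_mask(90, 120, 15, c(200, 200))
  comps <- label_components(masks)
  circles <- detect_circles(masks, 10, 20)
  sel <- select_good_topview(comps, circles)
  expect_true(all(sel$good))
  expect_equal(nrow(sel), length(comps))  # good/bad partitions the input

  # a half disc clipped at the border fails the Jaccard rule
  half <- matrix(FALSE, 120, 120)
  half <- half | perfect_circle_mask(60, 0, 15, c(120, 120))
  half <- half | perfect_circle_mask(40, 60, 15, c(120, 120))
  half <- half | perfect_circle_mask(90, 60, 15, c(120, 120))
  hc <- label_components(half)
  hcirc <- detect_circles(half, 10, 20)
  hsel <- select_good_topview(hc, hcirc)
  clipped_row <- which(vapply(hc, function(c) c$offset[["y"]] == 0,
                              logical(1)))
  expect_false(hsel$good[clipped_row])
  expect_true(all(hsel$good[-clipped_row]))
  expect_lt(hsel$jaccard[clipped_row], 0.8)

  # empty input
  empty <- select_good_topview(list(), hcirc)
  expect_equal(nrow(empty), 0)
})

test_that("selection is invariant to component order", {
  sim <- simulate_micrograph(n_particles = 17, n_clipped = 3, snr = 0.3,
                             seed = 2)
  s1 <- stage1_pick(sim$pixels, particle_size = 24, shape = "disc",
                    keep_clipped = TRUE)
  sel <- select_good_topview(s1$components, s1$detections)
  perm <- rev(seq_along(s1$components))
  sel_p <- select_good_topview(s1$components[perm], s1$detections)
  expect_equal(sel$good[perm], sel_p$good)
})

test_that("side-view selection bands on Feret ratio and removes fusions", {
  m <- matrix(FALSE, 120, 200)
  for (y in c(10, 40, 70)) for (x in c(10, 50)) m[y:(y + 9), x:(x + 9)] <- TRUE
  m <- m | perfect_circle_mask(120, 30, 6, c(120, 200))  # a disc intruder
  m[95:104, 100:119] <- TRUE                             # fused double square
  sel <- select_good_sideview(label_components(m))
  expect_equal(sum(sel$good), 6)
  disc_row <- which.max(sel$ratio)
  expect_false(sel$good[disc_row])
  expect_gt(sel$ratio[disc_row], 0.9)
  fused_row <- which.max(sel$max_diameter)
  expect_false(sel$good[fused_row])
  # replacement masks exist only for good components and are square-ish
  expect_true(all(!vapply(sel$square_mask[sel$good], is.null, logical(1))))
  sq <- sel$square_mask[sel$good][[1]]
  expect_equal(sum(sq), 100, tolerance = 0.2)
})

test_that("irregular selection applies the area and center rules", {
  sim <- simulate_micrograph(shape = "irregular", n_particles = 10,
                             seed = 5, noise_sigma = 0)
  comps <- label_components(ibc_cluster(
    normalize_micrograph(sim$pixels), 2)$mask)
  sel <- select_good_irregular(comps)
  expect_true(all(sel$good))

  # a fragment at 30% of the mean area is rejected
  frag <- comps
  big <- matrix(FALSE, 256, 256)
  for (c in comps) big[cbind(c$pixels[, "y"] + 1, c$pixels[, "x"] + 1)] <- TRUE
  keep <- comps[[1]]$pixels
  keep <- keep[keep[, "x"] < stats::quantile(keep[, "x"], 0.3), , drop = FALSE]
  small <- matrix(FALSE, 256, 256)
  small[cbind(keep[, "y"] + 1, keep[, "x"] + 1)] <- TRUE
  for (c in comps[-1]) small[cbind(c$pixels[, "y"] + 1,
                                   c$pixels[, "x"] + 1)] <- TRUE
  sel2 <- select_good_irregular(label_components(small))
  expect_equal(sum(!sel2$good), 1)

  # centroid in the patch corner violates the center rule
  centers <- tibble::tibble(cx = sel$cx, cy = sel$cy)
  centers$cx[1] <- centers$cx[1] + 20  # component now off-center in patch
  sel3 <- select_good_irregular(comps, patch_centers = centers,
                                patch_size = 32)
  expect_false(sel3$good[1])
  expect_true(all(sel3$good[-1]))
})

test_that("background crops avoid particles; negatives come from bad masks", {
  sim <- simulate_micrograph(n_particles = 10, snr = 0.5, seed = 6)
  pre <- preprocess_chain(sim$pixels)
  bg <- harvest_negatives(pre, sim$truth, n = 15, patch_size = 32, seed = 3)
  expect_equal(sum(bg$label == "background"), 15)
  for (i in which(bg$label == "background")) {
    overlap <- sim$truth$x < bg$x[i] + 32 & sim$truth$x + sim$truth$w > bg$x[i] &
      sim$truth$y < bg$y[i] + 32 & sim$truth$y + sim$truth$h > bg$y[i]
    expect_false(any(overlap))
  }
  bg2 <- harvest_negatives(pre, sim$truth, n = 15, patch_size = 32, seed = 3)
  expect_identical(bg$x, bg2$x)

  # no particles: pure background crops
  sim0 <- simulate_micrograph(n_particles = 0, noise_sigma = 0.3, seed = 1)
  b0 <- harvest_negatives(sim0$pixels, sim0$truth, n = 5, patch_size = 32,
                          seed = 1)
  expect_equal(nrow(b0), 5)

  # negatives from bad components
  s1 <- stage1_pick(sim$pixels, particle_size = 24, shape = "disc")
  neg <- harvest_negatives(pre, sim$truth, n = 2, patch_size = 32, seed = 1,
                           bad_components = s1$components)
  expect_true(any(neg$label == "negative"))
})

test_that("rotation augmentation yields exactly four coherent samples", {
  set.seed(8)
  p <- matrix(stats::runif(64), 8)
  r <- augment_rotations(p, "top_view")
  expect_equal(nrow(r), 4)
  expect_equal(r$rotation, c(0, 90, 180, 270))
  expect_identical(cryopickr:::rotate90(r$patch[[4]]), r$patch[[1]])
  sym <- matrix(1, 6, 6)
  rs <- augment_rotations(sym)
  expect_true(all(vapply(rs$patch, identical, logical(1), sym)))
  expect_error(augment_rotations(matrix(0, 3, 4)), "square")
})

test_that("balancing and splitting reproduce the 1500-sample arithmetic", {
  samples <- tibble::tibble(
    patch = replicate(1600, matrix(0, 2, 2), simplify = FALSE),
    label = "top_view")
  sp <- balance_and_split(samples, 1500, seed = 1)
  expect_equal(sum(sp$split %in% c("train", "val")), 1200)
  expect_equal(sum(sp$split == "train"), 960)
  expect_equal(sum(sp$split == "val"), 240)
  expect_equal(sum(sp$split == "test"), 300)

  # small-target floor-and-remainder rule and conservation
  s10 <- tibble::tibble(
    patch = replicate(12, matrix(0, 2, 2), simplify = FALSE), label = "a")
  sp10 <- balance_and_split(s10, 10, seed = 2)
  expect_equal(as.integer(table(sp10$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L))

  # seeded reproducibility, per-class equality, augmentation path
  two <- tibble::tibble(
    patch = c(replicate(30, matrix(stats::runif(4), 2), simplify = FALSE),
              replicate(90, matrix(stats::runif(4), 2), simplify = FALSE)),
    label = rep(c("a", "b"), c(30, 90)))
  spa <- balance_and_split(two, 80, seed = 3)
  spb <- balance_and_split(two, 80, seed = 3)
  expect_identical(spa$split, spb$split)
  expect_true(all(table(spa$label) == 80))
  expect_error(balance_and_split(two, 500, seed = 1), "class 'a'")
})
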