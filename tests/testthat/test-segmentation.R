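test_that("gaussian_blur preserves constants and matches EBImage away from edges", {
  m <- matrix(0.7, 10, 12)
  expect_equal(gaussian_blur(m), m)
  set.seed(31)
  img <- matrix(runif(30 * 25), 30, 25)
  sm <- gaussian_blur(img, 5L, 1)
  expect_equal(dim(sm), dim(img))
  skip_if_not_installed("EBImage")
  brush <- EBImage::makeBrush(5, shape = "gaussian", sigma = 1)
  ref <- EBImage::imageData(EBImage::filter2(EBImage::Image(img), brush))
  # identical interior; boundary handling differs (replicate vs circular)
  expect_equal(sm[3:28, 3:23], ref[3:28, 3:23], tolerance = 1e-7)
})

test_that("fused index image composes its documented steps and stays in [0, 2]", {
  cc <- hypercube(array(0.4, dim = c(8, 8, 100)))
  # constant cube: both normalized maps are 1 everywhere (StO2 may be NA->0,
  # but a pure constant has zero curvature everywhere => NA -> 0 map, so only
  # TWI contributes; use a curved constant model instead for the 2.0 case)
  g <- make_default_grid()
  v <- 0.4 * (1 - 0.3 * exp(-(g - 576)^2 / 200)) * (1 - 0.2 * exp(-(g - 970)^2 / 1800))
  dat <- array(rep(v, each = 64), dim = c(8, 8, 100))
  fused <- fused_index_image(hypercube(dat))
  expect_equal(max(abs(fused - 2)), 0, tolerance = 1e-9)
  # step-by-step oracle on a two-region synthetic scene
  set.seed(32)
  sim <- simulate_hypercube(24, 20, ellipse = list(center = c(11.5, 9.5), axes = c(8, 6)))
  fused2 <- fused_index_image(sim$cube)
  twi_img <- gaussian_blur(index_image(sim$cube, "TWI"), 5L, 1)
  sto2_img <- index_image(sim$cube, "STO2")
  sto2_img[is.na(sto2_img)] <- 0
  sto2_img <- gaussian_blur(sto2_img, 5L, 1)
  expect_equal(fused2, twi_img / max(twi_img) + sto2_img / max(sto2_img))
  expect_true(all(fused2 >= 0 & fused2 <= 2))
})

test_that("otsu_threshold matches the brute-force between-class-variance maximizer", {
  expect_gt(otsu_threshold(c(0, 0, 0, 2, 2, 2)), 0)
  expect_lt(otsu_threshold(c(0, 0, 0, 2, 2, 2)), 2)
  set.seed(33)
  mix <- c(rnorm(600, 0.4, 0.1), rnorm(400, 1.6, 0.1))
  thr <- otsu_threshold(mix)
  expect_gt(thr, 0.8); expect_lt(thr, 1.2)
  expect_otsu_equivalent(mix)
  for (i in 1:25) {
    vals <- switch(1 + i %% 3,
                   runif(1000, 0, 2),
                   c(rnorm(500, runif(1, 0.2, 0.8), 0.1),
                     rnorm(500, runif(1, 1.2, 1.8), 0.15)),
                   rbeta(1000, 2, 5) * 2)
    expect_otsu_equivalent(vals)
  }
  expect_error(otsu_threshold(rep(1, 50)), "constant")
})

test_that("bimodality flag separates one- and two-mode samples", {
  set.seed(35)
  expect_false(is_bimodal(rnorm(5000, 1, 0.15)))
  expect_true(is_bimodal(c(rnorm(2500, 0.4, 0.1), rnorm(2500, 1.6, 0.1))))
  expect_false(is_bimodal(rnorm(5)))           # too few values
  expect_false(is_bimodal(rep(1.3, 100)))      # constant
  # decreasing separation: flag flips from TRUE to FALSE exactly once
  seps <- c(10, 8, 6, 1.5, 1, 0.5)
  flags <- sapply(seps, function(k) {
    x <- c(rnorm(4000, 1, 0.08), rnorm(4000, 1 + k * 0.08, 0.08))
    is_bimodal(x)
  })
  expect_true(all(diff(as.integer(flags)) <= 0))
  expect_true(flags[1]); expect_false(flags[length(flags)])
})

test_that("body_mask recovers synthetic scenes and records its provenance", {
  set.seed(36)
  sim <- simulate_hypercube(64, 48, body = skin_model(noise_sd = 0),
                            background = background_model(noise_sd = 0))
  bm <- body_mask(sim$cube, roi_diameter = 10)
  expect_s3_class(bm, "body_mask")
  expect_equal(bm$method, "otsu")
  recall <- sum(bm$mask & sim$truth) / sum(sim$truth)
  precision <- sum(bm$mask & sim$truth) / sum(bm$mask)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
  expect_true(bm$threshold >= 0 && bm$threshold <= 2)
  # uniform background scene: non-bimodal path, fixed threshold 1
  sim_bg <- simulate_hypercube(64, 48, ellipse = list(center = c(-900, -900), axes = c(1, 1)))
  bm_bg <- body_mask(sim_bg$cube, roi_diameter = 10)
  expect_equal(bm_bg$method, "fixed")
  expect_equal(bm_bg$threshold, 1.0)
  # body filling the frame: handled without error via the fixed path
  sim_full <- simulate_hypercube(64, 48, ellipse = list(center = c(31.5, 23.5), axes = c(500, 500)))
  bm_full <- body_mask(sim_full$cube, roi_diameter = 10)
  expect_equal(bm_full$method, "fixed")
})

test_that("method is otsu exactly when the fused histogram is bimodal", {
  set.seed(37)
  scenes <- list(
    simulate_hypercube(48, 40),
    simulate_hypercube(48, 40, ellipse = list(center = c(-900, -900), axes = c(1, 1))),
    simulate_hypercube(48, 40, ellipse = list(center = c(23.5, 19.5), axes = c(400, 400)))
  )
  for (sim in scenes) {
    bm <- body_mask(sim$cube, roi_diameter = 10)
    fused <- fused_index_image(sim$cube)
    expect_identical(bm$method == "otsu", is_bimodal(as.vector(fused), range = c(0, 2)))
  }
})

test_that("body_mask is invariant to global illumination rescaling", {
  set.seed(38)
  sim <- simulate_hypercube(32, 28)
  bm1 <- body_mask(sim$cube, roi_diameter = 8)
  scaled <- hypercube(sim$cube$data * 3.7, sim$cube$wavelengths)
  bm2 <- body_mask(scaled, roi_diameter = 8)
  expect_identical(bm1$mask, bm2$mask)
  expect_equal(bm1$threshold, bm2$threshold)
})

test_that("segmentation degrades gracefully with noise", {
  ious <- sapply(c(0, 0.01, 0.03, 0.1), function(ns) {
    set.seed(42)
    sim <- simulate_hypercube(64, 48, body = skin_model(noise_sd = ns),
                              background = background_model(noise_sd = ns))
    iou(body_mask(sim$cube, roi_diameter = 10)$mask, sim$truth)
  })
  expect_true(all(diff(ious) <= 1e-6))
  expect_gte(ious[1], 0.99)
})

test_that("select_best_repeat maximizes central coverage with first-index ties", {
  central <- central_roi_mask(c(20, 20), 10)
  mk <- function(frac) {
    m <- matrix(FALSE, 20, 20)
    idx <- which(central)
    m[idx[seq_len(round(frac * length(idx)))]] <- TRUE
    m
  }
  expect_equal(as.integer(select_best_repeat(list(mk(0.2), mk(0.9), mk(0.5)))), 2L)
  expect_equal(as.integer(select_best_repeat(list(mk(0.5), mk(0.5), mk(0.5)))), 1L)
  expect_error(select_best_repeat(list(mk(0.5), matrix(FALSE, 5, 5))), "shape")
  # jittered triplicates: the chosen repeat has maximal true central coverage
  set.seed(39)
  cfg <- cohort_config()
  for (rep_i in 1:3) {
    h <- 48; w <- 40
    sims <- lapply(1:3, function(r) {
      off <- rnorm(2, 0, c(0.25 * h, 0.25 * w))
      simulate_hypercube(h, w, ellipse = list(
        center = c((h - 1) / 2, (w - 1) / 2) + off, axes = c(0.35 * h, 0.3 * w)))
    })
    central2 <- central_roi_mask(c(h, w), 10)
    masks <- lapply(sims, function(s) body_mask(s$cube, roi_diameter = 10))
    chosen <- as.integer(select_best_repeat(masks, central2))
    true_cov <- sapply(sims, function(s) mean(s$truth[central2]))
    expect_equal(true_cov[chosen], max(true_cov))
  }
})
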