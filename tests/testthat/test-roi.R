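test_that("central ROI disk matches brute-force enumeration", {
  # full-frame default: count every pixel center within radius 50 of
  # ((640-1)/2, (480-1)/2)
  disk <- central_roi_mask(c(640, 480), 100)
  brute <- 0L
  for (i in 0:639) {
    d2 <- (i - 319.5)^2
    if (d2 < 2500) brute <- brute + sum((0:479 - 239.5)^2 < 2500 - d2)
  }
  expect_equal(sum(disk), brute)
  expect_equal(dim(disk), c(640, 480))
})

test_that("ROI disk is reflection-symmetric and honors the center convention", {
  disk <- central_roi_mask(c(64, 48), 20)
  expect_identical(disk, disk[64:1, ])
  expect_identical(disk, disk[, 48:1])
  # diameter 1: strict-radius membership leaves exactly the center pixel on
  # odd dimensions and no pixel on even ones (center falls between pixels)
  d_odd <- central_roi_mask(c(11, 11), 1)
  expect_equal(sum(d_odd), 1L)
  expect_true(d_odd[6, 6])
  expect_equal(sum(central_roi_mask(c(10, 10), 1)), 0L)
  expect_error(central_roi_mask(c(30, 20), 25), "exceeds")
})

test_that("representative spectrum normalizes per pixel then averages", {
  g <- make_default_grid()
  # identical pixels: result is the L1-normalized common spectrum
  v <- runif(100, 0.2, 1)
  dat <- array(rep(v, each = 16), dim = c(4, 4, 100))
  cube <- hypercube(dat, g)
  all_true <- matrix(TRUE, 4, 4)
  rs <- representative_spectrum(cube, all_true, all_true)
  expect_equal(as.numeric(rs), v / sum(v))
  expect_equal(sum(rs), 1)
  # two-pixel toy: explicit hand average of the two normalized spectra
  v2 <- rev(v)
  dat2 <- array(0, dim = c(1, 2, 100))
  dat2[1, 1, ] <- v; dat2[1, 2, ] <- 3 * v2
  cube2 <- hypercube(dat2, g)
  rs2 <- representative_spectrum(cube2, matrix(TRUE, 1, 2), matrix(TRUE, 1, 2))
  expect_equal(as.numeric(rs2), (v / sum(v) + v2 / sum(v2)) / 2)
  # unit sum on random masks
  set.seed(41)
  dat3 <- array(runif(6 * 6 * 100, 0.05, 1), dim = c(6, 6, 100))
  cube3 <- hypercube(dat3, g)
  body <- matrix(runif(36) < 0.6, 6, 6)
  roi <- central_roi_mask(c(6, 6), 5)
  if (sum(body & roi) > 0)
    expect_equal(sum(representative_spectrum(cube3, body, roi)), 1)
  # empty intersection: flagged missing, not a zero spectrum
  rs_miss <- representative_spectrum(cube3, matrix(FALSE, 6, 6), roi)
  expect_true(isTRUE(attr(rs_miss, "missing")))
  expect_true(all(is.na(rs_miss)))
})

test_that("indices are computed from the average spectrum, not averaged per pixel", {
  set.seed(42)
  g <- make_default_grid()
  dat <- array(runif(3 * 3 * 100, 0.05, 1), dim = c(3, 3, 100))
  cube <- hypercube(dat, g)
  m <- matrix(TRUE, 3, 3)
  rs <- representative_spectrum(cube, m, m)
  pipeline_value <- side_indices(rs)$lwr
  expect_equal(pipeline_value, lwr(rs))
  mean_of_pixel_indices <- mean(index_image(cube, "LWR"))
  expect_false(isTRUE(all.equal(pipeline_value, mean_of_pixel_indices)))
  # scale invariance: rescaled side yields the identical index set
  cube_scaled <- hypercube(dat * 5.5, g)
  rs_scaled <- representative_spectrum(cube_scaled, m, m)
  expect_equal(side_indices(rs_scaled)$lwr, pipeline_value, tolerance = 1e-12)
  expect_equal(side_indices(rs_scaled)$twi_raw, side_indices(rs)$twi_raw,
               tolerance = 1e-12)
})

test_that("delta metrics subtract affected minus unaffected and antisymmetrize", {
  set.seed(43)
  a <- index_set(spectrum(runif(100, 0.1, 1)))
  u <- index_set(spectrum(runif(100, 0.1, 1)))
  d <- delta_metrics(a, u)
  expect_equal(d$d_lwr, a$lwr - u$lwr)
  d_swap <- delta_metrics(u, a)
  expect_equal(d$d_lwr, -d_swap$d_lwr)
  expect_equal(d$d_twi, -d_swap$d_twi)
  expect_equal(d$d_tli, -d_swap$d_tli)
  expect_equal(delta_metrics(a, a), list(d_lwr = 0, d_twi = 0, d_tli = 0))
  # explicit arithmetic
  a2 <- a; a2$lwr <- 0.95
  u2 <- u; u2$lwr <- 1.05
  expect_equal(delta_metrics(a2, u2)$d_lwr, -0.10)
  expect_null(delta_metrics(NULL, u))
})

test_that("interlimb deltas track the affected-side water increment", {
  # severity sweep at low noise: |d_lwr| monotone in the water increment
  g <- make_default_grid()
  base <- skin_model(d_water = 0.3, d_lipid = 0.15, noise_sd = 0)
  u_spec <- spectrum(pmax(lymphspec:::model_clean_values(base, g), 1e-6), g)
  u_idx <- index_set(normalize_l1(u_spec))
  incs <- seq(0, 0.3, length.out = 12)
  d_lwrs <- sapply(incs, function(inc) {
    m <- skin_model(d_water = 0.3 + inc, d_lipid = 0.15, noise_sd = 0)
    s <- spectrum(pmax(lymphspec:::model_clean_values(m, g), 1e-6), g)
    delta_metrics(index_set(normalize_l1(s)), u_idx)$d_lwr
  })
  expect_equal(d_lwrs[1], 0)
  expect_true(all(diff(d_lwrs) > 0))
  expect_gte(spearman(incs, abs(d_lwrs)), 0.95)
})
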