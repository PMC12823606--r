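test_that("noise-free spectrum equals the analytic model", {
  m <- skin_model(noise_sd = 0)
  s <- simulate_spectrum(m)
  g <- make_default_grid()
  u <- (g - 500) / 495
  base <- 0.25 + 0.6 * u - 0.35 * u^2
  att <- (1 - 0.35 * exp(-(g - 542)^2 / 200)) * (1 - 0.35 * exp(-(g - 576)^2 / 200)) *
    (1 - 0.15 * exp(-(g - 930)^2 / 450)) * (1 - 0.30 * exp(-(g - 970)^2 / 1800))
  expect_equal(as.numeric(s), base * att, tolerance = 1e-12)
  expect_error(spectral_model(features = list(c(900, -5, 0.1))), "width")
})

test_that("water dip deepening raises LWR; lipid dip deepening lowers it", {
  lv <- sapply(seq(0, 0.5, length.out = 20), function(d)
    lwr(simulate_spectrum(skin_model(d_water = d, noise_sd = 0))))
  expect_true(all(diff(lv) > 0))
  lv2 <- sapply(seq(0, 0.5, length.out = 20), function(d)
    lwr(simulate_spectrum(skin_model(d_lipid = d, noise_sd = 0))))
  expect_true(all(diff(lv2) < 0))
})

test_that("affected/unaffected spectral ratio shows the lipid peak and water dip", {
  g <- make_default_grid()
  un <- simulate_spectrum(skin_model(d_water = 0.3, d_lipid = 0.15, noise_sd = 0))
  af <- simulate_spectrum(skin_model(d_water = 0.5, d_lipid = 0.10, noise_sd = 0))
  ratio <- as.numeric(normalize_l1(af)) / as.numeric(normalize_l1(un))
  upper <- which(g >= 850)
  expect_equal(g[upper][which.min(ratio[upper])], 970, tolerance = 10)
  expect_equal(g[upper][which.max(ratio[upper])], 920, tolerance = 15)
})

test_that("simulated hypercubes are deterministic and carry ground truth", {
  set.seed(81)
  s1 <- simulate_hypercube(24, 20)
  set.seed(81)
  s2 <- simulate_hypercube(24, 20)
  expect_identical(s1$cube$data, s2$cube$data)
  expect_identical(s1$truth, s2$truth)
  expect_true(any(s1$truth) && !all(s1$truth))
  expect_error(simulate_hypercube(24, 20, ellipse = list(center = c(10, 10), axes = c(0, 5))),
               "degenerate")
})

test_that("default cohort reproduces the study composition", {
  cfg <- cohort_config()
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$patients), 58)
  expect_equal(as.integer(table(factor(co$patients$stage, levels = 0:3))),
               c(11, 13, 28, 6))
  # 3 sites x 2 sides per patient
  expect_equal(nrow(co$measurements), 58 * 6)
  expect_true(all(table(co$measurements$patient) == 6))
  # (patient, site, side) unique
  expect_false(any(duplicated(co$measurements[c("patient", "site", "side")])))
  # determinism, bit-exact
  co2 <- simulate_cohort(cfg)
  expect_identical(co$measurements, co2$measurements)
  expect_identical(co$clinical_sites, co2$clinical_sites)
  expect_error(cohort_config(water_inc_mean = c(0.1, 0, 0, 0)), "monotone")
})

test_that("triplicate repeats share tissue but differ in framing and noise", {
  cfg <- cohort_config()
  co <- simulate_cohort(cfg)
  row <- co$measurements[5, ]
  reps <- realize_measurement(row, cfg)
  expect_length(reps, 3)
  expect_false(identical(reps[[1]]$truth, reps[[2]]$truth))
  expect_false(identical(reps[[1]]$cube$data, reps[[2]]$cube$data))
  # bit-exact regeneration
  reps2 <- realize_measurement(row, cfg)
  expect_identical(reps[[2]]$cube$data, reps2[[2]]$cube$data)
})

test_that("stage-0 interlimb deltas center at zero and severity grows with stage", {
  cfg <- cohort_config(seed = 82)
  # null case: 50 stage-0 patients
  set.seed(82)
  d0 <- replicate(50, {
    p <- simulate_patient(0, "X", cfg)
    m <- p$measurements[p$measurements$affected_site, ]
    a <- m[m$side == "affected", ]; u <- m[m$side == "unaffected", ]
    s_a <- lwr(simulate_spectrum(skin_model(a$d_water[1], a$d_lipid[1], noise_sd = 0)))
    s_u <- lwr(simulate_spectrum(skin_model(u$d_water[1], u$d_lipid[1], noise_sd = 0)))
    s_a - s_u
  })
  expect_lt(abs(mean(d0)), 2 * sd(d0) / sqrt(length(d0)))
  # Monte-Carlo trend: mean true water increment grows with stage
  set.seed(83)
  mean_inc <- sapply(0:3, function(st) {
    mean(replicate(200, {
      p <- simulate_patient(st, "X", cfg)
      m <- p$measurements[p$measurements$affected_site, ]
      mean(m$d_water[m$side == "affected"]) - mean(m$d_water[m$side == "unaffected"])
    }))
  })
  expect_true(all(diff(mean_inc) > 0))
})

test_that("cohort CSV export writes the clinical schema", {
  co <- simulate_cohort(cohort_config(stage_counts = c(2L, 2L, 3L, 2L)))
  dir <- tempfile()
  write_cohort_csv(co, dir)
  cs <- read.csv(file.path(dir, "clinical_sites.csv"))
  expect_true(all(c("patient", "stage", "site", "affected_site",
                    "circumference_affected", "circumference_unaffected",
                    "cutis_affected", "subcutis_affected") %in% names(cs)))
  qa <- read.csv(file.path(dir, "questionnaire.csv"))
  expect_true(all(qa$response %in% 1:4))
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), nrow(co$measurements))
})
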