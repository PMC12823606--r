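#' Generative spectral model of tissue reflectance
#'
#' Reflectance is a smooth low-order polynomial baseline multiplied by
#' Gaussian absorption dips, plus per-band Gaussian noise, clipped positive:
#' `R(lambda) = baseline(lambda) * prod_i (1 - depth_i * exp(-(lambda -
#' center_i)^2 / (2 width_i^2))) + noise`. This is the minimal structure
#' that reproduces the characteristic affected/unaffected spectral-ratio
#' signature (a relative peak near 920 nm and a dip near 970 nm) and gives
#' every index a monotone response to its chromophore. The polynomial is in
#' the normalized coordinate `u = (lambda - 500) / 495`.
#'
#' @param baseline_coef polynomial coefficients in `u` (ascending powers).
#' @param features list of `c(center, width, depth)` absorption dips (nm,
#'   nm, dimensionless depth in [0, 1)).
#' @param noise_sd per-band additive Gaussian noise standard deviation.
#' @return A `spectral_model` object.
#' @export
spectral_model <- function(baseline_coef = c(0.25, 0.6, -0.35),
                           features = list(), noise_sd = 0.01) {
  for (f in features) {
    if (length(f) != 3L || f[2L] <= 0 || f[3L] < 0)
      stop("each feature must be c(center, width > 0, depth >= 0)")
  }
  structure(list(baseline_coef = baseline_coef, features = features,
                 noise_sd = noise_sd), class = "spectral_model")
}

#' Skin-like spectral model
#'
#' Baseline typical of fair skin over 500--995 nm with hemoglobin absorption
#' dips at 542 and 576 nm, a lipid dip at 930 nm (width 15 nm) and a water
#' dip at 970 nm (width 30 nm). Edema deepens the water dip and shallows
#' the lipid dip.
#'
#' @param d_water,d_lipid water and lipid dip depths.
#' @param d_hemoglobin depth of the two hemoglobin dips.
#' @param noise_sd per-band noise sd.
#' @export
skin_model <- function(d_water = 0.30, d_lipid = 0.15, d_hemoglobin = 0.35,
                       noise_sd = 0.01) {
  spectral_model(
    baseline_coef = c(0.25, 0.6, -0.35),
    features = list(c(542, 10, d_hemoglobin), c(576, 10, d_hemoglobin),
                    c(930, 15, d_lipid), c(970, 30, d_water)),
    noise_sd = noise_sd
  )
}

#' Background (matte black surface) spectral model
#'
#' Low, nearly flat reflectance without hemoglobin or water features,
#' emulating the black support surface used during acquisition.
#'
#' @param noise_sd per-band noise sd.
#' @export
background_model <- function(noise_sd = 0.01) {
  spectral_model(baseline_coef = c(0.05, 0.01, 0), features = list(),
                 noise_sd = noise_sd)
}

model_clean_values <- function(model, grid = make_default_grid()) {
  u <- (grid - 500) / 495
  base <- numeric(length(grid))
  for (p in seq_along(model$baseline_coef))
    base <- base + model$baseline_coef[p] * u^(p - 1)
  att <- rep(1, length(grid))
  for (f in model$features)
    att <- att * (1 - f[3L] * exp(-(grid - f[1L])^2 / (2 * f[2L]^2)))
  base * att
}

#' Draw one spectrum from a spectral model
#'
#' Deterministic clean spectrum plus per-band Gaussian noise, clipped to
#' stay strictly positive. Uses the R session RNG (seed it for
#' reproducibility).
#'
#' @param model a [spectral_model].
#' @param grid wavelength grid.
#' @return A `spectrum`.
#' @export
simulate_spectrum <- function(model, grid = make_default_grid()) {
  clean <- model_clean_values(model, grid)
  v <- clean + stats::rnorm(length(grid), sd = model$noise_sd)
  spectrum(pmax(v, 1e-6), grid)
}

ellipse_mask <- function(shape, center, axes, angle = 0) {
  h <- shape[1L]; w <- shape[2L]
  if (any(axes <= 0)) stop("degenerate ellipse axes")
  yy <- matrix(seq_len(h) - 1, h, w)
  xx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  dy <- yy - center[1L]; dx <- xx - center[2L]
  c1 <- dy * cos(angle) + dx * sin(angle)
  c2 <- -dy * sin(angle) + dx * cos(angle)
  (c1 / axes[1L])^2 + (c2 / axes[2L])^2 <= 1
}

#' Simulate one hyperspectral acquisition
#'
#' Fills an elliptical body region with spectra drawn from `body` (noise
#' redrawn per pixel and band) and the remainder with spectra from
#' `background`, returning the cube together with the ground-truth body
#' mask. Defaults produce the instrument's full 640 x 480 x 100 frame; the
#' 64 x 48 small-frame mode is used throughout the test suite for speed.
#'
#' @param height,width spatial frame size in pixels.
#' @param body,background [spectral_model]s for the two regions.
#' @param ellipse list with `center` (c(row, col), 0-based), `axes`
#'   (c(semi_h, semi_w) px) and optional `angle` (radians); `NULL` centers
#'   an ellipse covering roughly a third of the frame.
#' @param grid wavelength grid.
#' @return List with `cube` (a [hypercube]) and `truth` (logical body
#'   mask).
#' @export
simulate_hypercube <- function(height = 640L, width = 480L,
                               body = skin_model(), background = background_model(),
                               ellipse = NULL, grid = make_default_grid()) {
  if (is.null(ellipse))
    ellipse <- list(center = c((height - 1) / 2, (width - 1) / 2),
                    axes = c(0.38 * height, 0.33 * width), angle = 0)
  if (is.null(ellipse$angle)) ellipse$angle <- 0
  mask <- ellipse_mask(c(height, width), ellipse$center, ellipse$axes,
                       ellipse$angle)
  nb <- length(grid)
  body_clean <- model_clean_values(body, grid)
  bg_clean <- model_clean_values(background, grid)
  dat <- array(rep(bg_clean, each = height * width),
               dim = c(height, width, nb))
  if (any(mask)) {
    idx <- which(mask)
    for (b in seq_len(nb)) {
      plane <- dat[, , b]
      plane[idx] <- body_clean[b]
      dat[, , b] <- plane
    }
  }
  # single noise field; body noise sd applies to body pixels, background's
  # to the rest (they are equal under the defaults)
  noise <- array(stats::rnorm(length(dat)), dim = dim(dat))
  sd_map <- ifelse(mask, body$noise_sd, background$noise_sd)
  dat <- dat + noise * array(rep(sd_map, nb), dim = dim(dat))
  dat <- pmax(dat, 1e-6)
  list(cube = hypercube(dat, grid), truth = mask)
}

#' Cohort generator configuration
#'
#' Defines the study conditions the generator emulates: a 58-patient
#' cohort with ISL stage counts 11/13/28/6 (stages 0--III), three imaging
#' sites per arm acquired in triplicate on both sides, stage-conditional
#' water/lipid absorption changes on the affected side, and stage-correlated
#' clinical covariates. Effect-size defaults are calibrated (documented in
#' the package vignette) so that the default cohort yields stage
#' correlations of realistic strength (`target_spearman_hsi`,
#' `target_spearman_cutis`); they are configuration, not predictions.
#'
#' @param seed RNG seed (integer).
#' @param stage_counts patients per ISL stage 0--III.
#' @param frame spatial frame `c(height, width)`; the small 64 x 48 frame
#'   by default (use `c(640, 480)` for full-fidelity runs).
#' @param roi_diameter central ROI diameter in px; `NULL` scales the
#'   full-frame 100 px disk to the frame.
#' @param noise_sd per-band spectral noise sd.
#' @param base_water,base_lipid unaffected-side dip depths.
#' @param water_inc_mean,water_inc_sd per-stage affected-side water-depth
#'   increment mean/sd (stage II deliberately overdispersed).
#' @param lipid_dec_mean,lipid_dec_sd per-stage lipid-depth decrement.
#' @param patient_sd between-patient sd of the baseline water depth.
#' @param site_sd per-measurement sd added to each side's water depth.
#' @param affected_sites_by_stage number of physician-flagged sites per
#'   patient at each stage.
#' @param n_roi_pixels pixels averaged in the spectra-level fast path.
#' @param circ_effect,cutis_effect,subcutis_effect per-stage fractional
#'   increases of circumference / cutis / subcutis on the affected side.
#' @param tpd_effect per-stage two-point-discrimination increase (mm).
#' @param mobility_effect per-stage mobility loss (degrees).
#' @param quest_effect per-stage latent shift of arm-symptom items (1--4
#'   scale).
#' @param staging_direction sign mapping `d_lwr` to severity; +1 because
#'   edema raises affected-side LWR (deeper water dip lowers the
#'   denominator band), so larger `d_lwr` means more severe.
#' @param target_spearman_hsi,target_spearman_cutis calibrated stage
#'   correlations the default cohort was tuned to produce (used by
#'   regression tests).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(seed = 20260101L,
                          stage_counts = c(11L, 13L, 28L, 6L),
                          frame = c(64L, 48L),
                          roi_diameter = NULL,
                          noise_sd = 0.01,
                          base_water = 0.30, base_lipid = 0.15,
                          water_inc_mean = c(0.000, 0.008, 0.065, 0.130),
                          water_inc_sd   = c(0.012, 0.018, 0.060, 0.045),
                          lipid_dec_mean = c(0.000, 0.005, 0.025, 0.045),
                          lipid_dec_sd   = c(0.005, 0.005, 0.020, 0.015),
                          patient_sd = 0.03, site_sd = 0.012,
                          affected_sites_by_stage = c(1L, 1L, 2L, 2L),
                          n_roi_pixels = 60L,
                          circ_effect = c(0.00, 0.01, 0.03, 0.06),
                          cutis_effect = c(0.00, 0.04, 0.22, 0.42),
                          subcutis_effect = c(0.00, 0.04, 0.25, 0.50),
                          tpd_effect = c(0.0, 0.2, 0.8, 1.5),
                          mobility_effect = c(0, 1, 5, 10),
                          quest_effect = c(0.0, 0.2, 0.5, 0.9),
                          staging_direction = 1,
                          target_spearman_hsi = 0.64,
                          target_spearman_cutis = 0.56) {
  cfg <- as.list(environment())
  if (length(cfg$stage_counts) != 4L) stop("stage_counts must have 4 entries")
  for (nm in c("water_inc_mean", "lipid_dec_mean", "circ_effect",
               "cutis_effect", "subcutis_effect", "tpd_effect",
               "mobility_effect", "quest_effect"))
    if (is.unsorted(cfg[[nm]]))
      stop("effect sizes must be monotone non-decreasing in stage: ", nm)
  if (is.null(cfg$roi_diameter))
    cfg$roi_diameter <- max(8L, round(min(cfg$frame) * 100 / 480))
  cfg$n_patients <- sum(cfg$stage_counts)
  class(cfg) <- "cohort_config"
  cfg
}

sites <- function() c("hand", "forearm", "upper_arm")

rtrunc_norm <- function(n, mean, sd, lower = 0) pmax(stats::rnorm(n, mean, sd), lower)

#' Simulate one patient
#'
#' Draws the patient's spectral ground truth (water/lipid dip depths per
#' site and side; stage effects applied only at physician-flagged sites)
#' and the stage-correlated clinical covariates: circumference and
#' cutis/subcutis thickness per site and side, two-point discrimination,
#' joint mobility and questionnaire items per patient. Uses the session
#' RNG; [simulate_cohort()] seeds it.
#'
#' @param stage ISL stage 0--3.
#' @param patient_id identifier.
#' @param config a [cohort_config].
#' @return List with `measurements` (per site x side spectral truth, incl.
#'   a per-measurement realization seed), `clinical_sites`,
#'   `clinical_patient`, `questionnaire`.
#' @export
simulate_patient <- function(stage, patient_id, config = cohort_config()) {
  stopifnot(stage %in% 0:3)
  s <- stage + 1L
  n_aff <- min(config$affected_sites_by_stage[s], 3L)
  aff_sites <- sort(sample.int(3L, n_aff))
  pat_water <- rtrunc_norm(1, config$base_water, config$patient_sd, 0.05)
  pat_lipid <- rtrunc_norm(1, config$base_lipid, config$patient_sd / 2, 0.02)

  meas <- list()
  for (k in 1:3) {
    affected_site <- k %in% aff_sites
    es <- if (affected_site) s else 1L
    w_inc <- rtrunc_norm(1, config$water_inc_mean[es], config$water_inc_sd[es])
    l_dec <- rtrunc_norm(1, config$lipid_dec_mean[es], config$lipid_dec_sd[es])
    for (side in c("affected", "unaffected")) {
      w <- pat_water + stats::rnorm(1, 0, config$site_sd)
      l <- pat_lipid + stats::rnorm(1, 0, config$site_sd / 2)
      if (side == "affected") { w <- w + w_inc; l <- l - l_dec }
      meas[[length(meas) + 1L]] <- data.frame(
        patient = patient_id, stage = stage, site = sites()[k], side = side,
        affected_site = affected_site,
        d_water = max(w, 0.02), d_lipid = max(l, 0.01),
        meas_seed = sample.int(.Machine$integer.max - 1L, 1L)
      )
    }
  }
  measurements <- do.call(rbind, meas)

  site_base <- c(hand = 20, forearm = 26, upper_arm = 30)
  cl_sites <- do.call(rbind, lapply(1:3, function(k) {
    affected_site <- k %in% aff_sites
    es <- if (affected_site) s else 1L
    circ_u <- site_base[k] * exp(stats::rnorm(1, 0, 0.06))
    cutis_u <- 1.8 * exp(stats::rnorm(1, 0, 0.10))
    subc_u <- 8.0 * exp(stats::rnorm(1, 0, 0.15))
    data.frame(
      patient = patient_id, stage = stage, site = sites()[k],
      affected_site = affected_site,
      circumference_affected = circ_u *
        (1 + rtrunc_norm(1, config$circ_effect[es], 0.02, -0.05)),
      circumference_unaffected = circ_u,
      cutis_affected = cutis_u *
        (1 + rtrunc_norm(1, config$cutis_effect[es], 0.18, -0.15)),
      cutis_unaffected = cutis_u,
      subcutis_affected = subc_u *
        (1 + rtrunc_norm(1, config$subcutis_effect[es], 0.22, -0.2)),
      subcutis_unaffected = subc_u,
      row.names = NULL
    )
  }))

  tpd_u <- stats::rnorm(2, 4, 0.5)
  mob_u <- c(shoulder_abduction = stats::rnorm(1, 170, 5),
             elbow_flexion = stats::rnorm(1, 145, 5),
             wrist_extension = stats::rnorm(1, 65, 5))
  mob_a <- pmax(mob_u - rtrunc_norm(3, config$mobility_effect[s], 6, -3), 0)
  cl_patient <- data.frame(
    patient = patient_id, stage = stage,
    tpd_index_affected = tpd_u[1] + rtrunc_norm(1, config$tpd_effect[s], 1.1, -0.5),
    tpd_index_unaffected = tpd_u[1],
    tpd_little_affected = tpd_u[2] + rtrunc_norm(1, config$tpd_effect[s], 1.1, -0.5),
    tpd_little_unaffected = tpd_u[2],
    shoulder_abduction_affected = mob_a[1], shoulder_abduction_unaffected = mob_u[1],
    elbow_flexion_affected = mob_a[2], elbow_flexion_unaffected = mob_u[2],
    wrist_extension_affected = mob_a[3], wrist_extension_unaffected = mob_u[3]
  )

  q_items <- function(shift, n_items = 4L) {
    latent <- 1.2 + shift + stats::rnorm(n_items, 0, 0.8)
    pmin(pmax(round(latent), 1), 4)
  }
  cat_mult <- c(arm_symptoms = 1.0, functioning = 0.6, body_image = 0.4)
  quest <- do.call(rbind, lapply(names(cat_mult), function(cat) {
    items <- q_items(cat_mult[[cat]] * config$quest_effect[s])
    data.frame(patient = patient_id, stage = stage, category = cat,
               item = seq_along(items), response = items)
  }))

  list(measurements = measurements, clinical_sites = cl_sites,
       clinical_patient = cl_patient, questionnaire = quest)
}

#' Simulate a full cohort
#'
#' Deterministic under the config seed: assigns ISL stages according to the
#' configured stage counts and simulates every patient. Hypercubes are not
#' materialized here (a full cohort is 1044 acquisitions); each measurement
#' row carries a derived seed from which [realize_measurement()]
#' regenerates its triplicate cubes bit-exactly on demand.
#'
#' @param config a [cohort_config].
#' @return An `hsi_cohort` object: list with `config`, `patients`,
#'   `measurements`, `clinical_sites`, `clinical_patients`,
#'   `questionnaire`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  stages <- rep(0:3, times = config$stage_counts)
  n <- length(stages)
  out <- vector("list", n)
  for (i in seq_len(n))
    out[[i]] <- simulate_patient(stages[i], patient_id = sprintf("P%03d", i),
                                 config = config)
  cohort <- list(
    config = config,
    patients = data.frame(patient = sprintf("P%03d", seq_len(n)),
                          stage = stages),
    measurements = do.call(rbind, lapply(out, `[[`, "measurements")),
    clinical_sites = do.call(rbind, lapply(out, `[[`, "clinical_sites")),
    clinical_patients = do.call(rbind, lapply(out, `[[`, "clinical_patient")),
    questionnaire = do.call(rbind, lapply(out, `[[`, "questionnaire"))
  )
  rownames(cohort$measurements) <- NULL
  rownames(cohort$clinical_sites) <- NULL
  rownames(cohort$clinical_patients) <- NULL
  rownames(cohort$questionnaire) <- NULL
  class(cohort) <- "hsi_cohort"
  cohort
}

#' @export
print.hsi_cohort <- function(x, ...) {
  cat(sprintf("<hsi_cohort> %d patients (stages 0-III: %s), %d measurements\n",
              nrow(x$patients),
              paste(table(factor(x$patients$stage, levels = 0:3)), collapse = "/"),
              nrow(x$measurements)))
  invisible(x)
}

measurement_models <- function(row, config) {
  list(body = skin_model(d_water = row$d_water, d_lipid = row$d_lipid,
                         noise_sd = config$noise_sd),
       background = background_model(noise_sd = config$noise_sd))
}

#' Regenerate the triplicate cubes of one cohort measurement
#'
#' Uses the measurement's stored seed, so regeneration is bit-exact. The
#' three repeats share the tissue model and differ in framing (jittered
#' ellipse placement) and noise, emulating repositioning between repeats.
#'
#' @param row one row of `cohort$measurements`.
#' @param config the cohort's [cohort_config].
#' @return List of 3 elements, each `list(cube, truth)`.
#' @export
realize_measurement <- function(row, config) {
  set.seed(row$meas_seed %% .Machine$integer.max)
  h <- config$frame[1L]; w <- config$frame[2L]
  models <- measurement_models(row, config)
  lapply(1:3, function(r) {
    jitter <- stats::rnorm(2, 0, 0.05 * c(h, w))
    simulate_hypercube(
      height = h, width = w,
      body = models$body, background = models$background,
      ellipse = list(center = c((h - 1) / 2, (w - 1) / 2) + jitter,
                     axes = c(0.38 * h, 0.33 * w) *
                       exp(stats::rnorm(2, 0, 0.05)),
                     angle = stats::rnorm(1, 0, 0.1))
    )
  })
}

#' Spectra-level representative spectrum of one cohort measurement
#'
#' Fast path that bypasses image formation: draws `n_roi_pixels` noisy
#' pixel spectra from the measurement's tissue model, L1-normalizes each
#' and averages — exactly what [representative_spectrum()] computes from
#' the ROI of a segmented cube. Deterministic via the measurement seed.
#'
#' @inheritParams realize_measurement
#' @return A normalized `spectrum`.
#' @export
measurement_roi_spectrum <- function(row, config) {
  set.seed((row$meas_seed + 1L) %% .Machine$integer.max)
  model <- measurement_models(row, config)$body
  mat <- replicate(config$n_roi_pixels,
                   as.numeric(simulate_spectrum(model)))
  mat <- t(mat) / colSums(mat)
  spectrum(colMeans(mat), normalized = TRUE)
}

#' Write a cohort's tables to CSV
#'
#' Writes the clinical tables consumed by the statistics layer
#' (`clinical_sites.csv`, `clinical_patients.csv`, `questionnaire.csv`) and
#' the spectral ground truth (`ground_truth.csv`) to a directory.
#'
#' @param cohort an `hsi_cohort`.
#' @param dir destination directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$clinical_sites, file.path(dir, "clinical_sites.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$clinical_patients,
                   file.path(dir, "clinical_patients.csv"), row.names = FALSE)
  utils::write.csv(cohort$questionnaire, file.path(dir, "questionnaire.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$measurements, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
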