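#' Process one site measurement (triplicate acquisition)
#'
#' Runs the per-measurement stage sequence: segment each repeat, select the
#' best-framed repeat by central body coverage, extract the L1-normalized
#' representative ROI spectrum from it, and compute the index set. Fewer
#' than three repeats are processed with a warning; an empty body-ROI
#' intersection yields a row flagged missing rather than an error.
#'
#' @param cubes list of up to 3 [hypercube]s (the repeats).
#' @param meta named list giving at least `patient`, `site`, `side`.
#' @param roi_diameter central ROI diameter in px (clipped to the frame).
#' @param bands,scaling index configuration.
#' @return One-row `data.frame`: identifiers, selected repeat, segmentation
#'   threshold/method, ROI pixel count, raw LWR/TWI/TLI/StO2 and scaled
#'   TWI/TLI, plus `missing` flag.
#' @export
run_measurement <- function(cubes, meta = list(), roi_diameter = 100L,
                            bands = index_bands(), scaling = index_scaling()) {
  if (!length(cubes)) stop("no repeats supplied")
  if (length(cubes) < 3L)
    warning(sprintf("expected 3 repeats, got %d; using available", length(cubes)))
  masks <- lapply(cubes, body_mask, bands = bands, scaling = scaling,
                  roi_diameter = roi_diameter)
  shape <- dim(masks[[1L]]$mask)
  d <- min(roi_diameter, shape)
  central <- central_roi_mask(shape, d)
  best <- if (length(masks) > 1L) as.integer(select_best_repeat(masks, central)) else 1L
  spec <- representative_spectrum(cubes[[best]], masks[[best]], central)
  missing <- isTRUE(attr(spec, "missing"))
  idx <- if (missing) NULL else index_set(spec, bands, scaling)
  data.frame(
    patient = meta$patient %||% NA_character_,
    site = meta$site %||% NA_character_,
    side = meta$side %||% NA_character_,
    repeat_selected = best,
    threshold = masks[[best]]$threshold,
    method = masks[[best]]$method,
    n_roi_pixels = attr(spec, "n_pixels") %||% 0L,
    lwr = if (missing) NA_real_ else idx$lwr,
    twi_raw = if (missing) NA_real_ else idx$twi_raw,
    tli_raw = if (missing) NA_real_ else idx$tli_raw,
    sto2_raw = if (missing) NA_real_ else idx$sto2_raw,
    twi = if (missing) NA_real_ else idx$twi,
    tli = if (missing) NA_real_ else idx$tli,
    missing = missing,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full cohort analysis
#'
#' Executes the pipeline over a (synthetic) cohort and emits the
#' study-level outputs:
#' \itemize{
#'   \item per-measurement index table (one row per patient x site x side);
#'   \item interlimb delta table (`d_lwr`, `d_twi`, `d_tli` per patient x
#'     site), with the physician-affected-site flag;
#'   \item spectral staging of the affected-site severity values
#'     (`staging_direction * d_lwr`) by [hsi_stage()];
#'   \item Spearman correlations of every metric with ISL stage
#'     (circumference %, cutis %, subcutis %, TPD and mobility differences,
#'     questionnaire category scores, deltas, HSI stage);
#'   \item Mann-Whitney U comparisons of severity between adjacent ISL
#'     stages.
#' }
#' The affected-site filter (only physician-flagged sites and their
#' contralateral counterparts enter the circumference, ultrasound and
#' staging analyses) is one shared predicate. `image_mode = "full"` runs
#' segmentation and ROI extraction on simulated triplicate cubes;
#' `"spectra"` uses the generator's spectra-level fast path, identical from
#' the representative spectrum onward.
#'
#' @param cohort an `hsi_cohort` from [simulate_cohort()].
#' @param image_mode `"spectra"` (default) or `"full"`.
#' @param k number of spectral stages.
#' @return List with `measurements`, `deltas`, `staging` (table +
#'   `hsi_staging` object), `correlations` (data.frame metric/spearman_r/n),
#'   `adjacent_tests` (Mann-Whitney per adjacent stage pair).
#' @export
run_cohort <- function(cohort, image_mode = c("spectra", "full"), k = 3L) {
  image_mode <- match.arg(image_mode)
  config <- cohort$config
  mrows <- cohort$measurements

  specs <- vector("list", nrow(mrows))
  meas <- vector("list", nrow(mrows))
  for (i in seq_len(nrow(mrows))) {
    row <- mrows[i, ]
    if (image_mode == "full") {
      reps <- realize_measurement(row, config)
      m <- run_measurement(lapply(reps, `[[`, "cube"),
                           meta = list(patient = row$patient, site = row$site,
                                       side = row$side),
                           roi_diameter = config$roi_diameter)
    } else {
      spec <- measurement_roi_spectrum(row, config)
      idx <- index_set(spec)
      m <- data.frame(patient = row$patient, site = row$site, side = row$side,
                      repeat_selected = NA_integer_, threshold = NA_real_,
                      method = "spectra", n_roi_pixels = config$n_roi_pixels,
                      lwr = idx$lwr, twi_raw = idx$twi_raw,
                      tli_raw = idx$tli_raw, sto2_raw = idx$sto2_raw,
                      twi = idx$twi, tli = idx$tli, missing = FALSE,
                      stringsAsFactors = FALSE)
    }
    m$stage <- row$stage
    m$affected_site <- row$affected_site
    meas[[i]] <- m
  }
  measurements <- do.call(rbind, meas)

  # deltas per (patient, site)
  key <- interaction(measurements$patient, measurements$site, drop = TRUE)
  deltas <- do.call(rbind, lapply(split(measurements, key), function(g) {
    a <- g[g$side == "affected", ]; u <- g[g$side == "unaffected", ]
    if (nrow(a) != 1L || nrow(u) != 1L || a$missing || u$missing) return(NULL)
    data.frame(patient = a$patient, site = a$site, stage = a$stage,
               affected_site = a$affected_site,
               d_lwr = a$lwr - u$lwr,
               d_twi = a$twi_raw - u$twi_raw,
               d_tli = a$tli_raw - u$tli_raw,
               stringsAsFactors = FALSE)
  }))
  rownames(deltas) <- NULL

  aff <- deltas[deltas$affected_site, ]
  severity <- config$staging_direction * aff$d_lwr
  staging_obj <- hsi_stage(severity, k = k)
  staging <- data.frame(patient = aff$patient, site = aff$site,
                        stage = aff$stage, d_lwr = aff$d_lwr,
                        severity = severity,
                        hsi_stage = staging_obj$labels,
                        stringsAsFactors = FALSE)

  # correlation table vs ISL stage
  cs <- cohort$clinical_sites[cohort$clinical_sites$affected_site, ]
  cp <- cohort$clinical_patients
  qs <- do.call(rbind, lapply(split(cohort$questionnaire,
                                    cohort$questionnaire[c("patient", "category")]),
                              function(g) data.frame(
                                patient = g$patient[1L], stage = g$stage[1L],
                                category = g$category[1L],
                                score = questionnaire_score(g$response))))
  cor_rows <- list(
    data.frame(metric = "circumference_pct", stage = cs$stage,
               value = percent_change(cs$circumference_affected, cs$circumference_unaffected)),
    data.frame(metric = "cutis_pct", stage = cs$stage,
               value = percent_change(cs$cutis_affected, cs$cutis_unaffected)),
    data.frame(metric = "subcutis_pct", stage = cs$stage,
               value = percent_change(cs$subcutis_affected, cs$subcutis_unaffected)),
    data.frame(metric = "tpd_index_diff", stage = cp$stage,
               value = side_difference(cp$tpd_index_affected, cp$tpd_index_unaffected)),
    data.frame(metric = "tpd_little_diff", stage = cp$stage,
               value = side_difference(cp$tpd_little_affected, cp$tpd_little_unaffected)),
    data.frame(metric = "shoulder_abduction_diff", stage = cp$stage,
               value = side_difference(cp$shoulder_abduction_affected,
                                       cp$shoulder_abduction_unaffected)),
    data.frame(metric = "elbow_flexion_diff", stage = cp$stage,
               value = side_difference(cp$elbow_flexion_affected,
                                       cp$elbow_flexion_unaffected)),
    data.frame(metric = "wrist_extension_diff", stage = cp$stage,
               value = side_difference(cp$wrist_extension_affected,
                                       cp$wrist_extension_unaffected))
  )
  for (cat in unique(qs$category))
    cor_rows[[length(cor_rows) + 1L]] <-
      data.frame(metric = paste0("questionnaire_", cat),
                 stage = qs$stage[qs$category == cat],
                 value = qs$score[qs$category == cat])
  cor_rows[[length(cor_rows) + 1L]] <-
    data.frame(metric = "d_lwr_severity", stage = aff$stage,
               value = config$staging_direction * aff$d_lwr)
  cor_rows[[length(cor_rows) + 1L]] <-
    data.frame(metric = "d_twi", stage = aff$stage, value = aff$d_twi)
  cor_rows[[length(cor_rows) + 1L]] <-
    data.frame(metric = "d_tli", stage = aff$stage, value = aff$d_tli)
  cor_rows[[length(cor_rows) + 1L]] <-
    data.frame(metric = "hsi_stage", stage = staging$stage,
               value = as.integer(staging$hsi_stage))
  correlations <- do.call(rbind, lapply(cor_rows, function(d) {
    d <- d[is.finite(d$value), ]
    data.frame(metric = d$metric[1L], spearman_r = spearman(d$stage, d$value),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(correlations) <- NULL

  adjacent_tests <- lapply(list(c(0, 1), c(1, 2), c(2, 3)), function(pr) {
    a <- staging$severity[staging$stage == pr[1L]]
    b <- staging$severity[staging$stage == pr[2L]]
    res <- mann_whitney_u(a, b)
    res$stages <- pr
    res
  })
  names(adjacent_tests) <- c("0_vs_1", "1_vs_2", "2_vs_3")

  list(measurements = measurements, deltas = deltas,
       staging = list(table = staging, clustering = staging_obj),
       correlations = correlations, adjacent_tests = adjacent_tests)
}

#' Spearman correlations of published-style per-measurement tables
#'
#' Statistics-layer entry point for externally supplied source tables (one
#' row per measurement or patient, a `stage` column plus metric columns):
#' computes the Spearman correlation of each metric with stage. Feeding the
#' per-patient source values published with the study through this function
#' reproduces its reported correlation figures.
#'
#' @param df data.frame with a `stage` column and numeric metric columns.
#' @return data.frame with `metric`, `spearman_r`, `n`.
#' @export
published_table_correlations <- function(df) {
  if (!"stage" %in% names(df)) stop("table must contain a `stage` column")
  metrics <- setdiff(names(df), "stage")
  out <- lapply(metrics, function(m) {
    ok <- is.finite(df[[m]]) & is.finite(df$stage)
    data.frame(metric = m, spearman_r = spearman(df$stage[ok], df[[m]][ok]),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
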