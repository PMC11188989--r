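# End-to-end orchestration: simulate (or accept) an epoched recording,
# condition the signals, and run the four analyses per segment:
# sensor-correlation summaries, band-power distances, AEC connectivity,
# and single-trial leave-one-pair-out classification.

#' Run the full analysis pipeline
#'
#' Executes signal conditioning (zero-phase low-pass, line notch,
#' segment parsing, amplitude rejection and trial cap) followed by the
#' four analyses for each requested segment, and aggregates a single
#' report: per-cell correlation densities with cohort t-tests, the
#' band-power distance ANOVA with its argmax band, per-band AEC
#' connectivity densities with one-sided t-tests, and per-band
#' leave-one-pair-out median classification accuracies.
#'
#' @param config a `meg_config` from [default_config()] / [load_config()].
#' @param es an `epoch_set`; if `NULL`, one is simulated from `params`.
#' @param params a [synth_params()] object used when `es` is `NULL`
#'   (default: the `"beta-effect"` preset at reduced scale).
#' @param segments segment names to analyze.
#' @param aec_bands band names for the connectivity stage (default: all
#'   configured bands).
#' @param classify_bands band names for the classification stage
#'   (default: all configured bands plus broadband).
#' @param run_classification set `FALSE` to skip the classifier stage.
#' @param seed integer seed; fans out deterministically to the
#'   simulation and per-fold tuning.
#' @param out_dir optional directory; when given, the report and run
#'   manifest are written there as JSON.
#' @return List with `report` (per-segment results), `manifest` (config
#'   hash, seed, stage timings) and the preprocessed data sizes.
#' @export
run_all <- function(config = default_config(), es = NULL, params = NULL,
                    segments = c("covert", "overt"), aec_bands = NULL,
                    classify_bands = NULL, run_classification = TRUE,
                    seed = config$seed, out_dir = NULL) {
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, nm) {
    timings[nm] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  if (is.null(es)) {
    if (is.null(params)) params <- synth_params("beta-effect", seed = seed)
    es <- generate_cohorts(params)
  }
  toc(t0, "simulate")

  t0 <- tic()
  es <- lowpass_and_resample(es, cutoff = config$lowpass$cutoff,
                             order = config$lowpass$order,
                             target_fs = min(config$target_fs, es$fs))
  es <- notch_line(es, base = config$notch$base, bw = config$notch$bw)
  toc(t0, "condition")

  bands <- config$bands
  bb <- broadband_spec(config$broadband)
  if (is.null(aec_bands)) aec_bands <- names(bands)
  if (is.null(classify_bands)) classify_bands <- c(names(bands), bb$name)

  report <- list()
  for (seg_name in segments) {
    t0 <- tic()
    seg <- parse_segment(es, config$segments[[seg_name]])
    seg <- reject_and_cap_trials(seg, cap = config$trial_cap,
                                 mult = config$amp_thresh_mult)
    toc(t0, paste0(seg_name, ".segment"))

    res <- list()

    # --- sensor correlation -------------------------------------------
    t0 <- tic()
    ca <- trial_correlation(seg)
    avg <- average_correlation(ca, seg$trials, fisher_z = config$fisher_z)
    cells <- avg$cells
    cells$density <- vapply(avg$matrices, correlation_density, 0)
    cells$strong_pairs <- vapply(avg$matrices, strong_pair_count, 0,
                                 thresh = config$strong_pair_threshold)
    cells$strong_sensors <- vapply(avg$matrices, strong_sensor_count, 0,
                                   thresh = config$strong_pair_threshold)
    pat <- cells$cohort == "patient"
    res$correlation <- list(
      cells = cells,
      density_t = two_sample_t(cells$density[pat], cells$density[!pat],
                               alternative = "greater"),
      # degenerate (e.g., all-zero) counts leave this test undefined
      strong_pairs_t = tryCatch(
        two_sample_t(cells$strong_pairs[pat], cells$strong_pairs[!pat],
                     alternative = "greater"),
        error = function(e) NULL),
      range = lapply(c(healthy = "healthy", patient = "patient"),
                     function(ch) {
        vals <- unlist(lapply(avg$matrices[cells$cohort == ch],
                              upper_tri_values))
        correlation_range(vals, seed = seed + 17L)
      })
    )
    toc(t0, paste0(seg_name, ".correlation"))

    # --- band power and cohort distances ------------------------------
    t0 <- tic()
    bpt <- band_power(seg, bands = c(bands, list(broadband = bb)),
                      window_s = config$welch_window_s)
    gm <- group_mean_band_power(bpt)
    res$band_distance <- band_dissimilarity_summary(gm, bands = names(bands))
    toc(t0, paste0(seg_name, ".band_power"))

    # --- AEC functional connectivity ----------------------------------
    t0 <- tic()
    conn <- list()
    key <- interaction(seg$trials$participant_id, seg$trials$phrase_id,
                       drop = TRUE)
    ucells <- unique(data.frame(participant_id = seg$trials$participant_id,
                                cohort = as.character(seg$trials$cohort),
                                phrase_id = seg$trials$phrase_id,
                                key = as.character(key),
                                stringsAsFactors = FALSE))
    for (bn in aec_bands) {
      if (config$aec_mode == "single-trial-averaged") {
        mats <- aec_trial_matrices(seg, bands[[bn]],
                                   edge_trim_s = config$aec_edge_trim_s)
        dens <- vapply(ucells$key, function(kk) {
          idx <- which(as.character(key) == kk)
          connectivity_density(apply(mats[idx, , , drop = FALSE],
                                     c(2, 3), mean))
        }, 0)
      } else {
        dens <- vapply(ucells$key, function(kk) {
          sub <- subset_trials(seg, which(as.character(key) == kk))
          connectivity_density(aec(sub, bands[[bn]], mode = config$aec_mode,
                                   edge_trim_s = config$aec_edge_trim_s))
        }, 0)
      }
      patc <- ucells$cohort == "patient"
      conn[[bn]] <- list(
        cells = cbind(ucells[, c("participant_id", "cohort", "phrase_id")],
                      density = dens),
        density_t = two_sample_t(dens[patc], dens[!patc],
                                 alternative = "greater"))
    }
    res$connectivity <- conn
    toc(t0, paste0(seg_name, ".connectivity"))

    # --- single-trial classification ----------------------------------
    if (run_classification) {
      t0 <- tic()
      cls <- list()
      for (bn in classify_bands) {
        fm <- extract_features(bpt, band = bn,
                               log10_transform = config$log_features)
        cls[[bn]] <- lopo_cv(fm, gamma_grid = config$gamma_grid,
                             delta_grid = config$delta_grid,
                             k = config$tune_folds,
                             seed = seed + 101L)
      }
      res$classification <- list(
        reports = cls,
        median_accuracy = vapply(cls, `[[`, 0, "median_accuracy"),
        best_band = names(cls)[which.max(
          vapply(cls, `[[`, 0, "median_accuracy"))])
      toc(t0, paste0(seg_name, ".classification"))
    }
    report[[seg_name]] <- res
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = seed,
    stages = names(timings),
    timings_s = as.list(round(timings, 3)),
    r_version = as.character(getRversion())
  )
  out <- list(report = report, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(simplify_report(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# JSON-friendly view of the report (drops fitted model objects).
simplify_report <- function(x) {
  if (inherits(x, "meg_test")) {
    return(list(statistic = x$statistic, df = x$df, p = x$p,
                alternative = x$alternative))
  }
  if (inherits(x, "cv_report")) {
    return(list(median_accuracy = x$median_accuracy, folds = x$folds))
  }
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, simplify_report))
  x
}
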