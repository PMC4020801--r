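#' Pipeline configuration
#'
#' Collects the thresholds and paths the pipeline needs. All thresholds
#' default to the values the analysis is built around: SNR cutoff 4,
#' reference frequency 0.35, 22 internal standards, minimum two peptides per
#' protein, significance level 0.05, one missed cleavage in the digest.
#'
#' @param peak_dir Directory of per-sample peak TSVs (`<sample>_peaks.tsv`),
#'   or `NULL` to simulate a cohort in memory.
#' @param fasta,manifest Paths to the protein FASTA and cohort manifest; only
#'   needed with `peak_dir`.
#' @param out_dir Output directory for stage CSVs and the provenance log;
#'   `NULL` keeps everything in memory.
#' @param snr SNR threshold for deconvolution.
#' @param ref_freq Reference-feature frequency threshold.
#' @param n_standards Number of internal standards.
#' @param standard_min_freq Minimum standard detection frequency.
#' @param min_peptides Minimum peptides per protein.
#' @param alpha Significance level.
#' @param max_missed Missed cleavages in the in-silico digest.
#' @param detected_only Use detected-only protein means (see
#'   [protein_abundance_matrix()]).
#' @param cohort A [cohort_design()] used when simulating (default one with
#'   `seed`).
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(peak_dir = NULL, fasta = NULL, manifest = NULL,
                            out_dir = NULL,
                            snr = 4, ref_freq = 0.35, n_standards = 22,
                            standard_min_freq = 0.8, min_peptides = 2,
                            alpha = 0.05, max_missed = 1,
                            detected_only = FALSE,
                            cohort = NULL, seed = 1) {
  stopifnot(snr > 0, ref_freq > 0, ref_freq <= 1, n_standards >= 1)
  stopifnot(min_peptides >= 1, alpha > 0, alpha < 1)
  stopifnot(max_missed >= 0, max_missed <= 3)
  structure(
    list(
      peak_dir = peak_dir, fasta = fasta, manifest = manifest,
      out_dir = out_dir, snr = snr, ref_freq = ref_freq,
      n_standards = n_standards, standard_min_freq = standard_min_freq,
      min_peptides = min_peptides, alpha = alpha, max_missed = max_missed,
      detected_only = detected_only, cohort = cohort, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full CE-MS peptidomics pipeline
#'
#' Executes simulate (when no peak directory is configured) → deconvolute →
#' calibrate → match → normalize → annotate → differential statistics, and
#' writes every stage output plus a provenance log when `out_dir` is set.
#' Samples that fail calibration are dropped with a warning; any other stage
#' failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `manifest`,
#'   `features` (raw per-sample), `aligned` (calibrated per-sample),
#'   `alignments`, `refmap`, `consensuses` (normalized, singleton-filtered),
#'   `scaler`, `standards`, `assignments`, `quant`, `results`, `funnel`
#'   (per-stage counts) and `truth` when simulated.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  funnel <- list()
  truth <- NULL

  # --- input / simulate ------------------------------------------------
  if (is.null(config$peak_dir)) {
    cohort <- config$cohort %||% cohort_design(seed = config$seed)
    sim <- stage("simulate", simulate_cohort(cohort))
    peak_lists <- lapply(sim$samples, function(s) s$peaks)
    manifest <- sim$manifest
    db <- cohort$protein_db
    truth <- sim
  } else {
    manifest <- stage("input", read_manifest(config$manifest))
    db <- stage("input", read_protein_fasta(config$fasta))
    paths <- file.path(config$peak_dir, paste0(manifest$sample_id, "_peaks.tsv"))
    peak_lists <- stage("input", lapply(paths, read_peak_table))
    names(peak_lists) <- manifest$sample_id
  }
  funnel$samples <- length(peak_lists)

  # --- deconvolute ------------------------------------------------------
  features <- stage("deconvolute", lapply(peak_lists, function(p) {
    deconvolute_peaks(p, estimate_noise(p), snr_threshold = config$snr)
  }))
  funnel$features <- sum(vapply(features, nrow, integer(1)))

  # --- calibrate --------------------------------------------------------
  calib <- stage(
    "calibrate",
    calibrate_cohort(features, threshold = config$ref_freq)
  )
  refmap <- calib$refmap
  alignments <- calib$alignments
  aligned <- calib$aligned
  funnel$references <- nrow(refmap)
  if (length(calib$failed) > 0) {
    manifest <- manifest[!manifest$sample_id %in% calib$failed, ]
  }
  if (length(aligned) < 3) abort("Pipeline stage 'calibrate' failed: fewer than 3 samples aligned.")

  # --- match ------------------------------------------------------------
  combined <- bind_rows(aligned, .id = "sample_id")
  cons <- stage("match", match_features(combined, n_samples = length(aligned)))
  funnel$consensus_raw <- nrow(cons$peptides)
  cons <- filter_singletons(cons)
  funnel$consensus <- nrow(cons$peptides)

  # --- normalize --------------------------------------------------------
  standards <- stage("normalize", select_internal_standards(
    cons, manifest,
    n_standards = config$n_standards, min_freq = config$standard_min_freq
  ))
  norm <- stage("normalize", normalize_intensities(cons, standards))
  cons <- norm$consensuses
  funnel$standards <- nrow(standards)

  # --- annotate ---------------------------------------------------------
  digest_db <- stage("annotate", digest_proteins(db, max_missed = config$max_missed))
  assignments <- stage("annotate", annotate_features(cons, digest_db))
  funnel$annotated <- sum(assignments$annotated)

  # --- stats ------------------------------------------------------------
  quant <- stage("stats", protein_abundance_matrix(
    cons, assignments, manifest,
    min_peptides = config$min_peptides, detected_only = config$detected_only
  ))
  funnel$proteins <- nrow(quant$abundance)
  results <- stage("stats", summarize_results(quant, alpha = config$alpha))
  funnel$significant_adj <- sum(results$significant_adj)
  if (min(table(manifest$group)) < 5) {
    warn("Small group size (< 5); differential statistics are unstable.")
  }

  out <- structure(
    list(
      manifest = manifest, features = features, aligned = aligned,
      alignments = alignments, refmap = refmap, consensuses = cons,
      scaler = norm$scaler, standards = standards,
      assignments = assignments, quant = quant, results = results,
      funnel = funnel, truth = truth, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$funnel)) {
    cat(sprintf("  %-15s %d\n", nm, x$funnel[[nm]]))
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(result$features)) {
    write_feature_table(
      result$features[[sid]],
      file.path(out_dir, paste0(sid, "_features.csv"))
    )
  }
  readr::write_csv(result$refmap, file.path(out_dir, "reference_map.csv"))
  align_report <- purrr::imap_dfr(result$alignments, function(m, sid) {
    tibble(
      sample_id = sid,
      time_slope = m$time["slope"], time_intercept = m$time["intercept"],
      mass_slope = m$mass["slope"], mass_intercept = m$mass["intercept"],
      n_support = m$n_support
    )
  })
  readr::write_csv(align_report, file.path(out_dir, "alignment_report.csv"))
  readr::write_csv(result$scaler, file.path(out_dir, "intensity_scaler.csv"))
  readr::write_csv(
    consensus_matrix(result$consensuses),
    file.path(out_dir, "consensus_matrix.csv")
  )
  readr::write_csv(result$assignments, file.path(out_dir, "assignments.csv"))
  readr::write_csv(result$quant$abundance, file.path(out_dir, "protein_abundance.csv"))
  readr::write_csv(result$results, file.path(out_dir, "differential_report.csv"))
  prov <- list(
    package = as.character(packageVersion("cemspep")),
    r_version = R.version.string,
    seed = result$config$seed,
    thresholds = result$config[c(
      "snr", "ref_freq", "n_standards", "standard_min_freq",
      "min_peptides", "alpha", "max_missed"
    )],
    funnel = result$funnel
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}
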