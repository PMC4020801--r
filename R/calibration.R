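#' Select high-frequency reference features for calibration
#'
#' Provisionally clusters the (unaligned) per-sample feature tables with
#' [match_features()] and keeps clusters detected in at least `threshold` of
#' the samples. The canonical coordinates of each reference are the
#' across-sample medians of its member features. The result is
#' order-independent: permuting the samples yields the same references.
#'
#' @param feature_tables Named list of per-sample feature tibbles (names =
#'   sample ids), as produced by [deconvolute_peaks()].
#' @param threshold Minimum detection frequency (default 0.35).
#' @return A tibble `ref_id`, `mass`, `time`, `frequency` (class
#'   `reference_map`).
#' @export
select_reference_features <- function(feature_tables, threshold = 0.35) {
  if (length(feature_tables) < 3) {
    abort("Need at least 3 samples to select reference features.")
  }
  combined <- bind_rows(feature_tables, .id = "sample_id")
  cons <- match_features(combined, n_samples = length(feature_tables))
  keep <- cons$peptides$frequency >= threshold
  if (!any(keep)) {
    abort("No cluster reaches the reference frequency threshold; calibration impossible.")
  }
  # canonical coordinates: across-sample medians of member features
  refs <- cons$peptides[keep, ]
  member_medians <- member_coordinates(combined, cons)
  refs <- left_join(refs, member_medians, by = "id") |>
    transmute(
      ref_id = .data$id,
      mass = .data$median_mass,
      time = .data$median_time,
      frequency = .data$frequency
    ) |>
    arrange(.data$mass)
  class(refs) <- c("reference_map", class(refs))
  refs
}

# Median member coordinates per consensus id, via the feature_row membership
# bookkeeping of match_features.
member_coordinates <- function(combined, cons) {
  cons$intensities |>
    mutate(
      median_mass = combined$neutral_mass[.data$feature_row],
      median_time = combined$migration_time_min[.data$feature_row]
    ) |>
    group_by(.data$id) |>
    summarise(
      median_mass = median(.data$median_mass),
      median_time = median(.data$median_time),
      .groups = "drop"
    )
}

#' @importFrom dplyr transmute
NULL

#' Calibrate a cohort of feature tables by iterated reference alignment
#'
#' One calibration pass selects references with
#' [select_reference_features()], fits each sample with [fit_alignment()] and
#' transforms it with [apply_alignment()]. Because the first reference set is
#' built from still-drifted features, its clusters are fragmented and biased;
#' a second pass re-selects references from the aligned features and refits
#' the original coordinates against them, which tightens the cohort frame
#' considerably. Samples that fail to align are dropped with a warning.
#'
#' @param features Named list of per-sample feature tibbles.
#' @param threshold Reference frequency threshold (default 0.35).
#' @param n_iter Number of calibration passes (default 2).
#' @return A list: `aligned` (named list of aligned feature tables),
#'   `alignments` (named list of `alignment_model`s from the final pass),
#'   `refmap` (final reference map), `failed` (character vector of dropped
#'   sample ids).
#' @export
calibrate_cohort <- function(features, threshold = 0.35, n_iter = 2) {
  current <- features
  models <- setNames(vector("list", length(features)), names(features))
  refmap <- NULL
  for (pass in seq_len(n_iter)) {
    refmap <- select_reference_features(current, threshold = threshold)
    # coarse first pass: inflated matching windows absorb gross drift
    wscale <- if (pass == 1) 3 else 1
    aligned <- list()
    for (sid in names(current)) {
      model <- tryCatch(
        fit_alignment(current[[sid]], refmap, window_scale = wscale),
        error = function(e) NULL
      )
      if (is.null(model)) next
      models[[sid]] <- compose_alignment(models[[sid]], model)
      aligned[[sid]] <- apply_alignment(current[[sid]], model)
    }
    current <- aligned
  }
  failed <- setdiff(names(features), names(current))
  models <- models[names(current)]
  if (length(failed) > 0) {
    warn(sprintf(
      "Dropped %d sample(s) that failed calibration: %s.",
      length(failed), paste(failed, collapse = ", ")
    ))
  }
  list(
    aligned = current, alignments = models, refmap = refmap,
    failed = failed
  )
}

# Compose two linear calibrations: `outer` is applied after `inner`; the
# result maps the original coordinates directly into the final frame.
compose_alignment <- function(inner, outer) {
  if (is.null(inner)) {
    return(outer)
  }
  comp_axis <- function(a, b) {
    c(
      slope = unname(b["slope"] * a["slope"]),
      intercept = unname(b["slope"] * a["intercept"] + b["intercept"])
    )
  }
  structure(
    list(
      time = comp_axis(inner$time, outer$time),
      mass = comp_axis(inner$mass, outer$mass),
      n_support = outer$n_support,
      pairs = outer$pairs
    ),
    class = "alignment_model"
  )
}

#' Fit a per-sample linear calibration against the reference map
#'
#' Matches the sample's features to the cohort references (nearest feature
#' within the mass tolerance and CE window of each reference, evaluated at the
#' reference coordinates) and fits ordinary least squares of canonical on
#' observed coordinates, separately for migration time and mass. The returned
#' model therefore maps observed coordinates into the cohort reference frame.
#' Matches must be reciprocal (mutual nearest), and an optional iterated
#' robust trim (3.5 x MAD of the residuals, two rounds) removes mismatched
#' pairs before the final fit.
#'
#' Samples matching fewer than `min_support` references, or yielding a slope
#' outside (0.5, 2), raise an alignment-failure error rather than passing
#' silently.
#'
#' @param features One sample's feature tibble.
#' @param refmap A `reference_map` from [select_reference_features()].
#' @param min_support Minimum matched references (default 5).
#' @param trim Apply the 3-SD outlier-trim refit pass (default TRUE).
#' @param window_scale Inflation factor on the time matching window (used by
#'   the coarse first pass of [calibrate_cohort()]); the mass window is never
#'   inflated because mass drift stays well inside the nominal tolerance.
#' @return An `alignment_model`: list with `time` and `mass` coefficient
#'   vectors `(slope, intercept)`, `n_support`, and the matched pairs.
#' @export
fit_alignment <- function(features, refmap, min_support = 5, trim = TRUE,
                          window_scale = 1) {
  pairs <- match_to_references(features, refmap, window_scale)
  if (nrow(pairs) < min_support) {
    abort(sprintf(
      "Alignment failure: only %d reference(s) matched (need >= %d).",
      nrow(pairs), min_support
    ))
  }
  fit_axis <- function(obs, can) {
    fit <- lm(can ~ obs)
    if (trim && nrow(pairs) > min_support) {
      # iterated robust trim: mismatched reference pairs are gross outliers
      # relative to the residual scale of correct pairs and would otherwise
      # attenuate the fitted drift toward the identity
      cf <- coef(fit)
      for (it in 1:2) {
        r <- can - (cf[1] + cf[2] * obs)
        s <- mad(r)
        keep <- if (s > 0) abs(r) <= 3.5 * s else rep(TRUE, length(r))
        if (sum(keep) >= min_support && any(!keep)) {
          cf <- coef(lm(can[keep] ~ obs[keep]))
        } else {
          break
        }
      }
      return(c(slope = unname(cf[2]), intercept = unname(cf[1])))
    }
    c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  }
  time_c <- fit_axis(pairs$obs_time, pairs$ref_time)
  mass_c <- fit_axis(pairs$obs_mass, pairs$ref_mass)
  for (sl in c(time_c["slope"], mass_c["slope"])) {
    if (sl <= 0.5 || sl >= 2) {
      abort(sprintf("Calibration failure: slope %.3f outside (0.5, 2).", sl))
    }
  }
  structure(
    list(
      time = time_c, mass = mass_c,
      n_support = nrow(pairs), pairs = pairs
    ),
    class = "alignment_model"
  )
}

# One observed feature per reference: nearest in tolerance-normalized units,
# kept only when the match is reciprocal (the reference is also that
# feature's nearest reference) — one-sided nearest matching preferentially
# pairs drifted features with time-closer wrong references and attenuates
# the fitted drift.
match_to_references <- function(features, refmap, window_scale = 1) {
  fm <- features$neutral_mass
  ft <- features$migration_time_min
  tol_m <- mass_window_da(refmap$mass)
  tol_t <- time_window_min(refmap$time) * window_scale
  # nearest feature for each reference
  best_feat <- vapply(seq_len(nrow(refmap)), function(i) {
    dm <- abs(fm - refmap$mass[i])
    dt <- abs(ft - refmap$time[i])
    ok <- which(dm <= tol_m[i] & dt <= tol_t[i])
    if (length(ok) == 0) {
      return(NA_integer_)
    }
    ok[which.min((dm[ok] / tol_m[i])^2 + (dt[ok] / tol_t[i])^2)]
  }, integer(1))
  # reciprocal check: the reference must also be its feature's nearest
  best_ref <- vapply(unique(best_feat[!is.na(best_feat)]), function(j) {
    dm <- abs(refmap$mass - fm[j])
    dt <- abs(refmap$time - ft[j])
    ok <- which(dm <= tol_m & dt <= tol_t)
    if (length(ok) == 0) {
      return(NA_integer_)
    }
    ok[which.min((dm[ok] / tol_m[ok])^2 + (dt[ok] / tol_t[ok])^2)]
  }, integer(1))
  names(best_ref) <- as.character(unique(best_feat[!is.na(best_feat)]))
  keep <- which(
    !is.na(best_feat) &
      best_ref[as.character(best_feat)] == seq_along(best_feat)
  )
  out <- tibble(
    ref_id = refmap$ref_id[keep],
    ref_mass = refmap$mass[keep],
    ref_time = refmap$time[keep],
    obs_mass = fm[best_feat[keep]],
    obs_time = ft[best_feat[keep]]
  )
  # a feature may not serve two references
  distinct(out, .data$obs_mass, .data$obs_time, .keep_all = TRUE)
}

#' @export
print.alignment_model <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<alignment_model> n_support = %d\n",
      "  time: slope %.5f, intercept %+.4f min\n",
      "  mass: slope %.7f, intercept %+.5f Da\n"
    ),
    x$n_support, x$time["slope"], x$time["intercept"],
    x$mass["slope"], x$mass["intercept"]
  ))
  invisible(x)
}

#' Apply an alignment model to a sample's features
#'
#' Transforms coordinates into the cohort reference frame; intensities and
#' feature count are untouched. The transformation is recorded in attribute
#' `alignment` as provenance.
#'
#' @param features One sample's feature tibble.
#' @param model An `alignment_model` from [fit_alignment()].
#' @return The transformed feature tibble.
#' @export
apply_alignment <- function(features, model) {
  stopifnot(inherits(model, "alignment_model"))
  out <- features
  out$migration_time_min <- model$time["slope"] * features$migration_time_min +
    model$time["intercept"]
  out$neutral_mass <- model$mass["slope"] * features$neutral_mass +
    model$mass["intercept"]
  attr(out, "alignment") <- list(time = model$time, mass = model$mass)
  out
}

#' Select internal-standard consensus peptides
#'
#' Candidates are consensus peptides detected in at least `min_freq` of the
#' samples whose case/control rank-sum p-value exceeds `p_threshold` — i.e.
#' consistently detected peptides with no evidence of disease association.
#' The top `n_standards` candidates by detection frequency are returned.
#'
#' @param consensuses A `consensus_set`.
#' @param manifest Tibble `sample_id`, `group` (`case` / `control`).
#' @param n_standards Number of standards to select (default 22).
#' @param min_freq Minimum detection frequency (default 0.8).
#' @param p_threshold Minimum rank-sum p-value (default 0.5).
#' @return Tibble `id`, `frequency`, `p_value` of the selected standards.
#' @export
select_internal_standards <- function(consensuses, manifest, n_standards = 22,
                                      min_freq = 0.8, p_threshold = 0.5) {
  stopifnot(inherits(consensuses, "consensus_set"))
  cand <- consensuses$peptides |> filter(.data$frequency >= min_freq)
  if (nrow(cand) == 0) {
    abort("No consensus peptide reaches the standard frequency threshold.")
  }
  labels <- setNames(manifest$group, manifest$sample_id)
  pvals <- vapply(cand$id, function(cid) {
    v <- consensuses$intensities |> filter(.data$id == cid)
    g <- labels[v$sample_id]
    x <- v$intensity[g == "case"]
    y <- v$intensity[g == "control"]
    if (length(x) < 2 || length(y) < 2) {
      return(0)
    }
    suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    )
  }, numeric(1))
  cand$p_value <- pvals
  cand |>
    filter(.data$p_value > p_threshold) |>
    arrange(desc(.data$frequency), desc(.data$p_value), .data$id) |>
    head(n_standards) |>
    select("id", "frequency", "p_value")
}

#' Normalize intensities to the internal standards
#'
#' Each sample is scaled by `reference median / sample median`, where the
#' sample median is taken over the standard peptides it detects and the
#' cohort reference median is the median over samples of those per-sample
#' medians. After scaling, every sample's median standard intensity equals
#' the cohort reference median, which makes the operation idempotent.
#' Samples detecting fewer than 3 standards are flagged and left unscaled
#' (factor 1).
#'
#' @param consensuses A `consensus_set` (aligned, singleton-filtered).
#' @param standards Standards tibble from [select_internal_standards()] or a
#'   character vector of consensus ids.
#' @return A list: `consensuses` (scaled `consensus_set`) and `scaler`
#'   (tibble `sample_id`, `factor`, `n_standards_detected`, `flagged`; class
#'   `intensity_scaler`).
#' @export
normalize_intensities <- function(consensuses, standards) {
  stopifnot(inherits(consensuses, "consensus_set"))
  std_ids <- if (is.character(standards)) standards else standards$id
  std_values <- consensuses$intensities |> filter(.data$id %in% std_ids)
  if (nrow(std_values) == 0) abort("No standard intensities found.")
  all_samples <- unique(consensuses$intensities$sample_id)
  per_sample <- std_values |>
    group_by(.data$sample_id) |>
    summarise(
      n_standards_detected = n(),
      sample_median = median(.data$intensity),
      .groups = "drop"
    )
  # cohort reference level: median over samples of the per-sample medians
  ref_median <- median(per_sample$sample_median)
  scaler <- tibble(sample_id = all_samples) |>
    left_join(per_sample, by = "sample_id") |>
    mutate(
      n_standards_detected = dplyr::coalesce(.data$n_standards_detected, 0L),
      flagged = .data$n_standards_detected < 3,
      factor = ifelse(.data$flagged, 1, ref_median / .data$sample_median)
    ) |>
    select("sample_id", "factor", "n_standards_detected", "flagged")
  if (any(scaler$flagged)) {
    warn(sprintf(
      "%d sample(s) detected < 3 standards; left unscaled (factor 1).",
      sum(scaler$flagged)
    ))
  }
  fac <- setNames(scaler$factor, scaler$sample_id)
  out <- consensuses
  out$intensities$intensity <-
    unname(out$intensities$intensity * fac[out$intensities$sample_id])
  class(scaler) <- c("intensity_scaler", class(scaler))
  list(consensuses = out, scaler = scaler)
}
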