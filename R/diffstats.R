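#' Roll consensus peptides up to a protein abundance matrix
#'
#' The abundance of a protein in a sample is the arithmetic mean of the
#' normalized intensities of that protein's peptides detected in the sample;
#' a protein with no detected peptide in a sample gets 0. Only annotated
#' consensus peptides belonging to proteins that survive the
#' minimum-peptides rule contribute.
#'
#' @param consensuses A `consensus_set` (aligned, normalized,
#'   singleton-filtered).
#' @param assignments Tibble from [annotate_features()].
#' @param manifest Tibble `sample_id`, `group`; every sample carrying
#'   intensities must be listed.
#' @param min_peptides Minimum distinct peptides per protein (default 2),
#'   enforced via [enforce_min_peptides()].
#' @param detected_only If `TRUE`, undetected (zero) abundances are dropped
#'   from the group vectors instead of entering as 0; default `FALSE`.
#' @return An object of class `protein_quant`: list with `abundance` (tibble,
#'   one row per protein, one column per sample), `labels` (manifest) and
#'   `detected_only`.
#' @export
protein_abundance_matrix <- function(consensuses, assignments, manifest,
                                     min_peptides = 2, detected_only = FALSE) {
  stopifnot(inherits(consensuses, "consensus_set"))
  samples_seen <- unique(consensuses$intensities$sample_id)
  missing_lab <- setdiff(samples_seen, manifest$sample_id)
  if (length(missing_lab) > 0) {
    abort(sprintf(
      "Sample(s) without a manifest label: %s.",
      paste(missing_lab, collapse = ", ")
    ))
  }
  kept <- enforce_min_peptides(assignments, k = min_peptides)
  use <- assignments |>
    filter(.data$annotated, .data$protein %in% kept$protein) |>
    select("id", "protein")
  per_cell <- consensuses$intensities |>
    dplyr::inner_join(use, by = "id") |>
    group_by(.data$protein, .data$sample_id) |>
    summarise(abundance = mean(.data$intensity), .groups = "drop")
  all_samples <- manifest$sample_id
  wide <- per_cell |>
    tidyr::pivot_wider(
      names_from = "sample_id", values_from = "abundance"
    )
  # ensure every manifest sample has a column, undetected -> 0
  for (s in setdiff(all_samples, names(wide))) wide[[s]] <- NA_real_
  wide <- wide[, c("protein", all_samples)]
  wide <- wide |> mutate(across(all_of(all_samples), ~ tidyr::replace_na(.x, 0)))
  structure(
    list(
      abundance = wide,
      labels = manifest[, c("sample_id", "group")],
      detected_only = detected_only
    ),
    class = "protein_quant"
  )
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf(
    "<protein_quant> %d proteins x %d samples (%d case / %d control)\n",
    nrow(x$abundance), nrow(x$labels),
    sum(x$labels$group == "case"), sum(x$labels$group == "control")
  ))
  invisible(x)
}

#' Two-group differential test with an F-test gate
#'
#' A two-sided variance-ratio F-test at `alpha` decides the test: if the
#' variances are compatible (gate p >= `alpha`) a two-sided equal-variance
#' t-test is used; otherwise a two-sided Mann-Whitney rank-sum test (normal
#' approximation without continuity correction, so a perfectly symmetric
#' split yields p = 1 exactly). If both groups have zero variance the test
#' is undefined: p = 1 by convention when the means are equal, and the
#' rank-sum branch handles the separated case.
#'
#' @param case,control Numeric vectors (>= 3 values each).
#' @param alpha Gate level for the F-test (default 0.05).
#' @return A one-row tibble: `raw_p`, `test_used` (`"t"` or `"ranksum"`),
#'   `gate_p` (the F-test p-value, `NA` when the gate was undefined).
#' @export
differential_test <- function(case, control, alpha = 0.05) {
  if (length(case) < 3 || length(control) < 3) {
    abort("Need at least 3 values per group.")
  }
  vx <- var(case)
  vy <- var(control)
  if (vx == 0 && vy == 0) {
    if (mean(case) == mean(control)) {
      return(tibble(raw_p = 1, test_used = "none", gate_p = NA_real_))
    }
    # complete separation with no within-group spread: rank-sum
    p <- mann_whitney_p(case, control)
    return(tibble(raw_p = p, test_used = "ranksum", gate_p = NA_real_))
  }
  if (vx > 0 && vy > 0) {
    gate_p <- var.test(case, control)$p.value
  } else {
    gate_p <- 0 # one degenerate variance: treat as non-normal
  }
  if (gate_p >= alpha) {
    p <- t.test(case, control, var.equal = TRUE)$p.value
    tibble(raw_p = p, test_used = "t", gate_p = gate_p)
  } else {
    tibble(raw_p = mann_whitney_p(case, control), test_used = "ranksum", gate_p = gate_p)
  }
}

mann_whitney_p <- function(x, y) {
  suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values with an explicit test count
#'
#' Step-up FDR adjustment: with the p-values sorted ascending, the adjusted
#' value at rank i is `min over j >= i of p(j) * m_total / j`, capped at 1,
#' and returned in the original input order. `m_total` may exceed the number
#' of p-values supplied when further tests were performed but not listed
#' (their p-values are assumed at least as large as the supplied maximum, so
#' they cannot lower any running minimum).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param m_total Total number of tests (defaults to `length(p)`; must be at
#'   least that).
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03), m_total = 10)
#' @export
bh_adjust <- function(p, m_total = length(p)) {
  if (length(p) == 0) {
    return(numeric())
  }
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  if (m_total < length(p)) {
    abort("`m_total` must be at least `length(p)`.")
  }
  n <- length(p)
  o <- order(p)
  stepped <- p[o] * m_total / seq_len(n)
  adj_sorted <- pmin(1, rev(cummin(rev(stepped))))
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

#' Fold change between case and control abundances
#'
#' `fold = mean(case) / mean(control)`. The accompanying spread,
#' `fold_sd`, is the standard deviation of the per-case-sample values divided
#' by the control mean — the dispersion of the case group expressed on the
#' fold scale.
#'
#' @param case,control Numeric abundance vectors.
#' @return One-row tibble `fold`, `fold_sd`; both `NA` (with a warning) when
#'   the control mean is not positive.
#' @examples
#' fold_change(c(2, 4), c(1, 1)) # fold 3
#' @export
fold_change <- function(case, control) {
  mc <- mean(control)
  if (!is.finite(mc) || mc <= 0) {
    warn("Control mean is not positive; fold change undefined.")
    return(tibble(fold = NA_real_, fold_sd = NA_real_))
  }
  tibble(fold = mean(case) / mc, fold_sd = sd(case) / mc)
}

#' Per-protein differential abundance report
#'
#' Runs [differential_test()] and [fold_change()] for every protein of a
#' [protein_abundance_matrix()] result and adjusts the raw p-values with
#' [bh_adjust()] across all tested proteins (`m_total` = number tested).
#' Proteins are reported sorted by raw p-value.
#'
#' @param quant A `protein_quant`.
#' @param alpha Significance level for the flags and the F-test gate.
#' @return A tibble of class `differential_results`: `protein`, `fold_change`,
#'   `fold_sd`, `raw_p`, `adj_p`, `test_used`, `significant_raw`,
#'   `significant_adj`; attributes `m_total` and `alpha`.
#' @export
summarize_results <- function(quant, alpha = 0.05) {
  stopifnot(inherits(quant, "protein_quant"))
  labels <- quant$labels
  case_ids <- labels$sample_id[labels$group == "case"]
  ctrl_ids <- labels$sample_id[labels$group == "control"]
  ab <- quant$abundance
  empty <- tibble(
    protein = character(), fold_change = numeric(), fold_sd = numeric(),
    raw_p = numeric(), adj_p = numeric(), test_used = character(),
    significant_raw = logical(), significant_adj = logical()
  )
  if (nrow(ab) == 0 || length(case_ids) == 0 || length(ctrl_ids) == 0) {
    return(structure(empty,
      class = c("differential_results", class(empty)),
      m_total = 0L, alpha = alpha
    ))
  }
  rows <- purrr::map_dfr(seq_len(nrow(ab)), function(i) {
    x <- unlist(ab[i, case_ids], use.names = FALSE)
    y <- unlist(ab[i, ctrl_ids], use.names = FALSE)
    if (isTRUE(quant$detected_only)) {
      x <- x[x > 0]
      y <- y[y > 0]
    }
    if (length(x) < 3 || length(y) < 3) {
      return(NULL)
    }
    dt <- differential_test(x, y, alpha = alpha)
    fc <- suppressWarnings(fold_change(x, y))
    tibble(
      protein = ab$protein[i],
      fold_change = fc$fold, fold_sd = fc$fold_sd,
      raw_p = dt$raw_p, test_used = dt$test_used
    )
  })
  if (nrow(rows) == 0) {
    return(structure(empty,
      class = c("differential_results", class(empty)),
      m_total = 0L, alpha = alpha
    ))
  }
  rows$adj_p <- bh_adjust(rows$raw_p, m_total = nrow(rows))
  rows <- rows |>
    mutate(
      significant_raw = .data$raw_p < alpha,
      significant_adj = .data$adj_p < alpha
    ) |>
    arrange(.data$raw_p) |>
    select(
      "protein", "fold_change", "fold_sd", "raw_p", "adj_p",
      "test_used", "significant_raw", "significant_adj"
    )
  structure(rows,
    class = c("differential_results", class(rows)),
    m_total = nrow(rows), alpha = alpha
  )
}
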