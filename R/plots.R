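#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_hline
#'   facet_wrap labs scale_x_log10 scale_y_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Peptide map of a consensus set
#'
#' Migration time against neutral mass, one point per consensus peptide,
#' shaded by detection frequency — the classic CE-MS peptide-map view.
#'
#' @param object A `consensus_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_set <- function(object, ...) {
  ggplot(object$peptides, aes(
    x = .data$time, y = .data$mass,
    colour = .data$frequency
  )) +
    geom_point(alpha = 0.7) +
    scale_y_log10() +
    labs(
      x = "Migration time (min)", y = "Neutral mass (Da)",
      colour = "Frequency", title = "Consensus peptide map"
    ) +
    theme_minimal()
}

#' Calibration scatter of an alignment model
#'
#' Observed against canonical coordinates of the matched references, with the
#' identity line for orientation, facetted by axis.
#'
#' @param object An `alignment_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.alignment_model <- function(object, ...) {
  p <- object$pairs
  df <- bind_rows(
    tibble(axis = "time (min)", observed = p$obs_time, canonical = p$ref_time),
    tibble(axis = "mass (Da)", observed = p$obs_mass, canonical = p$ref_mass)
  )
  ggplot(df, aes(x = .data$observed, y = .data$canonical)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    facet_wrap(~ .data$axis, scales = "free") +
    labs(
      x = "Observed", y = "Canonical",
      title = "Calibration against cohort references"
    ) +
    theme_minimal()
}

#' Volcano plot of differential results
#'
#' log2 fold change against -log10 raw p, coloured by BH significance.
#'
#' @param object A `differential_results` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.differential_results <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- tidy(object)
  ggplot(df, aes(
    x = log2(.data$fold_change), y = -log10(.data$raw_p),
    colour = .data$significant_adj
  )) +
    geom_point() +
    geom_hline(yintercept = -log10(alpha), linetype = 2) +
    labs(
      x = "log2 fold change (case / control)",
      y = "-log10 raw p",
      colour = sprintf("BH adj p < %.2g", alpha),
      title = "Differential protein abundance"
    ) +
    theme_minimal()
}
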