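#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an alignment model
#'
#' @param x An `alignment_model`.
#' @param ... Unused.
#' @return A tibble with one row per (axis, term) coefficient.
#' @export
tidy.alignment_model <- function(x, ...) {
  tibble(
    axis = rep(c("time", "mass"), each = 2),
    term = rep(c("slope", "intercept"), 2),
    estimate = c(
      x$time["slope"], x$time["intercept"],
      x$mass["slope"], x$mass["intercept"]
    )
  )
}

#' @rdname tidy.alignment_model
#' @export
glance.alignment_model <- function(x, ...) {
  tibble(
    n_support = x$n_support,
    time_slope = unname(x$time["slope"]),
    time_intercept = unname(x$time["intercept"]),
    mass_slope = unname(x$mass["slope"]),
    mass_intercept = unname(x$mass["intercept"])
  )
}

#' Tidy differential results
#'
#' `tidy()` returns the per-protein table as a plain tibble; `glance()` a
#' one-row summary.
#'
#' @param x A `differential_results` object.
#' @param ... Unused.
#' @export
tidy.differential_results <- function(x, ...) {
  as_tibble(unclass_results(x))
}

#' @rdname tidy.differential_results
#' @export
glance.differential_results <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    n_significant_raw = sum(x$significant_raw),
    n_significant_adj = sum(x$significant_adj),
    m_total = attr(x, "m_total"),
    alpha = attr(x, "alpha")
  )
}

unclass_results <- function(x) {
  class(x) <- setdiff(class(x), "differential_results")
  x
}
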