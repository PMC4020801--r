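#' Peptide-identity tolerance model
#'
#' Two features measured in different samples are treated as the same peptide
#' when their neutral masses and migration times agree within mass- and
#' time-dependent windows. Both windows grow linearly between two anchors and
#' are clamped outside them:
#'
#' * mass: ±50 ppm at 800 Da rising to ±75 ppm at 15 kDa;
#' * migration time: ±2% of the time at 19 min rising to ±5% at 50 min.
#'
#' The windows are half-widths, i.e. symmetric about the reference coordinate.
#'
#' @param mass Neutral peptide mass in Da (vectorised, all > 0).
#' @param anchors Numeric matrix-like list of two `(x, value)` anchors; the
#'   defaults encode the model above and rarely need changing.
#' @return `mass_tolerance()`: tolerance in ppm; `ce_window()`: half-width as a
#'   percentage of the migration time.
#' @examples
#' mass_tolerance(c(800, 7900, 15000)) # 50, 62.5, 75
#' ce_window(c(19, 34.5, 50)) # 2, 3.5, 5
#' @export
mass_tolerance <- function(mass,
                           anchors = list(c(800, 50), c(15000, 75))) {
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    abort("`mass` must be positive and finite.")
  }
  interp_clamped(mass, anchors[[1]], anchors[[2]])
}

#' @param time Migration time in minutes (vectorised, all > 0).
#' @rdname mass_tolerance
#' @export
ce_window <- function(time,
                      anchors = list(c(19, 2), c(50, 5))) {
  if (!is.numeric(time) || any(!is.finite(time)) || any(time <= 0)) {
    abort("`time` must be positive and finite.")
  }
  interp_clamped(time, anchors[[1]], anchors[[2]])
}

interp_clamped <- function(x, lo, hi) {
  slope <- (hi[2] - lo[2]) / (hi[1] - lo[1])
  out <- lo[2] + slope * (x - lo[1])
  pmin(pmax(out, min(lo[2], hi[2])), max(lo[2], hi[2]))
}

# Absolute windows in native units, evaluated at a reference coordinate.
mass_window_da <- function(mass) mass_tolerance(mass) * 1e-6 * mass
time_window_min <- function(time) ce_window(time) / 100 * time
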