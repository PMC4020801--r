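#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise
#'   ungroup left_join n row_number desc across all_of distinct pull rename
#' @importFrom stats median mad lm coef var t.test var.test wilcox.test rnorm
#'   runif rbinom rlnorm dbinom sd predict setNames quantile
#' @importFrom utils head packageVersion
NULL

# Run code with a temporary RNG state so generators are deterministic and do
# not disturb the caller's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a per-unit seed from a base seed; stays inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 9973) %% 2147483647)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

# Collapse an integer charge set to the serialized "2;3" form and back.
charges_to_chr <- function(charges) {
  vapply(charges, function(z) paste(sort(unique(z)), collapse = ";"), character(1))
}

chr_to_charges <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(s) sort(as.integer(s)))
}
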