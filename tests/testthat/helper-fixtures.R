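# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from disk.

# A small cohort design, cached per option set within one test run.
local({
  cache <- new.env(parent = emptyenv())
  small_cohort <<- function(seed = 7, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- cohort_design(
        n_case = 5, n_control = 5, n_proteins = 12, mean_length = 100,
        n_decoys = 500, seed = seed, ...
      )
    }
    cache[[key]]
  }
})

# Build a consensus_set by hand from a long intensity table.
make_consensus_set <- function(intensities, peptides = NULL, n_samples = NULL) {
  n_samples <- n_samples %||% dplyr::n_distinct(intensities$sample_id)
  if (is.null(peptides)) {
    peptides <- intensities |>
      dplyr::group_by(id) |>
      dplyr::summarise(
        mass = 1000, time = 30, n_samples = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::mutate(
        charges = list(2L),
        frequency = n_samples / !!n_samples
      )
  }
  structure(
    list(
      peptides = peptides, intensities = intensities,
      n_cohort_samples = n_samples
    ),
    class = "consensus_set"
  )
}

# Per-sample feature tables straight from a simulated sample's truth map
# (one feature per detected peptide), bypassing deconvolution.
truth_features <- function(sim_sample) {
  tr <- dplyr::filter(sim_sample$truth, !is_decoy, isotope == 0)
  tr |>
    dplyr::group_by(sequence) |>
    dplyr::summarise(
      neutral_mass = charge[1] * mz[1] - charge[1] * 1.00728,
      migration_time_min = migration_time_min[1],
      intensity = sum(intensity),
      charges = list(sort(unique(charge))),
      .groups = "drop"
    ) |>
    dplyr::select(-sequence)
}

`%||%` <- rlang::`%||%`
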