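#' Read and write per-sample peak tables
#'
#' Peak tables are tab-separated with the header
#' `mz  intensity  migration_time_min`. Reading validates the schema and the
#' values: missing columns raise a schema error naming the column, negative
#' intensities a validation error.
#'
#' @param path File path.
#' @return A tibble `mz`, `intensity`, `migration_time_min`.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("mz", "intensity", "migration_time_min")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Peak table '%s' is missing column(s): %s.",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  df <- df[, required]
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0) {
    abort(sprintf(
      "Column '%s' of '%s' is not numeric.", names(df)[bad[1]], path
    ))
  }
  neg <- which(df$intensity < 0)
  if (length(neg) > 0) {
    abort(sprintf(
      "Negative intensity at data line %d of '%s'.", neg[1], path
    ))
  }
  as_tibble(df)
}

#' @param peaks Peak tibble to write.
#' @rdname read_peak_table
#' @export
write_peak_table <- function(peaks, path) {
  required <- c("mz", "intensity", "migration_time_min")
  stopifnot(all(required %in% names(peaks)))
  readr::write_tsv(peaks[, required], path, progress = FALSE)
  invisible(path)
}

#' Read / write a protein database as FASTA
#'
#' @param path FASTA file path.
#' @return A tibble `accession`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble(
    accession = sub("\\s.*$", "", names(aa)),
    sequence = as.character(aa)
  )
}

#' @param db Tibble `accession`, `sequence`.
#' @rdname read_protein_fasta
#' @export
write_protein_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(setNames(db$sequence, db$accession))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path CSV with columns `sample_id`, `group` (values `case` or
#'   `control`).
#' @return A tibble `sample_id`, `group`.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    abort("Manifest must have columns `sample_id` and `group`.")
  }
  if (!all(df$group %in% c("case", "control"))) {
    abort("Manifest `group` values must be 'case' or 'control'.")
  }
  as_tibble(df[, c("sample_id", "group")])
}

#' Write a feature table to CSV
#'
#' Serializes the `charges` list-column as a `;`-separated string.
#'
#' @param features Feature tibble from [deconvolute_peaks()].
#' @param path Output path.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  if (is.list(out$charges)) out$charges <- charges_to_chr(out$charges)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df$charges <- chr_to_charges(df$charges)
  as_tibble(df)
}
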