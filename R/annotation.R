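#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (P), and emits every peptide carrying at most
#' `max_missed` missed cleavages. Carbamidomethylation of cysteine
#' (+57.02146 Da) is applied as a fixed modification; oxidation of methionine
#' and hydroxylation of proline (+15.99491 Da each) are enumerated as variable
#' modifications with at most `max_var_sites` modified sites per peptide.
#' Variable modifications are tracked as site counts, not positions: two
#' placements of the same modification on one peptide are isobaric and
#' indistinguishable by mass.
#'
#' @param sequence A single protein sequence over the 20 standard residues.
#' @param max_missed Maximum missed cleavages, between 0 and 3.
#' @param protein Optional accession carried through to the output.
#' @param fixed_cam Apply carbamidomethyl-C as a fixed modification.
#' @param variable_mods Enumerate oxidised-M / hydroxy-P variants.
#' @param max_var_sites Cap on variable-modification sites per peptide.
#' @return A tibble with one row per (peptide, modification state):
#'   `sequence`, `protein`, `missed`, `n_cam`, `n_ox`, `n_hyp`, `mods`
#'   (human-readable summary), `mass` (monoisotopic, Da), `charge`
#'   (predicted CE charge).
#' @examples
#' digest_protein("AARGGKPLLK", max_missed = 0)
#' @export
digest_protein <- function(sequence, max_missed = 1, protein = NA_character_,
                           fixed_cam = TRUE, variable_mods = TRUE,
                           max_var_sites = 2) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    abort("`sequence` must be a single non-empty string.")
  }
  if (!is.numeric(max_missed) || max_missed < 0 || max_missed > 3) {
    abort("`max_missed` must be between 0 and 3.")
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(RESIDUE_MASSES))
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid residue '%s' at position %d of `sequence`.", res[bad[1]], bad[1]
    ))
  }
  n <- length(res)
  # cleavage sites: index i means cut between i and i+1
  sites <- which(res %in% c("K", "R"))
  sites <- sites[sites < n & res[pmin(sites + 1L, n)] != "P"]
  bounds <- c(0L, sites, n)
  nfrag <- length(bounds) - 1L
  # enumerate fragment runs (i..j) with j - i <= max_missed, vectorised
  i_idx <- rep(seq_len(nfrag), each = max_missed + 1L)
  j_idx <- i_idx + rep(0:max_missed, times = nfrag)
  okrun <- j_idx <= nfrag
  i_idx <- i_idx[okrun]
  j_idx <- j_idx[okrun]
  start <- bounds[i_idx] + 1L
  end <- bounds[j_idx + 1L]
  peps <- substring(sequence, start, end)
  missed <- j_idx - i_idx
  # residue-sum masses via cumulative sums
  cs <- c(0, cumsum(unname(RESIDUE_MASSES[res])))
  base_mass <- cs[end + 1L] - cs[start]
  n_c <- as.integer(stringr::str_count(peps, stringr::fixed("C")))
  n_m <- as.integer(stringr::str_count(peps, stringr::fixed("M")))
  n_p <- as.integer(stringr::str_count(peps, stringr::fixed("P")))
  n_cam <- if (fixed_cam) n_c else 0L
  base_mass <- base_mass + WATER_MASS + n_cam * MOD_CARBAMIDOMETHYL
  combos <- if (variable_mods) {
    cb <- expand.grid(n_ox = 0:max_var_sites, n_hyp = 0:max_var_sites)
    cb[cb$n_ox + cb$n_hyp <= max_var_sites, , drop = FALSE]
  } else {
    data.frame(n_ox = 0L, n_hyp = 0L)
  }
  out <- purrr::pmap_dfr(combos, function(n_ox, n_hyp) {
    sel <- n_m >= n_ox & n_p >= n_hyp
    if (!any(sel)) {
      return(NULL)
    }
    cam_sel <- n_cam[sel]
    tibble(
      sequence = peps[sel],
      missed = missed[sel],
      n_cam = cam_sel,
      n_ox = as.integer(n_ox),
      n_hyp = as.integer(n_hyp),
      mods = mod_label(cam_sel, n_ox, n_hyp),
      mass = base_mass[sel] + n_ox * MOD_OXIDATION + n_hyp * MOD_HYDROXYLATION
    )
  })
  out$protein <- protein
  out$charge <- predict_charge(out$sequence)
  out <- out[order(out$missed, out$sequence, out$n_ox, out$n_hyp), ]
  out[, c(
    "sequence", "protein", "missed", "n_cam", "n_ox", "n_hyp",
    "mods", "mass", "charge"
  )]
}

mod_label <- function(n_cam, n_ox, n_hyp) {
  lab <- function(cam, ox, hyp) {
    parts <- c(
      if (cam > 0) sprintf("cam:%d", cam),
      if (ox > 0) sprintf("ox:%d", ox),
      if (hyp > 0) sprintf("hyp:%d", hyp)
    )
    if (length(parts) == 0) "" else paste(parts, collapse = ";")
  }
  mapply(lab, n_cam, n_ox, n_hyp, USE.NAMES = FALSE)
}

#' Digest every protein of a database
#'
#' @param db A tibble with columns `accession` and `sequence` (as returned by
#'   [generate_protein_db()] or [read_protein_fasta()]).
#' @inheritParams digest_protein
#' @return A tibble of theoretical peptides; see [digest_protein()].
#' @export
digest_proteins <- function(db, max_missed = 1, fixed_cam = TRUE,
                            variable_mods = TRUE, max_var_sites = 2) {
  stopifnot(all(c("accession", "sequence") %in% names(db)))
  purrr::map2_dfr(db$sequence, db$accession, function(s, a) {
    digest_protein(s, max_missed,
      protein = a, fixed_cam = fixed_cam,
      variable_mods = variable_mods, max_var_sites = max_var_sites
    )
  })
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water (18.01056 Da) plus
#' modification deltas.
#'
#' @param sequence Character vector of peptide sequences.
#' @param n_cam,n_ox,n_hyp Numbers of carbamidomethyl, oxidation and
#'   hydroxylation modifications. `n_cam = NULL` (default) fixes
#'   carbamidomethylation on every cysteine.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' peptide_mass("G") # 75.03202
#' @export
peptide_mass <- function(sequence, n_cam = NULL, n_ox = 0, n_hyp = 0) {
  base <- vapply(sequence, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!res %in% names(RESIDUE_MASSES))
    if (length(bad) > 0) {
      abort(sprintf("Invalid residue '%s' at position %d.", res[bad[1]], bad[1]))
    }
    sum(RESIDUE_MASSES[res])
  }, numeric(1), USE.NAMES = FALSE)
  if (is.null(n_cam)) {
    n_cam <- stringr::str_count(sequence, stringr::fixed("C"))
  }
  base + WATER_MASS + n_cam * MOD_CARBAMIDOMETHYL +
    n_ox * MOD_OXIDATION + n_hyp * MOD_HYDROXYLATION
}

#' Predicted CE charge of a peptide
#'
#' At the acidic pH of the CE separation the N-terminus and the side chains of
#' lysine, arginine and histidine are protonated, so the predicted solution
#' charge is `1 + #K + #R + #H`.
#'
#' @param sequence Character vector of peptide sequences.
#' @return Integer vector of predicted charges (>= 1).
#' @examples
#' predict_charge(c("GASA", "GKRA", "HHKK")) # 1, 3, 5
#' @export
predict_charge <- function(sequence) {
  1L + as.integer(stringr::str_count(sequence, "[KRH]"))
}

#' Assign consensus peptides to theoretical sequences
#'
#' For each consensus peptide, candidate theoretical peptides are those whose
#' monoisotopic mass lies within the mass tolerance (evaluated at the
#' theoretical mass). When several candidates remain, those whose predicted CE
#' charge is among the consensus's observed charge states are preferred —
#' near-isobaric peptides usually differ in basic-residue content and hence in
#' CE charge. Remaining ties go to the smallest absolute mass error, then to
#' fewer variable modifications, then to the lexicographically smaller
#' sequence. Consensus peptides without a candidate are returned unannotated.
#'
#' @param consensuses A `consensus_set` (see [match_features()]) or a tibble
#'   with columns `id`, `mass` and a `charges` list-column.
#' @param digest_db Theoretical peptide tibble from [digest_proteins()].
#' @return A tibble with one row per consensus: `id`, `annotated`, `sequence`,
#'   `protein`, `mods`, `theo_mass`, `mass_error_ppm`, `predicted_charge`,
#'   `charge_consistent`.
#' @export
annotate_features <- function(consensuses, digest_db) {
  if (inherits(consensuses, "consensus_set")) {
    consensuses <- consensuses$peptides
  }
  if (nrow(digest_db) == 0) abort("`digest_db` is empty.")
  ord <- order(digest_db$mass)
  db <- digest_db[ord, ]
  dbmass <- db$mass
  rows <- purrr::pmap(
    list(consensuses$id, consensuses$mass, consensuses$charges),
    function(id, m, zset) {
      # widest window any candidate could need
      w <- mass_window_da(m) * 1.6
      lo <- findInterval(m - w, dbmass) + 1L
      hi <- findInterval(m + w, dbmass)
      if (hi < lo) {
        return(unannotated_row(id))
      }
      cand <- db[lo:hi, ]
      err <- m - cand$mass
      ok <- abs(err) <= mass_window_da(cand$mass)
      cand <- cand[ok, ]
      err <- err[ok]
      if (nrow(cand) == 0) {
        return(unannotated_row(id))
      }
      consistent <- cand$charge %in% zset
      if (nrow(cand) > 1 && any(consistent)) {
        cand <- cand[consistent, ]
        err <- err[consistent]
        consistent <- rep(TRUE, nrow(cand))
      }
      ppm <- err / cand$mass * 1e6
      pick <- order(abs(ppm), cand$n_ox + cand$n_hyp, cand$sequence, cand$mods)[1]
      tibble(
        id = id, annotated = TRUE,
        sequence = cand$sequence[pick], protein = cand$protein[pick],
        mods = cand$mods[pick], theo_mass = cand$mass[pick],
        mass_error_ppm = ppm[pick],
        predicted_charge = cand$charge[pick],
        charge_consistent = cand$charge[pick] %in% zset
      )
    }
  )
  bind_rows(rows)
}

unannotated_row <- function(id) {
  tibble(
    id = id, annotated = FALSE, sequence = NA_character_,
    protein = NA_character_, mods = NA_character_, theo_mass = NA_real_,
    mass_error_ppm = NA_real_, predicted_charge = NA_integer_,
    charge_consistent = NA
  )
}

#' Enforce the minimum-peptides-per-protein rule
#'
#' Proteins represented by fewer than `k` distinct assigned peptide sequences
#' are dropped from protein-level analysis; the dropped accessions are
#' reported as an attribute and via a message.
#'
#' @param assignments Tibble from [annotate_features()].
#' @param k Minimum number of distinct peptide sequences (default 2).
#' @return A tibble `protein`, `n_peptides`, `peptides` (list-column of
#'   sequences) for the retained proteins, with attribute `dropped`.
#' @export
enforce_min_peptides <- function(assignments, k = 2) {
  if (!is.numeric(k) || k < 1) abort("`k` must be >= 1.")
  annotated <- dplyr::filter(assignments, .data$annotated)
  per_protein <- annotated |>
    group_by(.data$protein) |>
    summarise(
      n_peptides = dplyr::n_distinct(.data$sequence),
      peptides = list(sort(unique(.data$sequence))),
      .groups = "drop"
    )
  dropped <- per_protein$protein[per_protein$n_peptides < k]
  kept <- per_protein[per_protein$n_peptides >= k, ]
  if (length(dropped) > 0) {
    inform(sprintf(
      "Dropped %d protein(s) with fewer than %d peptides.", length(dropped), k
    ))
  }
  attr(kept, "dropped") <- dropped
  kept
}
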