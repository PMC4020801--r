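#' Robust noise-floor estimate for a peak list
#'
#' The random-noise level is estimated as 1.4826 times the median absolute
#' deviation of the intensities lying below the intensity median — a robust
#' floor estimate that ignores the (arbitrarily strong) signal population.
#' A degenerate estimate of zero is clamped to machine epsilon and flagged
#' with attribute `degenerate`.
#'
#' @param peaks A peak tibble with an `intensity` column (>= 10 rows).
#' @return A positive scalar noise level (counts).
#' @export
estimate_noise <- function(peaks) {
  x <- peaks$intensity
  if (length(x) < 10) {
    abort("Need at least 10 peaks to estimate the noise level.")
  }
  sub <- x[x < median(x)]
  est <- if (length(sub) >= 2) mad(sub) else 0
  if (!is.finite(est) || est <= 0) {
    est <- .Machine$double.eps
    attr(est, "degenerate") <- TRUE
  }
  est
}

#' Infer the charge of an isotope envelope from its peak spacings
#'
#' Successive isotopologue peaks of a charge-z peptide are spaced
#' `1.00235 / z` Th apart. Every successive spacing must match an integer
#' multiple (1 or 2, allowing one missing isotope) of `1.00235 / z` within
#' `tol_ppm` of the base m/z; the smallest charge in `charge_range` that fits
#' is returned, `NA` if none does or if the envelope has a single peak.
#'
#' @param mz Numeric vector of m/z values, sorted ascending, of co-eluting
#'   peaks presumed to form one envelope.
#' @param charge_range Candidate charges (default 1:10).
#' @param tol_ppm Spacing tolerance in ppm of the base m/z (default 20).
#' @return An integer charge, or `NA_integer_`.
#' @examples
#' infer_charge(c(500, 500.501175, 501.00235)) # 2
#' @export
infer_charge <- function(mz, charge_range = 1:10, tol_ppm = 20) {
  if (length(mz) < 2) {
    return(NA_integer_)
  }
  if (is.unsorted(mz)) abort("`mz` must be sorted ascending.")
  diffs <- diff(mz)
  tol <- tol_ppm * 1e-6 * mz[1]
  for (z in sort(charge_range)) {
    spacing <- ISOTOPE_SPACING / z
    mult <- round(diffs / spacing)
    ok <- mult >= 1 & mult <= 2 & abs(diffs - mult * spacing) <= tol
    if (all(ok)) {
      return(as.integer(z))
    }
  }
  NA_integer_
}

#' Deconvolute a peak list into neutral-mass features
#'
#' Three stages: (1) peaks with `intensity / noise <= snr_threshold` are
#' discarded; (2) surviving peaks are grouped into isotope envelopes —
#' starting from the most intense unassigned peak, co-eluting peaks (within
#' the CE time window) are matched to an isotope grid `mz0 + k * 1.00235 / z`
#' within `tol_ppm`, and the smallest charge explaining the most peaks wins;
#' (3) envelopes with charge <= 1 are dropped and the rest are merged across
#' charge states whenever their neutral masses agree within the mass tolerance
#' and their times within the CE window, giving one feature per molecule with
#' summed intensity and the union of its charge states.
#'
#' The neutral monoisotopic mass of an envelope is `z * mz_mono - z * 1.00728`
#' where `mz_mono` is the lowest-isotope peak retained.
#'
#' @param peaks Peak tibble (`mz`, `intensity`, `migration_time_min`).
#' @param noise Noise level from [estimate_noise()] (> 0).
#' @param snr_threshold Signal-to-noise cutoff (default 4; peaks must exceed
#'   it strictly).
#' @param charge_range Candidate charges for envelope fitting.
#' @param tol_ppm Isotope-grid tolerance in ppm of the seed m/z.
#' @return A feature tibble: `neutral_mass` (Da), `migration_time_min`,
#'   `intensity` (summed), `charges` (list-column of integer charge states),
#'   `snr` (max member peak over noise), `n_peaks`.
#' @export
deconvolute_peaks <- function(peaks, noise, snr_threshold = 4,
                              charge_range = 1:10, tol_ppm = 10) {
  if (!is.numeric(noise) || noise <= 0) abort("`noise` must be > 0.")
  empty <- tibble(
    neutral_mass = numeric(), migration_time_min = numeric(),
    intensity = numeric(), charges = list(), snr = numeric(),
    n_peaks = integer()
  )
  if (nrow(peaks) == 0) {
    return(empty)
  }
  keep <- peaks$intensity / noise > snr_threshold
  mz <- peaks$mz[keep]
  it <- peaks$intensity[keep]
  tm <- peaks$migration_time_min[keep]
  n <- length(mz)
  if (n == 0) {
    return(empty)
  }
  envelopes <- extract_envelopes(mz, it, tm, charge_range, tol_ppm)
  envelopes <- envelopes[envelopes$charge >= 2, , drop = FALSE]
  if (nrow(envelopes) == 0) {
    return(empty)
  }
  feats <- merge_charge_states(envelopes)
  feats$snr <- feats$max_peak / noise
  feats$max_peak <- NULL
  feats
}

# Indices of the maximal run of consecutive integers in sorted `kk` that
# contains the anchor value.
contiguous_run <- function(kk, anchor) {
  pos <- match(anchor, kk)
  lo <- pos
  while (lo > 1 && kk[lo - 1] == kk[lo] - 1L) lo <- lo - 1L
  hi <- pos
  while (hi < length(kk) && kk[hi + 1] == kk[hi] + 1L) hi <- hi + 1L
  lo:hi
}

# Greedy isotope-envelope extraction. Returns one row per envelope with
# monoisotopic neutral mass, time, summed intensity, charge, strongest peak.
extract_envelopes <- function(mz, it, tm, charge_range, tol_ppm) {
  n <- length(mz)
  assigned <- rep(FALSE, n)
  ord <- order(it, decreasing = TRUE)
  zmax <- max(charge_range)
  rows <- vector("list", n)
  nr <- 0L
  for (i in ord) {
    if (assigned[i]) next
    mz0 <- mz[i]
    t0 <- tm[i]
    twin <- time_window_min(max(t0, 1e-6))
    cand <- which(!assigned &
      abs(tm - t0) <= twin &
      mz >= mz0 - 2.1 & mz <= mz0 + 5.1)
    tol <- tol_ppm * 1e-6 * mz0
    best_z <- NA_integer_
    best_members <- i
    best_score <- 1L
    seed_int <- it[i]
    for (z in sort(charge_range)) {
      spacing <- ISOTOPE_SPACING / z
      k <- round((mz[cand] - mz0) / spacing)
      resid <- abs(mz[cand] - (mz0 + k * spacing))
      sel <- resid <= tol & k >= -2 & k <= 5
      if (sum(sel) < 2) next
      # one peak per isotope index: keep the closest
      idx <- cand[sel]
      kk <- k[sel]
      rr <- resid[sel]
      o <- order(kk, rr)
      dup <- duplicated(kk[o])
      members <- idx[o][!dup]
      kk <- kk[o][!dup]
      # an isotope pattern is a contiguous run of isotopologues containing
      # the seed; restricting to it avoids capturing strays from co-eluting
      # envelopes on a coincident grid point
      run <- contiguous_run(kk, 0L)
      members <- members[run]
      kk <- kk[run]
      # peaks below the monoisotopic seed must be plausibly intense
      ok_low <- kk >= 0 | it[members] >= 0.4 * seed_int
      members <- members[ok_low]
      score <- length(members)
      if (score > best_score) {
        best_z <- z
        best_members <- members
        best_score <- score
      }
    }
    assigned[best_members] <- TRUE
    if (is.na(best_z)) next # singleton: charge indeterminate, dropped
    mono <- best_members[which.min(mz[best_members])]
    nr <- nr + 1L
    rows[[nr]] <- list(
      neutral_mass = best_z * mz[mono] - best_z * PROTON_MASS,
      migration_time_min = sum(tm[best_members] * it[best_members]) /
        sum(it[best_members]),
      intensity = sum(it[best_members]),
      charge = best_z,
      max_peak = max(it[best_members]),
      n_peaks = length(best_members)
    )
  }
  if (nr == 0L) {
    return(tibble(
      neutral_mass = numeric(), migration_time_min = numeric(),
      intensity = numeric(), charge = integer(), max_peak = numeric(),
      n_peaks = integer()
    ))
  }
  bind_rows(lapply(rows[seq_len(nr)], as_tibble))
}

# Merge envelopes that are charge states of one molecule: greedy by
# intensity; a joining envelope must fall within the mass tolerance and CE
# window of the feature centroid. Nearest feature in normalized (mass, time)
# units wins; ties go to the lower-mass feature.
merge_charge_states <- function(envelopes) {
  o <- order(envelopes$intensity, decreasing = TRUE)
  env <- envelopes[o, ]
  nmax <- nrow(env)
  fm <- numeric(nmax) # centroid mass
  ft <- numeric(nmax) # centroid time
  fw <- numeric(nmax) # intensity weight
  fi <- numeric(nmax) # summed intensity
  fp <- numeric(nmax) # strongest member peak
  fn <- integer(nmax) # member peak count
  fz <- vector("list", nmax)
  nf <- 0L
  for (i in seq_len(nmax)) {
    m <- env$neutral_mass[i]
    t <- env$migration_time_min[i]
    w <- env$intensity[i]
    joined <- FALSE
    if (nf > 0L) {
      cm <- fm[seq_len(nf)]
      ct <- ft[seq_len(nf)]
      dm <- abs(cm - m)
      dt <- abs(ct - t)
      tol_m <- mass_window_da(cm)
      tol_t <- time_window_min(ct)
      # a feature never holds two envelopes of the same charge: those are
      # different molecules, not charge states of one
      zfree <- !vapply(
        fz[seq_len(nf)], function(zz) env$charge[i] %in% zz, logical(1)
      )
      ok <- which(dm <= tol_m & dt <= tol_t & zfree)
      if (length(ok) > 0) {
        d <- sqrt((dm[ok] / tol_m[ok])^2 + (dt[ok] / tol_t[ok])^2)
        best <- ok[order(d, cm[ok])][1]
        fm[best] <- (fm[best] * fw[best] + m * w) / (fw[best] + w)
        ft[best] <- (ft[best] * fw[best] + t * w) / (fw[best] + w)
        fw[best] <- fw[best] + w
        fi[best] <- fi[best] + env$intensity[i]
        fp[best] <- max(fp[best], env$max_peak[i])
        fn[best] <- fn[best] + env$n_peaks[i]
        fz[[best]] <- sort(unique(c(fz[[best]], env$charge[i])))
        joined <- TRUE
      }
    }
    if (!joined) {
      nf <- nf + 1L
      fm[nf] <- m
      ft[nf] <- t
      fw[nf] <- w
      fi[nf] <- env$intensity[i]
      fp[nf] <- env$max_peak[i]
      fn[nf] <- env$n_peaks[i]
      fz[[nf]] <- env$charge[i]
    }
  }
  idx <- seq_len(nf)
  tibble(
    neutral_mass = fm[idx],
    migration_time_min = ft[idx],
    intensity = fi[idx],
    charges = fz[idx],
    max_peak = fp[idx],
    n_peaks = fn[idx]
  ) |> arrange(.data$neutral_mass)
}
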