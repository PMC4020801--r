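#' Cluster aligned features across samples into consensus peptides
#'
#' Greedy intensity-ordered centroid clustering. Features from all samples are
#' visited in decreasing intensity order; each joins the nearest existing
#' consensus whose centroid lies within both the mass tolerance
#' ([mass_tolerance()], evaluated at the centroid mass) and the CE time window
#' ([ce_window()], evaluated at the centroid time), provided that consensus
#' has no feature from the same sample yet; otherwise it seeds a new
#' consensus. Centroids are intensity-weighted means and are updated as
#' members join; "nearest" is the smallest Euclidean distance in
#' tolerance-normalized (mass, time) units, with ties going to the lower-mass
#' centroid. The ordering rule makes the clustering fully deterministic.
#'
#' @param features A tibble of aligned, intensity-normalized features from all
#'   samples: columns `sample_id`, `neutral_mass`, `migration_time_min`,
#'   `intensity`, optionally `charges` (list-column).
#' @param n_samples Total number of samples in the cohort (defaults to the
#'   number of distinct `sample_id`s present); the denominator of detection
#'   frequency.
#' @return An object of class `consensus_set`: list with
#'   * `peptides`: tibble `id`, `mass`, `time`, `charges` (list-column of the
#'     union of member charge states), `n_samples`, `frequency`;
#'   * `intensities`: long tibble `id`, `sample_id`, `intensity` (absent
#'     combination = not detected);
#'   * `n_cohort_samples`.
#' @export
match_features <- function(features, n_samples = NULL) {
  stopifnot(all(c(
    "sample_id", "neutral_mass", "migration_time_min", "intensity"
  ) %in% names(features)))
  n_samples <- n_samples %||% dplyr::n_distinct(features$sample_id)
  has_charges <- "charges" %in% names(features)
  o <- order(features$intensity, decreasing = TRUE)
  f <- features[o, ]
  sample_idx <- match(f$sample_id, unique(features$sample_id))
  nmax <- nrow(f)
  cm <- numeric(nmax)
  ct <- numeric(nmax)
  cw <- numeric(nmax)
  cz <- vector("list", nmax)
  members <- vector("list", nmax) # row indices into f
  csamples <- vector("list", nmax) # sample index set
  nc <- 0L
  assign_to <- integer(nmax)
  for (i in seq_len(nmax)) {
    m <- f$neutral_mass[i]
    t <- f$migration_time_min[i]
    w <- f$intensity[i]
    s <- sample_idx[i]
    target <- 0L
    if (nc > 0L) {
      live <- seq_len(nc)
      dm <- abs(cm[live] - m)
      dt <- abs(ct[live] - t)
      tol_m <- mass_window_da(cm[live])
      tol_t <- time_window_min(ct[live])
      ok <- which(dm <= tol_m & dt <= tol_t)
      if (length(ok) > 0) {
        # drop consensuses already holding this sample
        free <- ok[!vapply(csamples[ok], function(ss) s %in% ss, logical(1))]
        if (length(free) > 0) {
          d <- sqrt((dm[free] / tol_m[free])^2 + (dt[free] / tol_t[free])^2)
          target <- free[order(d, cm[free])][1]
        }
      }
    }
    if (target > 0L) {
      cm[target] <- (cm[target] * cw[target] + m * w) / (cw[target] + w)
      ct[target] <- (ct[target] * cw[target] + t * w) / (cw[target] + w)
      cw[target] <- cw[target] + w
      members[[target]] <- c(members[[target]], i)
      csamples[[target]] <- c(csamples[[target]], s)
      if (has_charges) {
        cz[[target]] <- sort(unique(c(cz[[target]], f$charges[[i]])))
      }
      assign_to[i] <- target
    } else {
      nc <- nc + 1L
      cm[nc] <- m
      ct[nc] <- t
      cw[nc] <- w
      members[[nc]] <- i
      csamples[[nc]] <- s
      cz[[nc]] <- if (has_charges) sort(unique(f$charges[[i]])) else integer()
      assign_to[i] <- nc
    }
  }
  # maximality pass: centroid updates during the greedy sweep can leave two
  # consensuses inside each other's joint tolerance; merge such pairs while
  # their sample sets stay disjoint (sample uniqueness is preserved)
  live <- rep(TRUE, nc)
  repeat {
    merged_any <- FALSE
    ord_m <- order(cm[seq_len(nc)])
    ord_m <- ord_m[live[ord_m]]
    for (a_pos in seq_along(ord_m)) {
      a <- ord_m[a_pos]
      if (!live[a]) next
      b_pos <- a_pos + 1L
      while (b_pos <= length(ord_m)) {
        b <- ord_m[b_pos]
        b_pos <- b_pos + 1L
        if (!live[b]) next
        dm <- abs(cm[b] - cm[a])
        if (dm > mass_window_da(max(cm[a], cm[b]))) break
        dt <- abs(ct[b] - ct[a])
        in_tol <- (dm <= mass_window_da(cm[a]) & dt <= time_window_min(ct[a])) |
          (dm <= mass_window_da(cm[b]) & dt <= time_window_min(ct[b]))
        if (!in_tol) next
        if (length(intersect(csamples[[a]], csamples[[b]])) > 0) next
        cm[a] <- (cm[a] * cw[a] + cm[b] * cw[b]) / (cw[a] + cw[b])
        ct[a] <- (ct[a] * cw[a] + ct[b] * cw[b]) / (cw[a] + cw[b])
        cw[a] <- cw[a] + cw[b]
        members[[a]] <- c(members[[a]], members[[b]])
        csamples[[a]] <- c(csamples[[a]], csamples[[b]])
        cz[[a]] <- sort(unique(c(cz[[a]], cz[[b]])))
        live[b] <- FALSE
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  idx <- which(live[seq_len(nc)])
  # features of merged consensuses follow their new owner
  final_assign <- integer(nmax)
  for (k in seq_along(idx)) {
    final_assign[members[[idx[k]]]] <- k # members holds row indices into f
  }
  ids <- sprintf("C%05d", seq_along(idx))
  n_contrib <- lengths(csamples[idx])
  freq <- n_contrib / n_samples
  peptides <- tibble(
    id = ids,
    mass = cm[idx],
    time = ct[idx],
    charges = cz[idx],
    n_samples = n_contrib,
    frequency = freq
  )
  intensities <- tibble(
    id = ids[final_assign],
    sample_id = f$sample_id,
    intensity = f$intensity,
    feature_row = o # row index into the input feature table
  ) |> arrange(.data$id, .data$sample_id)
  structure(
    list(
      peptides = peptides, intensities = intensities,
      n_cohort_samples = n_samples
    ),
    class = "consensus_set"
  )
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf(
    "<consensus_set> %d consensus peptides across %d samples\n",
    nrow(x$peptides), x$n_cohort_samples
  ))
  print(head(x$peptides, 5))
  invisible(x)
}

#' Remove consensus peptides seen in only one sample
#'
#' Sporadically observed peptides carry no cross-sample information; any
#' consensus with a single contributing sample is removed. The number dropped
#' is reported as a message and stored in attribute `n_dropped`.
#'
#' @param x A `consensus_set`.
#' @return The filtered `consensus_set`.
#' @export
filter_singletons <- function(x) {
  stopifnot(inherits(x, "consensus_set"))
  drop_ids <- x$peptides$id[x$peptides$n_samples == 1]
  if (length(drop_ids) > 0) {
    inform(sprintf("Removed %d singleton consensus peptide(s).", length(drop_ids)))
    x$peptides <- x$peptides[!x$peptides$id %in% drop_ids, ]
    x$intensities <- x$intensities[!x$intensities$id %in% drop_ids, ]
  }
  attr(x, "n_dropped") <- length(drop_ids)
  x
}

#' Consensus intensity matrix in wide form
#'
#' @param x A `consensus_set`.
#' @return A tibble with one row per consensus (`id`, `mass`, `time`,
#'   `frequency`) and one column per sample; `NA` = not detected.
#' @export
consensus_matrix <- function(x) {
  stopifnot(inherits(x, "consensus_set"))
  wide <- tidyr::pivot_wider(
    x$intensities[, c("id", "sample_id", "intensity")],
    names_from = "sample_id", values_from = "intensity"
  )
  dplyr::left_join(
    x$peptides[, c("id", "mass", "time", "frequency")], wide,
    by = "id"
  )
}
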