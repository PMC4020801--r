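#' Generate a random protein database
#'
#' Sequences are drawn over the 20 standard residues with lysine/arginine
#' frequencies tuned so that a fully cleaved tryptic digest yields peptides of
#' roughly 8-12 residues, i.e. mostly inside the 804-3953 Da mass window the
#' pipeline works in. Each protein is redrawn (deterministically) until its
#' zero-missed-cleavage digest contains at least two in-range peptides, so any
#' generated database supports the minimum-two-peptides protein rule.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param mean_length Mean sequence length (>= 50).
#' @param seed Integer seed; the same call with the same seed is identical.
#' @return A tibble `accession`, `sequence`.
#' @export
generate_protein_db <- function(n_proteins, mean_length, seed = 1) {
  if (!is.numeric(n_proteins) || n_proteins < 2) {
    abort("`n_proteins` must be >= 2.")
  }
  if (!is.numeric(mean_length) || mean_length < 50) {
    abort("`mean_length` must be >= 50.")
  }
  # residue frequencies: uniform background with K/R boosted to ~11% combined
  freqs <- setNames(rep(1, 20), names(RESIDUE_MASSES))
  freqs[c("K", "R")] <- 2.4
  freqs[c("C", "W")] <- 0.4 # rare residues
  freqs <- freqs / sum(freqs)
  with_seed(seed, {
    seqs <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      repeat {
        len <- max(50L, round(rnorm(1, mean_length, 0.15 * mean_length)))
        s <- paste(
          sample(names(freqs), len, replace = TRUE, prob = freqs),
          collapse = ""
        )
        dig <- digest_protein(s,
          max_missed = 0, variable_mods = FALSE
        )
        in_range <- dig$mass >= PEPTIDE_MASS_RANGE[1] &
          dig$mass <= PEPTIDE_MASS_RANGE[2]
        if (sum(in_range) >= 2) break
      }
      seqs[i] <- s
    }
    tibble(
      accession = sprintf("SYNP%04d", seq_len(n_proteins)),
      sequence = seqs
    )
  })
}

# Fold-change magnitudes reported for the 19 differential vitreous proteins;
# used as the default spike-in pattern of the simulator.
DEFAULT_FOLD_MAGNITUDES <- c(
  6.56, 1.91, 3.14, 5.50, 4.55, 1.74, 3.28, 10.85, 2.78, 2.30,
  2.90, 35.34, 2.58, 1.74, 1.65, 2.92, 4.26, 1.73, 2.34
)

#' Design a ground-truth synthetic CE-MS cohort
#'
#' Builds the fixed, deterministic "truth" layer of a simulated case/control
#' cohort: a random protein database and its in-range tryptic peptides, true
#' case/control fold changes (by default the 19 reported differential-protein
#' magnitudes spiked onto randomly chosen proteins, all others at 1), a set of
#' invariant internal-standard peptides, per-sample linear drift in migration
#' time and mass, and the noise / missingness parameters used when samples are
#' materialised with [simulate_sample_peaks()].
#'
#' The migration model places a peptide of neutral mass M and predicted CE
#' charge z at a time proportional to `M^(2/3) / (z + 0.15 * n_polar)` —
#' classical electrophoretic mobility scaling with a neutral-polar-residue
#' correction (`n_polar` counts S, T, N, Q, Y, C, W), since composition as
#' well as mass and charge determines CE migration — affinely mapped into the
#' 19-50 min acquisition window.
#'
#' @param n_case,n_control Group sizes (default 20 / 15).
#' @param n_proteins,mean_length Protein database size passed to
#'   [generate_protein_db()].
#' @param fold_changes Optional named numeric vector `accession -> fold`;
#'   default spikes `DEFAULT_FOLD_MAGNITUDES` onto a seeded-random subset.
#' @param n_standards Number of spiked invariant internal-standard peptides.
#' @param noise_cv Coefficient of variation of multiplicative (lognormal)
#'   intensity noise.
#' @param detection_prob Per-peptide per-sample Bernoulli detection
#'   probability; `standard_detection_prob` the same for internal standards.
#' @param mass_jitter_ppm SD of per-(peptide, sample) Gaussian mass error, ppm.
#' @param time_jitter_pct SD of migration-time jitter as a percentage of the
#'   time.
#' @param drift If `TRUE`, each sample gets linear time drift (slope
#'   0.95-1.05, intercept ±1 min) and mass drift (slope 1±2e-5, intercept
#'   ±5 mDa); if `FALSE` all samples use the identity.
#' @param noise_floor Scale (counts) of the decoy noise floor.
#' @param n_decoys Number of decoy noise peaks per sample.
#' @param seed Integer seed controlling every random choice.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_case = 20, n_control = 15,
                          n_proteins = 97, mean_length = 120,
                          fold_changes = NULL,
                          n_standards = 22,
                          noise_cv = 0.2,
                          detection_prob = 0.7,
                          standard_detection_prob = 0.9,
                          mass_jitter_ppm = 5,
                          time_jitter_pct = 0.3,
                          drift = TRUE,
                          noise_floor = 50,
                          n_decoys = 3000,
                          seed = 1) {
  assert_scalar_number(n_case, "n_case", positive = TRUE)
  assert_scalar_number(n_control, "n_control", positive = TRUE)
  assert_scalar_number(noise_cv, "noise_cv")
  if (detection_prob <= 0 || detection_prob > 1) {
    abort("`detection_prob` must be in (0, 1].")
  }
  db <- generate_protein_db(n_proteins, mean_length, seed = seed)
  with_seed(derive_seed(seed, 1L), {
    # truth peptides: fully cleaved digest, fixed carbamidomethyl, in range
    peptides <- digest_proteins(db, max_missed = 0, variable_mods = FALSE) |>
      filter(
        .data$mass >= PEPTIDE_MASS_RANGE[1],
        .data$mass <= PEPTIDE_MASS_RANGE[2]
      ) |>
      distinct(.data$sequence, .keep_all = TRUE)
    if (is.null(fold_changes)) {
      k <- min(length(DEFAULT_FOLD_MAGNITUDES), n_proteins)
      spiked <- sample(db$accession, k)
      fold_changes <- setNames(rep(1, n_proteins), db$accession)
      fold_changes[spiked] <- DEFAULT_FOLD_MAGNITUDES[seq_len(k)]
    } else {
      missing_acc <- setdiff(db$accession, names(fold_changes))
      fold_changes <- c(fold_changes, setNames(rep(1, length(missing_acc)), missing_acc))
      fold_changes <- fold_changes[db$accession]
    }
    if (any(fold_changes <= 0)) abort("All true fold changes must be > 0.")
    # protein base abundances and fixed per-peptide ionization efficiencies
    base_abundance <- setNames(rlnorm(n_proteins, log(3e4), 1), db$accession)
    peptides$efficiency <- rlnorm(nrow(peptides), 0, 0.5)
    peptides$abundance <- base_abundance[peptides$protein] * peptides$efficiency
    # invariant internal-standard peptides (spiked, not in the FASTA)
    standards <- make_standard_peptides(n_standards)
    standards$abundance <- rlnorm(n_standards, log(3e4), 0.5)
    # migration model over everything the cohort can emit; the effective
    # charge carries a neutral-polar-residue term so that composition, not
    # only mass and charge, sets the migration coordinate
    all_mass <- c(peptides$mass, standards$mass)
    all_z <- c(peptides$charge, standards$charge)
    all_polar <- stringr::str_count(
      c(peptides$sequence, standards$sequence), "[STNQYCW]"
    )
    u <- all_mass^(2 / 3) / (all_z + 0.15 * all_polar)
    rng <- range(u)
    migration_map <- list(u_min = rng[1], u_max = rng[2])
    t0 <- map_migration(u, migration_map)
    peptides$time <- t0[seq_len(nrow(peptides))]
    standards$time <- t0[nrow(peptides) + seq_len(n_standards)]
    # per-sample manifest and drift
    n <- n_case + n_control
    samples <- tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      group = rep(c("case", "control"), c(n_case, n_control))
    )
    if (isTRUE(drift)) {
      samples$time_slope <- runif(n, 0.95, 1.05)
      samples$time_intercept <- runif(n, -1, 1)
      samples$mass_slope <- 1 + runif(n, -2e-5, 2e-5)
      samples$mass_intercept <- runif(n, -5e-3, 5e-3)
    } else {
      samples$time_slope <- 1
      samples$time_intercept <- 0
      samples$mass_slope <- 1
      samples$mass_intercept <- 0
    }
    structure(
      list(
        protein_db = db,
        peptides = peptides,
        standards = standards,
        true_fold_changes = fold_changes,
        samples = samples,
        migration_map = migration_map,
        noise_cv = noise_cv,
        detection_prob = detection_prob,
        standard_detection_prob = standard_detection_prob,
        mass_jitter_ppm = mass_jitter_ppm,
        time_jitter_pct = time_jitter_pct,
        noise_floor = noise_floor,
        n_decoys = n_decoys,
        group_sizes = c(case = n_case, control = n_control),
        seed = as.integer(seed)
      ),
      class = "cohort_design"
    )
  })
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cohort_design> %d case + %d control samples\n",
      "  %d proteins, %d truth peptides, %d internal standards\n",
      "  noise_cv %.2f, detection %.2f, seed %d\n"
    ),
    x$group_sizes["case"], x$group_sizes["control"],
    nrow(x$protein_db), nrow(x$peptides), nrow(x$standards),
    x$noise_cv, x$detection_prob, x$seed
  ))
  invisible(x)
}

map_migration <- function(u, mm) {
  if (mm$u_max == mm$u_min) {
    return(rep(mean(CE_TIME_RANGE), length(u)))
  }
  CE_TIME_RANGE[1] + diff(CE_TIME_RANGE) * (u - mm$u_min) / (mm$u_max - mm$u_min)
}

# Random tryptic-like standard peptides: start from a non-basic body, end in
# K or R, redraw until the mass is inside the working range.
make_standard_peptides <- function(n_standards) {
  body <- setdiff(names(RESIDUE_MASSES), c("K", "R"))
  seqs <- character(n_standards)
  i <- 1L
  while (i <= n_standards) {
    len <- sample(7:25, 1)
    s <- paste0(
      paste(sample(body, len, replace = TRUE), collapse = ""),
      sample(c("K", "R"), 1)
    )
    m <- peptide_mass(s)
    if (m >= PEPTIDE_MASS_RANGE[1] && m <= PEPTIDE_MASS_RANGE[2] &&
      !s %in% seqs) {
      seqs[i] <- s
      i <- i + 1L
    }
  }
  tibble(
    sequence = seqs,
    mass = peptide_mass(seqs),
    charge = predict_charge(seqs)
  )
}

#' Simulate the CE-MS peak list of one sample
#'
#' Materialises the peaks a single sample contributes: every truth peptide is
#' detected with its Bernoulli probability; a detected peptide emits one
#' isotope-resolved envelope at its predicted CE charge (70% of the signal)
#' and one at the next charge up (30%), with isotope peaks spaced
#' `1.00235 / z` and relative intensities from a binomial isotopologue model
#' (`size ~ 0.044 * M`, `p = 0.0107`, i.e. one heavy-atom parameter per
#' ~1000 Da). Intensities are the true abundance (times the group fold change
#' for case samples) under multiplicative lognormal noise; neutral masses and
#' migration times carry the sample's linear drift plus small random jitter;
#' peaks outside m/z 350-3000 are dropped; uniform decoy noise peaks are added
#' below the signal-to-noise threshold.
#'
#' @param cohort A [cohort_design()].
#' @param sample_id A sample id present in `cohort$samples`.
#' @return An object of class `simulated_sample`: list with `sample_id`,
#'   `group`, `peaks` (tibble `mz`, `intensity`, `migration_time_min`) and
#'   `truth` (tibble mapping each peak to its peptide, charge, isotope and
#'   protein; decoy rows have `is_decoy = TRUE`).
#' @export
simulate_sample_peaks <- function(cohort, sample_id) {
  stopifnot(inherits(cohort, "cohort_design"))
  idx <- match(sample_id, cohort$samples$sample_id)
  if (is.na(idx)) {
    abort(sprintf("Unknown sample_id '%s'.", sample_id))
  }
  smp <- cohort$samples[idx, ]
  sdlog <- sqrt(log(1 + cohort$noise_cv^2))
  with_seed(derive_seed(cohort$seed, 100L + idx), {
    is_case <- smp$group == "case"
    pep <- cohort$peptides
    std <- cohort$standards
    fold <- if (is_case) cohort$true_fold_changes[pep$protein] else 1
    truth_all <- tibble(
      sequence = c(pep$sequence, std$sequence),
      protein = c(pep$protein, rep(NA_character_, nrow(std))),
      mass = c(pep$mass, std$mass),
      charge = c(pep$charge, std$charge),
      time = c(pep$time, std$time),
      abundance = c(pep$abundance * fold, std$abundance),
      is_standard = rep(c(FALSE, TRUE), c(nrow(pep), nrow(std))),
      p_detect = rep(
        c(cohort$detection_prob, cohort$standard_detection_prob),
        c(nrow(pep), nrow(std))
      )
    )
    detected <- truth_all[
      rbinom(nrow(truth_all), 1, truth_all$p_detect) == 1,
    ]
    n_det <- nrow(detected)
    # per-(peptide, sample) measurement effects, shared by the whole envelope
    detected$obs_abundance <- detected$abundance * rlnorm(n_det, 0, sdlog)
    m_jit <- detected$mass * (1 + rnorm(n_det, 0, cohort$mass_jitter_ppm) * 1e-6)
    detected$obs_mass <- smp$mass_slope * m_jit + smp$mass_intercept
    t_jit <- detected$time *
      (1 + rnorm(n_det, 0, cohort$time_jitter_pct / 100))
    detected$obs_time <- smp$time_slope * t_jit + smp$time_intercept
    signal <- emit_envelopes(detected)
    decoys <- tibble(
      mz = runif(cohort$n_decoys, MZ_RANGE[1], MZ_RANGE[2]),
      intensity = runif(cohort$n_decoys, 0.5, 4) * cohort$noise_floor,
      migration_time_min = runif(cohort$n_decoys, CE_TIME_RANGE[1], CE_TIME_RANGE[2]),
      sequence = NA_character_, protein = NA_character_,
      charge = NA_integer_, isotope = NA_integer_, is_standard = NA,
      is_decoy = TRUE
    )
    signal$is_decoy <- FALSE
    all_peaks <- bind_rows(signal, decoys) |>
      arrange(.data$migration_time_min, .data$mz) |>
      mutate(peak_id = row_number())
    structure(
      list(
        sample_id = smp$sample_id,
        group = smp$group,
        peaks = all_peaks[, c("mz", "intensity", "migration_time_min")],
        truth = all_peaks[, c(
          "peak_id", "sequence", "protein", "charge", "isotope",
          "is_standard", "is_decoy", "mz", "intensity", "migration_time_min"
        )]
      ),
      class = "simulated_sample"
    )
  })
}

# Expand detected peptides into isotope-resolved charge envelopes
# (vectorised: one row per peptide x charge state x isotope).
emit_envelopes <- function(detected) {
  if (nrow(detected) == 0) {
    return(tibble(
      mz = numeric(), intensity = numeric(), migration_time_min = numeric(),
      sequence = character(), protein = character(), charge = integer(),
      isotope = integer(), is_standard = logical()
    ))
  }
  nd <- nrow(detected)
  # isotopologue shares from the binomial model, one column per isotope
  size <- pmax(1, round(0.044 * detected$mass))
  iso <- vapply(0:5, function(k) dbinom(k, size, 0.0107), numeric(nd))
  keep <- iso >= 0.02 * apply(iso, 1, max)
  iso <- iso * keep
  iso <- iso / rowSums(iso)
  # two charge states per peptide
  row <- rep(seq_len(nd), 2L)
  z <- c(detected$charge, detected$charge + 1L)
  share <- rep(c(0.7, 0.3), each = nd)
  ok_z <- z >= 1L & z <= 8L
  row <- row[ok_z]
  z <- z[ok_z]
  share <- share[ok_z]
  # expand isotopes
  nk <- 6L
  ridx <- rep(row, each = nk)
  zidx <- rep(z, each = nk)
  sidx <- rep(share, each = nk)
  k <- rep(0:5, times = length(row))
  iso_share <- iso[cbind(ridx, k + 1L)]
  present <- iso_share > 0
  ridx <- ridx[present]
  zidx <- zidx[present]
  k <- k[present]
  out <- tibble(
    mz = (detected$obs_mass[ridx] + zidx * PROTON_MASS) / zidx +
      k * ISOTOPE_SPACING / zidx,
    intensity = detected$obs_abundance[ridx] * sidx[present] * iso_share[present],
    migration_time_min = detected$obs_time[ridx],
    sequence = detected$sequence[ridx],
    protein = detected$protein[ridx],
    charge = as.integer(zidx),
    isotope = as.integer(k),
    is_standard = detected$is_standard[ridx]
  )
  filter(out, .data$mz >= MZ_RANGE[1], .data$mz <= MZ_RANGE[2])
}

#' Simulate a full cohort, optionally writing all pipeline inputs to disk
#'
#' Generates every sample of the design and (when `dir` is given) writes the
#' per-sample peak tables (TSV), the protein database (FASTA), the cohort
#' manifest (CSV), a protein-level truth table (CSV) and per-sample truth
#' peak maps (CSV).
#'
#' @param cohort A [cohort_design()].
#' @param dir Output directory, created if needed; `NULL` keeps everything in
#'   memory.
#' @return A list: `samples` (named list of `simulated_sample`), `manifest`
#'   (tibble `sample_id`, `group`), `truth_proteins` (tibble `protein`,
#'   `true_fold`, `n_peptides`, `peptides`), `cohort`, and `paths` when
#'   written.
#' @export
simulate_cohort <- function(cohort, dir = NULL) {
  stopifnot(inherits(cohort, "cohort_design"))
  if (min(cohort$group_sizes) < 3) {
    abort("Both group sizes must be >= 3 for downstream statistics.")
  }
  samples <- lapply(cohort$samples$sample_id, function(sid) {
    simulate_sample_peaks(cohort, sid)
  })
  names(samples) <- cohort$samples$sample_id
  manifest <- cohort$samples[, c("sample_id", "group")]
  truth_proteins <- cohort$peptides |>
    group_by(protein = .data$protein) |>
    summarise(
      n_peptides = n(),
      peptides = paste(.data$sequence, collapse = ";"),
      .groups = "drop"
    ) |>
    mutate(true_fold = unname(cohort$true_fold_changes[.data$protein])) |>
    select("protein", "true_fold", "n_peptides", "peptides")
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) abort(sprintf("Cannot create directory '%s'.", dir))
    peak_paths <- file.path(dir, paste0(manifest$sample_id, "_peaks.tsv"))
    truth_paths <- file.path(dir, paste0(manifest$sample_id, "_truth.csv"))
    for (i in seq_along(samples)) {
      write_peak_table(samples[[i]]$peaks, peak_paths[i])
      readr::write_csv(samples[[i]]$truth, truth_paths[i])
    }
    fasta_path <- file.path(dir, "proteins.fasta")
    write_protein_fasta(cohort$protein_db, fasta_path)
    manifest_path <- file.path(dir, "manifest.csv")
    readr::write_csv(manifest, manifest_path)
    truth_path <- file.path(dir, "truth_proteins.csv")
    readr::write_csv(truth_proteins, truth_path)
    paths <- list(
      peaks = peak_paths, truth = truth_paths, fasta = fasta_path,
      manifest = manifest_path, truth_proteins = truth_path
    )
  }
  list(
    samples = samples, manifest = manifest,
    truth_proteins = truth_proteins, cohort = cohort, paths = paths
  )
}
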