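test_that("generated protein databases satisfy the digestibility contract", {
  db <- generate_protein_db(2, 60, seed = 1)
  expect_identical(nrow(db), 2L)
  for (s in db$sequence) {
    d <- digest_protein(s, max_missed = 0, variable_mods = FALSE)
    in_range <- d$mass >= 804 & d$mass <= 3953
    expect_gte(sum(in_range), 2)
  }
  # determinism
  expect_identical(db, generate_protein_db(2, 60, seed = 1))
  expect_false(identical(db, generate_protein_db(2, 60, seed = 2)))
  expect_error(generate_protein_db(1, 60), ">= 2")
  expect_error(generate_protein_db(5, 10), ">= 50")
})

test_that("a large database yields a peptide space wider than the proteome", {
  db <- generate_protein_db(97, 300, seed = 7)
  expect_identical(nrow(db), 97L)
  expect_identical(anyDuplicated(db$accession), 0L)
  d <- digest_proteins(db, max_missed = 0, variable_mods = FALSE)
  in_range <- d[d$mass >= 804 & d$mass <= 3953, ]
  expect_gt(dplyr::n_distinct(in_range$sequence), 97)
})

test_that("emitted peaks follow the m/z algebra and acquisition bounds", {
  ch <- cohort_design(
    n_case = 3, n_control = 3, n_proteins = 6, mean_length = 100,
    drift = FALSE, mass_jitter_ppm = 0, time_jitter_pct = 0,
    n_decoys = 100, seed = 3
  )
  s <- simulate_sample_peaks(ch, "S001")
  expect_identical(s$group, "case")
  expect_true(all(s$peaks$mz >= 350 & s$peaks$mz <= 3000))
  expect_true(all(ch$peptides$mass >= 804 & ch$peptides$mass <= 3953))
  # with identity drift and no jitter, mono m/z = (M + z * 1.00728) / z
  tr <- dplyr::filter(s$truth, !is_decoy, isotope == 0)
  truth_mass <- setNames(
    c(ch$peptides$mass, ch$standards$mass),
    c(ch$peptides$sequence, ch$standards$sequence)
  )
  expect_equal(
    tr$mz,
    (truth_mass[tr$sequence] + tr$charge * 1.00728) / tr$charge,
    tolerance = 1e-9, ignore_attr = TRUE
  )
  expect_error(simulate_sample_peaks(ch, "nope"), "Unknown sample_id")
})

test_that("isotope envelopes are spaced 1.00235 / z within 1e-9", {
  ch <- small_cohort()
  s <- simulate_sample_peaks(ch, "S002")
  env <- s$truth |>
    dplyr::filter(!is_decoy) |>
    dplyr::arrange(sequence, charge, isotope)
  by_env <- split(env, paste(env$sequence, env$charge))
  checked <- 0L
  for (e in by_env) {
    if (nrow(e) < 2) next
    expect_equal(diff(e$mz), diff(e$isotope) * 1.00235 / e$charge[1],
      tolerance = 1e-9
    )
    checked <- checked + 1L
  }
  expect_gt(checked, 10)
})

test_that("every non-decoy peak traces to exactly one peptide and charge", {
  s <- simulate_sample_peaks(small_cohort(), "S001")
  tr <- dplyr::filter(s$truth, !is_decoy)
  expect_false(any(is.na(tr$sequence)))
  expect_false(any(is.na(tr$charge)))
  expect_identical(anyDuplicated(tr$peak_id), 0L)
  expect_true(all(tr$peak_id %in% seq_len(nrow(s$peaks))))
  # decoys carry no truth
  dc <- dplyr::filter(s$truth, is_decoy)
  expect_true(all(is.na(dc$sequence)))
})

test_that("regeneration with a fixed seed is identical, and seeds differ", {
  ch <- small_cohort()
  s1 <- simulate_sample_peaks(ch, "S003")
  s2 <- simulate_sample_peaks(ch, "S003")
  expect_identical(s1, s2)
  s3 <- simulate_sample_peaks(ch, "S004")
  expect_false(identical(s1$peaks, s3$peaks))
})

test_that("internal standards have invariant pre-noise abundance", {
  ch <- cohort_design(
    n_case = 3, n_control = 3, n_proteins = 6, mean_length = 100,
    noise_cv = 0, drift = FALSE, standard_detection_prob = 1,
    n_decoys = 100, seed = 5
  )
  std_int <- function(sid) {
    simulate_sample_peaks(ch, sid)$truth |>
      dplyr::filter(is_standard) |>
      dplyr::group_by(sequence) |>
      dplyr::summarise(total = sum(intensity), .groups = "drop")
  }
  a <- std_int("S001") # case
  b <- std_int("S004") # control
  j <- dplyr::inner_join(a, b, by = "sequence")
  expect_gt(nrow(j), 15)
  expect_equal(j$total.x, j$total.y, tolerance = 1e-9)
})

test_that("detection counts match the Bernoulli expectation", {
  # ~100 peptides at detection probability 0.8; mean detected count over
  # many samples must sit within 3 standard errors of 0.8 * n_peptides
  ch <- cohort_design(
    n_case = 150, n_control = 150, n_proteins = 20, mean_length = 110,
    detection_prob = 0.8, n_decoys = 50, seed = 13
  )
  # restrict to peptides whose primary-charge envelope lies inside the
  # acquisition window: high-charge short peptides fall below m/z 350 and are
  # invisible regardless of the detection draw
  visible <- ch$peptides$sequence[
    (ch$peptides$mass + ch$peptides$charge * 1.00728) / ch$peptides$charge >= 352
  ]
  n_pep <- length(visible)
  expect_gt(n_pep, 50)
  n_rep <- 300L
  counts <- vapply(seq_len(n_rep), function(i) {
    s <- simulate_sample_peaks(ch, sprintf("S%03d", i))
    sum(visible %in% s$truth$sequence[!s$truth$is_decoy])
  }, numeric(1))
  se <- sqrt(n_pep * 0.8 * 0.2 / n_rep)
  expect_lt(abs(mean(counts) - 0.8 * n_pep), 3 * se)
})

test_that("simulate_cohort writes one peak table per sample plus the truth set", {
  ch <- cohort_design(
    n_case = 3, n_control = 3, n_proteins = 5, mean_length = 100,
    n_decoys = 100, seed = 9
  )
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(ch, dir = dir)
  expect_length(sim$samples, 6)
  expect_identical(nrow(sim$manifest), 6L)
  expect_length(list.files(dir, pattern = "_peaks\\.tsv$"), 6)
  expect_true(file.exists(file.path(dir, "proteins.fasta")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth_proteins.csv")))
  # round trip of one sample through the writer
  rt <- read_peak_table(file.path(dir, "S001_peaks.tsv"))
  expect_equal(as.data.frame(rt), as.data.frame(sim$samples$S001$peaks),
    tolerance = 1e-9
  )
})

test_that("a null cohort has equal case and control truth abundances", {
  ch <- cohort_design(
    n_case = 3, n_control = 3, n_proteins = 5, mean_length = 100,
    fold_changes = setNames(rep(1, 5), sprintf("SYNP%04d", 1:5)),
    noise_cv = 0, detection_prob = 1, drift = FALSE,
    mass_jitter_ppm = 0, time_jitter_pct = 0, n_decoys = 100, seed = 21
  )
  expect_true(all(ch$true_fold_changes == 1))
  pep_int <- function(sid) {
    simulate_sample_peaks(ch, sid)$truth |>
      dplyr::filter(!is_decoy, !is_standard) |>
      dplyr::group_by(sequence) |>
      dplyr::summarise(total = sum(intensity), .groups = "drop")
  }
  j <- dplyr::inner_join(pep_int("S001"), pep_int("S006"), by = "sequence")
  expect_equal(j$total.x, j$total.y, tolerance = 1e-9)
})

test_that("an estimated fold change recovers a spiked 2.0 within [1.6, 2.5]", {
  # abundance-level replicate study at the pipeline's default noise level:
  # one protein spiked at fold 2, groups of 20 and 15 samples
  set.seed(404)
  n_rep <- 50
  hits <- 0L
  sdlog <- sqrt(log(1 + 0.2^2))
  for (r in seq_len(n_rep)) {
    pep_abund <- rlnorm(5, log(3e4), 0.5) # five peptides of the protein
    sim_group <- function(n, fold) {
      vapply(seq_len(n), function(i) {
        det <- runif(5) < 0.9
        mean(pep_abund[det] * fold * rlnorm(sum(det), 0, sdlog))
      }, numeric(1))
    }
    fc <- fold_change(sim_group(20, 2), sim_group(15, 1))
    hits <- hits + (fc$fold >= 1.6 && fc$fold <= 2.5)
  }
  expect_gte(hits / n_rep, 0.9)
})
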