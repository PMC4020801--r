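ref_features <- function(n = 12, seed = 2) {
  set.seed(seed)
  tibble::tibble(
    neutral_mass = sort(runif(n, 900, 3500)),
    migration_time_min = seq(20, 48, length.out = n),
    intensity = runif(n, 1e3, 1e5),
    charges = replicate(n, 2L, simplify = FALSE)
  )
}

test_that("reference selection respects the frequency threshold", {
  base <- ref_features()
  # 10 samples; peptide rows 1..8 shared by all, row 9 in 4 (40%), row 10 in 3
  tables <- lapply(1:10, function(i) {
    keep <- c(1:8, if (i <= 4) 9, if (i <= 3) 10)
    base[keep, ]
  })
  names(tables) <- sprintf("S%02d", 1:10)
  refs <- select_reference_features(tables, threshold = 0.35)
  hit <- function(m) any(abs(refs$mass - m) < 1e-6)
  expect_true(hit(base$neutral_mass[9])) # 40% >= 35%
  expect_false(hit(base$neutral_mass[10])) # 30% < 35%
  expect_error(select_reference_features(tables[1:2]), "3 samples")
})

test_that("reference selection is order-independent", {
  base <- ref_features()
  tables <- lapply(1:6, function(i) base[sample(12), ])
  names(tables) <- sprintf("S%02d", 1:6)
  r1 <- select_reference_features(tables)
  r2 <- select_reference_features(rev(tables))
  expect_equal(r1$mass, r2$mass, tolerance = 1e-12)
  expect_equal(r1$time, r2$time, tolerance = 1e-12)
})

test_that("identity data fits an identity alignment", {
  f <- ref_features()
  refmap <- tibble::tibble(
    ref_id = sprintf("R%02d", seq_len(nrow(f))),
    mass = f$neutral_mass, time = f$migration_time_min,
    frequency = 1
  )
  m <- fit_alignment(f, refmap)
  expect_equal(unname(m$time["slope"]), 1, tolerance = 1e-9)
  expect_equal(unname(m$time["intercept"]), 0, tolerance = 1e-9)
  expect_equal(unname(m$mass["slope"]), 1, tolerance = 1e-9)
  # applying identity leaves features unchanged
  out <- apply_alignment(f, m)
  expect_equal(out$migration_time_min, f$migration_time_min, tolerance = 1e-9)
  expect_equal(out$neutral_mass, f$neutral_mass, tolerance = 1e-9)
  expect_identical(out$intensity, f$intensity)
})

test_that("fewer than five matched references is an alignment failure", {
  f <- ref_features()[1:4, ]
  refmap <- tibble::tibble(
    ref_id = sprintf("R%02d", 1:4),
    mass = f$neutral_mass, time = f$migration_time_min, frequency = 1
  )
  expect_error(fit_alignment(f, refmap), "Alignment failure")
})

test_that("a known linear drift is recovered and inverted", {
  f <- ref_features(n = 40, seed = 6)
  refmap <- tibble::tibble(
    ref_id = sprintf("R%02d", seq_len(nrow(f))),
    mass = f$neutral_mass, time = f$migration_time_min, frequency = 1
  )
  drifted <- f
  drifted$migration_time_min <- 1.05 * f$migration_time_min + 0.3
  # gross drift exceeds the nominal CE window at early times, so match with
  # the same coarse window the cohort calibration's first pass uses
  m <- fit_alignment(drifted, refmap, window_scale = 4)
  # recovered drift = inverse of the fitted observed -> canonical map
  slope_drift <- 1 / unname(m$time["slope"])
  int_drift <- -unname(m$time["intercept"]) / unname(m$time["slope"])
  expect_equal(slope_drift, 1.05, tolerance = 1e-6)
  expect_equal(int_drift, 0.3, tolerance = 1e-6)
  # round trip: align then un-align returns the original coordinates
  aligned <- apply_alignment(drifted, m)
  expect_equal(aligned$migration_time_min, f$migration_time_min,
    tolerance = 1e-6
  )
  # tidy/glance expose the coefficients
  td <- tidy(m)
  expect_identical(nrow(td), 4L)
  expect_equal(glance(m)$time_slope, unname(m$time["slope"]))
})

test_that("cohort calibration shrinks cross-sample reference spread", {
  ch <- cohort_design(
    n_case = 4, n_control = 4, n_proteins = 12, mean_length = 100,
    noise_cv = 0.05, n_decoys = 300, seed = 17
  )
  feats <- lapply(
    setNames(ch$samples$sample_id, ch$samples$sample_id),
    function(sid) {
      s <- simulate_sample_peaks(ch, sid)
      deconvolute_peaks(s$peaks, estimate_noise(s$peaks))
    }
  )
  calib <- calibrate_cohort(feats)
  expect_length(calib$failed, 0)
  spread <- function(tables, masses) {
    vapply(masses, function(m) {
      ts <- unlist(lapply(tables, function(f) {
        f$migration_time_min[abs(f$neutral_mass - m) / m * 1e6 < 30]
      }))
      if (length(ts) >= 4) sd(ts) else NA_real_
    }, numeric(1))
  }
  probe <- ch$peptides$mass[order(-ch$peptides$abundance)][1:15]
  before <- spread(feats, probe)
  after <- spread(calib$aligned, probe)
  ok <- !is.na(before) & !is.na(after)
  expect_gt(sum(ok), 5)
  expect_lt(median(after[ok]), median(before[ok]))
})

test_that("internal standards are frequent, disease-unassociated peptides", {
  set.seed(8)
  manifest <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:10),
    group = rep(c("case", "control"), each = 5)
  )
  long <- function(id, samples, vals) {
    tibble::tibble(id = id, sample_id = samples, intensity = vals)
  }
  ints <- dplyr::bind_rows(
    # symmetric case/control values: rank-sum p = 1, frequency 1
    long("C1", manifest$sample_id, c(101:105, 105:101)),
    long("C2", manifest$sample_id, c(rnorm(5, 200, 5), rnorm(5, 90, 5))), # disease-linked
    long("C3", manifest$sample_id[1:7], rnorm(7, 50, 3)) # freq 0.7 < 0.8
  )
  peps <- tibble::tibble(
    id = c("C1", "C2", "C3"), mass = c(1000, 1100, 1200),
    time = c(25, 30, 35), charges = list(2L, 2L, 2L),
    n_samples = c(10L, 10L, 7L), frequency = c(1, 1, 0.7)
  )
  cs <- make_consensus_set(ints, peps, n_samples = 10)
  std <- select_internal_standards(cs, manifest, n_standards = 5)
  expect_identical(std$id, "C1")
})

test_that("median-ratio normalization restores a doubled sample exactly", {
  samples <- sprintf("S%02d", 1:4)
  ids <- sprintf("C%d", 1:6)
  set.seed(5)
  base <- rlnorm(6, log(1000), 0.4)
  ints <- dplyr::bind_rows(lapply(seq_along(samples), function(i) {
    tibble::tibble(
      id = ids, sample_id = samples[i],
      intensity = base * ifelse(i == 2, 2, 1) # sample 2 doubled
    )
  }))
  cs <- make_consensus_set(ints, n_samples = 4)
  out <- normalize_intensities(cs, standards = ids)
  expect_equal(out$scaler$factor[out$scaler$sample_id == "S02"], 0.5)
  restored <- out$consensuses$intensities |>
    dplyr::filter(sample_id == "S02") |>
    dplyr::arrange(id)
  expect_equal(restored$intensity, base[order(ids)], tolerance = 1e-12)
  # identical samples get unit factors
  expect_true(all(out$scaler$factor[-2] == 1))
  # idempotence: renormalizing yields factors of exactly 1
  again <- normalize_intensities(out$consensuses, standards = ids)
  expect_equal(again$scaler$factor, rep(1, 4), tolerance = 1e-9)
})

test_that("samples with too few standards are flagged and left unscaled", {
  ints <- dplyr::bind_rows(
    tibble::tibble(id = c("C1", "C2", "C3"), sample_id = "S1", intensity = c(10, 20, 30)),
    tibble::tibble(id = c("C1", "C2", "C3"), sample_id = "S2", intensity = c(40, 50, 60)),
    tibble::tibble(id = c("C1"), sample_id = "S3", intensity = 25)
  )
  cs <- make_consensus_set(ints, n_samples = 3)
  expect_warning(
    out <- normalize_intensities(cs, standards = c("C1", "C2", "C3")),
    "unscaled"
  )
  expect_true(out$scaler$flagged[out$scaler$sample_id == "S3"])
  expect_identical(out$scaler$factor[out$scaler$sample_id == "S3"], 1)
})

test_that("per-sample gains are flattened across replicate simulations", {
  set.seed(99)
  n_rep <- 50
  better <- 0L
  for (r in seq_len(n_rep)) {
    samples <- sprintf("S%02d", 1:8)
    ids <- sprintf("C%d", 1:10)
    base <- rlnorm(10, log(1000), 0.3)
    gains <- rlnorm(8, 0, 0.3)
    ints <- dplyr::bind_rows(lapply(1:8, function(i) {
      tibble::tibble(id = ids, sample_id = samples[i], intensity = base * gains[i])
    }))
    cs <- make_consensus_set(ints, n_samples = 8)
    out <- normalize_intensities(cs, standards = ids)
    cv <- function(x) sd(x) / mean(x)
    pre <- ints |>
      dplyr::group_by(id) |>
      dplyr::summarise(cv = cv(intensity), .groups = "drop")
    post <- out$consensuses$intensities |>
      dplyr::group_by(id) |>
      dplyr::summarise(cv = cv(intensity), .groups = "drop")
    better <- better + (mean(post$cv) < mean(pre$cv))
  }
  expect_gte(better / n_rep, 0.95)
})
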