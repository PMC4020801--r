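# The 19 raw p-values of the reported differential-protein table, used as a
# worked example of the BH arithmetic with 97 tests in total.
TABLE_P <- c(
  4.58e-6, 3.27e-5, 6.54e-5, 7.16e-5, 1.30e-4, 3.99e-4, 1.93e-3, 2.45e-3,
  2.72e-3, 3.88e-3, 3.94e-3, 2.32e-3, 1.55e-2, 1.61e-2, 2.33e-2, 3.34e-2,
  3.79e-2, 4.04e-2, 4.82e-2
)

test_that("BH adjustment reproduces the published worked example", {
  adj <- bh_adjust(TABLE_P, m_total = 97)
  srt <- sort(adj)
  # rank 4 and rank 6 direct values; rank 3 is overridden by the running
  # minimum (its direct value 2.11E-03 exceeds rank 4's 1.74E-03)
  expect_identical(signif(srt[4], 3), 1.74e-3)
  expect_identical(signif(srt[6], 3), 6.45e-3)
  expect_identical(signif(srt[3], 3), 1.74e-3)
  expect_gt(6.54e-5 * 97 / 3, srt[3]) # the override actually engaged
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  brute_bh <- function(p, m) {
    o <- order(p)
    ps <- p[o]
    n <- length(p)
    adj <- numeric(n)
    for (i in seq_len(n)) {
      adj[i] <- min(1, min(ps[i:n] * m / (i:n)))
    }
    out <- numeric(n)
    out[o] <- adj
    out
  }
  set.seed(42)
  for (r in 1:200) {
    n <- sample(1:40, 1)
    p <- runif(n)
    m <- n + sample(0:20, 1)
    expect_equal(bh_adjust(p, m), brute_bh(p, m), tolerance = 1e-12)
  }
})

test_that("BH output is valid, monotone and order-invariant", {
  set.seed(7)
  p <- runif(500)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # adjusted values non-decreasing in raw-p rank
  expect_true(all(diff(adj[order(p)]) >= 0))
  # order invariance
  perm <- sample(500)
  expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  # independent implementation cross-check
  expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bh_adjust(runif(10), m_total = 5), "at least")
})

test_that("fold changes reproduce the published ratios of group means", {
  expect_identical(round(fold_change(1618.6, 689.5)$fold, 2), 2.35)
  expect_identical(round(fold_change(1169.8, 747.4)$fold, 2), 1.57)
  expect_identical(round(fold_change(1925.3, 1463.2)$fold, 2), 1.32)
  expect_equal(fold_change(c(3, 5), c(3, 5))$fold, 1)
})

test_that("fold change is scale-invariant and guards a zero control mean", {
  set.seed(3)
  x <- rlnorm(10, 3, 1)
  y <- rlnorm(8, 3, 1)
  f1 <- fold_change(x, y)
  f2 <- fold_change(x * 7.3, y * 7.3)
  expect_equal(f1$fold, f2$fold, tolerance = 1e-12)
  expect_equal(f1$fold_sd, f2$fold_sd, tolerance = 1e-12)
  # fold_sd definition: sd of case values over control mean
  expect_equal(f1$fold_sd, sd(x) / mean(y))
  expect_warning(out <- fold_change(x, rep(0, 5)), "undefined")
  expect_true(is.na(out$fold))
})

test_that("the F-test gate selects the test and symmetric splits give p = 1", {
  # identical distributions: equal variances -> t-test, t = 0, p exactly 1
  r <- differential_test(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_identical(r$test_used, "t")
  expect_identical(r$raw_p, 1)
  # grossly unequal variances -> rank-sum branch
  set.seed(10)
  r2 <- differential_test(rnorm(20, 0, 1), rnorm(20, 0, 30))
  expect_identical(r2$test_used, "ranksum")
  # rank-sum on a perfectly symmetric split is exactly 1 as well
  r3 <- differential_test(c(0, 0, 0, 5), c(5, 0, 0, 0))
  expect_identical(r3$raw_p, 1)
  # zero variance in both groups with equal means: p = 1 by convention
  r4 <- differential_test(rep(2, 4), rep(2, 5))
  expect_identical(r4$raw_p, 1)
  expect_error(differential_test(1:2, 1:5), "3 values")
})

test_that("a 2-SD location shift is detected with power >= 0.9", {
  set.seed(77)
  n_rep <- 500
  hits <- vapply(seq_len(n_rep), function(i) {
    differential_test(rnorm(20, 2, 1), rnorm(15, 0, 1))$raw_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("protein abundances average detected peptides, zero when absent", {
  manifest <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4", "S5", "S6"),
    group = rep(c("case", "control"), each = 3)
  )
  ints <- dplyr::bind_rows(
    tibble::tibble(id = "C1", sample_id = c("S1", "S2"), intensity = c(2, 6)),
    tibble::tibble(id = "C2", sample_id = c("S1", "S3"), intensity = c(4, 8))
  )
  peps <- tibble::tibble(
    id = c("C1", "C2"), mass = c(1000, 1200), time = c(25, 30),
    charges = list(2L, 2L), n_samples = c(2L, 2L), frequency = c(1 / 3, 1 / 3)
  )
  cs <- make_consensus_set(ints, peps, n_samples = 6)
  asg <- tibble::tibble(
    id = c("C1", "C2"), annotated = TRUE,
    sequence = c("AAK", "CCR"), protein = "P1"
  )
  q <- protein_abundance_matrix(cs, asg, manifest, min_peptides = 2)
  expect_identical(unname(unlist(q$abundance[1, "S1"])), 3) # mean(2, 4)
  expect_identical(unname(unlist(q$abundance[1, "S4"])), 0) # undetected
  # a sample carrying intensities but no manifest label is an error
  expect_error(
    protein_abundance_matrix(cs, asg, manifest[1:2, ]),
    "manifest"
  )
})

test_that("a null protein set keeps false positives inside the 99% envelope", {
  # 97 proteins, no true differences: the number of raw p < 0.05 must fall
  # inside the 99% binomial envelope around 4.85
  lo <- qbinom(0.005, 97, 0.05)
  hi <- qbinom(0.995, 97, 0.05)
  set.seed(123)
  for (r in 1:3) {
    n_sig <- sum(vapply(1:97, function(i) {
      differential_test(rnorm(20, 10, 2), rnorm(15, 10, 2))$raw_p < 0.05
    }, logical(1)))
    expect_gte(n_sig, lo)
    expect_lte(n_sig, hi)
  }
})

test_that("a spiked fold-4 protein dominates the ranking", {
  set.seed(55)
  n_rep <- 50
  sdlog <- sqrt(log(1 + 0.2^2))
  top <- 0L
  for (r in seq_len(n_rep)) {
    n_prot <- 20
    base <- rlnorm(n_prot, log(1e4), 0.5)
    ab <- rbind(
      sapply(seq_len(35), function(j) base * rlnorm(n_prot, 0, sdlog))
    )
    ab[1, 1:20] <- ab[1, 1:20] * 4 # protein 1 spiked in the 20 case samples
    wide <- tibble::as_tibble(
      cbind(data.frame(protein = sprintf("P%02d", 1:n_prot)), as.data.frame(ab))
    )
    names(wide) <- c("protein", sprintf("S%02d", 1:35))
    quant <- structure(
      list(
        abundance = wide,
        labels = tibble::tibble(
          sample_id = sprintf("S%02d", 1:35),
          group = rep(c("case", "control"), c(20, 15))
        ),
        detected_only = FALSE
      ),
      class = "protein_quant"
    )
    res <- summarize_results(quant)
    top <- top + (res$protein[1] == "P01")
  }
  expect_gte(top / n_rep, 0.9)
})

test_that("an empty quantification yields an empty report", {
  quant <- structure(
    list(
      abundance = tibble::tibble(protein = character()),
      labels = tibble::tibble(sample_id = character(), group = character()),
      detected_only = FALSE
    ),
    class = "protein_quant"
  )
  res <- summarize_results(quant)
  expect_identical(nrow(res), 0L)
  expect_s3_class(res, "differential_results")
})
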