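lfq_fixture <- function() {
  lfq <- matrix(10^c(7.0, 7.2, 6.9, 6.5, 6.6, 6.8,
                     6.0, 6.1, 5.9, 6.0, 6.1, 5.9,
                     7.5, NA,  7.4, 7.5, 7.6, NA,
                     5.5, 5.6, 5.4, 5.5, 5.6, 5.4),
                nrow = 4, byrow = TRUE)
  colnames(lfq) <- c("C1", "C2", "C3", "T1", "T2", "T3")
  make_pg(lfq, peptides = c(5L, 2L, 1L, 3L))
}

test_that("peptide-count filter keeps >= threshold, boundary at two peptides", {
  pg <- make_pg(matrix(1e6, 5, 2, dimnames = list(NULL, c("C1", "T1"))),
                peptides = c(0L, 1L, 2L, 3L, 7L))
  kept <- suppressMessages(filter_proteins(pg, 2L))
  expect_equal(n_proteins(kept), 3L)                      # 2, 3, 7 retained
  expect_equal(kept$meta$razor_unique_peptides, c(2L, 3L, 7L))
  # count 1 is "less than two" and excluded; count 2 retained
  expect_false("P2" %in% kept$meta$leading_accession)
  expect_true("P3" %in% kept$meta$leading_accession)
  # threshold 0 is the identity
  expect_equal(n_proteins(suppressMessages(filter_proteins(pg, 0L))), 5L)
})

test_that("filtering is monotone in the threshold", {
  set.seed(11)
  pg <- make_pg(matrix(1e6, 30, 2, dimnames = list(NULL, c("C1", "T1"))),
                peptides = sample(0:10, 30, replace = TRUE))
  sizes <- vapply(0:11, function(k) {
    n_proteins(suppressMessages(filter_proteins(pg, k)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("log matrix holds exact log10 of observed LFQ and flags missing", {
  m <- to_log_matrix(lfq_fixture(), toy_design())
  expect_identical(m$values["P1", "C1"], 7.0)
  expect_false(m$observed["P3", "C2"])
  expect_true(is.na(m$values["P3", "C2"]))
  expect_false(m$imputed)
  # unpaired design is rejected
  expect_error(paired_design(c("C1", "C2"), c("T1", "T2", "T3")), "unpaired")
})

test_that("imputation draws from Normal(pooled low quantile, sd) and only fills missing cells", {
  m <- to_log_matrix(lfq_fixture(), toy_design())
  imp <- impute_missing(m, seed = 1L)
  # observed cells bitwise unchanged
  expect_identical(imp$values[m$observed], m$values[m$observed])
  expect_identical(imp$observed, m$observed)
  expect_true(all(is.finite(imp$values)))
  # seeding contract
  imp2 <- impute_missing(m, seed = 1L)
  expect_identical(imp$values, imp2$values)
  imp3 <- impute_missing(m, seed = 2L)
  expect_false(identical(imp$values, imp3$values))
  # no-missing matrix returned unchanged
  full <- m
  full$values[!full$observed] <- 5
  full$observed[] <- TRUE
  expect_identical(impute_missing(full, seed = 99L)$values, full$values)
  # all-missing matrix is an error
  none <- m
  none$observed[] <- FALSE
  expect_error(impute_missing(none, seed = 1L), "no observed")
})

test_that("imputed values match the stated Normal(q05, 0.1) law at large n", {
  set.seed(3)
  n <- 200L
  lfq <- matrix(10^rnorm(n * 6, 7, 0.7), nrow = n,
                dimnames = list(NULL, c("C1", "C2", "C3", "T1", "T2", "T3")))
  lfq[sample(length(lfq), 60)] <- NA
  m <- to_log_matrix(make_pg(lfq), toy_design())
  q <- oracle_quantile7(m$values[m$observed], 0.05)
  imp <- impute_missing(m, seed = 7L)
  draws <- imp$values[!imp$observed]
  expect_equal(mean(draws), q, tolerance = 0.1)  # 60 draws: loose moment check
  expect_lt(abs(sd(draws) - 0.1), 0.05)
})

test_that("paired log2 ratios match hand-computed arithmetic", {
  lfq <- matrix(10^c(6.5, 6.6, 6.8, 7.0, 7.2, 6.9), nrow = 1)
  colnames(lfq) <- c("C1", "C2", "C3", "T1", "T2", "T3")
  m <- to_log_matrix(make_pg(lfq), toy_design())
  r <- compute_log2_ratios(m)
  # pairs (7.0, 6.5), (7.2, 6.6), (6.9, 6.8): mean(0.5, 0.6, 0.1)/log10(2)
  expect_equal(r$log2_ratio, mean(c(0.5, 0.6, 0.1)) / log10(2),
               tolerance = 1e-12)
  expect_equal(r$log2_ratio, 1.3287712, tolerance = 1e-6)
  expect_equal(r$mean_log10_intensity, mean(c(6.5, 6.6, 6.8, 7.0, 7.2, 6.9)))
})

test_that("ratio identities: equal intensities give 0, doubling gives 1", {
  lfq <- matrix(c(2e6, 1e6, 2e6, 2e6), nrow = 2,
                dimnames = list(NULL, c("C1", "T1")))
  m <- to_log_matrix(make_pg(lfq), paired_design("C1", "T1"))
  r <- compute_log2_ratios(m)
  expect_equal(r$log2_ratio, c(0, 1), tolerance = 1e-12)
  # ratio-of-means agrees for a single replicate
  expect_equal(compute_log2_ratios(m, "ratio-of-means")$log2_ratio,
               r$log2_ratio, tolerance = 1e-12)
})

test_that("un-imputed matrix with missing cells cannot be ratioed", {
  m <- to_log_matrix(lfq_fixture(), toy_design())
  expect_error(compute_log2_ratios(m), "impute")
})

test_that("IQR-fence classification reproduces the worked example", {
  x <- c(-0.2, -0.1, 0.0, 0.1, 0.2, 5.0)
  # independent check of the quartiles themselves
  expect_equal(oracle_quantile7(x, 0.25), -0.075, tolerance = 1e-12)
  expect_equal(oracle_quantile7(x, 0.75), 0.175, tolerance = 1e-12)
  out <- classify_enrichment(data.frame(accession = paste0("P", 1:6),
                                        log2_ratio = x))
  expect_equal(out$significance, c(0L, 0L, 0L, 0L, 0L, 2L))
  expect_equal(out$direction, c(0L, 0L, 0L, 0L, 0L, 1L))
})

test_that("degenerate and error cases of fence classification", {
  # all-equal ratios: IQR 0, fences collapse, strict inequality => class 0
  same <- classify_enrichment(data.frame(accession = paste0("P", 1:5),
                                         log2_ratio = rep(0.3, 5)))
  expect_true(all(same$significance == 0L))
  expect_error(classify_enrichment(data.frame(accession = "P1",
                                              log2_ratio = 1)), "at least 4")
  expect_error(classify_enrichment(data.frame(accession = paste0("P", 1:4),
                                              log2_ratio = c(1, 2, NA, 4))),
               "non-finite")
  expect_error(fence_params(k_potential = 2, k_extreme = 1))
})

test_that("fence classes are invariant under shift and positive scaling", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(4:50, 1))
    base <- classify_enrichment(data.frame(accession = seq_along(x),
                                           log2_ratio = x))$significance
    shifted <- classify_enrichment(data.frame(accession = seq_along(x),
                                              log2_ratio = x + 3.7))$significance
    scaled <- classify_enrichment(data.frame(accession = seq_along(x),
                                             log2_ratio = x * 2.5))$significance
    expect_identical(shifted, base)
    expect_identical(scaled, base)
  }
})

test_that("class 2 nests inside the 1.5x fence (every extreme is also potential)", {
  set.seed(6)
  for (i in 1:20) {
    x <- c(rnorm(30), rnorm(3, 0, 8))   # heavy tail to populate both classes
    df <- data.frame(accession = seq_along(x), log2_ratio = x)
    sig2 <- classify_enrichment(df)$significance == 2L
    only_pot <- classify_enrichment(df, fence_params(k_potential = 1.5,
                                                     k_extreme = 1e9))
    expect_true(all(only_pot$significance[sig2] == 1L))
  }
})
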