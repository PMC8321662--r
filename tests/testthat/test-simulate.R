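test_that("simulation spec is validated with all offending fields listed", {
  expect_error(lfq_sim_spec(n_proteins = 0, spike_fraction = 2),
               "n_proteins.*spike_fraction")
  expect_silent(lfq_sim_spec())
})

test_that("LFQ simulation has the requested dimensions and truth bookkeeping", {
  sim <- generate_lfq_experiment(lfq_sim_spec(n_proteins = 500L,
                                              n_replicates = 3L),
                                 seed = 1L)
  expect_equal(n_proteins(sim$table), 500L)
  expect_equal(ncol(sim$table$lfq), 6L)
  expect_equal(nrow(sim$design), 6L)
  expect_equal(sum(sim$truth$spiked), 25L)          # 5% of 500
  expect_true(all(sim$truth$true_log2_fc[sim$truth$spiked] == 5))
  expect_true(all(sim$truth$true_log2_fc[!sim$truth$spiked] == 0))
  expect_true(all(sim$table$meta$razor_unique_peptides >= 1L))

  none <- generate_lfq_experiment(lfq_sim_spec(n_proteins = 50L,
                                               spike_fraction = 0),
                                  seed = 1L)
  expect_true(all(none$truth$true_log2_fc == 0))
})

test_that("simulation is deterministic under the seed", {
  spec <- lfq_sim_spec(n_proteins = 100L)
  a <- generate_lfq_experiment(spec, seed = 5L)
  b <- generate_lfq_experiment(spec, seed = 5L)
  expect_identical(a, b)
  c <- generate_lfq_experiment(spec, seed = 6L)
  expect_false(identical(a$table$lfq, c$table$lfq))
})

test_that("spiked log2 ratios recover the planted fold change without missingness", {
  spec <- lfq_sim_spec(n_proteins = 1000L, spike_fraction = 0.2,
                       spike_log2_fc = 5, missingness = FALSE,
                       replicate_noise_sd = 0.1, low_peptide_fraction = 0)
  sim <- generate_lfq_experiment(spec, seed = 11L)
  m <- to_log_matrix(sim$table, sim$design)
  m$imputed <- TRUE   # nothing to impute: missingness is off
  r <- compute_log2_ratios(m)
  spiked <- sim$truth$spiked
  expect_equal(sum(spiked), 200L)
  expect_lt(abs(mean(r$log2_ratio[spiked]) - 5), 0.05)
  expect_lt(abs(mean(r$log2_ratio[!spiked])), 0.05)
})

test_that("missingness is monotone decreasing in latent intensity", {
  spec <- lfq_sim_spec(n_proteins = 2000L, spike_fraction = 0,
                       base_log10_sd = 1.0)
  sim <- generate_lfq_experiment(spec, seed = 21L)
  lfq <- sim$table$lfq           # 12,000 cells
  expect_gte(length(lfq), 10000L)
  # bin by the protein's mean observed log10 intensity
  latent <- rowMeans(log10(lfq), na.rm = TRUE)
  bins <- cut(latent, breaks = stats::quantile(latent, probs = seq(0, 1, 0.2),
                                               na.rm = TRUE),
              include.lowest = TRUE)
  miss_rate <- tapply(rowMeans(is.na(lfq)), bins, mean)
  expect_true(all(diff(miss_rate) <= 0))
})

test_that("proteomes without plants contain no motif at all", {
  prot <- generate_proteome(30L, length_range = c(50L, 150L), seed = 3L)
  expect_equal(nrow(scan_proteome(prot$records, motif_pattern("full"))), 0L)
  expect_equal(nrow(scan_proteome(prot$records, motif_pattern("partial"))),
               0L)
  expect_equal(nrow(prot$truth), 0L)
})

test_that("planted sites are recovered exactly: no misses, no extras", {
  plant <- data.frame(protein_index = c(1L, 1L, 2L, 3L, 3L, 3L),
                      acceptor_pos = c(16L, 40L, 10L, 8L, 30L, 60L),
                      kind = c("full", "partial", "full",
                               "partial", "full", "partial"),
                      stringsAsFactors = FALSE)
  prot <- generate_proteome(5L, length_range = c(70L, 90L),
                            plant_spec = plant, seed = 13L)
  # partial scan finds every planted acceptor (full sites are partial too)
  partial_hits <- scan_proteome(prot$records, motif_pattern("partial"))
  expect_equal(
    partial_hits[order(partial_hits$accession, partial_hits$acceptor_pos),
                 c("accession", "acceptor_pos")],
    prot$truth[order(prot$truth$accession, prot$truth$acceptor_pos),
               c("accession", "acceptor_pos")],
    ignore_attr = TRUE)
  # full scan finds exactly the sites planted as full
  full_hits <- scan_proteome(prot$records, motif_pattern("full"))
  full_truth <- prot$truth[prot$truth$kind == "full", ]
  expect_equal(
    full_hits[order(full_hits$accession, full_hits$acceptor_pos),
              c("accession", "acceptor_pos")],
    full_truth[order(full_truth$accession, full_truth$acceptor_pos),
               c("accession", "acceptor_pos")],
    ignore_attr = TRUE)
})

test_that("plant validation rejects out-of-bounds and overlapping windows", {
  expect_error(generate_proteome(2L, length_range = c(30L, 30L),
                                 plant_spec = data.frame(protein_index = 1L,
                                                         acceptor_pos = 40L,
                                                         kind = "full"),
                                 seed = 1L), "does not fit")
  expect_error(generate_proteome(2L, length_range = c(50L, 50L),
                                 plant_spec = data.frame(
                                   protein_index = c(1L, 1L),
                                   acceptor_pos = c(20L, 23L),
                                   kind = "full"),
                                 seed = 1L), "overlap")
})

test_that("12 proteins planted with 30 sites yield a motif-count total of 30", {
  site_counts <- c(3L, 3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L)
  plant <- do.call(rbind, lapply(seq_along(site_counts), function(i) {
    data.frame(protein_index = i,
               acceptor_pos = 10L + 10L * seq_len(site_counts[i]),
               kind = "full", stringsAsFactors = FALSE)
  }))
  prot <- generate_proteome(20L, length_range = c(60L, 80L),
                            plant_spec = plant, seed = 7L)
  counts <- proteome_motif_counts(prot$records, motif_pattern("full"))
  expect_equal(attr(counts, "total"), 30L)
  expect_equal(sum(counts >= 1L), 12L)
})

test_that("known-site generation samples the requested exact fraction", {
  plant <- data.frame(protein_index = rep(1:6, each = 5),
                      acceptor_pos = rep(c(10L, 20L, 30L, 40L, 50L), 6),
                      kind = "full", stringsAsFactors = FALSE)
  prot <- generate_proteome(6L, length_range = c(60L, 60L),
                            plant_spec = plant, seed = 17L)
  expect_equal(nrow(prot$truth), 30L)
  all_known <- generate_known_sites(prot$truth, prot$records, 1, seed = 1L)
  expect_equal(nrow(all_known), 30L)
  expect_true(all(all_known$residue %in% c("S", "T")))
  none <- generate_known_sites(prot$truth, prot$records, 0, seed = 1L)
  expect_equal(nrow(none), 0L)
  eleven <- generate_known_sites(prot$truth, prot$records, 11 / 30, seed = 1L)
  expect_equal(nrow(eleven), 11L)
  # xref marks exactly the sampled subset as reported
  hits <- scan_proteome(prot$records, motif_pattern("full"))
  x <- xref_known_sites(hits, eleven)
  expect_equal(attr(x, "n_reported"), 11L)
  expect_equal(attr(x, "n_novel"), 19L)
})
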