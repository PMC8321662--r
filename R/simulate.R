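#' Specification of a simulated paired-replicate LFQ screen
#'
#' Emulates the study design the pipeline is built for: paired biological
#' replicates of a control (EGFP) versus a kinase-activated (PKD3ca)
#' condition, log-scale protein intensities with intensity-dependent
#' (left-censored, MNAR-like) missingness, and a minority of proteins
#' spiked with a large positive log2 fold change.
#'
#' @param n_proteins number of simulated protein groups.
#' @param n_replicates paired replicates per condition (3, one per donor
#'   animal, in the emulated design).
#' @param base_log10_mean,base_log10_sd latent log10 abundance distribution
#'   (typical LFQ scale).
#' @param replicate_noise_sd per-cell log10 measurement noise.
#' @param spike_fraction fraction of proteins receiving a spiked fold
#'   change.
#' @param spike_log2_fc spiked log2 fold change, scalar or per-spiked-protein
#'   vector.
#' @param missingness switch the MNAR mechanism on/off.
#' @param missing_logistic_midpoint log10 intensity at which a cell is
#'   missing with probability 0.5.
#' @param missing_logistic_slope steepness of the missingness logistic
#'   (larger = sharper censoring).
#' @param low_peptide_fraction fraction of proteins assigned a single
#'   razor+unique peptide (below the default identification filter).
#' @return validated `LfqSimSpec` list.
#' @export
lfq_sim_spec <- function(n_proteins = 500L, n_replicates = 3L,
                         base_log10_mean = 7.0, base_log10_sd = 0.7,
                         replicate_noise_sd = 0.1,
                         spike_fraction = 0.05, spike_log2_fc = 5.0,
                         missingness = TRUE,
                         missing_logistic_midpoint = 6.0,
                         missing_logistic_slope = 2.0,
                         low_peptide_fraction = 0.1) {
  problems <- character(0)
  if (n_proteins < 1) problems <- c(problems, "n_proteins must be >= 1")
  if (n_replicates < 1) problems <- c(problems, "n_replicates must be >= 1")
  if (spike_fraction < 0 || spike_fraction > 1) {
    problems <- c(problems, "spike_fraction must be in [0, 1]")
  }
  if (base_log10_sd <= 0) problems <- c(problems, "base_log10_sd must be > 0")
  if (replicate_noise_sd <= 0) {
    problems <- c(problems, "replicate_noise_sd must be > 0")
  }
  if (low_peptide_fraction < 0 || low_peptide_fraction > 1) {
    problems <- c(problems, "low_peptide_fraction must be in [0, 1]")
  }
  if (length(problems) > 0L) {
    stop("invalid simulation spec: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 base_log10_mean = base_log10_mean,
                 base_log10_sd = base_log10_sd,
                 replicate_noise_sd = replicate_noise_sd,
                 spike_fraction = spike_fraction,
                 spike_log2_fc = spike_log2_fc,
                 missingness = missingness,
                 missing_logistic_midpoint = missing_logistic_midpoint,
                 missing_logistic_slope = missing_logistic_slope,
                 low_peptide_fraction = low_peptide_fraction),
            class = "LfqSimSpec")
}

#' Simulate a paired two-condition LFQ experiment with known truth
#'
#' Per protein i, a latent log10 abundance `a_i ~ N(base_log10_mean,
#' base_log10_sd)`. Control replicate r measures `a_i + eps`, treatment
#' `a_i + fc_i * log10(2) + eps`, with `eps ~ N(0, replicate_noise_sd)`
#' independent per cell and `fc_i` the protein's true log2 fold change
#' (0 except for spiked proteins). Each cell is then independently set
#' missing with probability `1 / (1 + exp(slope * (log10 value -
#' midpoint)))` — lower intensity, more missing. Peptide counts are drawn
#' >= 1 with `low_peptide_fraction` of proteins below the default filter.
#'
#' @param spec an [lfq_sim_spec()].
#' @param seed integer seed; identical spec + seed gives identical output.
#' @param accession_prefix prefix for the generated accessions.
#' @param spike_indices optional integer vector naming the spiked proteins
#'   explicitly (overrides `spike_fraction` random placement).
#' @return list with `table` (a `ProteinGroups`), `design`
#'   ([paired_design()]), and `truth` (data.frame: `accession`,
#'   `true_log2_fc`, `spiked`).
#' @export
generate_lfq_experiment <- function(spec, seed, accession_prefix = "SIMP",
                                    spike_indices = NULL) {
  stopifnot(inherits(spec, "LfqSimSpec"))
  with_local_seed(seed, {
    n <- spec$n_proteins
    r <- spec$n_replicates
    accession <- sprintf("%s%04d", accession_prefix, seq_len(n))

    spiked_idx <- if (!is.null(spike_indices)) {
      stopifnot(all(spike_indices >= 1L), all(spike_indices <= n))
      as.integer(spike_indices)
    } else if (round(spec$spike_fraction * n) > 0) {
      sample.int(n, round(spec$spike_fraction * n))
    } else {
      integer(0)
    }
    fc <- numeric(n)
    fc[spiked_idx] <- spec$spike_log2_fc

    a <- stats::rnorm(n, spec$base_log10_mean, spec$base_log10_sd)
    eps <- matrix(stats::rnorm(n * 2L * r, 0, spec$replicate_noise_sd),
                  nrow = n)
    log10_vals <- cbind(matrix(a, n, r),                    # control
                        matrix(a + fc * log10(2), n, r)) + eps
    if (spec$missingness) {
      p_miss <- 1 / (1 + exp(spec$missing_logistic_slope *
                               (log10_vals - spec$missing_logistic_midpoint)))
      miss <- matrix(stats::runif(length(p_miss)) < p_miss,
                     nrow = n)
    } else {
      miss <- matrix(FALSE, n, 2L * r)
    }
    lfq <- 10^log10_vals
    lfq[miss] <- NA_real_

    low <- stats::runif(n) < spec$low_peptide_fraction
    peptides <- ifelse(low, 1L, 2L + stats::rpois(n, 6))

    control <- paste0("EGFP_", seq_len(r))
    treatment <- paste0("PKD3ca_", seq_len(r))
    colnames(lfq) <- c(control, treatment)
    rownames(lfq) <- accession
    meta <- data.frame(group_id = accession,
                       leading_accession = accession,
                       razor_unique_peptides = as.integer(peptides),
                       reverse = FALSE, contaminant = FALSE,
                       stringsAsFactors = FALSE)
    meta$accessions <- as.list(accession)
    meta$gene_names <- as.list(paste0("Gene", seq_len(n)))
    list(table = new_protein_groups(meta, lfq),
         design = paired_design(control, treatment),
         truth = data.frame(accession = accession, true_log2_fc = fc,
                            spiked = seq_len(n) %in% spiked_idx,
                            stringsAsFactors = FALSE))
  })
}

# 20-letter alphabet minus R/S/T: no accidental partial or full motif can
# form in the background, so the planted truth is exact.
MOTIF_FREE_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                         "M", "N", "P", "Q", "V", "W", "Y")
AA_ALPHABET <- c(MOTIF_FREE_ALPHABET, "R", "S", "T")

#' Simulate a proteome with consensus motifs planted at recorded positions
#'
#' Background residues are drawn uniformly from the 20-letter alphabet
#' excluding R, S and T (`background = "motif_free"`, the default), so the
#' only motif acceptors are the planted ones and recovery can be checked
#' exactly. Planted windows splice in `[LVI] x R x x [ST]` (full) or
#' `R x x [ST]` (partial) with wildcards drawn from the background
#' alphabet; for a partial plant the residue five positions before the
#' acceptor is additionally forced outside {L, V, I} so the plant cannot
#' accidentally satisfy the full pattern. `background = "realistic"` keeps
#' all 20 residues (accidental sites then possible; use the scanner as
#' truth).
#'
#' @param n_proteins number of sequences.
#' @param length_range integer vector of length 2: sequence length bounds.
#' @param plant_spec data.frame with columns `protein_index` (1-based),
#'   `acceptor_pos` (1-based) and `kind` (`"full"`/`"partial"`); planted
#'   footprints must fit inside their sequence and not overlap.
#' @param seed integer seed.
#' @param background `"motif_free"` or `"realistic"`.
#' @return list with `records` (data.frame as from [read_fasta()]) and
#'   `truth` (the planted sites: `accession`, `acceptor_pos`, `kind`).
#' @export
generate_proteome <- function(n_proteins, length_range = c(80L, 400L),
                              plant_spec = NULL, seed,
                              background = c("motif_free", "realistic")) {
  background <- match.arg(background)
  alphabet <- switch(background, motif_free = MOTIF_FREE_ALPHABET,
                     realistic = AA_ALPHABET)
  if (is.null(plant_spec)) {
    plant_spec <- data.frame(protein_index = integer(0),
                             acceptor_pos = integer(0),
                             kind = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(plant_spec$kind %in% c("full", "partial")),
            all(plant_spec$protein_index >= 1L),
            all(plant_spec$protein_index <= n_proteins))
  with_local_seed(seed, {
    lens <- length_range[1L] - 1L +
      sample.int(length_range[2L] - length_range[1L] + 1L, n_proteins,
                 replace = TRUE)
    accession <- sprintf("SEQ%04d", seq_len(n_proteins))
    seqs <- lapply(lens, function(L) sample(alphabet, L, replace = TRUE))

    for (i in seq_len(nrow(plant_spec))) {
      pi <- plant_spec$protein_index[i]
      p <- plant_spec$acceptor_pos[i]
      kind <- plant_spec$kind[i]
      w <- if (kind == "full") 6L else 4L
      if (p < w || p > lens[pi]) {
        stop("planted ", kind, " site at position ", p,
             " does not fit in protein ", pi, " (length ", lens[pi], ")",
             call. = FALSE)
      }
      # footprint includes offset -5 so partial plants can mask it
      foot_lo <- max(1L, p - 5L)
      same <- plant_spec$protein_index == pi &
        seq_len(nrow(plant_spec)) < i
      for (j in which(same)) {
        pj <- plant_spec$acceptor_pos[j]
        if (max(foot_lo, max(1L, pj - 5L)) <= min(p, pj)) {
          stop("planted sites at positions ", pj, " and ", p,
               " overlap in protein ", pi, call. = FALSE)
        }
      }
      wc <- function(k) sample(MOTIF_FREE_ALPHABET, k, replace = TRUE)
      if (kind == "full") {
        seqs[[pi]][(p - 5L):p] <- c(sample(c("L", "V", "I"), 1L), wc(1L),
                                    "R", wc(2L), sample(c("S", "T"), 1L))
      } else {
        seqs[[pi]][(p - 3L):p] <- c("R", wc(2L), sample(c("S", "T"), 1L))
        if (p >= 6L) {
          seqs[[pi]][p - 5L] <- sample(setdiff(MOTIF_FREE_ALPHABET,
                                               c("L", "V", "I")), 1L)
        }
      }
    }
    records <- data.frame(
      accession = accession,
      description = paste0("synthetic protein ", seq_len(n_proteins)),
      sequence = vapply(seqs, paste, character(1), collapse = ""),
      stringsAsFactors = FALSE)
    truth <- data.frame(accession = accession[plant_spec$protein_index],
                        acceptor_pos = plant_spec$acceptor_pos,
                        kind = plant_spec$kind, stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Derive a synthetic known-site table from planted truth
#'
#' Samples a seeded subset of the planted sites (without replacement) into
#' a known-site table, standing in for a phosphosite repository: exactly
#' `round(fraction_reported * n_sites)` sites become "previously reported".
#'
#' @param truth planted-site data.frame from [generate_proteome()].
#' @param records the matching proteome (residues are read off the
#'   sequences).
#' @param fraction_reported fraction of planted sites to include, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @return known-site data.frame (`accession`, `position`, `residue`,
#'   `annotation`).
#' @export
generate_known_sites <- function(truth, records, fraction_reported, seed) {
  stopifnot(fraction_reported >= 0, fraction_reported <= 1)
  n_take <- round(fraction_reported * nrow(truth))
  idx <- with_local_seed(seed, {
    if (n_take > 0) sort(sample.int(nrow(truth), n_take)) else integer(0)
  })
  taken <- truth[idx, , drop = FALSE]
  residue <- vapply(seq_len(nrow(taken)), function(i) {
    s <- records$sequence[records$accession == taken$accession[i]]
    substr(s, taken$acceptor_pos[i], taken$acceptor_pos[i])
  }, character(1))
  data.frame(accession = taken$accession,
             position = as.integer(taken$acceptor_pos),
             residue = residue,
             annotation = sprintf("synthetic known site (%s)", taken$kind),
             stringsAsFactors = FALSE)
}

#' Simulate a complete two-screen substrate-nomination study
#'
#' Builds the full synthetic counterpart of a two-antibody enrichment study
#' with a known comparison chain: two paired-replicate LFQ screens whose
#' spiked sets share 24 proteins, a proteome in which 12 of those shared
#' proteins carry 30 full consensus motifs in total, and a known-site table
#' containing 11 of the 30 planted sites. Running [run_all()] on the result
#' therefore has ground truth for every stage of the comparison report.
#'
#' @param seed integer seed driving all generators.
#' @param n_proteins proteins per screen.
#' @param spike_log2_fc planted log2 fold change of spiked proteins.
#' @return list with `screen_a` / `screen_b` (each `table`, `design`,
#'   `label`), `records` (proteome), `truth` (planted sites), `known`
#'   (known-site table), and the truth sets `spiked_a`, `spiked_b`,
#'   `motif_bearing`.
#' @export
simulate_two_screen_study <- function(seed = 42L, n_proteins = 300L,
                                      spike_log2_fc = 5) {
  n <- as.integer(n_proteins)
  stopifnot(n >= 40L)
  spec <- lfq_sim_spec(n_proteins = n, spike_log2_fc = spike_log2_fc)
  # deterministic spike placement: the screens share spiked proteins 1..24
  sim_a <- generate_lfq_experiment(spec, seed = seed, spike_indices = 1:30)
  sim_b <- generate_lfq_experiment(spec, seed = seed + 1L,
                                   spike_indices = c(1:24, 31:36))
  # spiked proteins are well-identified in this design: keep them above the
  # peptide-count filter so the comparison chain is fully determined
  keep2 <- function(sim, idx) {
    sim$table$meta$razor_unique_peptides[idx] <-
      pmax(sim$table$meta$razor_unique_peptides[idx], 2L)
    sim
  }
  sim_a <- keep2(sim_a, 1:30)
  sim_b <- keep2(sim_b, c(1:24, 31:36))

  site_counts <- c(3L, 3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L)  # = 30
  plant <- do.call(rbind, lapply(seq_along(site_counts), function(i) {
    data.frame(protein_index = i,
               acceptor_pos = 10L + 10L * seq_len(site_counts[i]),
               kind = "full", stringsAsFactors = FALSE)
  }))
  prot <- generate_proteome(n_proteins = n, length_range = c(60L, 120L),
                            plant_spec = plant, seed = seed + 2L)
  prot$records$accession <- sim_a$truth$accession
  prot$truth$accession <- sim_a$truth$accession[plant$protein_index]
  known <- generate_known_sites(prot$truth, prot$records,
                                fraction_reported = 11 / 30,
                                seed = seed + 3L)
  list(screen_a = list(table = sim_a$table, design = sim_a$design,
                       label = "LxRxxST"),
       screen_b = list(table = sim_b$table, design = sim_b$design,
                       label = "RxxST"),
       records = prot$records, truth = prot$truth, known = known,
       spiked_a = sim_a$truth$accession[1:30],
       spiked_b = sim_a$truth$accession[c(1:24, 31:36)],
       motif_bearing = sim_a$truth$accession[1:12])
}
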