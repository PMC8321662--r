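#!/usr/bin/env Rscript
# Two-screen comparison: intersect the enriched sets, summarise motif
# possession, derive the shared motif-bearing protein list and
# cross-reference their sites against the known-site table. This is the
# substrate-nomination chain; its counts are checked against the planted
# truth from 01_simulate_screens.R.

suppressPackageStartupMessages(library(pkdscreen))

seed <- 42L
data_dir <- "results/data"
out <- "results/comparison"

labels <- c("EGFP_1", "EGFP_2", "EGFP_3", "PKD3ca_1", "PKD3ca_2", "PKD3ca_3")
design <- paired_design(labels[1:3], labels[4:6])
records <- read_fasta(file.path(data_dir, "proteome_synthetic.fa"))
known <- read_known_sites(file.path(data_dir, "known_sites_synthetic.tsv"))

load_screen <- function(screen) {
  list(table = read_protein_groups(
         file.path(data_dir, paste0("proteinGroups_", screen, ".tsv")),
         sample_labels = labels),
       design = design, label = screen)
}
report <- run_all(load_screen("LxRxxST"), load_screen("RxxST"),
                  records, known, seed = seed, out_dir = out)
print(report)

truth <- read.delim(file.path(data_dir, "truth_planted_sites.tsv"))
cat(sprintf(
  "Planted truth: %d motif-bearing proteins, %d sites, %d in the known-site table\n",
  length(unique(truth$accession)), nrow(truth),
  nrow(known)))
cat(sprintf(
  "Recovered:     %d motif-bearing shared proteins, %d sites, %d previously reported\n",
  report$summary$n_shared_with_motif, report$summary$n_total_motifs_shared,
  report$summary$n_reported))
cat("Comparison outputs written under", out, "\n")
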