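#!/usr/bin/env Rscript
# Simulate the two-antibody substrate-nomination study and write its raw
# inputs to disk in the same formats a real study would arrive in:
# MaxQuant-style proteinGroups tables, a proteome FASTA, and a known-site
# TSV. Planted ground truth is written alongside for later stages.

suppressPackageStartupMessages(library(pkdscreen))

seed <- 42L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_two_screen_study(seed = seed)

write_protein_groups(study$screen_a$table,
                     file.path(out, "proteinGroups_LxRxxST.tsv"))
write_protein_groups(study$screen_b$table,
                     file.path(out, "proteinGroups_RxxST.tsv"))
write_fasta(study$records, file.path(out, "proteome_synthetic.fa"))
write_known_sites(study$known, file.path(out, "known_sites_synthetic.tsv"))
write.table(study$truth, file.path(out, "truth_planted_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(c(paste0("seed\t", seed),
             paste0("spiked_a\t", paste(study$spiked_a, collapse = ";")),
             paste0("spiked_b\t", paste(study$spiked_b, collapse = ";")),
             paste0("motif_bearing\t",
                    paste(study$motif_bearing, collapse = ";"))),
           file.path(out, "truth_spikes.tsv"))

cat("Simulated two screens of", nrow(study$screen_a$table$meta),
    "protein groups (3 paired replicates each).\n")
cat("Screen A spikes:", length(study$spiked_a),
    "| screen B spikes:", length(study$spiked_b),
    "| shared:", length(intersect(study$spiked_a, study$spiked_b)), "\n")
cat("Planted", nrow(study$truth), "consensus sites in",
    length(study$motif_bearing), "shared proteins;",
    nrow(study$known), "sites in the known-site table.\n")
cat("Inputs written under", out, "\n")
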