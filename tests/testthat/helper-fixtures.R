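# In-code fixtures shared across test files.

toy_protein_groups_tsv <- function(path) {
  lines <- c(
    paste("Majority protein IDs", "Gene names", "Razor + unique peptides",
          "Reverse", "Potential contaminant",
          "LFQ intensity C1", "LFQ intensity C2", "LFQ intensity C3",
          "LFQ intensity T1", "LFQ intensity T2", "LFQ intensity T3",
          sep = "\t"),
    paste("P1;P9", "Gnm1", "5", "", "",
          "1e7", "1.2e7", "9e6", "2e7", "2.5e7", "1.8e7", sep = "\t"),
    paste("P2", "Gnm2", "1", "", "",
          "0", "5e6", "", "6e6", "7e6", "5e6", sep = "\t"),
    paste("P3", "Gnm3", "3", "", "",
          "3e6", "4e6", "3e6", "3e6", "4e6", "3e6", sep = "\t"))
  writeLines(lines, path)
  path
}

toy_design <- function() {
  paired_design(c("C1", "C2", "C3"), c("T1", "T2", "T3"))
}

# A ProteinGroups object built directly in memory (bypasses file IO).
make_pg <- function(lfq, peptides = rep(5L, nrow(lfq)),
                    accessions = sprintf("P%d", seq_len(nrow(lfq)))) {
  rownames(lfq) <- accessions
  meta <- data.frame(group_id = accessions,
                     leading_accession = accessions,
                     razor_unique_peptides = as.integer(peptides),
                     reverse = FALSE, contaminant = FALSE,
                     stringsAsFactors = FALSE)
  meta$accessions <- as.list(accessions)
  meta$gene_names <- as.list(paste0("G", seq_len(nrow(lfq))))
  pkdscreen:::new_protein_groups(meta, lfq)
}

# Two-screen synthetic study with a fully controlled comparison chain
# (24 shared spikes, 12 motif-bearing with 30 sites, 11 known).
end_to_end_fixture <- function(seed = 42L) {
  simulate_two_screen_study(seed = seed)
}
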