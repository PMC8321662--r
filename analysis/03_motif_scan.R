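#!/usr/bin/env Rscript
# Consensus-motif scan of the study proteome with both patterns: the full
# PKD motif [L/V/I]xRxx[S/T] and the partial motif Rxx[S/T]. Writes the
# hit tables and per-protein counts, and checks the scan against the
# planted truth table.

suppressPackageStartupMessages(library(pkdscreen))

data_dir <- "results/data"
out <- "results/motifs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

records <- read_fasta(file.path(data_dir, "proteome_synthetic.fa"))
truth <- read.delim(file.path(data_dir, "truth_planted_sites.tsv"))

for (kind in c("full", "partial")) {
  hits <- scan_proteome(records, motif_pattern(kind))
  counts <- proteome_motif_counts(records, motif_pattern(kind))
  write.table(hits, file.path(out, paste0("hits_", kind, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(accession = names(counts),
                         n_motifs = as.vector(counts)),
              file.path(out, paste0("counts_", kind, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s pattern: %d sites in %d of %d proteins\n", kind,
              attr(counts, "total"), sum(counts >= 1), length(counts)))
}

full_hits <- scan_proteome(records, motif_pattern("full"))
planted_full <- truth[truth$kind == "full", ]
norm <- function(d) { rownames(d) <- NULL; d }
agree <- identical(
  norm(full_hits[order(full_hits$accession, full_hits$acceptor_pos),
                 c("accession", "acceptor_pos")]),
  norm(planted_full[order(planted_full$accession, planted_full$acceptor_pos),
                    c("accession", "acceptor_pos")]))
cat("Full-pattern hits match the planted truth exactly:", agree, "\n")
cat("Motif tables written under", out, "\n")
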