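# pkdscreen

Enrichment analysis and consensus-motif scanning for kinase
substrate-motif immunoprecipitation (IP) proteomics screens, built around
the protein kinase D (PKD) motif `[L/V/I]xRxx[S/T]`.

## What it is for

Phospho-motif antibodies can pull candidate kinase substrates out of
lysates from cells with active versus inactive kinase; label-free
quantification (LFQ) mass spectrometry of the pull-downs yields a
MaxQuant-style proteinGroups table per screen. `pkdscreen` implements the
computational workflow that turns two such screens into a ranked
substrate nomination list, for proteomics analysts who want the whole
chain scripted, seeded and testable:

1. **Filter** — protein groups with fewer than 2 razor + unique peptides
   are excluded.
2. **Impute** — LFQ intensities are log10-transformed; missing cells
   (left-censored, low-abundance) are drawn from `Normal(q05, 0.1)`,
   where `q05` is the 5% quantile of all observed log10 intensities
   pooled across conditions and replicates.
3. **Ratio** — paired per-replicate log2 ratios,
   `mean_r[(log10 T_r − log10 C_r)] / log10 2`, treatment vs control.
4. **Classify** — Tukey-style two-tier IQR fences over all ratios of a
   screen: class 2 ("significantly enriched") strictly outside
   `Q3 + 3·IQR`, class 1 ("potentially enriched") outside `Q3 + 1.5·IQR`
   (two-sided internally, upper side reported).
5. **Scan** — positional-constraint scanner for the full PKD consensus
   motif `[L/V/I]xRxx[S/T]` (acceptor S/T at 0, mandatory R at −3,
   hydrophobic L/V/I at −5) and the partial motif `Rxx[S/T]`, reporting
   1-based acceptor positions.
6. **Compare** — intersect the enriched sets of two antibody screens,
   count motif-bearing proteins and their sites, and cross-reference the
   sites against a local known-phosphosite table (exact
   accession + position join; residue mismatches are conflicts, never
   matches).

A seeded synthetic-data module generates paired-replicate LFQ screens
with spiked fold changes and intensity-dependent (MNAR) missingness, and
proteomes with motifs planted at recorded positions, so every stage can
be validated against known ground truth.

## Worked example

```r
library(pkdscreen)

study  <- simulate_two_screen_study(seed = 42)   # two screens + proteome + known sites
report <- run_all(study$screen_a, study$screen_b,
                  study$records, study$known, seed = 42)
print(report)
#> ComparisonReport
#>   enriched: 33 / 37 (intersection 24)
#>   motif-bearing: 36% / 32%
#>   shared with motif: 12 proteins, 30 sites (11 previously reported, 19 novel)
```

Reading the output: 33 and 37 proteins were enriched (class 1 or 2,
upper fence) in the two screens and 24 in both; 36%/32% of each screen's
enriched proteins carry at least one full consensus motif; 12 of the 24
shared proteins are motif-bearing with 30 candidate acceptor sites
between them, of which 11 are already present in the known-site table
and 19 are novel. The study's planted truth is exactly 12 proteins /
30 sites / 11 known, so the chain recovers it in full.

The `analysis/` directory holds the same workflow as numbered drivers
that exchange data through files (proteinGroups TSV, FASTA, known-site
TSV) instead of in-memory objects:

```sh
Rscript analysis/01_simulate_screens.R    # write synthetic raw inputs
Rscript analysis/02_enrichment.R          # per-screen filter/impute/ratio/classify
Rscript analysis/03_motif_scan.R          # full + partial pattern scans
Rscript analysis/04_compare_screens.R     # two-screen comparison + xref
Rscript analysis/05_recovery_benchmark.R  # sensitivity/FPR over 20 seeds
```

Tables land under `results/`. On real data, point
`read_protein_groups()` at your proteinGroups files, `read_fasta()` at
the matching proteome and `read_known_sites()` at a phosphosite export,
and skip driver 01.

## Scope

The package starts from quantified protein groups: raw spectra
processing, protein inference, between-sample normalisation, FDR
machinery and live database queries are out of scope. See
`vignettes/substrate-screen-methods.Rmd` for the model, its assumptions
and known limitations.
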