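---
title: "Methods: enrichment statistics and motif scanning for substrate-motif IP screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment statistics and motif scanning for substrate-motif IP screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkdscreen)
```

## The problem

Protein kinase D (PKD) family kinases phosphorylate serine/threonine
residues in a characteristic sequence context: an arginine three residues
before the phospho-acceptor is essential, and a hydrophobic residue
(leucine, or sometimes valine/isoleucine) five residues before it is
typical — the full consensus `[L/V/I]xRxx[S/T]`, with the relaxed partial
form `Rxx[S/T]`. Antibodies raised against the phosphorylated motif can
immunoprecipitate candidate substrates from lysates of cells in which the
kinase is active versus an inactive control; label-free quantification
(LFQ) mass spectrometry of the pull-downs then yields per-protein
intensities in each sample. This package implements the downstream
computational half of such a study: deciding which proteins are enriched
by the kinase-active pull-down, which of those carry a consensus motif,
which survive a two-antibody comparison, and which of their candidate
sites are already annotated.

## Enrichment model

The quantification chain is deliberately simple and distribution-free:

1. **Identification filter.** Protein groups supported by fewer than two
   razor + unique peptides are excluded. The filter runs first: rows that
   would be excluded must not influence the imputation anchor computed in
   step 3. The threshold applies to the table's total razor + unique
   count; a per-sample variant can be emulated by remapping the
   peptide-count column.

2. **Log transform.** Observed LFQ intensities are carried as log10
   values end-to-end. LFQ cells equal to 0 or blank are treated as
   *missing*, not as zero intensity — upstream quantification writes 0
   when a protein was not quantified in a sample.

3. **Left-censored imputation.** Missing LFQ values in IP proteomics are
   predominantly low-abundance censoring (missing not at random), so each
   missing cell receives an independent draw from
   `Normal(q, sd)` in log10 space, with `q` the 5% quantile of *all*
   observed log10 intensities pooled across both conditions and all
   replicates, and `sd = 0.1`. Both parameters are exposed
   (`impute.quantile`, `impute.sd`). Imputation never alters observed
   cells, and the observed/imputed mask is retained.

4. **Paired log2 ratios.** Replicates are paired by donor animal. The
   default ratio is the per-pair log difference converted to log2,
   `(log10 T_r − log10 C_r)/log10 2`, averaged over pairs; a
   ratio-of-means mode is available for unpaired-minded users. Keeping
   the matrix in log10 and dividing by `log10 2` at this one step avoids
   double-transforming. Each protein also carries its mean log10
   intensity — the x coordinate of the familiar ratio-versus-abundance
   scatter.

5. **Two-tier IQR fences.** With Q1, Q3 and IQR computed over all ratios
   of the screen, a ratio strictly outside `Q3 + 3·IQR` / `Q1 − 3·IQR`
   is class 2 ("significantly enriched"), strictly outside the 1.5×
   fences class 1 ("potentially enriched"), else class 0. This is
   Tukey's outlier rule applied twice; it is a pure function of the
   ratio vector, free of distributional assumptions, and invariant under
   shifting all ratios or scaling them by a positive constant. Fences
   are two-sided, but pull-down enrichment is one-sided, so the default
   "enriched" set is class ≥ 1 on the upper side (`direction = +1`);
   lower-side outliers remain in the full table.

### Numerical conventions

* Quartiles and the imputation quantile use linear interpolation between
  order statistics (R's type 7), configurable via `quantile_type`; the
  choice matters only in small screens.
* If IQR = 0 (all ratios equal up to quartile collapse), the fences
  coincide with Q1 = Q3 and the strict inequalities classify every tied
  value as class 0.
* The extreme fence is tested first and classes are mutually exclusive;
  every class-2 protein would also breach the 1.5× fence (nesting).
* Classification refuses fewer than 4 ratios (quartiles are not
  meaningful) and non-finite ratios.
* Randomness: a single run seed is combined with a per-stage label to
  derive the imputation seed, so adding a screen or stage never changes
  another stage's draws, and identical seed implies byte-identical
  output tables.

## Motif scanner

The scanner is a positional constraint table, not a regular expression:
offset −5 ∈ {L, V, I} (full pattern only), offset −3 = R, offset 0 ∈
{S, T}; all other offsets are wildcards. Acceptor positions are reported
1-based, in the `Ser16`-style coordinate convention, and the stored
window is the inclusive slice ending at the acceptor (length 6 full,
4 partial). All overlapping hits are reported — two acceptors three
residues apart legitimately share an arginine — because per-protein
motif burdens are site-level counts. Ambiguity codes (X, B, Z, U) match
wildcard offsets but never a constrained offset: an unknown residue
cannot be asserted to be L/V/I, R, S or T. The scanner operates on plain
sequence; it does not know phosphorylation state, exactly like
pattern-based web scanners.

Cross-referencing against a known-site table joins on exact
`(accession, 1-based position)`; a positional match with a different
residue is flagged a conflict, never a match. No ±1 positional tolerance
is applied by default because none is defensible without knowing the
source database's isoform conventions.

## What the synthetic generator emulates — and what it does not

`generate_lfq_experiment()` draws a latent log10 abundance per protein
(`Normal(7.0, 0.7)`, a typical LFQ intensity scale), adds per-cell
replicate noise (`sd 0.1` log10), shifts treatment replicates of spiked
proteins by `fc·log10 2`, and censors each cell with probability
`1/(1 + exp(slope·(log10 x − midpoint)))` (midpoint 6.0, slope 2.0) —
a logistic left-censoring mechanism chosen to match the assumption
behind low-quantile imputation. Defaults of 3 paired replicates per
condition mirror the three-donor paired design the pipeline targets;
spike defaults (5% of proteins at log2 FC +5) produce unambiguous
positives against a null background. About 10% of proteins are assigned
a single razor+unique peptide to exercise the identification filter.

`generate_proteome()` draws background residues uniformly from the
17-letter alphabet excluding R, S and T, so *no* motif can form outside
the planted windows and recovery can be asserted exactly (zero misses,
zero extras). Planted full motifs draw their −5 residue from {L, V, I}
and wildcards from the background alphabet; planted partial motifs
additionally force the −5 residue outside {L, V, I} so a partial plant
cannot accidentally satisfy the full pattern. A "realistic" background
mode keeps all 20 residues for workloads where accidental sites are
wanted; truth is then defined by the scanner itself.

`simulate_two_screen_study()` composes these into a complete study with
a known comparison chain: 24 spiked proteins shared between two screens,
12 of them carrying 30 full-consensus sites in total, 11 of those sites
present in the synthetic known-site table. Spiked proteins in this
composed design are pinned above the peptide filter — the study asks
whether the *statistics* recover the plants, not whether identification
sampled enough peptides.

What the generator does **not** emulate: peptide-to-protein roll-up and
shared-peptide protein inference, between-sample normalisation error
(LFQ is assumed pre-normalised), intensity-dependent variance,
correlated missingness within a replicate, and realistic amino-acid
composition or homology in sequences. Passing recovery tests on this
generator therefore demonstrates the correctness of the statistics and
scanning, not robustness to every pathology of real LFQ data.

## Operating characteristics and known limitations

On the default study conditions (500 proteins, 3 paired replicates, 5%
spiked at log2 FC +5, censoring on), pooled over 20 seeds, class-2
recovery runs at ≈ 98% sensitivity with a false-positive rate below 1%
(`analysis/05_recovery_benchmark.R` recomputes this table). Sensitivity
is counted over spiked proteins that survive the peptide filter; a
protein the filter removes is not recoverable by any downstream
statistic.

The characteristic failure mode is *censoring compression*: a protein
whose control intensities are entirely missing has its control imputed
near the pooled 5% quantile, so its estimated ratio is capped at roughly
`(treatment − q05)/log10 2` regardless of the true fold change. Very
low-abundance spiked proteins can therefore land between the 1.5× and 3×
fences (class 1) or, rarely, inside them. This is a faithful property of
low-quantile imputation, not an implementation artifact; it is why the
end-to-end chain is validated at a fixed generator seed and why
screen-level counts in repeated runs fluctuate by a protein or two.

Problem sizes in the test-suite and the acceptance script (500–6,000
proteins, 20 seeds, 1,000 property cases) were chosen so each check's
sampling error is far below its asserted tolerance while the whole suite
stays fast on a laptop.

Other limitations, by design: no p-values or FDR — the fence rule *is*
the criterion, and exporting a significance class plus the ratio is more
honest than inventing a test statistic; no between-database isoform
mapping for the known-site join; no PSSM or probabilistic motif scoring;
no network access anywhere — repository lookups are replaced by a local
known-site table.

## A worked example

```{r example, eval = FALSE}
study <- simulate_two_screen_study(seed = 42)
report <- run_all(study$screen_a, study$screen_b,
                  study$records, study$known, seed = 42)
print(report)
#> ComparisonReport
#>   enriched: 33 / 37 (intersection 24)
#>   motif-bearing: 36% / 32%
#>   shared with motif: 12 proteins, 30 sites (11 previously reported, 19 novel)
```

The planted truth of that study is exactly 12 shared motif-bearing
proteins, 30 sites, 11 known — the report recovers the full chain.
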