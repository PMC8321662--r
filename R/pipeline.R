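#' Default pipeline parameters
#'
#' One place for every tunable the enrichment stages use; all overridable
#' per call.
#'
#' @param min_razor_unique peptide-count inclusion filter.
#' @param impute_quantile,impute_sd imputation anchor quantile and spread
#'   (log10 scale).
#' @param fences [fence_params()].
#' @param ratio_mode `"paired-mean"` or `"ratio-of-means"`.
#' @param quantile_type quantile algorithm for imputation anchor and
#'   quartiles.
#' @return named list of parameters.
#' @export
pipeline_params <- function(min_razor_unique = 2L,
                            impute_quantile = 0.05, impute_sd = 0.1,
                            fences = fence_params(),
                            ratio_mode = "paired-mean",
                            quantile_type = 7L) {
  list(min_razor_unique = min_razor_unique,
       impute_quantile = impute_quantile, impute_sd = impute_sd,
       fences = fences, ratio_mode = ratio_mode,
       quantile_type = quantile_type)
}

#' Run the enrichment pipeline on one screen
#'
#' filter -> log10 matrix -> impute -> paired log2 ratios -> IQR-fence
#' classification. The imputation seed is derived from the run seed and the
#' screen label, so adding screens or stages never changes another screen's
#' imputed values.
#'
#' @param table a `ProteinGroups` object.
#' @param design a [paired_design()].
#' @param label screen label.
#' @param params [pipeline_params()].
#' @param seed integer run seed.
#' @return a `ScreenResult`; its `records` carry gene names alongside the
#'   enrichment columns.
#' @export
run_screen <- function(table, design, label, params = pipeline_params(),
                       seed = 1L) {
  filtered <- filter_proteins(table, params$min_razor_unique)
  m <- to_log_matrix(filtered, design)
  m <- impute_missing(m, quantile = params$impute_quantile,
                      sd = params$impute_sd,
                      seed = stage_seed(seed, paste0("impute:", label)),
                      quantile_type = params$quantile_type)
  ratios <- compute_log2_ratios(m, mode = params$ratio_mode)
  records <- classify_enrichment(ratios, params$fences)
  records$gene_names <- vapply(filtered$meta$gene_names, paste, character(1),
                               collapse = ";")
  records$razor_unique_peptides <- filtered$meta$razor_unique_peptides
  message("run_screen '", label, "': ", nrow(records), " proteins, ",
          sum(records$significance == 2L), " class 2, ",
          sum(records$significance == 1L), " class 1")
  screen_result(records, label)
}

#' Top enriched proteins, sorted by descending log2 ratio
#'
#' The per-screen headline table: accession, gene names, peptide count and
#' log2 ratio for the `n` most enriched proteins.
#'
#' @param screen a `ScreenResult`.
#' @param n number of rows.
#' @return data.frame sorted by descending `log2_ratio`.
#' @export
top_enriched <- function(screen, n = 15L) {
  rec <- screen$records
  rec <- rec[order(-rec$log2_ratio), , drop = FALSE]
  rec <- utils::head(rec, n)
  rownames(rec) <- NULL
  rec[, c("accession", "gene_names", "razor_unique_peptides",
          "log2_ratio", "significance")]
}

#' Run the complete two-screen workflow
#'
#' Runs both screens, scans the proteome with the full consensus pattern,
#' compares the enriched sets and cross-references the shared
#' motif-bearing proteins' sites against the known-site table. When
#' `out_dir` is given, writes per-screen enrichment TSVs, top-protein
#' tables, the annotated hits, the comparison summary JSON and a run
#' summary.
#'
#' @param screen_a,screen_b lists with elements `table`, `design`, `label`.
#' @param records proteome data.frame ([read_fasta()]).
#' @param known known-site data.frame, or `NULL`.
#' @param params [pipeline_params()].
#' @param seed integer run seed.
#' @param out_dir optional output directory.
#' @return a `ComparisonReport` (with attribute `screens` holding both
#'   `ScreenResult`s).
#' @export
run_all <- function(screen_a, screen_b, records, known = NULL,
                    params = pipeline_params(), seed = 1L, out_dir = NULL) {
  a <- run_screen(screen_a$table, screen_a$design, screen_a$label,
                  params, seed)
  b <- run_screen(screen_b$table, screen_b$design, screen_b$label,
                  params, seed)
  report <- build_report(a, b, records, known)
  attr(report, "screens") <- list(a = a, b = b)
  if (!is.null(out_dir)) {
    tables <- list(
      enrichment_a = a$records,
      enrichment_b = b$records,
      top_a = top_enriched(a),
      top_b = top_enriched(b),
      shared_motif_hits = report$xref
    )
    paths <- write_results(tables, out_dir,
                           params = c(params[c("min_razor_unique",
                                               "impute_quantile",
                                               "impute_sd", "ratio_mode")],
                                      list(k_potential = params$fences$k_potential,
                                           k_extreme = params$fences$k_extreme)),
                           seed = seed)
    jsonlite::write_json(report$summary,
                         file.path(out_dir, "comparison_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(report, "paths") <- c(paths,
                               comparison_summary =
                                 file.path(out_dir, "comparison_summary.json"))
  }
  report
}
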