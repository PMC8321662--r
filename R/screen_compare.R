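#' Bundle a screen's enrichment records
#'
#' "Enriched" follows the screens' own counting: significance 1 or 2
#' (potentially or significantly enriched), upper-fence side by default
#' since the pull-down enriches, not depletes.
#'
#' @param records classified data.frame from [classify_enrichment()].
#' @param label screen label (e.g. the antibody motif name).
#' @param direction restrict the enriched set to one fence side
#'   (`+1` upper, `-1` lower, `NULL` for both).
#' @return a `ScreenResult`: list with `label`, `records`, `enriched`
#'   (accession character vector).
#' @export
screen_result <- function(records, label, direction = 1L) {
  sel <- records$significance >= 1L
  if (!is.null(direction)) sel <- sel & records$direction == direction
  structure(list(label = label, records = records,
                 enriched = records$accession[sel]),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat("ScreenResult '", x$label, "': ", nrow(x$records), " proteins, ",
      length(x$enriched), " enriched (significance 1 or 2)\n", sep = "")
  invisible(x)
}

#' Intersect the enriched sets of two screens
#'
#' @param a,b `ScreenResult` objects keyed on the same accession namespace.
#' @return character vector of accessions enriched in both screens.
#' @export
intersect_enriched <- function(a, b) {
  out <- intersect(a$enriched, b$enriched)
  message("intersect_enriched: ", length(a$enriched), " ('", a$label,
          "') x ", length(b$enriched), " ('", b$label, "') -> ",
          length(out), " shared")
  out
}

#' Motif-bearing proteins within an intersection
#'
#' @param intersection accession character vector.
#' @param counts named motif-count vector ([proteome_motif_counts()]);
#'   intersection members absent from `counts` are treated as count 0 and
#'   reported in a message.
#' @return list with `accessions` (members with >= 1 motif) and
#'   `total_motifs` (summed site count over that subset).
#' @export
shared_motif_proteins <- function(intersection, counts) {
  missing <- setdiff(intersection, names(counts))
  if (length(missing) > 0L) {
    message("shared_motif_proteins: no motif counts for ", length(missing),
            " accession(s); treated as 0")
  }
  present <- intersect(intersection, names(counts))
  with_motif <- present[counts[present] >= 1L]
  list(accessions = with_motif,
       total_motifs = as.integer(sum(counts[with_motif])))
}

#' Cross-reference motif hits against a known-site table
#'
#' A hit is `previously_reported` iff the known-site table contains an exact
#' (accession, position) match with the same acceptor residue. A positional
#' match whose residue differs is flagged as a `conflict`, not a match.
#'
#' @param hits hits data.frame from [scan_proteome()].
#' @param known known-site data.frame ([read_known_sites()]).
#' @return `hits` with `previously_reported`, `conflict` and `annotation`
#'   columns appended; attributes `n_reported` / `n_novel` summarise.
#' @export
xref_known_sites <- function(hits, known) {
  key <- function(acc, pos) paste(acc, pos, sep = "\r")
  idx <- match(key(hits$accession, hits$acceptor_pos),
               key(known$accession, known$position))
  found <- !is.na(idx)
  same_residue <- found & hits$acceptor_residue == known$residue[idx]
  hits$previously_reported <- same_residue
  hits$conflict <- found & !same_residue
  hits$annotation <- ifelse(same_residue, known$annotation[idx],
                            NA_character_)
  attr(hits, "n_reported") <- sum(hits$previously_reported)
  attr(hits, "n_novel") <- sum(!hits$previously_reported)
  hits
}

#' Assemble the full two-screen comparison report
#'
#' The computational chain behind substrate nomination: intersect the two
#' enriched sets, summarise motif possession per screen, list the shared
#' motif-bearing proteins with their total site count, and cross-reference
#' those proteins' motif sites against the known-site table.
#'
#' @param a,b `ScreenResult` objects.
#' @param records proteome data.frame ([read_fasta()]).
#' @param known known-site data.frame; `NULL` for no cross-reference.
#' @param pattern motif pattern used for possession/counting (default full).
#' @return a `ComparisonReport`: list with `intersection`,
#'   `per_screen_motif_fraction`, `shared_with_motif`,
#'   `total_motifs_in_shared`, `xref` (annotated hits for shared
#'   motif-bearing proteins), and `summary` (named counts).
#' @export
build_report <- function(a, b, records, known = NULL,
                         pattern = motif_pattern("full")) {
  counts <- proteome_motif_counts(records, pattern)
  intersection <- intersect_enriched(a, b)
  frac_a <- fraction_with_motif(a$enriched, counts)
  frac_b <- fraction_with_motif(b$enriched, counts)
  shared <- shared_motif_proteins(intersection, counts)
  hits <- scan_proteome(records[records$accession %in% shared$accessions, ,
                                drop = FALSE], pattern)
  if (is.null(known)) {
    known <- data.frame(accession = character(0), position = integer(0),
                        residue = character(0), annotation = character(0),
                        stringsAsFactors = FALSE)
  }
  xref <- xref_known_sites(hits, known)
  summary <- list(
    n_enriched_a = length(a$enriched),
    n_enriched_b = length(b$enriched),
    n_intersection = length(intersection),
    pct_motif_a = as.integer(attr(frac_a, "percent")),
    pct_motif_b = as.integer(attr(frac_b, "percent")),
    n_shared_with_motif = length(shared$accessions),
    n_total_motifs_shared = shared$total_motifs,
    n_reported = attr(xref, "n_reported"),
    n_novel = attr(xref, "n_novel")
  )
  structure(list(intersection = intersection,
                 per_screen_motif_fraction = stats::setNames(
                   c(as.numeric(frac_a), as.numeric(frac_b)),
                   c(a$label, b$label)),
                 shared_with_motif = shared$accessions,
                 total_motifs_in_shared = shared$total_motifs,
                 xref = xref,
                 summary = summary),
            class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  s <- x$summary
  cat("ComparisonReport\n",
      "  enriched: ", s$n_enriched_a, " / ", s$n_enriched_b,
      " (intersection ", s$n_intersection, ")\n",
      "  motif-bearing: ", s$pct_motif_a, "% / ", s$pct_motif_b, "%\n",
      "  shared with motif: ", s$n_shared_with_motif, " proteins, ",
      s$n_total_motifs_shared, " sites (", s$n_reported,
      " previously reported, ", s$n_novel, " novel)\n", sep = "")
  invisible(x)
}
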