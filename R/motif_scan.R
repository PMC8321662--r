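#' Consensus-motif patterns recognised by the scanner
#'
#' The full PKD consensus motif is `[L/V/I]xRxx[S/T]`: a phospho-acceptor
#' serine or threonine at offset 0, a mandatory arginine at offset -3, and a
#' hydrophobic leucine/valine/isoleucine at offset -5 (window length 6). The
#' partial motif `Rxx[S/T]` drops the -5 constraint (window length 4).
#' Wildcard offsets match any residue; ambiguity codes (X, B, Z, U) match
#' wildcards but never a constrained offset — an unknown residue cannot be
#' asserted to be L/V/I, R, S or T.
#'
#' @param kind `"full"` or `"partial"`.
#' @return a `MotifPattern`: list with `kind`, `window_length`, and
#'   `constraints` (named list, offset-from-acceptor -> allowed residues).
#' @export
motif_pattern <- function(kind = c("full", "partial")) {
  kind <- match.arg(kind)
  constraints <- switch(kind,
    full = list(`-5` = c("L", "V", "I"), `-3` = "R", `0` = c("S", "T")),
    partial = list(`-3` = "R", `0` = c("S", "T")))
  structure(list(kind = kind,
                 window_length = switch(kind, full = 6L, partial = 4L),
                 constraints = constraints),
            class = "MotifPattern")
}

#' Scan one protein sequence for consensus-motif acceptor sites
#'
#' Reports every phospho-acceptor position p (1-based) whose constrained
#' offsets all match: for each constraint offset o, `sequence[p + o]` must
#' be in the allowed residue set. Overlapping hits are all reported;
#' sequences shorter than the window return no hits.
#'
#' @param sequence uppercase amino-acid string, or a one-row data.frame as
#'   returned by [read_fasta()].
#' @param pattern a [motif_pattern()].
#' @param accession accession recorded in the hits (taken from the
#'   data.frame when one is supplied).
#' @return data.frame with columns `accession`, `acceptor_pos`,
#'   `acceptor_residue`, `window`, `kind`, ordered by ascending position.
#'   The window is the inclusive slice ending at the acceptor.
#' @export
scan_motifs <- function(sequence, pattern = motif_pattern("full"),
                        accession = NA_character_) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    accession <- sequence$accession
    sequence <- sequence$sequence
  }
  stopifnot(inherits(pattern, "MotifPattern"), is.character(sequence),
            length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  w <- pattern$window_length
  if (n < w) return(empty_hits())
  ok <- rep(TRUE, n - w + 1L)          # candidate acceptors: positions w..n
  acceptors <- seq.int(w, n)
  for (off_name in names(pattern$constraints)) {
    off <- as.integer(off_name)
    ok <- ok & chars[acceptors + off] %in% pattern$constraints[[off_name]]
  }
  pos <- acceptors[ok]
  if (length(pos) == 0L) return(empty_hits())
  data.frame(accession = accession,
             acceptor_pos = pos,
             acceptor_residue = chars[pos],
             window = vapply(pos, function(p) {
               paste(chars[(p - w + 1L):p], collapse = "")
             }, character(1)),
             kind = pattern$kind,
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(accession = character(0), acceptor_pos = integer(0),
             acceptor_residue = character(0), window = character(0),
             kind = character(0), stringsAsFactors = FALSE)
}

#' Scan a whole proteome
#'
#' @param records data.frame from [read_fasta()] (columns `accession`,
#'   `sequence`); accessions must be unique.
#' @param pattern a [motif_pattern()].
#' @return one hits data.frame (see [scan_motifs()]) over all records.
#' @export
scan_proteome <- function(records, pattern = motif_pattern("full")) {
  if (anyDuplicated(records$accession)) {
    stop("duplicate accession(s) in proteome", call. = FALSE)
  }
  hits <- lapply(seq_len(nrow(records)), function(i) {
    scan_motifs(records$sequence[i], pattern,
                accession = records$accession[i])
  })
  do.call(rbind, c(list(empty_hits()), hits))
}

#' Per-protein motif counts
#'
#' Site-level counts: two overlapping acceptors are two sites. Proteins
#' without a hit get count 0.
#'
#' @param records proteome data.frame (unique accessions).
#' @param pattern a [motif_pattern()].
#' @return named integer vector, accession -> hit count; attribute
#'   `total` holds the summed count.
#' @export
proteome_motif_counts <- function(records, pattern = motif_pattern("full")) {
  hits <- scan_proteome(records, pattern)
  counts <- integer(nrow(records))
  names(counts) <- records$accession
  if (nrow(hits) > 0L) {
    tab <- table(hits$accession)
    counts[names(tab)] <- as.integer(tab)
  }
  attr(counts, "total") <- sum(counts)
  counts
}

#' Fraction of proteins carrying at least one motif
#'
#' @param accessions character vector (a set) of protein accessions.
#' @param counts named count vector from [proteome_motif_counts()];
#'   accessions absent from `counts` (no sequence available) are counted as
#'   motif-free and reported in a message.
#' @return the fraction in `[0, 1]`, with attribute `percent` holding the
#'   integer-rounded percentage.
#' @export
fraction_with_motif <- function(accessions, counts) {
  accessions <- unique(accessions)
  if (length(accessions) == 0L) {
    stop("empty accession set: fraction undefined", call. = FALSE)
  }
  absent <- setdiff(accessions, names(counts))
  if (length(absent) > 0L) {
    message("fraction_with_motif: no sequence for ", length(absent),
            " accession(s); counted as motif-free")
  }
  have <- sum(counts[intersect(accessions, names(counts))] >= 1L)
  frac <- have / length(accessions)
  attr(frac, "percent") <- round(100 * frac)
  frac
}
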