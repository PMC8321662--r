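#' Default column mapping for MaxQuant-style proteinGroups tables
#'
#' Column names follow the MaxQuant proteinGroups.txt convention. Every entry
#' can be remapped when a table uses a different schema. The `lfq_prefix` is
#' pasted in front of each sample label to locate the per-sample intensity
#' columns.
#'
#' @param ids column holding the semicolon-separated accession list.
#' @param peptides column holding the razor + unique peptide count.
#' @param gene_names column holding gene names (optional in the file).
#' @param lfq_prefix prefix of the per-sample LFQ intensity columns.
#' @param reverse,contaminant flag columns marking decoy / contaminant rows;
#'   set to `NULL` if the table has none.
#' @return a named list usable as `column_map` in [read_protein_groups()].
#' @export
default_column_map <- function(ids = "Majority protein IDs",
                               peptides = "Razor + unique peptides",
                               gene_names = "Gene names",
                               lfq_prefix = "LFQ intensity ",
                               reverse = "Reverse",
                               contaminant = "Potential contaminant") {
  list(ids = ids, peptides = peptides, gene_names = gene_names,
       lfq_prefix = lfq_prefix, reverse = reverse, contaminant = contaminant)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-separated protein-group table into the rectangular container
#' used by the pipeline: per-row metadata plus an LFQ intensity matrix in
#' which both `0` and blank cells are normalised to `NA` (unquantified --
#' MaxQuant writes 0 for proteins without an LFQ value in a sample).
#'
#' @param path path to a tab-separated file with a header row.
#' @param sample_labels character vector of sample labels; for each label the
#'   column `paste0(column_map$lfq_prefix, label)` must exist.
#' @param column_map see [default_column_map()].
#' @param drop_flagged drop rows marked reverse / potential contaminant when
#'   those columns exist (standard proteinGroups hygiene).
#' @param duplicate_policy what to do when two rows share a leading
#'   accession: `"error"` or `"keep_first"`.
#' @return a `ProteinGroups` object: list with `meta` (data.frame with
#'   columns `group_id`, `leading_accession`, `accessions` (list),
#'   `gene_names` (list), `razor_unique_peptides`, `reverse`, `contaminant`)
#'   and `lfq` (numeric matrix, proteins x samples, `NA` = missing).
#' @export
read_protein_groups <- function(path, sample_labels,
                                column_map = default_column_map(),
                                drop_flagged = TRUE,
                                duplicate_policy = c("error", "keep_first")) {
  duplicate_policy <- match.arg(duplicate_policy)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", stringsAsFactors = FALSE)
  need <- c(column_map$ids, column_map$peptides,
            paste0(column_map$lfq_prefix, sample_labels))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("protein-groups table is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  accessions <- strsplit(df[[column_map$ids]], ";", fixed = TRUE)
  leading <- vapply(accessions, function(a) if (length(a)) a[[1L]] else NA_character_,
                    character(1))
  peptides <- suppressWarnings(as.integer(df[[column_map$peptides]]))
  if (anyNA(peptides)) {
    bad <- which(is.na(peptides))[1L]
    stop("non-numeric peptide count in row ", bad, call. = FALSE)
  }

  gene_names <- if (!is.null(column_map$gene_names) &&
                    column_map$gene_names %in% names(df)) {
    strsplit(df[[column_map$gene_names]], ";", fixed = TRUE)
  } else {
    rep(list(character(0)), nrow(df))
  }

  flag_col <- function(name) {
    if (!is.null(name) && name %in% names(df)) df[[name]] == "+" else
      rep(FALSE, nrow(df))
  }
  reverse <- flag_col(column_map$reverse)
  contaminant <- flag_col(column_map$contaminant)

  lfq <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_labels),
                dimnames = list(NULL, sample_labels))
  for (j in seq_along(sample_labels)) {
    raw <- df[[paste0(column_map$lfq_prefix, sample_labels[j])]]
    raw[raw == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0L) {
      stop("non-numeric LFQ cell in row ", bad[1L], ", column '",
           paste0(column_map$lfq_prefix, sample_labels[j]), "'", call. = FALSE)
    }
    if (any(val < 0, na.rm = TRUE)) {
      stop("negative LFQ intensity in column '",
           paste0(column_map$lfq_prefix, sample_labels[j]), "'", call. = FALSE)
    }
    val[!is.na(val) & val == 0] <- NA_real_   # 0 means unquantified
    lfq[, j] <- val
  }

  meta <- data.frame(group_id = as.character(seq_len(nrow(df))),
                     leading_accession = leading,
                     razor_unique_peptides = peptides,
                     reverse = reverse, contaminant = contaminant,
                     stringsAsFactors = FALSE)
  meta$accessions <- accessions
  meta$gene_names <- gene_names

  keep <- rep(TRUE, nrow(meta))
  if (drop_flagged) keep <- !(meta$reverse | meta$contaminant)
  meta <- meta[keep, , drop = FALSE]
  lfq <- lfq[keep, , drop = FALSE]

  dup <- duplicated(meta$leading_accession)
  if (any(dup)) {
    if (duplicate_policy == "error") {
      stop("duplicate leading accession(s): ",
           paste(unique(meta$leading_accession[dup]), collapse = ", "),
           call. = FALSE)
    }
    meta <- meta[!dup, , drop = FALSE]
    lfq <- lfq[!dup, , drop = FALSE]
  }
  rownames(meta) <- NULL
  rownames(lfq) <- meta$leading_accession
  new_protein_groups(meta, lfq)
}

new_protein_groups <- function(meta, lfq) {
  structure(list(meta = meta, lfq = lfq), class = "ProteinGroups")
}

#' @export
print.ProteinGroups <- function(x, ...) {
  cat("ProteinGroups: ", nrow(x$meta), " protein groups x ",
      ncol(x$lfq), " samples (",
      sum(is.na(x$lfq)), " missing LFQ cells)\n", sep = "")
  invisible(x)
}

#' Number of protein groups
#' @param x a `ProteinGroups` object.
#' @return integer row count.
#' @export
n_proteins <- function(x) nrow(x$meta)

#' Write a ProteinGroups object as a MaxQuant-style TSV
#'
#' Inverse of [read_protein_groups()] on the package's own dialect:
#' missing LFQ cells are written as `0`, accession and gene lists are
#' re-joined with semicolons.
#'
#' @param x a `ProteinGroups` object.
#' @param path output file path.
#' @param column_map see [default_column_map()].
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(x, path, column_map = default_column_map()) {
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = vapply(x$meta$accessions, paste, character(1), collapse = ";"),
    g = vapply(x$meta$gene_names, paste, character(1), collapse = ";"),
    p = x$meta$razor_unique_peptides,
    r = ifelse(x$meta$reverse, "+", ""),
    c = ifelse(x$meta$contaminant, "+", ""))
  names(df) <- c(column_map$ids, column_map$gene_names, column_map$peptides,
                 column_map$reverse, column_map$contaminant)
  lfq <- x$lfq
  lfq[is.na(lfq)] <- 0
  lfq_df <- as.data.frame(lfq, check.names = FALSE)
  names(lfq_df) <- paste0(column_map$lfq_prefix, colnames(x$lfq))
  out <- cbind(df, lfq_df)
  utils::write.table(format_floats(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Accessions are extracted from the header: the middle field of a
#' UniProt-style `db|ACC|NAME` header, otherwise the first
#' whitespace-delimited token. Sequences are uppercased.
#'
#' @param path FASTA file path.
#' @param duplicate_policy `"error"` or `"keep_first"` for repeated
#'   accessions.
#' @return data.frame with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path, duplicate_policy = c("error", "keep_first")) {
  duplicate_policy <- match.arg(duplicate_policy)
  # BStringSet tolerates lowercase input; residues are uppercased below
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) stop("FASTA file contains no records: ", path,
                              call. = FALSE)
  headers <- names(aas)
  if (any(Biostrings::width(aas) == 0L)) {
    bad <- headers[Biostrings::width(aas) == 0L][1L]
    stop("FASTA record with empty sequence: '", bad, "'", call. = FALSE)
  }
  accession <- vapply(headers, parse_fasta_accession, character(1),
                      USE.NAMES = FALSE)
  description <- sub("^\\S+\\s*", "", headers)
  sequence <- toupper(gsub("\\s", "", as.character(aas)))
  dup <- duplicated(accession)
  if (any(dup) && duplicate_policy == "error") {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(accession[dup]), collapse = ", "), call. = FALSE)
  }
  data.frame(accession = accession, description = description,
             sequence = sequence, stringsAsFactors = FALSE)[!dup, ,
                                                            drop = FALSE]
}

parse_fasta_accession <- function(header) {
  token <- sub("\\s.*$", "", header)
  parts <- strsplit(token, "|", fixed = TRUE)[[1L]]
  if (length(parts) >= 2L) parts[[2L]] else parts[[1L]]
}

#' Write sequence records to FASTA
#' @param records data.frame with `accession`, `description`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  header <- ifelse(nchar(records$description) > 0,
                   paste(records$accession, records$description),
                   records$accession)
  writeLines(paste0(">", header, "\n", records$sequence), path)
  invisible(path)
}

#' Read a known-phosphosite table
#'
#' Local stand-in for a phosphosite repository lookup: a TSV with header
#' `accession`, `position`, `residue`, `annotation`.
#'
#' @param path TSV path.
#' @return data.frame with those four columns; positions 1-based.
#' @export
read_known_sites <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(accession = "character",
                                         position = "integer",
                                         residue = "character",
                                         annotation = "character"))
  need <- c("accession", "position", "residue", "annotation")
  if (!all(need %in% names(df))) {
    stop("known-site table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(df$position < 1L)) stop("known-site positions must be >= 1",
                                  call. = FALSE)
  if (anyDuplicated(df[c("accession", "position")])) {
    stop("duplicate (accession, position) in known-site table", call. = FALSE)
  }
  df
}

#' Write a known-site table
#' @param sites data.frame as returned by [read_known_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_known_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# 6-significant-digit formatting for numeric columns, leaving other
# columns untouched; keeps output TSVs byte-stable across runs.
format_floats <- function(df, digits = 6L) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(signif(df[[j]], digits), digits = digits,
                         format = "g")
    }
  }
  df
}

#' Write pipeline result tables and a JSON run summary
#'
#' One TSV per named table plus `run_summary.json` holding per-stage row
#' counts, the parameters used, and the seed — the machine-readable audit
#' trail of the run. Floats are written with 6 significant digits.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param params named list of run parameters recorded in the summary.
#' @param seed integer seed recorded in the summary.
#' @return named character vector of paths written.
#' @export
write_results <- function(tables, out_dir, params = list(), seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(format_floats(tables[[nm]]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[nm] <- p
  }
  summary <- list(
    stages = lapply(tables, function(t) list(rows = nrow(t))),
    params = params,
    seed = seed
  )
  sp <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths["run_summary"] <- sp
  paths
}
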