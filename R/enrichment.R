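#' Filter protein groups by razor + unique peptide count
#'
#' Identification-confidence filter: protein groups with fewer than
#' `min_razor_unique` razor + unique peptides are excluded (default 2, i.e.
#' groups with fewer than two supporting peptides are dropped). Applied
#' before imputation so excluded rows cannot shift the imputation anchor.
#'
#' @param x a `ProteinGroups` object.
#' @param min_razor_unique minimum peptide count to retain a row.
#' @return filtered `ProteinGroups`, row order preserved.
#' @export
filter_proteins <- function(x, min_razor_unique = 2L) {
  stopifnot(inherits(x, "ProteinGroups"), min_razor_unique >= 0)
  keep <- x$meta$razor_unique_peptides >= min_razor_unique
  message("filter_proteins: ", sum(keep), "/", length(keep),
          " protein groups retained (min razor+unique = ",
          min_razor_unique, ")")
  new_protein_groups(x$meta[keep, , drop = FALSE],
                     x$lfq[keep, , drop = FALSE])
}

#' Build a paired sample design
#'
#' @param control,treatment sample labels in replicate order; replicate `r`
#'   of `treatment` is paired with replicate `r` of `control` (replicates
#'   are paired by donor animal).
#' @return data.frame with columns `sample`, `role`, `replicate`.
#' @export
paired_design <- function(control, treatment) {
  if (length(control) != length(treatment)) {
    stop("unpaired design: ", length(control), " control vs ",
         length(treatment), " treatment samples", call. = FALSE)
  }
  if (length(control) < 1L) stop("design needs at least one replicate pair",
                                 call. = FALSE)
  data.frame(sample = c(control, treatment),
             role = rep(c("control", "treatment"), each = length(control)),
             replicate = rep(seq_along(control), 2L),
             stringsAsFactors = FALSE)
}

#' Convert LFQ intensities to a log10 matrix
#'
#' Observed cells hold `log10(LFQ)`; missing cells stay `NA` with
#' `observed = FALSE`. No imputation happens here.
#'
#' @param x a `ProteinGroups` object.
#' @param design a [paired_design()] data.frame covering every LFQ column
#'   of `x` (columns are reordered to the design order).
#' @return a `LogIntensityMatrix`: list with `values` (log10 matrix),
#'   `observed` (logical matrix), `design`, and `imputed` flag.
#' @export
to_log_matrix <- function(x, design) {
  stopifnot(inherits(x, "ProteinGroups"))
  missing_samples <- setdiff(design$sample, colnames(x$lfq))
  if (length(missing_samples) > 0L) {
    stop("design names sample(s) absent from the table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  lfq <- x$lfq[, design$sample, drop = FALSE]
  values <- log10(lfq)
  observed <- !is.na(lfq)
  structure(list(values = values, observed = observed, design = design,
                 imputed = FALSE),
            class = "LogIntensityMatrix")
}

#' @export
print.LogIntensityMatrix <- function(x, ...) {
  cat("LogIntensityMatrix: ", nrow(x$values), " proteins x ",
      ncol(x$values), " samples; ", sum(!x$observed), " cells ",
      if (x$imputed) "imputed" else "missing (not yet imputed)", "\n",
      sep = "")
  invisible(x)
}

#' Impute missing log10 intensities from a low-quantile normal
#'
#' Left-censored (MNAR) imputation: every missing cell receives an
#' independent draw from Normal(q, sd) in log10 space, where q is the
#' `quantile`-quantile of all observed log10 intensities pooled across the
#' whole matrix (both conditions, all replicates — "combined"). Defaults:
#' the 5% quantile and sd 0.1.
#'
#' @param m a `LogIntensityMatrix`.
#' @param quantile probability in (0, 1) anchoring the imputation mean.
#' @param sd standard deviation of the imputation distribution (log10).
#' @param seed integer seed; identical seed gives identical imputations.
#' @param quantile_type quantile algorithm passed to [stats::quantile()].
#' @return the matrix with every `NA` filled in; `observed` unchanged.
#' @export
impute_missing <- function(m, quantile = 0.05, sd = 0.1, seed,
                           quantile_type = 7L) {
  stopifnot(inherits(m, "LogIntensityMatrix"),
            quantile > 0, quantile < 1, sd > 0)
  obs <- m$values[m$observed]
  if (length(obs) == 0L) {
    stop("cannot impute: matrix has no observed values", call. = FALSE)
  }
  n_missing <- sum(!m$observed)
  if (n_missing > 0L) {
    q <- stats::quantile(obs, probs = quantile, type = quantile_type,
                         names = FALSE)
    draws <- with_local_seed(seed, stats::rnorm(n_missing, mean = q, sd = sd))
    m$values[!m$observed] <- draws
  }
  m$imputed <- TRUE
  m
}

# Run `expr` under set.seed(seed) without disturbing the caller's RNG
# stream; a fixed kind makes draws reproducible across R sessions.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive a reproducible sub-seed for a named pipeline stage so adding
# stages never changes another stage's draws. Kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.double(seed) * 1009 + h) %% 2147483629
}

#' Paired log2 ratios and mean intensities
#'
#' Default mode `"paired-mean"`: per replicate pair r, the log2 ratio is
#' `(log10 T_r - log10 C_r) / log10(2)`, then averaged over replicates.
#' Mode `"ratio-of-means"` instead differences the per-condition means.
#' `mean_log10_intensity` is the mean of all the protein's log10 values
#' (the scatter-plot x coordinate).
#'
#' @param m an imputed `LogIntensityMatrix`.
#' @param mode `"paired-mean"` or `"ratio-of-means"`.
#' @return data.frame with `accession`, `mean_log10_intensity`, `log2_ratio`.
#' @export
compute_log2_ratios <- function(m, mode = c("paired-mean", "ratio-of-means")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "LogIntensityMatrix"))
  if (!m$imputed && any(!m$observed)) {
    stop("matrix has missing cells; run impute_missing() first",
         call. = FALSE)
  }
  d <- m$design
  ctrl <- d$sample[d$role == "control"][order(d$replicate[d$role == "control"])]
  trt <- d$sample[d$role == "treatment"][order(d$replicate[d$role == "treatment"])]
  C <- m$values[, ctrl, drop = FALSE]
  T_ <- m$values[, trt, drop = FALSE]
  log2_ratio <- switch(mode,
    "paired-mean" = rowMeans((T_ - C) / log10(2)),
    "ratio-of-means" = (rowMeans(T_) - rowMeans(C)) / log10(2))
  data.frame(accession = rownames(m$values),
             mean_log10_intensity = rowMeans(m$values),
             log2_ratio = log2_ratio,
             stringsAsFactors = FALSE)
}

#' Fence parameters for IQR-based enrichment classification
#'
#' @param k_potential fence multiplier for class 1 ("potentially enriched").
#' @param k_extreme fence multiplier for class 2 ("significantly enriched");
#'   must exceed `k_potential`.
#' @param quantile_type quartile algorithm for [stats::quantile()]
#'   (7 = linear interpolation between order statistics).
#' @return list of validated fence parameters.
#' @export
fence_params <- function(k_potential = 1.5, k_extreme = 3.0,
                         quantile_type = 7L) {
  stopifnot(k_potential > 0, k_extreme > k_potential)
  list(k_potential = k_potential, k_extreme = k_extreme,
       quantile_type = quantile_type)
}

#' Two-tier IQR-fence enrichment classification
#'
#' Tukey-style outlier classification of log2 ratios: with Q1, Q3 and
#' IQR = Q3 - Q1 computed over all ratios in the screen, a protein is
#' class 2 ("significantly enriched") if its ratio lies strictly outside
#' the `k_extreme` x IQR fences, class 1 ("potentially enriched") if
#' strictly outside the `k_potential` x IQR fences, else class 0.
#' `direction` is +1 above the upper fence, -1 below the lower fence,
#' 0 for class 0. A pure function of the ratio vector.
#'
#' @param ratios data.frame from [compute_log2_ratios()] (or any data.frame
#'   with `accession` and `log2_ratio`).
#' @param fences see [fence_params()].
#' @return the input with `significance` (0/1/2) and `direction` (-1/0/+1)
#'   columns appended.
#' @export
classify_enrichment <- function(ratios, fences = fence_params()) {
  x <- ratios$log2_ratio
  if (length(x) < 4L) {
    stop("need at least 4 ratios for quartile-based fences, got ",
         length(x), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite log2 ratio encountered",
                               call. = FALSE)
  qs <- stats::quantile(x, probs = c(0.25, 0.75),
                        type = fences$quantile_type, names = FALSE)
  q1 <- qs[1L]; q3 <- qs[2L]
  iqr <- q3 - q1
  sig <- integer(length(x))
  dir <- integer(length(x))
  for (k in c(list(c(fences$k_potential, 1L)),
              list(c(fences$k_extreme, 2L)))) {
    upper <- x > q3 + k[[1L]] * iqr
    lower <- x < q1 - k[[1L]] * iqr
    sig[upper | lower] <- as.integer(k[[2L]])
    dir[upper] <- 1L
    dir[lower] <- -1L
  }
  ratios$significance <- sig
  ratios$direction <- dir
  ratios
}
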