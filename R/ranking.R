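# Ranking of Phase I predictions by CYP activity x abundance.
#
# Multi-study activity (pmol substrate/min/mg protein) and abundance
# (pmol CYP/mg protein) matrices (rows = the 9 liver CYPs, columns =
# studies) are normalized by iterated {impute missing -> column min-max
# scale -> quantile normalize -> re-impute from row means} until the
# imputed entries converge (relative tolerance 0.1%).  Per-CYP averages
# are then sum-normalized so each kind totals 1, and a predicted product
# scores the sum over its annotated enzymes (those with data) of
# average activity times average abundance; ranks are ordinal on the
# descending scores with stable tie order.

#' Min-max scale the columns of a matrix
#'
#' Each column is scaled to `[0, 1]` by subtracting the column minimum and
#' dividing by the column range.  Constant columns map to 0.
#'
#' @param m numeric matrix (no missing values).
#' @return scaled matrix.
#' @export
minmax_scale <- function(m) {
  apply(m, 2, function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) return(rep(0, length(x)))
    (x - min(x)) / rng
  })
}

#' Quantile-normalize the columns of a matrix
#'
#' Classic quantile normalization: the value distributions of all columns
#' are forced to the mean of the sorted columns.  Tied values receive the
#' mean of the reference distribution over their tied ranks.
#'
#' @param m numeric matrix (no missing values).
#' @return normalized matrix.
#' @export
quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    pos <- integer(length(x)); pos[o] <- seq_along(x)   # rank positions
    val <- numeric(length(x))
    for (grp in split(seq_along(x), x)) {
      val[grp] <- mean(ref[pos[grp]])
    }
    out[, j] <- val
  }
  out
}

#' Normalize a CYP activity or abundance matrix
#'
#' Implements the iterative imputation/normalization routine: missing
#' values start at their row mean; each iteration fills the missing cells
#' with the current estimates, min-max scales every column, quantile
#' normalizes across columns, and re-estimates the missing cells from the
#' row means of the normalized matrix, until the largest relative change
#' of any imputed entry falls below `tol`.
#'
#' @param m numeric matrix with `NA` for missing values; rows are enzymes
#'   (rownames required), columns are studies.
#' @param tol relative convergence tolerance for imputed entries
#'   (default 0.001, i.e. 0.1%).
#' @param max_iter iteration cap (default 1000); exceeding it is an error
#'   reporting the residual.
#' @return list with `matrix` (normalized, imputed cells filled),
#'   `imputed` (data frame of imputed cells and final values),
#'   `iterations`, and `dropped` (rows without any observation).
#' @export
normalize_enzyme_matrix <- function(m, tol = 0.001, max_iter = 1000L) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  all_na <- rowSums(!is.na(m)) == 0L
  dropped <- rownames(m)[all_na]
  if (any(all_na)) {
    warning("dropping enzyme row(s) without observations: ",
            paste(dropped, collapse = ", "))
    m <- m[!all_na, , drop = FALSE]
  }
  miss <- which(is.na(m), arr.ind = TRUE)
  work <- m
  if (nrow(miss)) work[miss] <- rowMeans(m, na.rm = TRUE)[miss[, 1]]
  iter <- 0L
  fill <- NULL
  repeat {
    iter <- iter + 1L
    norm <- quantile_normalize(minmax_scale(work))
    rownames(norm) <- rownames(m)
    if (!nrow(miss)) return(list(matrix = norm, imputed = data.frame(),
                                 iterations = iter, dropped = dropped))
    new_est <- rowMeans(norm)[miss[, 1]]
    # running-average update: preserves any fixed point and forces the
    # rank-flip oscillation that quantile normalization can induce near
    # ties to settle (successive changes shrink as 1/iteration)
    prev <- fill
    fill <- if (is.null(prev)) new_est
            else ((iter - 1) * prev + new_est) / iter
    work <- norm
    work[miss] <- fill
    if (!is.null(prev)) {
      rel <- abs(fill - prev) / pmax(abs(prev), .Machine$double.eps)
      if (max(rel) < tol) {
        out <- norm; out[miss] <- fill
        return(list(matrix = out,
                    imputed = data.frame(enzyme = rownames(m)[miss[, 1]],
                                         study = colnames(m)[miss[, 2]],
                                         value = fill),
                    iterations = iter, dropped = dropped))
      }
      if (iter >= max_iter)
        stop(sprintf("imputation did not converge in %d iterations (residual %.3g)",
                     max_iter, max(rel)))
    }
  }
}

#' Summarize normalized activity and abundance matrices
#'
#' Per-enzyme row averages of the two normalized matrices, sum-normalized
#' so the averages of each kind total 1; row minima and maxima (scaled
#' identically) are carried as descriptive metadata.
#'
#' @param norm_activity,norm_abundance normalized matrices over the same
#'   enzyme rows (e.g. from [normalize_enzyme_matrix()]).
#' @return an `enzyme_stats` data frame with columns `enzyme`,
#'   `abundance_avg/min/max`, `activity_avg/min/max`.
#' @export
summarize_enzyme_stats <- function(norm_activity, norm_abundance) {
  stopifnot(identical(rownames(norm_activity), rownames(norm_abundance)))
  one <- function(m) {
    avg <- rowMeans(m)
    if (sum(avg) == 0) stop("zero total across enzymes; cannot sum-normalize")
    list(avg = avg / sum(avg),
         min = apply(m, 1, min) / sum(avg),
         max = apply(m, 1, max) / sum(avg))
  }
  act <- one(norm_activity); abd <- one(norm_abundance)
  structure(data.frame(enzyme = rownames(norm_activity),
                       abundance_avg = abd$avg, abundance_min = abd$min,
                       abundance_max = abd$max,
                       activity_avg = act$avg, activity_min = act$min,
                       activity_max = act$max,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("enzyme_stats", "data.frame"))
}

#' Load packaged CYP activity/abundance averages
#'
#' The normalized per-CYP averages (and descriptive min/max) for the nine
#' liver CYPs 1A2, 2A6, 2B6, 2C8, 2C9, 2C19, 2D6, 2E1, 3A4; the averages
#' of each kind sum to 1 (within rounding of the published values).
#'
#' @param path TSV file; defaults to the packaged table.
#' @return an `enzyme_stats` data frame.
#' @export
load_enzyme_stats <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cyp_stats.tsv", package = "proximal")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(enzyme = "character"))
  structure(df, class = c("enzyme_stats", "data.frame"))
}

#' Load the packaged case-study enzyme annotations
#'
#' CYP sets responsible for each Phase I metabolite of the bisphenol A and
#' 4-chlorobiphenyl case studies.
#'
#' @param case optional `"BPA"` or `"PCB3"` filter.
#' @return data frame with `case`, `metabolite`, `enzymes`.
#' @export
load_case_enzyme_sets <- function(case = NULL) {
  df <- utils::read.delim(system.file("extdata", "case_enzyme_sets.tsv",
                                      package = "proximal"),
                          stringsAsFactors = FALSE)
  if (!is.null(case)) df <- df[df$case == case, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Score an enzyme set
#'
#' Sum over the enzymes that have activity/abundance data of
#' (average activity) x (average abundance).  Enzymes absent from the
#' statistics table (e.g. 1A1, 1B1, 2C18, 3A5) contribute nothing and are
#' reported in `missing`.
#'
#' @param enzymes character vector of CYP names (normalized with
#'   [normalize_enzyme()]), or a single comma-separated string.
#' @param stats an `enzyme_stats` table.
#' @return list with `score` (full precision), `score_reported` (rounded
#'   half-even to 4 decimals), `used`, `missing`.
#' @export
score_enzymes <- function(enzymes, stats = load_enzyme_stats()) {
  if (length(enzymes) == 1L && grepl(",", enzymes))
    enzymes <- strsplit(enzymes, ",")[[1]]
  enzymes <- normalize_enzyme(enzymes)
  hit <- match(enzymes, stats$enzyme)
  used <- enzymes[!is.na(hit)]
  score <- sum(stats$activity_avg[hit[!is.na(hit)]] *
                 stats$abundance_avg[hit[!is.na(hit)]])
  list(score = score, score_reported = round(score, 4),
       used = used, missing = enzymes[is.na(hit)])
}

#' Score and rank predicted Phase I products
#'
#' Products are sorted by descending score with stable tie order (input
#' order preserved within ties) and assigned ordinal ranks `1..n`; tied
#' scores receive distinct consecutive ranks.
#'
#' @param predictions data frame with columns `id` and `enzymes`
#'   (comma-separated enzyme names).
#' @param stats an `enzyme_stats` table.
#' @return data frame with `id`, `enzymes`, `score` (rounded to 4 decimals
#'   for reporting; full precision in `score_full`), `rank`,
#'   `no_data_enzymes`.
#' @export
rank_predictions <- function(predictions, stats = load_enzyme_stats()) {
  stopifnot(all(c("id", "enzymes") %in% names(predictions)))
  sc <- lapply(predictions$enzymes, score_enzymes, stats = stats)
  full <- vapply(sc, `[[`, numeric(1), "score")
  o <- order(-full)   # stable in R
  out <- data.frame(
    id = predictions$id[o],
    enzymes = predictions$enzymes[o],
    score = vapply(sc, `[[`, numeric(1), "score_reported")[o],
    score_full = full[o],
    rank = seq_along(o),
    no_data_enzymes = vapply(sc, function(s)
      paste(s$missing, collapse = ","), character(1))[o],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
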