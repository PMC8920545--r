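#' Single-sample gene set enrichment scores
#'
#' Rank-based per-sample pathway activity scores. For each sample, genes
#' are ranked by expression (ties get average ranks; the most expressed
#' gene carries the largest rank). Walking the gene list in decreasing
#' expression order, the enrichment score of a set is the integrated
#' difference between the weighted in-set empirical CDF (weights
#' `rank^alpha`, normalized to sum to 1 within the set) and the
#' unweighted out-of-set ECDF -- the running-sum total, not its
#' supremum. Ties in the walk order are broken by gene symbol so the
#' score is deterministic. If `normalize`, the whole score matrix is
#' divided by its `max - min` so scores are comparable across samples.
#'
#' Sets with fewer than `min_overlap` members present in the matrix are
#' dropped with a warning, as is the degenerate set containing every gene
#' of the matrix (its out-of-set ECDF is undefined).
#'
#' @param expr Gene x sample log2 matrix (no missing values).
#' @param gene_sets A `gene_set_collection` (or plain named list of
#'   character vectors).
#' @param alpha Rank weighting exponent.
#' @param min_overlap Minimum set members present in the matrix.
#' @param normalize Divide the score matrix by its overall range.
#' @return Sets x samples numeric matrix with attribute `normalized`.
#' @export
ssgsea_scores <- function(expr, gene_sets, alpha = 0.25, min_overlap = 3L,
                          normalize = TRUE) {
  validate_expression(expr)
  sets <- if (inherits(gene_sets, "gene_set_collection")) {
    gene_sets$sets
  } else {
    gene_sets
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  genes <- rownames(expr)
  n <- length(genes)
  kept <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    if (length(members) < min_overlap) {
      warning("set '", nm, "' dropped: fewer than ", min_overlap,
              " members present")
      next
    }
    if (length(members) == n) {
      warning("set '", nm, "' dropped: contains every gene in the matrix")
      next
    }
    kept[[nm]] <- members
  }
  if (length(kept) == 0L) stop("no gene set survives the overlap filter")

  inset <- lapply(kept, function(members) genes %in% members)
  scores <- matrix(0, length(kept), ncol(expr),
                   dimnames = list(names(kept), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    v <- expr[, j]
    r <- rank(v, ties.method = "average")
    # decreasing expression, gene-symbol tie-break
    ord <- order(-v, genes)
    w <- r^alpha
    for (k in seq_along(kept)) {
      hit <- inset[[k]][ord]
      wk <- w[ord] * hit
      step_in <- cumsum(wk) / sum(wk)
      step_out <- cumsum(!hit) / (n - length(kept[[k]]))
      scores[k, j] <- sum(step_in - step_out)
    }
  }
  normalized <- FALSE
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) {
      scores <- scores / rng
      normalized <- TRUE
    } else {
      warning("score range is zero; normalization skipped")
    }
  }
  attr(scores, "normalized") <- normalized
  scores
}

#' Median pathway score per osteogenic stage
#'
#' Summarizes a set x sample score matrix to set x stage medians; control
#' samples form stage 0. Stages with no samples are omitted.
#'
#' @param scores Sets x samples matrix from [ssgsea_scores()].
#' @param meta Sample metadata aligned with the score columns (needs
#'   `day`).
#' @return Sets x stages matrix, stage columns in increasing day order.
#' @export
stage_median_scores <- function(scores, meta) {
  stopifnot(is.matrix(scores))
  if (!identical(colnames(scores), meta$sample_id)) {
    stop("score columns and metadata rows are not aligned")
  }
  stages <- sort(unique(meta$day))
  out <- matrix(NA_real_, nrow(scores), length(stages),
                dimnames = list(rownames(scores), paste0("day", stages)))
  for (i in seq_along(stages)) {
    idx <- which(meta$day == stages[i])
    out[, i] <- apply(scores[, idx, drop = FALSE], 1L, stats::median)
  }
  out
}
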