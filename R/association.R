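#' Gene-pathway association table
#'
#' Pearson correlation between each gene's expression and each pathway's
#' per-sample enrichment score, with a two-sided p-value from the exact t
#' transform `r sqrt((n-2) / (1 - r^2))` on `n - 2` df and BH adjustment
#' across the entire gene x pathway table. A constant gene or pathway
#' vector has undefined correlation; such pairs are reported as `r = 0`,
#' `p = 1` with a warning.
#'
#' @param expr Gene x sample log2 matrix.
#' @param genes Genes to test (e.g. the DEGs).
#' @param scores Pathway x sample score matrix aligned with `expr`
#'   samples.
#' @param alpha Significance level on the adjusted (or raw) p-value.
#' @param use_adjusted Use BH-adjusted p for the `significant` flag
#'   (default); `FALSE` flags on the raw p.
#' @return data.frame with columns `gene`, `pathway`, `r`, `p_value`,
#'   `adj_p_value`, `significant`.
#' @export
gene_pathway_association <- function(expr, genes, scores, alpha = 0.05,
                                     use_adjusted = TRUE) {
  validate_expression(expr)
  stopifnot(is.matrix(scores))
  if (!identical(colnames(expr), colnames(scores))) {
    stop("expression and score matrices must share aligned samples")
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L) {
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  n <- ncol(expr)
  if (n < 3L) stop("need at least 3 samples")
  grid <- expand.grid(gene = genes, pathway = rownames(scores),
                      stringsAsFactors = FALSE)
  r <- numeric(nrow(grid))
  warned <- FALSE
  for (i in seq_len(nrow(grid))) {
    x <- expr[grid$gene[i], ]
    y <- scores[grid$pathway[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r[i] <- NA_real_
      warned <- TRUE
    } else {
      r[i] <- stats::cor(x, y)
    }
  }
  if (warned) {
    warning("constant gene or pathway vector(s): correlation reported ",
            "as r = 0, p = 1")
  }
  p <- correlation_p(r, n)
  r[is.na(r)] <- 0
  out <- data.frame(grid, r = r, p_value = p,
                    adj_p_value = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out$significant <- if (use_adjusted) out$adj_p_value < alpha else
    out$p_value < alpha
  out
}

correlation_p <- function(r, n) {
  p <- rep(1, length(r))
  ok <- !is.na(r)
  rr <- pmin(pmax(r[ok], -1), 1)
  t <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  t[abs(rr) == 1] <- sign(rr[abs(rr) == 1]) * Inf
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

#' Pairwise gene-gene Pearson correlation matrix
#'
#' @param expr Gene x sample log2 matrix.
#' @param genes Genes to include (all must be present).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
gene_gene_correlation <- function(expr, genes) {
  validate_expression(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L) {
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  cm <- stats::cor(t(expr[genes, , drop = FALSE]))
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  cm
}
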