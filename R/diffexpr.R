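#' Moderated two-group differential expression
#'
#' Per gene: a two-group linear-model fit on the log2 matrix (difference
#' of group means, pooled residual variance `s_g^2` with `d_g = n1 + n2 -
#' 2` residual df), followed by empirical-Bayes variance moderation. A
#' scaled inverse-chi-square prior `(d0, s0^2)` is fitted to the observed
#' `s_g^2` by moment matching on the log variances; the posterior
#' variance is `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, the moderated t is
#' `logFC / (s_tilde sqrt(1/n1 + 1/n2))`, and two-sided p-values use a t
#' distribution with `d0 + d_g` df. If the moment system is infeasible
#' (underdispersed log variances), `d0 = Inf` (full shrinkage to `s0^2`)
#' is used with a warning.
#'
#' The log fold change is the mean of the second factor level minus the
#' mean of the first (so with levels control/induced: induced minus
#' control; with low/high: high minus low).
#'
#' @param expr Gene x sample log2 matrix.
#' @param labels Two-level factor over the columns of `expr`; both groups
#'   need at least 2 samples.
#' @param shrink Set `FALSE` to disable moderation (`d0 = 0`); the
#'   statistic is then the ordinary pooled-variance two-sample t.
#' @return A `de_result` data.frame with columns `gene`, `logFC`,
#'   `mean_expr`, `t`, `p_value`, `adj_p_value`, `label` (all `ns` until
#'   [classify_degs()] is applied), plus attributes `d0` and `s0_2`.
#' @export
moderated_de <- function(expr, labels, shrink = TRUE) {
  validate_expression(expr)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (length(labels) != ncol(expr)) {
    stop("labels length must match the number of samples")
  }
  i1 <- which(labels == levels(labels)[1L])
  i2 <- which(labels == levels(labels)[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 samples")
  d_g <- n1 + n2 - 2L

  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  logfc <- m2 - m1
  ss <- rowSums((expr[, i1, drop = FALSE] - m1)^2) +
    rowSums((expr[, i2, drop = FALSE] - m2)^2)
  s2 <- ss / d_g
  if (all(s2 <= 0)) stop("zero residual variance for all genes")

  if (shrink) {
    hyper <- fit_variance_prior(s2, d_g)
    d0 <- hyper$d0
    s0_2 <- hyper$s0_2
    if (is.finite(d0)) {
      s2_post <- (d0 * s0_2 + d_g * s2) / (d0 + d_g)
      df_total <- d0 + d_g
    } else {
      s2_post <- rep(s0_2, length(s2))
      df_total <- Inf
    }
  } else {
    d0 <- 0
    s0_2 <- NA_real_
    s2_post <- s2
    df_total <- d_g
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, logfc / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene = rownames(expr),
                    logFC = unname(logfc),
                    mean_expr = unname((n1 * m1 + n2 * m2) / (n1 + n2)),
                    t = unname(tstat),
                    p_value = unname(p),
                    adj_p_value = unname(bh_adjust(p)),
                    label = "ns",
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  class(out) <- c("de_result", "data.frame")
  out
}

# moment matching of a scaled inverse-chi-square prior on log variances:
# if s^2 ~ s0^2 F(d_g, d0), then e = log s^2 - digamma(d_g/2) + log(d_g/2)
# has mean log s0^2 - digamma(d0/2) + log(d0/2) and excess variance
# trigamma(d0/2) beyond trigamma(d_g/2).
fit_variance_prior <- function(s2, d_g) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e) - trigamma(d_g / 2)
  if (is.na(e_var) || e_var <= 0) {
    warning("log-variance underdispersion: using full shrinkage (d0 = Inf)")
    return(list(d0 = Inf, s0_2 = exp(e_mean)))
  }
  d0 <- 2 * trigamma_inverse(e_var)
  list(d0 = d0, s0_2 = exp(e_mean + digamma(d0 / 2) - log(d0 / 2)))
}

# Newton solve of trigamma(x) = y
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Classify differentially expressed genes with asymmetric gates
#'
#' A gene is `up` if the BH-adjusted p-value is below `alpha` and the
#' log2 fold change exceeds `up_lfc`; `down` if the adjusted p-value is
#' below `alpha` and the log2 fold change is below `down_lfc`; otherwise
#' `ns`. The default gates are deliberately asymmetric (+1 / -0.8): a
#' symmetric -1 gate yields very few downregulated genes in osteogenic
#' induction data.
#'
#' @param de A `de_result` from [moderated_de()].
#' @param alpha Adjusted-p threshold.
#' @param up_lfc,down_lfc log2 fold-change gates.
#' @return The `de_result` with the `label` column filled in.
#' @export
classify_degs <- function(de, alpha = 0.05, up_lfc = 1.0, down_lfc = -0.8) {
  stopifnot(is.data.frame(de), all(c("logFC", "adj_p_value") %in% names(de)))
  label <- rep("ns", nrow(de))
  label[de$adj_p_value < alpha & de$logFC > up_lfc] <- "up"
  label[de$adj_p_value < alpha & de$logFC < down_lfc] <- "down"
  de$label <- label
  de
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment with cumulative-minimum
#' enforcement, capped at 1; the output order matches the input order.
#'
#' @param p Vector of raw p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

#' Split samples by the median expression of one gene
#'
#' Samples strictly above the gene's median expression form the `high`
#' group; samples at or below the median form the `low` group (ties go to
#' `low` -- a deterministic, documented rule; on continuous data the
#' strict-inequality rule restores balanced splits).
#'
#' @param expr Gene x sample log2 matrix.
#' @param gene Gene symbol present in `expr`.
#' @return Factor with levels `low`, `high`, named by sample.
#' @export
split_by_median <- function(expr, gene) {
  validate_expression(expr)
  if (!gene %in% rownames(expr)) stop("gene not in matrix: ", gene)
  v <- expr[gene, ]
  med <- stats::median(v)
  grp <- factor(ifelse(v > med, "high", "low"), levels = c("low", "high"))
  if (any(table(grp) == 0L)) {
    stop("degenerate median split for gene ", gene,
         ": all samples on one side")
  }
  names(grp) <- colnames(expr)
  grp
}

#' Rank genes by fold change
#'
#' Descending log2 fold change; ties are broken by ascending raw p-value,
#' then lexicographic gene symbol, so the ordering is strict and
#' deterministic.
#'
#' @param de A `de_result`.
#' @return A data.frame with columns `gene` and `stat` (the logFC),
#'   ordered; covers every tested gene exactly once.
#' @export
rank_by_fold_change <- function(de) {
  stopifnot(is.data.frame(de), all(c("gene", "logFC", "p_value") %in%
                                     names(de)))
  o <- order(-de$logFC, de$p_value, de$gene)
  out <- data.frame(gene = de$gene[o], stat = de$logFC[o],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
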