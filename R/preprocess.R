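#' Collapse a probe-level matrix to gene level
#'
#' Probes without a gene mapping are removed; when several probes map to
#' the same gene, the gene's expression is the arithmetic mean of the
#' probe values per sample. Gene order in the output is lexicographic.
#'
#' @param values Numeric matrix, probes x samples, probe ids as rownames.
#' @param probe_map data.frame with columns `probe_id` and `gene_id`
#'   (`gene_id` may be `NA`/empty for unmapped probes; probes absent from
#'   the map are unmapped).
#' @return Gene x sample numeric matrix.
#' @export
collapse_probes <- function(values, probe_map) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("probe matrix must have unique probe rownames")
  }
  stopifnot(all(c("probe_id", "gene_id") %in% colnames(probe_map)))
  map <- probe_map[!is.na(probe_map$gene_id) & nzchar(probe_map$gene_id), ]
  gene <- map$gene_id[match(rownames(values), map$probe_id)]
  keep <- !is.na(gene)
  if (!any(keep)) stop("no probe maps to any gene")
  values <- values[keep, , drop = FALSE]
  gene <- gene[keep]
  agg <- rowsum(values, group = gene, reorder = TRUE)
  counts <- as.vector(table(gene)[rownames(agg)])
  agg / counts
}

#' Parametric empirical-Bayes batch adjustment
#'
#' Location/scale batch-effect adjustment in the classic parametric
#' empirical-Bayes formulation: per gene, the data are standardized under
#' a linear model with batch indicators and (optionally) the biological
#' group as a protected covariate; per-batch gene-wise location
#' (`gamma`) and scale (`delta^2`) effects are estimated, shrunk toward
#' batch-level parametric priors (normal for location, inverse-gamma for
#' scale) by iterative empirical-Bayes estimation, and removed; the data
#' are then back-transformed. Including `group` as covariate protects the
#' control-vs-induced signal from being absorbed into the batch means.
#'
#' @param expr Gene x sample log2 matrix.
#' @param meta Sample metadata aligned with `expr` columns (needs `batch`
#'   and, if used, `group`).
#' @param covariate `"group"` (default) to protect the biological group
#'   during standardization, or `"none"`.
#' @param conv Convergence tolerance of the EB iteration.
#' @param maxit Maximum EB iterations per batch.
#' @return Adjusted matrix with identical dimensions and dimnames.
#' @export
combat_adjust <- function(expr, meta, covariate = c("group", "none"),
                          conv = 1e-4, maxit = 100L) {
  covariate <- match.arg(covariate)
  validate_expression(expr, meta)
  batch <- factor(meta$batch, levels = unique(meta$batch))
  n_batches <- nlevels(batch)
  if (n_batches < 2L) stop("batch adjustment needs at least 2 batches")
  n_per <- table(batch)
  if (any(n_per < 2L)) {
    stop("batch(es) with a single sample: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "))
  }
  v <- apply(expr, 1L, stats::var)
  if (any(v <= 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v <= 0], 5L), collapse = ", "))
  }
  n <- ncol(expr)

  batch_design <- stats::model.matrix(~ -1 + batch)
  design <- batch_design
  if (covariate == "group") {
    grp <- factor(meta$group)
    if (nlevels(grp) > 1L) {
      design <- cbind(batch_design,
                      stats::model.matrix(~ grp)[, -1L, drop = FALSE])
    }
  }
  n_cov <- ncol(design) - n_batches

  ## gene-wise OLS fit, batch-size-weighted grand mean, pooled variance
  B_hat <- solve(crossprod(design), t(design) %*% t(expr))
  grand_mean <- crossprod(matrix(as.numeric(n_per) / n, ncol = 1L),
                          B_hat[seq_len(n_batches), , drop = FALSE])
  # ML pooled residual variance (denominator n)
  var_pooled <- rowMeans((expr - t(design %*% B_hat))^2)
  stand_mean <- matrix(rep(t(grand_mean), n), nrow(expr), n)
  if (n_cov > 0L) {
    stand_mean <- stand_mean +
      t(design[, n_batches + seq_len(n_cov), drop = FALSE] %*%
          B_hat[n_batches + seq_len(n_cov), , drop = FALSE])
  }
  z <- (expr - stand_mean) / sqrt(var_pooled)

  ## per-batch EB shrinkage of location/scale, fixed batch order
  adjusted <- z
  for (b in levels(batch)) {
    idx <- which(batch == b)
    zb <- z[, idx, drop = FALSE]
    n_b <- length(idx)
    gamma_hat <- rowMeans(zb)
    delta_hat <- apply(zb, 1L, stats::var)
    gamma_bar <- mean(gamma_hat)
    tau2 <- stats::var(gamma_hat)
    m <- mean(delta_hat)
    s2 <- stats::var(delta_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (it in seq_len(maxit)) {
      gamma_new <- (n_b * tau2 * gamma_hat + delta_star * gamma_bar) /
        (n_b * tau2 + delta_star)
      ss <- rowSums((zb - gamma_new)^2)
      delta_new <- (0.5 * ss + b_prior) / (n_b / 2 + a_prior - 1)
      change <- max(abs(gamma_new - gamma_star) /
                      pmax(abs(gamma_star), 1e-12),
                    abs(delta_new - delta_star) / delta_star)
      gamma_star <- gamma_new
      delta_star <- delta_new
      if (change < conv) break
    }
    adjusted[, idx] <- (zb - gamma_star) / sqrt(delta_star)
  }
  out <- adjusted * sqrt(var_pooled) + stand_mean
  dimnames(out) <- dimnames(expr)
  out
}
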