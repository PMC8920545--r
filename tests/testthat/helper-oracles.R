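# Independent brute-force oracles and tiny fixture builders shared across
# the suite. The oracles deliberately use naive enumeration, separate from
# the package's vectorized implementations.

toy_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# Benjamini-Hochberg by the definition: adj for the i-th smallest p is
# min over j >= i of n p_(j) / j, capped at 1.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# upper-tail hypergeometric by full enumeration
ora_brute <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# ssGSEA integrated running sum, term by term
ssgsea_brute <- function(v, members, alpha = 0.25) {
  genes <- names(v)
  r <- rank(v, ties.method = "average")
  ord <- order(-v, genes)
  K <- length(members)
  n_out <- length(v) - K
  sum_w <- sum(r[members]^alpha)
  p_in <- 0
  p_out <- 0
  es <- 0
  for (i in seq_along(ord)) {
    g <- genes[ord[i]]
    if (g %in% members) {
      p_in <- p_in + r[[g]]^alpha / sum_w
    } else {
      p_out <- p_out + 1 / n_out
    }
    es <- es + (p_in - p_out)
  }
  es
}

# pre-ranked GSEA signed maximum deviation, term by term
gsea_es_brute <- function(genes, stats, members, weight_p = 1) {
  n <- length(genes)
  hit <- genes %in% members
  w <- abs(stats)^weight_p
  denom <- sum(w[hit])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + w[i] / denom
    } else {
      run <- run - 1 / (n - sum(hit))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

quiet_pipeline <- function(sim, ...) {
  suppressWarnings(suppressMessages(
    run_osteo_pipeline(sim$expr, sim$meta, sim$gene_sets, sim$ppi_edges,
                       ...)))
}
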