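#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and each annotated term, against a finite gene universe. Terms are
#' intersected with the universe before testing; every term with at least
#' one member in the universe is reported. BH adjustment is applied
#' across the tested terms.
#'
#' @param query Character vector of query genes (must be a subset of the
#'   universe).
#' @param universe Character vector: the gene universe.
#' @param annotation data.frame with columns `term` and `gene`.
#' @param alpha Significance level on the adjusted p-value.
#' @return data.frame with columns `term`, `overlap` (k), `term_size`
#'   (K), `query_size` (n), `universe_size` (N), `p_value`,
#'   `adj_p_value`, `significant`, `overlap_genes` (comma-separated),
#'   ordered by increasing p.
#' @export
hypergeometric_ora <- function(query, universe, annotation, alpha = 0.05) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  extra <- setdiff(query, universe)
  if (length(extra) > 0L) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  stopifnot(all(c("term", "gene") %in% colnames(annotation)))
  terms <- split(annotation$gene, annotation$term)
  terms <- lapply(terms, function(g) intersect(unique(g), universe))
  terms <- terms[lengths(terms) > 0L]
  if (length(terms) == 0L) stop("no term overlaps the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(nm) {
    members <- terms[[nm]]
    K <- length(members)
    ov <- intersect(query, members)
    k <- length(ov)
    # P(X >= k), upper tail
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, overlap = k, term_size = K, query_size = n,
               universe_size = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p_value <- bh_adjust(out$p_value)
  out$significant <- out$adj_p_value < alpha
  out <- out[order(out$p_value, out$term),
             c("term", "overlap", "term_size", "query_size",
               "universe_size", "p_value", "adj_p_value", "significant",
               "overlap_genes")]
  rownames(out) <- NULL
  out
}

# signed maximum deviation of the weighted Kolmogorov-Smirnov running sum
# over a 0/1 hit vector in ranked order; weight = |stat|^p for hits.
gsea_running_es <- function(hit, stat_abs, weight_p) {
  n <- length(hit)
  n_hit <- sum(hit)
  n_miss <- n - n_hit
  w <- stat_abs^weight_p * hit
  if (sum(w) == 0) w <- as.numeric(hit)  # all in-set stats zero
  inc <- w / sum(w)
  run <- cumsum(inc - (!hit) / n_miss)
  peak <- which.max(abs(run))
  list(es = run[peak], peak = peak, running = run)
}

#' Pre-ranked gene set enrichment analysis with a permutation null
#'
#' Classic weighted Kolmogorov-Smirnov running-sum statistic on a ranked
#' gene list: hits increment by `|stat|^p / sum(in-set |stat|^p)`
#' (`p = 1` by default), misses decrement by `1/(N - K)`; the enrichment
#' score is the signed maximum deviation of the running sum. The null is
#' built by gene-label permutation (random sets of the same size, the
#' standard null for a pre-ranked list), seeded and bit-reproducible:
#' `p = (1 + #{|ES_perm| >= |ES|}) / (nperm + 1)`, with BH adjustment
#' across sets. Leading-edge genes are the in-set genes up to (or from,
#' for negative scores) the running-sum peak.
#'
#' @param ranked data.frame from [rank_by_fold_change()] (columns `gene`,
#'   `stat`), ordered by decreasing ranking statistic.
#' @param gene_sets A `gene_set_collection` or named list.
#' @param nperm Number of permutations (a warning below 100).
#' @param seed Integer seed for the permutation null.
#' @param weight_p Weight exponent on `|stat|` (0 = unweighted).
#' @param min_overlap Minimum set members present in the ranking.
#' @return data.frame with columns `set`, `size`, `es`, `p_value`,
#'   `adj_p_value`, `leading_edge` (comma-separated).
#' @export
preranked_gsea <- function(ranked, gene_sets, nperm = 1000L, seed = 1L,
                           weight_p = 1, min_overlap = 3L) {
  stopifnot(is.data.frame(ranked),
            all(c("gene", "stat") %in% colnames(ranked)))
  if (anyDuplicated(ranked$gene)) stop("ranked list has duplicate genes")
  if (any(!is.finite(ranked$stat))) stop("ranking statistic must be finite")
  if (nperm < 100L) warning("fewer than 100 permutations: p-values coarse")
  sets <- if (inherits(gene_sets, "gene_set_collection")) {
    gene_sets$sets
  } else {
    gene_sets
  }
  genes <- ranked$gene
  n <- length(genes)
  stat_abs <- abs(ranked$stat)
  kept <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    if (length(members) < min_overlap || length(members) >= n) {
      message("set '", nm, "' dropped from GSEA (overlap filter)")
      next
    }
    kept[[nm]] <- members
  }
  if (length(kept) == 0L) stop("no gene set survives the overlap filter")

  sizes <- sort(unique(lengths(kept)))
  set.seed(as.integer(seed))
  # one shared null per set size, built from gene-label permutations
  null_abs <- list()
  for (K in sizes) {
    es_perm <- numeric(nperm)
    for (b in seq_len(nperm)) {
      hit <- logical(n)
      hit[sample.int(n, K)] <- TRUE
      es_perm[b] <- gsea_running_es(hit, stat_abs, weight_p)$es
    }
    null_abs[[as.character(K)]] <- abs(es_perm)
  }
  rows <- lapply(names(kept), function(nm) {
    hit <- genes %in% kept[[nm]]
    res <- gsea_running_es(hit, stat_abs, weight_p)
    le <- if (res$es >= 0) {
      genes[seq_len(res$peak)][hit[seq_len(res$peak)]]
    } else {
      genes[res$peak:n][hit[res$peak:n]]
    }
    nulls <- null_abs[[as.character(sum(hit))]]
    p <- (1 + sum(nulls >= abs(res$es))) / (nperm + 1)
    data.frame(set = nm, size = sum(hit), es = res$es, p_value = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p_value <- bh_adjust(out$p_value)
  out <- out[, c("set", "size", "es", "p_value", "adj_p_value",
                 "leading_edge")]
  rownames(out) <- NULL
  out
}
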