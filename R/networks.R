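#' Build co-expression networks over a threshold sweep
#'
#' One undirected network per threshold: genes are connected when the
#' absolute Pearson correlation is at least the threshold. Edge sets are
#' nested: every edge at a higher threshold is present at any lower one.
#'
#' @param cm Symmetric correlation matrix (e.g. from
#'   [gene_gene_correlation()]).
#' @param thresholds Correlation thresholds in [0, 1].
#' @param signed Use signed correlation `r >= t` instead of `|r| >= t`.
#' @return List of `threshold_network` objects: each a list with
#'   `threshold`, `genes`, `adjacency` (logical matrix), `degree`.
#' @export
build_threshold_networks <- function(cm, thresholds = c(0.6, 0.7, 0.8, 0.9),
                                     signed = FALSE) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (nrow(cm) == 0L) stop("empty node set")
  if (is.null(rownames(cm))) stop("correlation matrix needs gene names")
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  lapply(thresholds, function(t) {
    adj <- if (signed) cm >= t else abs(cm) >= t
    diag(adj) <- FALSE
    structure(list(threshold = t, genes = rownames(cm), adjacency = adj,
                   degree = rowSums(adj)),
              class = "threshold_network")
  })
}

#' Call hub genes in one threshold network
#'
#' Hubs are the nodes with the `top_k` largest degrees; every node tied
#' with the k-th degree is included. Isolated nodes are never hubs.
#'
#' @param net A `threshold_network`.
#' @param top_k Number of top degrees to call.
#' @return Named logical vector of hub indicators.
#' @export
call_hubs_per_network <- function(net, top_k = 5L) {
  stopifnot(inherits(net, "threshold_network"), top_k >= 1L)
  deg <- net$degree
  hub <- stats::setNames(rep(FALSE, length(deg)), names(deg))
  pos <- deg[deg > 0]
  if (length(pos) == 0L) {
    warning("all nodes isolated at threshold ", net$threshold,
            ": no hubs")
    return(hub)
  }
  kth <- sort(pos, decreasing = TRUE)[min(top_k, length(pos))]
  hub[deg >= kth & deg > 0] <- TRUE
  hub
}

#' Frequency-consensus hubs across a threshold sweep
#'
#' A gene's hub frequency is the fraction of threshold networks in which
#' it is called a hub; the consensus flag requires the frequency to reach
#' `consensus_fraction`. The per-threshold indicators are kept in the
#' report so any other consensus rule can be audited.
#'
#' @param nets List of `threshold_network` objects over the same genes.
#' @param top_k Per-network hub rule (see [call_hubs_per_network()]).
#' @param consensus_fraction Minimum hub frequency for consensus.
#' @return data.frame with columns `gene`, one `hub_t<threshold>`
#'   indicator per network, `frequency`, `consensus`, sorted by
#'   decreasing frequency.
#' @export
consensus_hubs <- function(nets, top_k = 5L, consensus_fraction = 0.5) {
  stopifnot(length(nets) >= 1L)
  genes <- nets[[1L]]$genes
  ind <- sapply(nets, function(nt) {
    stopifnot(identical(nt$genes, genes))
    call_hubs_per_network(nt, top_k = top_k)
  })
  ind <- matrix(ind, nrow = length(genes),
                dimnames = list(genes, sprintf("hub_t%g", vapply(
                  nets, function(nt) nt$threshold, numeric(1L)))))
  freq <- rowMeans(ind)
  out <- data.frame(gene = genes, ind, frequency = unname(freq),
                    consensus = unname(freq >= consensus_fraction),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(-out$frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree hubs of a protein-protein interaction network
#'
#' Induces the subgraph on `restrict_to` (e.g. the DEGs), ranks nodes by
#' degree and flags the `top_k` largest, with ties at the k-th degree
#' included. Nodes of `restrict_to` absent from the induced subgraph have
#' degree 0 and are never hubs.
#'
#' @param edges Canonical edge list (see [read_edge_list()]).
#' @param restrict_to Genes defining the induced subgraph.
#' @param top_k Number of top degrees to flag.
#' @return data.frame with columns `gene`, `ppi_degree`, `ppi_hub`,
#'   sorted by decreasing degree.
#' @export
ppi_degree_hubs <- function(edges, restrict_to, top_k = 9L) {
  stopifnot(is.data.frame(edges), top_k >= 1L)
  restrict_to <- unique(as.character(restrict_to))
  sub <- edges[edges$gene_a %in% restrict_to &
                 edges$gene_b %in% restrict_to, , drop = FALSE]
  deg <- stats::setNames(rep(0L, length(restrict_to)), restrict_to)
  if (nrow(sub) == 0L) {
    warning("induced PPI subgraph is empty: no hubs")
    hub <- rep(FALSE, length(restrict_to))
  } else {
    tab <- table(c(sub$gene_a, sub$gene_b))
    deg[names(tab)] <- as.integer(tab)
    pos <- deg[deg > 0]
    kth <- sort(pos, decreasing = TRUE)[min(top_k, length(pos))]
    hub <- deg >= kth & deg > 0
  }
  out <- data.frame(gene = restrict_to, ppi_degree = as.integer(deg),
                    ppi_hub = unname(hub), stringsAsFactors = FALSE)
  out <- out[order(-out$ppi_degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
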