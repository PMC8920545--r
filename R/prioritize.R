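#' Integrate evidence lines into a ranked candidate list
#'
#' Each differentially expressed gene receives an evidence vector -- DE
#' label, count of significant positive and negative pathway
#' associations, co-expression consensus-hub flag, PPI-hub flag, known
#' flag -- and an additive evidence score
#' `w1 [DE] + w2 (positive associations / #pathways) + w3 [co-expression
#' hub] + w4 [PPI hub]`. Genes on the exclusion list ("previously
#' studied") and genes that are themselves members of the osteoblast
#' pathway gene sets ("involved in osteoblast-related pathways") are
#' moved to the excluded table with their reason; the remaining
#' candidates are ranked by descending score, ties broken by positive
#' association count and then gene symbol.
#'
#' @param de A classified `de_result` (see [classify_degs()]).
#' @param assoc Association table from [gene_pathway_association()].
#' @param hubs data.frame with columns `gene`, `coexp_hub`, `ppi_hub`
#'   (see [combine_hub_reports()]).
#' @param known Character vector of previously studied genes (the
#'   user-supplied exclusion list).
#' @param pathway_genes Character vector of genes belonging to the
#'   pathway gene sets themselves (defaults to none).
#' @param weights Numeric length-4 weights for the DE, association,
#'   co-expression-hub and PPI-hub evidence lines.
#' @return A `candidate_ranking`: list with data.frames `candidates`
#'   (ranked) and `excluded` (with `reason`).
#' @export
integrate_evidence <- function(de, assoc, hubs, known = character(0),
                               pathway_genes = character(0),
                               weights = c(1, 1, 1, 1)) {
  stopifnot(is.data.frame(de), "label" %in% names(de),
            length(weights) == 4L, all(weights >= 0))
  degs <- de$gene[de$label != "ns"]
  if (length(degs) == 0L) stop("empty DEG set: nothing to prioritize")
  n_path <- max(length(unique(assoc$pathway)), 1L)
  pos <- with(assoc, tapply(significant & r > 0, gene, sum))
  neg <- with(assoc, tapply(significant & r < 0, gene, sum))
  getn <- function(tab, g) {
    v <- tab[g]
    v[is.na(v)] <- 0
    as.integer(v)
  }
  ev <- data.frame(gene = degs,
                   de_label = de$label[match(degs, de$gene)],
                   n_pos_assoc = getn(pos, degs),
                   n_neg_assoc = getn(neg, degs),
                   stringsAsFactors = FALSE)
  hi <- match(degs, hubs$gene)
  ev$coexp_hub <- !is.na(hi) & hubs$coexp_hub[hi]
  ev$ppi_hub <- !is.na(hi) & hubs$ppi_hub[hi]
  ev$known <- ev$gene %in% known
  in_pathway <- ev$gene %in% pathway_genes
  ev$score <- weights[1L] * (ev$de_label != "ns") +
    weights[2L] * ev$n_pos_assoc / n_path +
    weights[3L] * ev$coexp_hub +
    weights[4L] * ev$ppi_hub

  excl_mask <- ev$known | in_pathway
  excluded <- ev[excl_mask, , drop = FALSE]
  in_pw <- in_pathway[excl_mask]
  studied <- ev$known[excl_mask]
  excluded$reason <- ifelse(
    in_pw & studied,
    "involved in osteoblast-related pathways; previously studied",
    ifelse(in_pw, "involved in osteoblast-related pathways",
           "previously studied"))
  candidates <- ev[!excl_mask, , drop = FALSE]
  o <- order(-candidates$score, -candidates$n_pos_assoc, candidates$gene)
  candidates <- candidates[o, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- rownames(excluded) <- NULL
  structure(list(candidates = candidates, excluded = excluded,
                 weights = weights),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat("candidate_ranking:", nrow(x$candidates), "candidates,",
      nrow(x$excluded), "excluded\n")
  print(utils::head(x$candidates[, c("rank", "gene", "de_label", "score",
                                     "n_pos_assoc", "coexp_hub",
                                     "ppi_hub")], 10L))
  invisible(x)
}

#' Merge co-expression and PPI hub reports into one table
#'
#' @param coexp_reports List of consensus-hub reports (e.g. one for the
#'   upregulated and one for the downregulated network) from
#'   [consensus_hubs()].
#' @param ppi_report Report from [ppi_degree_hubs()].
#' @return data.frame with columns `gene`, `coexp_hub`, `ppi_hub`.
#' @export
combine_hub_reports <- function(coexp_reports, ppi_report) {
  if (is.data.frame(coexp_reports)) coexp_reports <- list(coexp_reports)
  coexp <- unique(unlist(lapply(coexp_reports,
                                function(r) r$gene[r$consensus])))
  genes <- unique(c(unlist(lapply(coexp_reports, `[[`, "gene")),
                    ppi_report$gene))
  data.frame(gene = genes,
             coexp_hub = genes %in% coexp,
             ppi_hub = genes %in% ppi_report$gene[ppi_report$ppi_hub],
             stringsAsFactors = FALSE)
}

#' Run the full candidate-discovery pipeline
#'
#' Batch adjustment, moderated differential expression with the
#' asymmetric gates, ssGSEA pathway scoring, gene-pathway association,
#' direction-separated threshold-swept co-expression consensus hubs, PPI
#' degree hubs, and evidence integration with the novelty filter.
#' Upregulated and downregulated genes are analyzed in separate
#' co-expression networks throughout.
#'
#' @param expr Gene x sample log2 matrix (pre-merge, may carry batch
#'   effects).
#' @param meta Aligned sample metadata.
#' @param gene_sets Osteoblast `gene_set_collection`.
#' @param ppi_edges Canonical PPI edge list.
#' @param known Exclusion list of previously studied genes.
#' @param alpha,up_lfc,down_lfc DEG gates (see [classify_degs()]).
#' @param thresholds Correlation threshold sweep.
#' @param hub_top_k Per-network co-expression hub rule.
#' @param consensus_fraction Consensus hub frequency cutoff.
#' @param ppi_top_k PPI degree hub rule.
#' @param ssgsea_alpha ssGSEA rank weighting exponent.
#' @param batch_covariate Covariate protection for [combat_adjust()]
#'   (`"group"` or `"none"`); `"skip"` skips batch adjustment.
#' @param weights Evidence weights for [integrate_evidence()].
#' @return List with elements `adjusted`, `de`, `scores`,
#'   `stage_medians`, `assoc`, `hubs_up`, `hubs_down`, `ppi`, `hubs`,
#'   `ranking`.
#' @export
run_osteo_pipeline <- function(expr, meta, gene_sets, ppi_edges,
                               known = character(0),
                               alpha = 0.05, up_lfc = 1.0, down_lfc = -0.8,
                               thresholds = c(0.6, 0.7, 0.8, 0.9),
                               hub_top_k = 5L, consensus_fraction = 0.5,
                               ppi_top_k = 9L, ssgsea_alpha = 0.25,
                               batch_covariate = "group",
                               weights = c(1, 1, 1, 1)) {
  adjusted <- if (identical(batch_covariate, "skip")) {
    expr
  } else {
    combat_adjust(expr, meta, covariate = batch_covariate)
  }
  de <- classify_degs(moderated_de(adjusted, meta$group),
                      alpha = alpha, up_lfc = up_lfc, down_lfc = down_lfc)
  up <- de$gene[de$label == "up"]
  down <- de$gene[de$label == "down"]
  scores <- ssgsea_scores(adjusted, gene_sets, alpha = ssgsea_alpha)
  medians <- stage_median_scores(scores, meta)
  assoc <- gene_pathway_association(adjusted, c(up, down), scores,
                                    alpha = alpha)
  hub_report <- function(genes) {
    if (length(genes) < 2L) return(NULL)
    cm <- gene_gene_correlation(adjusted, genes)
    nets <- build_threshold_networks(cm, thresholds)
    consensus_hubs(nets, top_k = hub_top_k,
                   consensus_fraction = consensus_fraction)
  }
  hubs_up <- hub_report(up)
  hubs_down <- hub_report(down)
  ppi <- ppi_degree_hubs(ppi_edges, c(up, down), top_k = ppi_top_k)
  hubs <- combine_hub_reports(Filter(Negate(is.null),
                                     list(hubs_up, hubs_down)), ppi)
  pathway_genes <- unique(unlist(gene_sets$sets, use.names = FALSE))
  ranking <- integrate_evidence(de, assoc, hubs, known = known,
                                pathway_genes = pathway_genes,
                                weights = weights)
  list(adjusted = adjusted, de = de, scores = scores,
       stage_medians = medians, assoc = assoc, hubs_up = hubs_up,
       hubs_down = hubs_down, ppi = ppi, hubs = hubs, ranking = ranking)
}
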