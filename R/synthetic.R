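#' Configuration for the synthetic osteogenic time-course generator
#'
#' Builds a validated configuration for [simulate_timecourse()]. The
#' defaults emulate the structure of a merged multi-platform osteogenic
#' induction study: four batches (datasets of origin), a day-0 control
#' group plus induced samples at days 1/3/7/14, strong planted up/down
#' differentially expressed genes about half of which respond fully by day
#' 1, latent-activity-driven osteoblast pathway modules, and one planted
#' regulator gene that tracks its module's activity and is hub-like in
#' both the co-expression and the protein-protein interaction layer.
#'
#' @param n_genes Number of genes.
#' @param n_batches Number of batches (datasets).
#' @param samples_per_batch_per_stage Replicates per batch at each stage.
#' @param stages Integer day labels; must include 0 (the control stage).
#' @param n_up_degs,n_down_degs Planted up-/down-regulated gene counts.
#' @param effect_size_lfc Full planted shift in log2 units.
#' @param early_response_fraction Fraction of planted DEGs reaching the
#'   full shift at day 1 and holding it; the remainder ramp linearly to
#'   the final stage.
#' @param n_pathway_modules Number of latent pathway modules (>= 2; the
#'   first hosts the regulator, the last has decreasing "development"
#'   activity).
#' @param module_size Genes per module.
#' @param latent_activity_effect log2 shift added to module members per
#'   unit latent activity.
#' @param regulator_gene_flag Plant the regulator gene (logical).
#' @param batch_shift_sd SD of the per-batch per-gene additive shift
#'   (log2 units).
#' @param batch_scale_shape Shape of the inverse-gamma multiplicative
#'   batch scale (mean 1); `Inf` disables scale effects.
#' @param noise_sd Prior scale of the gene-wise Gaussian noise SD (log2
#'   units); gene variances are drawn from a scaled inverse chi-square
#'   around `noise_sd^2`.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_batches = 4L,
                       samples_per_batch_per_stage = 3L,
                       stages = c(0L, 1L, 3L, 7L, 14L),
                       n_up_degs = 40L,
                       n_down_degs = 30L,
                       effect_size_lfc = 3,
                       early_response_fraction = 0.5,
                       n_pathway_modules = 8L,
                       module_size = 15L,
                       latent_activity_effect = 0.6,
                       regulator_gene_flag = TRUE,
                       batch_shift_sd = 1,
                       batch_scale_shape = 5,
                       noise_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_batches = as.integer(n_batches),
              samples_per_batch_per_stage =
                as.integer(samples_per_batch_per_stage),
              stages = sort(unique(as.integer(stages))),
              n_up_degs = as.integer(n_up_degs),
              n_down_degs = as.integer(n_down_degs),
              effect_size_lfc = as.numeric(effect_size_lfc),
              early_response_fraction = as.numeric(early_response_fraction),
              n_pathway_modules = as.integer(n_pathway_modules),
              module_size = as.integer(module_size),
              latent_activity_effect = as.numeric(latent_activity_effect),
              regulator_gene_flag = isTRUE(regulator_gene_flag),
              batch_shift_sd = as.numeric(batch_shift_sd),
              batch_scale_shape = as.numeric(batch_scale_shape),
              noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0L, n_batches > 0L,
              samples_per_batch_per_stage > 0L,
              n_up_degs >= 0L, n_down_degs >= 0L,
              n_pathway_modules >= 2L, module_size > 0L,
              effect_size_lfc >= 0, latent_activity_effect >= 0,
              early_response_fraction >= 0, early_response_fraction <= 1,
              batch_shift_sd >= 0, noise_sd > 0,
              batch_scale_shape > 2)
    if (!0L %in% stages) stop("stages must include day 0 (controls)")
    if (length(stages) < 2L) stop("need at least one induced stage")
  })
  budget <- cfg$n_up_degs + cfg$n_down_degs +
    cfg$n_pathway_modules * cfg$module_size
  if (budget > cfg$n_genes) {
    stop(sprintf("gene budget infeasible: %d DEG + module genes > %d genes",
                 budget, cfg$n_genes))
  }
  structure(cfg, class = "sim_config")
}

# deterministic per-component RNG substreams derived from the one seed
substream_seed <- function(seed, component) {
  offsets <- c(layout = 11L, genes = 23L, noise = 37L, activity = 53L,
               values = 71L, batch = 97L, ppi = 131L, annotation = 173L)
  (as.integer(seed) %% 599999L) * 3001L + offsets[[component]]
}

# saturating latent activity: 0 in controls, near-full by day 1
latent_activity <- function(day) day / (day + 0.25)

deg_kinetic <- function(day, type, max_day) {
  switch(type,
         early = as.numeric(day > 0),
         ramp  = day / max_day,
         stop("unknown kinetic type"))
}

#' Simulate a multi-batch osteogenic induction time course
#'
#' Generates a log2 expression matrix with known ground truth:
#' * baseline expression `mu_g ~ Uniform(6, 12)` with gene-wise Gaussian
#'   noise whose variance follows a scaled inverse chi-square law around
#'   `noise_sd^2` (the classic microarray variance model);
#' * planted up/down DEGs shifted by `effect_size_lfc` in induced samples
#'   -- an early fraction reaches the full shift at day 1 and holds, the
#'   remainder ramps linearly to the final stage;
#' * latent pathway modules whose per-sample activity is a saturating
#'   function of day (0 in controls) with sample-level Gaussian jitter;
#'   member genes add `latent_activity_effect * activity`; the last module
#'   is a "development" module with decreasing activity;
#' * one planted regulator (an up-DEG) whose profile follows its module's
#'   realized activity, with low residual noise, so it correlates with the
#'   module's enrichment score and co-expresses strongly with other
#'   up-DEGs;
#' * planted low-noise co-expression hub genes and a designated
#'   high-degree PPI hub set; those competitor hub genes (never the
#'   regulator) are also annotated into the emitted osteoblast gene sets,
#'   which is what a downstream novelty filter keys on;
#' * per-batch per-gene additive shifts and inverse-gamma multiplicative
#'   scale effects applied after the biology.
#'
#' @param config A [sim_config()].
#' @return A list of class `osteo_simulation` with elements `expr`
#'   (genes x samples log2 matrix), `meta` (sample metadata), `gene_sets`
#'   (the emitted osteoblast `gene_set_collection`), `ppi_edges`
#'   (canonical edge list), `truth` (ground truth: `true_up_genes`,
#'   `true_down_genes`, `module_membership`, `module_direction`,
#'   `regulator_gene_id`, `coexp_hub_genes`, `ppi_hub_genes`,
#'   `batch_shift`, `batch_scale`, `noise_sd_gene`, `ppi_truth_edges`),
#'   and `config`.
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  ## ---- sample layout (deterministic) ----
  days <- rep(rep(cfg$stages, each = cfg$samples_per_batch_per_stage),
              times = cfg$n_batches)
  batch <- rep(seq_len(cfg$n_batches),
               each = length(cfg$stages) * cfg$samples_per_batch_per_stage)
  rep_id <- rep(seq_len(cfg$samples_per_batch_per_stage),
                times = length(cfg$stages) * cfg$n_batches)
  sample_id <- sprintf("B%dD%02dR%d", batch, days, rep_id)
  meta <- data.frame(sample_id = sample_id,
                     group = factor(ifelse(days == 0L, "control", "induced"),
                                    levels = c("control", "induced")),
                     day = as.integer(days),
                     batch = paste0("batch", batch),
                     stringsAsFactors = FALSE)
  n_samp <- nrow(meta)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  max_day <- max(cfg$stages)

  ## ---- gene role assignment ----
  set.seed(substream_seed(cfg$seed, "genes"))
  n_special <- cfg$n_up_degs + cfg$n_down_degs +
    cfg$n_pathway_modules * cfg$module_size
  special <- sample(genes, n_special)
  up <- special[seq_len(cfg$n_up_degs)]
  down <- special[cfg$n_up_degs + seq_len(cfg$n_down_degs)]
  module_pool <- special[cfg$n_up_degs + cfg$n_down_degs +
                           seq_len(cfg$n_pathway_modules * cfg$module_size)]
  modules <- split(module_pool,
                   rep(seq_len(cfg$n_pathway_modules), each = cfg$module_size))
  names(modules) <- module_set_names(cfg$n_pathway_modules)
  module_dir <- c(rep(1, cfg$n_pathway_modules - 1L), -1)
  names(module_dir) <- names(modules)

  regulator <- if (cfg$regulator_gene_flag && cfg$n_up_degs > 0L) up[1L] else NA_character_
  # planted hub structure: low-noise genes dominate co-expression degree
  n_up_hubs <- min(4L, max(cfg$n_up_degs - 1L, 0L))
  n_down_hubs <- min(3L, cfg$n_down_degs)
  up_hubs <- if (n_up_hubs > 0L) up[1L + seq_len(n_up_hubs)] else character(0)
  down_hubs <- if (n_down_hubs > 0L) down[seq_len(n_down_hubs)] else character(0)
  coexp_hubs <- c(if (!is.na(regulator)) regulator, up_hubs, down_hubs)

  # designated PPI hubs: high-degree competitors, mixed direction
  n_ppi_up <- min(4L, max(cfg$n_up_degs - 1L - n_up_hubs, 0L))
  n_ppi_down <- min(4L, max(cfg$n_down_degs - n_down_hubs, 0L))
  ppi_designated <- c(if (n_ppi_up > 0L) up[1L + n_up_hubs + seq_len(n_ppi_up)],
                      if (n_ppi_down > 0L) down[n_down_hubs + seq_len(n_ppi_down)])

  # DEG kinetics: early fraction steps at day 1, rest ramps linearly
  kin <- function(ids) {
    n_early <- round(cfg$early_response_fraction * length(ids))
    stats::setNames(rep(c("early", "ramp"),
                        c(n_early, length(ids) - n_early)), ids)
  }
  kinetics <- c(kin(up), kin(down))

  ## ---- gene-wise noise (scaled inverse chi-square around noise_sd^2) ----
  set.seed(substream_seed(cfg$seed, "noise"))
  noise_df <- 8
  sd_gene <- cfg$noise_sd * sqrt(noise_df / stats::rchisq(cfg$n_genes, noise_df))
  names(sd_gene) <- genes
  mu <- stats::runif(cfg$n_genes, 6, 12)
  names(mu) <- genes
  # induced genes start from dynamic-range-respecting baselines
  mu[up] <- stats::runif(length(up), 6, 9)
  mu[down] <- stats::runif(length(down), 9, 12)
  # planted hubs are the low-noise genes; other DEGs get a noise floor so
  # hub identity is stable across correlation thresholds
  degs <- c(up, down)
  sd_gene[degs] <- pmax(sd_gene[degs], 0.9 * cfg$noise_sd)
  sd_gene[coexp_hubs] <- 0.6 * cfg$noise_sd
  if (!is.na(regulator)) sd_gene[regulator] <- 0.4 * cfg$noise_sd

  ## ---- latent module activity (deterministic in day + sample jitter) ----
  set.seed(substream_seed(cfg$seed, "activity"))
  act_jitter_sd <- 0.15
  base_act <- latent_activity(meta$day)
  activity <- matrix(0, cfg$n_pathway_modules, n_samp,
                     dimnames = list(names(modules), meta$sample_id))
  for (m in seq_len(cfg$n_pathway_modules)) {
    activity[m, ] <- module_dir[m] *
      (base_act + stats::rnorm(n_samp, 0, act_jitter_sd))
  }

  ## ---- assemble signal + noise ----
  set.seed(substream_seed(cfg$seed, "values"))
  signal <- matrix(0, cfg$n_genes, n_samp,
                   dimnames = list(genes, meta$sample_id))
  for (g in up) {
    signal[g, ] <- cfg$effect_size_lfc *
      deg_kinetic(meta$day, kinetics[[g]], max_day)
  }
  for (g in down) {
    signal[g, ] <- -cfg$effect_size_lfc *
      deg_kinetic(meta$day, kinetics[[g]], max_day)
  }
  for (m in seq_len(cfg$n_pathway_modules)) {
    signal[modules[[m]], ] <- signal[modules[[m]], , drop = FALSE] +
      rep(cfg$latent_activity_effect * activity[m, ], each = cfg$module_size)
  }
  if (!is.na(regulator)) {
    # regulator tracks the deterministic stage activity of its module;
    # its own (low) residual noise is added below like any other gene
    signal[regulator, ] <- cfg$effect_size_lfc * base_act
  }
  noise <- matrix(stats::rnorm(cfg$n_genes * n_samp), cfg$n_genes, n_samp) *
    sd_gene

  ## ---- batch effects (additive shift + inverse-gamma scale) ----
  set.seed(substream_seed(cfg$seed, "batch"))
  batch_levels <- unique(meta$batch)
  shift <- matrix(stats::rnorm(cfg$n_genes * cfg$n_batches,
                               0, cfg$batch_shift_sd),
                  cfg$n_genes, cfg$n_batches,
                  dimnames = list(genes, batch_levels))
  # batch offsets are relative to each gene's overall level, so batch
  # structure does not move the gene's grand mean
  if (cfg$n_batches > 1L) shift <- shift - rowMeans(shift)
  if (is.finite(cfg$batch_scale_shape)) {
    scl <- matrix((cfg$batch_scale_shape - 1) /
                    stats::rgamma(cfg$n_genes * cfg$n_batches,
                                  cfg$batch_scale_shape),
                  cfg$n_genes, cfg$n_batches,
                  dimnames = list(genes, batch_levels))
  } else {
    scl <- matrix(1, cfg$n_genes, cfg$n_batches,
                  dimnames = list(genes, batch_levels))
  }
  bcol <- match(meta$batch, batch_levels)
  expr <- mu + signal + shift[, bcol] + noise * sqrt(scl[, bcol])
  dimnames(expr) <- list(genes, meta$sample_id)

  ## ---- PPI fixture: regulator has maximal degree among DEGs ----
  set.seed(substream_seed(cfg$seed, "ppi"))
  ppi <- build_ppi_fixture(genes, degs, regulator, ppi_designated)

  ## ---- emitted osteoblast gene sets: modules + annotated hub genes ----
  overlap_genes <- c(up_hubs, down_hubs, ppi_designated)
  sets <- modules
  if (length(overlap_genes) > 0L) {
    slot <- rep(seq_along(sets), length.out = length(overlap_genes))
    for (i in seq_along(overlap_genes)) {
      sets[[slot[i]]] <- c(sets[[slot[i]]], overlap_genes[i])
    }
  }
  gs <- gene_set_collection(sets, module_set_categories(cfg$n_pathway_modules))

  truth <- list(true_up_genes = up,
                true_down_genes = down,
                module_membership = modules,
                module_direction = module_dir,
                module_activity = activity,
                regulator_gene_id = regulator,
                coexp_hub_genes = coexp_hubs,
                ppi_hub_genes = c(if (!is.na(regulator)) regulator,
                                  ppi_designated),
                kinetics = kinetics,
                batch_shift = shift,
                batch_scale = scl,
                noise_sd_gene = sd_gene,
                ppi_truth_edges = ppi)
  structure(list(expr = expr, meta = meta, gene_sets = gs,
                 ppi_edges = ppi, truth = truth, config = cfg),
            class = "osteo_simulation")
}

module_set_categories <- function(n_modules) {
  cats <- rep("differentiation", n_modules)
  extra <- c("proliferation", "proliferation", "transcription_factor",
             "signaling")
  mid <- seq_len(min(length(extra), max(n_modules - 2L, 0L)))
  cats[1L + mid] <- extra[mid]
  cats[n_modules] <- "development"
  stats::setNames(cats, module_set_names(n_modules))
}

module_set_names <- function(n_modules) {
  cats <- rep("DIFFERENTIATION", n_modules)
  extra <- c("PROLIFERATION", "PROLIFERATION", "TRANSCRIPTION_FACTOR",
             "SIGNALING")
  mid <- seq_len(min(length(extra), max(n_modules - 2L, 0L)))
  cats[1L + mid] <- extra[mid]
  cats[n_modules] <- "DEVELOPMENT"
  sprintf("OSTEOBLAST_%s_M%d", cats, seq_len(n_modules))
}

build_ppi_fixture <- function(genes, degs, regulator, designated) {
  edges <- list()
  if (!is.na(regulator)) {
    others <- setdiff(degs, regulator)
    edges[[length(edges) + 1L]] <-
      data.frame(gene_a = regulator, gene_b = others,
                 stringsAsFactors = FALSE)
  }
  for (g in designated) {
    partners <- sample(setdiff(degs, g), min(18L, length(degs) - 1L))
    edges[[length(edges) + 1L]] <-
      data.frame(gene_a = g, gene_b = partners, stringsAsFactors = FALSE)
  }
  # sparse random edges inside the DEG set
  if (length(degs) >= 2L) {
    n_bg_deg <- max(1L, round(0.02 * choose(length(degs), 2)))
    a <- sample(degs, n_bg_deg, replace = TRUE)
    b <- sample(degs, n_bg_deg, replace = TRUE)
    keep <- a != b
    if (any(keep)) {
      edges[[length(edges) + 1L]] <-
        data.frame(gene_a = a[keep], gene_b = b[keep],
                   stringsAsFactors = FALSE)
    }
  }
  # random background edges across the whole gene universe
  n_bg <- length(genes)
  a <- sample(genes, n_bg, replace = TRUE)
  b <- sample(genes, n_bg, replace = TRUE)
  keep <- a != b
  edges[[length(edges) + 1L]] <-
    data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE)
  all <- do.call(rbind, edges)
  all$weight <- 1
  canonicalize_edges(all)
}

#' @export
print.osteo_simulation <- function(x, ...) {
  cat("osteo_simulation:", nrow(x$expr), "genes x", ncol(x$expr),
      "samples\n")
  cat("  batches:", length(unique(x$meta$batch)),
      " stages:", paste(sort(unique(x$meta$day)), collapse = "/"), "\n")
  cat("  planted:", length(x$truth$true_up_genes), "up,",
      length(x$truth$true_down_genes), "down; regulator",
      x$truth$regulator_gene_id, "\n")
  invisible(x)
}

#' Build a GO-style term-to-gene annotation fixture
#'
#' Emits an annotation table for over-representation tests: one planted
#' "ossification-like" term enriched in the planted up-DEGs plus module
#' genes (at least half of the term's members are true up-DEGs), and
#' random background terms. Deterministic given the simulation config.
#'
#' @param config The [sim_config()] used for the simulation.
#' @param truth The `truth` element of an [simulate_timecourse()] result.
#' @param n_terms Total number of terms (>= 20).
#' @return A data.frame with columns `term` and `gene`.
#' @export
make_annotation_fixture <- function(config, truth, n_terms = 25L) {
  stopifnot(inherits(config, "sim_config"))
  n_terms <- as.integer(n_terms)
  if (n_terms < 20L) stop("annotation fixture must contain at least 20 terms")
  up <- truth$true_up_genes
  if (length(up) == 0L) {
    stop("annotation fixture requires planted up-regulated genes")
  }
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  set.seed(substream_seed(config$seed, "annotation"))
  module_genes <- unique(unlist(truth$module_membership, use.names = FALSE))
  term_size <- min(30L, max(4L, length(up)))
  n_from_up <- min(length(up), ceiling(0.6 * term_size))
  n_filler <- term_size - n_from_up
  filler_pool <- setdiff(module_genes, up)
  filler <- if (n_filler > 0L && length(filler_pool) > 0L) {
    sample(filler_pool, min(n_filler, length(filler_pool)))
  } else character(0)
  planted <- c(sample(up, n_from_up), filler)
  out <- list(data.frame(term = "TERM_OSSIFICATION_LIKE", gene = planted,
                         stringsAsFactors = FALSE))
  for (i in seq_len(n_terms - 1L)) {
    sz <- sample(20:50, 1L)
    out[[i + 1L]] <- data.frame(term = sprintf("TERM_BACKGROUND_%03d", i),
                                gene = sample(genes, sz),
                                stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann
}
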