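test_that("probe collapsing averages multi-probe genes and drops unmapped", {
  pm <- toy_expr(matrix(c(2, 4, 10, 1, 3, 20), 3, 2),
                 genes = c("P1", "P2", "P3"))
  map <- data.frame(probe_id = c("P1", "P2", "P3"),
                    gene_id = c("G1", "G1", NA))
  out <- collapse_probes(pm, map)
  expect_identical(rownames(out), "G1")
  expect_equal(out["G1", ], c(s01 = 3, s02 = 2))

  # one probe per gene is the identity (up to lexicographic reorder)
  map2 <- data.frame(probe_id = c("P1", "P2", "P3"),
                     gene_id = c("GB", "GA", "GC"))
  out2 <- collapse_probes(pm, map2)
  expect_identical(rownames(out2), c("GA", "GB", "GC"))
  expect_equal(out2["GA", ], pm["P2", ])

  map3 <- data.frame(probe_id = "PX", gene_id = "G1")
  expect_error(collapse_probes(pm, map3), "no probe")
})

test_that("batch adjustment enforces its preconditions", {
  sim <- simulate_timecourse(sim_config(seed = 1, n_genes = 100L,
                                        n_pathway_modules = 2L,
                                        module_size = 5L,
                                        n_up_degs = 5L, n_down_degs = 5L))
  one <- sim$meta$batch == "batch1"
  expect_error(combat_adjust(sim$expr[, one], sim$meta[one, ]),
               "at least 2 batches")
  keep <- c(which(one), which(sim$meta$batch == "batch2")[1L])
  expect_error(combat_adjust(sim$expr[, keep], sim$meta[keep, ]),
               "single sample")
  x <- sim$expr
  x["G0001", ] <- 5
  expect_error(combat_adjust(x, sim$meta), "G0001")
})

test_that("adjustment reproduces the reference parametric formulation", {
  sim <- simulate_timecourse(sim_config(seed = 3, n_genes = 400L))
  adj <- combat_adjust(sim$expr, sim$meta)
  mod <- stats::model.matrix(~ group, data = sim$meta)
  ref <- suppressMessages(
    sva::ComBat(sim$expr, batch = sim$meta$batch, mod = mod,
                par.prior = TRUE))
  expect_lt(max(abs(adj - ref)), 1e-8)
  adj0 <- combat_adjust(sim$expr, sim$meta, covariate = "none")
  ref0 <- suppressMessages(
    sva::ComBat(sim$expr, batch = sim$meta$batch, par.prior = TRUE))
  expect_lt(max(abs(adj0 - ref0)), 1e-8)
})

test_that("identically generated batches are left nearly untouched", {
  set.seed(4)
  x <- toy_expr(matrix(rnorm(200 * 40, 8, 1), 200, 40))
  meta <- data.frame(sample_id = colnames(x),
                     group = factor(rep(c("control", "induced"), 20),
                                    levels = c("control", "induced")),
                     day = rep(c(0L, 3L), 20),
                     batch = rep(c("b1", "b2"), each = 20))
  adj <- combat_adjust(x, meta)
  b1 <- meta$batch == "b1"
  pre <- abs(rowMeans(x[, b1]) - rowMeans(x[, !b1]))
  post <- abs(rowMeans(adj[, b1]) - rowMeans(adj[, !b1]))
  expect_lt(max(abs(adj - x)), 1.5)
  expect_lt(mean(post), mean(pre))
  expect_gt(mean(post < pre), 0.9)
})

test_that("a planted additive batch shift is removed", {
  sim <- simulate_timecourse(sim_config(seed = 5))
  x <- sim$expr
  b2 <- sim$meta$batch == "batch2"
  x[, b2] <- x[, b2] + 2
  adj <- combat_adjust(x, sim$meta)
  d_post <- abs(rowMeans(adj[, b2]) - rowMeans(adj[, !b2]))
  d_pre <- abs(rowMeans(x[, b2]) - rowMeans(x[, !b2]))
  expect_gt(mean(d_post < 0.1), 0.98)
  expect_gt(stats::median(d_pre), 1)
})

test_that("group covariate protects the planted induction signal", {
  ch <- sapply(1:5, function(s) {
    sim <- simulate_timecourse(sim_config(seed = 40 + s))
    adj <- combat_adjust(sim$expr, sim$meta)
    ctl <- sim$meta$group == "control"
    degs <- c(sim$truth$true_up_genes, sim$truth$true_down_genes)
    pre <- rowMeans(sim$expr[degs, !ctl]) - rowMeans(sim$expr[degs, ctl])
    post <- rowMeans(adj[degs, !ctl]) - rowMeans(adj[degs, ctl])
    mean(abs(post - pre))
  })
  expect_true(all(ch < 0.1))
})

test_that("re-adjustment changes far less than the first adjustment", {
  sim <- simulate_timecourse(sim_config(seed = 6))
  adj1 <- combat_adjust(sim$expr, sim$meta)
  adj2 <- combat_adjust(adj1, sim$meta)
  first <- mean(abs(adj1 - sim$expr))
  second <- mean(abs(adj2 - adj1))
  expect_lt(second, 0.1 * first)
  # grand per-gene means are preserved (balanced batches)
  expect_lt(max(abs(rowMeans(adj1) - rowMeans(sim$expr))), 0.05)
})
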