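test_that("moderated fit matches the reference empirical-Bayes pipeline", {
  sim <- simulate_timecourse(sim_config(seed = 2, n_genes = 500L))
  de <- moderated_de(sim$expr, sim$meta$group)
  design <- stats::model.matrix(~ group, data = sim$meta)
  fit <- limma::eBayes(limma::lmFit(sim$expr, design))
  tt <- limma::topTable(fit, coef = 2L, number = Inf, sort.by = "none")
  expect_lt(max(abs(de$logFC - tt$logFC)), 1e-10)
  expect_lt(max(abs(de$t - tt$t)), 1e-8)
  expect_lt(max(abs(de$p_value - tt$P.Value)), 1e-10)
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-6)
})

test_that("disabling shrinkage recovers the ordinary pooled-variance t", {
  sim <- simulate_timecourse(sim_config(seed = 3, n_genes = 200L))
  de <- moderated_de(sim$expr, sim$meta$group, shrink = FALSE)
  g <- sim$meta$group
  ora <- apply(sim$expr, 1L, function(v) {
    ht <- stats::t.test(v[g == "induced"], v[g == "control"],
                        var.equal = TRUE)
    c(ht$statistic, ht$p.value)
  })
  expect_lt(max(abs(de$t - ora[1L, ])), 1e-10)
  expect_lt(max(abs(de$p_value - ora[2L, ])), 1e-10)
})

test_that("degenerate and symmetry cases behave exactly", {
  x <- toy_expr(rbind(c(1, 2, 1, 2), c(1, 2, 2, 1)))
  labels <- factor(c("a", "a", "b", "b"))
  de <- moderated_de(x, labels, shrink = FALSE)
  expect_equal(de$logFC[2L], 0)
  expect_equal(de$t[2L], 0)
  expect_equal(de$p_value[2L], 1)

  sim <- simulate_timecourse(sim_config(seed = 7, n_genes = 100L,
                                        n_up_degs = 5L, n_down_degs = 5L,
                                        n_pathway_modules = 2L,
                                        module_size = 5L))
  g <- sim$meta$group
  de1 <- moderated_de(sim$expr, g)
  de2 <- moderated_de(sim$expr, factor(g, levels = rev(levels(g))))
  expect_equal(de2$logFC, -de1$logFC)
  expect_equal(de2$t, -de1$t)
  # permuting samples within groups changes nothing
  perm <- c(sample(which(g == "control")), sample(which(g == "induced")))
  de3 <- moderated_de(sim$expr[, perm], g[perm])
  expect_equal(de3$t, de1$t, tolerance = 1e-12)

  mixed <- c(which(g == "control")[1L], which(g == "induced")[1:2])
  expect_error(moderated_de(sim$expr[, mixed], g[mixed]), "2 samples")
})

test_that("asymmetric gates label genes exactly as stated", {
  de <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   logFC = c(1.2, -0.9, -0.7, 3.0, 1.0),
                   p_value = 0.001,
                   adj_p_value = c(0.01, 0.01, 0.01, 0.2, 0.01))
  got <- classify_degs(de)
  expect_identical(got$label, c("up", "down", "ns", "ns", "ns"))
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.5, 5)), rep(0.5, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1L))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-14)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-14)
  }
})

test_that("median split sends ties to the low group", {
  x <- toy_expr(rbind(c(1, 2, 3, 4)), genes = "AOX1")
  grp <- split_by_median(x, "AOX1")
  expect_identical(unname(grp), factor(c("low", "low", "high", "high"),
                                       levels = c("low", "high")))
  x2 <- toy_expr(rbind(c(1, 2, 2, 4)), genes = "AOX1")
  grp2 <- split_by_median(x2, "AOX1")
  expect_identical(which(grp2 == "high"), 4L)
  expect_identical(names(grp2)[grp2 == "high"], "s04")
  expect_error(split_by_median(x, "MAOA"), "MAOA")
  x3 <- toy_expr(rbind(rep(1, 4)), genes = "AOX1")
  expect_error(split_by_median(x3, "AOX1"), "degenerate")
})

test_that("high-regulator samples are enriched for late-stage induction", {
  hits <- sapply(1:10, function(s) {
    sim <- simulate_timecourse(sim_config(seed = 60 + s))
    grp <- split_by_median(sim$expr, sim$truth$regulator_gene_id)
    late <- sim$meta$day >= 3
    mean(late[grp == "high"]) > mean(late[grp == "low"])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("fold-change ranking is a strict, tie-broken permutation", {
  de <- data.frame(gene = c("A", "B", "C", "D"),
                   logFC = c(2, -1, 0.5, 2),
                   p_value = c(0.01, 0.2, 0.05, 0.5),
                   adj_p_value = NA)
  r <- rank_by_fold_change(de)
  expect_identical(r$gene, c("A", "D", "C", "B"))
  expect_setequal(r$gene, de$gene)
  expect_identical(nrow(r), nrow(de))
})
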