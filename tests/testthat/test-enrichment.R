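test_that("ORA p-values match closed forms and full enumeration", {
  u <- sprintf("g%02d", 1:20)
  ann <- data.frame(term = "T1", gene = u[1:5])
  # query = term = universe: certainty, p = 1
  res <- hypergeometric_ora(u, u, data.frame(term = "T", gene = u))
  expect_equal(res$p_value, 1)
  # all five of a five-gene term drawn in five tries
  res2 <- hypergeometric_ora(u[1:5], u, ann)
  expect_equal(res2$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res2$overlap, 5L)
  set.seed(51)
  for (i in 1:40) {
    N <- sample(5:15, 1L)
    uu <- sprintf("x%02d", seq_len(N))
    K <- sample(1:N, 1L)
    n <- sample(1:N, 1L)
    term <- sample(uu, K)
    query <- sample(uu, N, replace = FALSE)[1:n]
    res <- hypergeometric_ora(query, uu, data.frame(term = "T", gene = term))
    k <- length(intersect(query, term))
    expect_equal(res$p_value, ora_brute(k, K, N, n), tolerance = 1e-12)
  }
  expect_error(hypergeometric_ora(character(0), u, ann), "query")
  expect_error(hypergeometric_ora(c(u[1], "zz"), u, ann), "outside")
})

test_that("GSEA scores match the brute-force running sum", {
  genes <- sprintf("g%02d", 1:10)
  ranked <- data.frame(gene = genes, stat = rep(2, 10))
  # a set occupying the top of an equal-stat list peaks at +1
  res <- suppressWarnings(preranked_gsea(ranked, list(TOP = genes[1:4]),
                                         nperm = 100L, seed = 1L))
  expect_equal(res$es, 1)
  # its complement is enriched at the bottom
  res2 <- suppressWarnings(preranked_gsea(
    data.frame(gene = genes, stat = 10:1), list(BOT = genes[7:10]),
    nperm = 100L, seed = 1L))
  expect_lt(res2$es, 0)
  set.seed(52)
  for (i in 1:25) {
    stat <- sort(stats::rnorm(10), decreasing = TRUE)
    ranked <- data.frame(gene = genes, stat = stat)
    members <- sample(genes, sample(3:6, 1L))
    res <- suppressWarnings(preranked_gsea(ranked, list(S = members),
                                           nperm = 100L, seed = i))
    expect_equal(res$es, gsea_es_brute(genes, stat, members),
                 tolerance = 1e-12)
  }
})

test_that("GSEA matches the reference implementation's statistic", {
  set.seed(53)
  stat <- sort(stats::rnorm(200), decreasing = TRUE)
  genes <- sprintf("g%03d", seq_along(stat))
  idx <- sort(sample(200, 20))
  mine <- suppressWarnings(preranked_gsea(
    data.frame(gene = genes, stat = stat), list(S = genes[idx]),
    nperm = 100L, seed = 1L))
  ref <- fgsea::calcGseaStat(stat, idx, gseaParam = 1)
  expect_equal(mine$es, ref, tolerance = 1e-10)
})

test_that("ES is scale invariant and the permutation p reproducible", {
  set.seed(54)
  genes <- sprintf("g%03d", 1:100)
  stat <- sort(stats::rexp(100), decreasing = TRUE)
  sets <- list(A = sample(genes, 10), B = sample(genes, 15))
  r1 <- preranked_gsea(data.frame(gene = genes, stat = stat), sets,
                       nperm = 199L, seed = 11L)
  r2 <- preranked_gsea(data.frame(gene = genes, stat = 3 * stat), sets,
                       nperm = 199L, seed = 11L)
  expect_equal(r1$es, r2$es, tolerance = 1e-12)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$leading_edge, r2$leading_edge)
  r3 <- preranked_gsea(data.frame(gene = genes, stat = stat), sets,
                       nperm = 199L, seed = 11L)
  expect_identical(r1, r3)
  # unweighted mode is invariant under order-preserving transforms
  u1 <- preranked_gsea(data.frame(gene = genes, stat = stat), sets,
                       nperm = 199L, seed = 11L, weight_p = 0)
  u2 <- preranked_gsea(data.frame(gene = genes, stat = rank(stat)), sets,
                       nperm = 199L, seed = 11L, weight_p = 0)
  expect_equal(u1$es, u2$es, tolerance = 1e-12)
  expect_gte(min(r1$p_value), 1 / 200)
  expect_warning(preranked_gsea(data.frame(gene = genes, stat = stat),
                                sets, nperm = 50L, seed = 1L), "100")
})

test_that("osteoblast sets enrich in the high-regulator group", {
  sim <- simulate_timecourse(sim_config(seed = 13))
  grp <- split_by_median(sim$expr, sim$truth$regulator_gene_id)
  de <- moderated_de(sim$expr, grp)
  ranked <- rank_by_fold_change(de)
  res <- suppressMessages(suppressWarnings(
    preranked_gsea(ranked, sim$gene_sets, nperm = 199L, seed = 2L)))
  inc <- setdiff(names(sim$truth$module_membership),
                 utils::tail(names(sim$truth$module_membership), 1L))
  expect_gt(stats::median(res$es[res$set %in% inc]), 0)
})
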