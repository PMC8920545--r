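make_de <- function(genes, labels) {
  data.frame(gene = genes, logFC = ifelse(labels == "up", 2, -2),
             p_value = 0.001, adj_p_value = 0.01, label = labels,
             stringsAsFactors = FALSE)
}

make_assoc <- function(genes, npos, npath = 4L) {
  do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(gene = genes[i], pathway = sprintf("P%d", seq_len(npath)),
               r = ifelse(seq_len(npath) <= npos[i], 0.8, 0.01),
               p_value = 0.001, adj_p_value = 0.01,
               significant = seq_len(npath) <= npos[i],
               stringsAsFactors = FALSE)
  }))
}

test_that("the additive evidence score and tie rules order candidates", {
  genes <- c("A", "B", "C", "D")
  de <- make_de(genes, c("up", "up", "up", "ns"))
  assoc <- make_assoc(genes, c(4L, 4L, 2L, 0L))
  hubs <- data.frame(gene = genes,
                     coexp_hub = c(TRUE, TRUE, TRUE, FALSE),
                     ppi_hub = c(TRUE, TRUE, FALSE, FALSE))
  r <- integrate_evidence(de, assoc, hubs)
  # A and B tie on every line -> alphabetical; C trails on two lines
  expect_identical(r$candidates$gene, c("A", "B", "C"))
  expect_equal(r$candidates$score[1L], 1 + 1 + 1 + 1)
  expect_equal(r$candidates$score[3L], 1 + 0.5 + 1 + 0)
  # input order is irrelevant
  perm <- c(3L, 1L, 4L, 2L)
  r2 <- integrate_evidence(de[perm, ], assoc, hubs)
  expect_identical(r2$candidates$gene, r$candidates$gene)
})

test_that("known genes and pathway members are excluded with reasons", {
  genes <- c("A", "B", "C")
  de <- make_de(genes, rep("up", 3))
  assoc <- make_assoc(genes, c(4L, 4L, 4L))
  hubs <- data.frame(gene = genes, coexp_hub = TRUE, ppi_hub = TRUE)
  r <- integrate_evidence(de, assoc, hubs, known = "B",
                          pathway_genes = "C")
  expect_identical(r$candidates$gene, "A")
  expect_identical(r$excluded$reason[r$excluded$gene == "B"],
                   "previously studied")
  expect_identical(r$excluded$reason[r$excluded$gene == "C"],
                   "involved in osteoblast-related pathways")
  expect_error(integrate_evidence(make_de("A", "ns"), assoc, hubs),
               "empty DEG set")
})

test_that("zeroing a weight never promotes the gene lacking that evidence", {
  genes <- c("A", "B")
  de <- make_de(genes, c("up", "up"))
  assoc <- make_assoc(genes, c(4L, 4L))
  hubs <- data.frame(gene = genes, coexp_hub = c(TRUE, FALSE),
                     ppi_hub = c(TRUE, TRUE))
  for (w3 in c(1, 0.5, 0)) {
    r <- integrate_evidence(de, assoc, hubs, weights = c(1, 1, w3, 1))
    expect_identical(r$candidates$gene[1L], "A")
  }
})

test_that("the full pipeline recovers the planted regulator end to end", {
  sim <- simulate_timecourse(sim_config(seed = 17))
  res <- quiet_pipeline(sim)
  reg <- sim$truth$regulator_gene_id
  top <- res$ranking$candidates
  expect_identical(top$gene[1L], reg)
  expect_identical(top$de_label[1L], "up")
  expect_true(top$coexp_hub[1L] && top$ppi_hub[1L])
  # planted competitor hubs end in the excluded table, as pathway members
  expect_true(all(sim$truth$ppi_hub_genes[-1L] %in% res$ranking$excluded$gene))
  # deterministic given the simulated input
  res2 <- quiet_pipeline(sim)
  expect_identical(res$ranking$candidates, res2$ranking$candidates)
})

test_that("2^-ddCt arithmetic is exact and symmetric", {
  rec <- function(t, r) data.frame(ct_target = t, ct_reference = r)
  same <- fold_change_ddct(rec(c(25, 26), c(20, 21)),
                           rec(c(24, 27), c(19, 22)))
  expect_equal(same$fold_change, 1)
  up <- fold_change_ddct(rec(24, 20), rec(25, 20))
  expect_equal(up$fold_change, 2)
  ex <- fold_change_ddct(rec(c(25.0, 25.2), c(20, 20)),
                         rec(c(27.1, 26.9), c(20, 20)))
  expect_equal(ex$ddct, -1.9, tolerance = 1e-12)
  expect_equal(ex$fold_change, 2^1.9, tolerance = 1e-12)
  inv <- fold_change_ddct(rec(c(27.1, 26.9), c(20, 20)),
                          rec(c(25.0, 25.2), c(20, 20)))
  expect_equal(inv$fold_change, 1 / ex$fold_change, tolerance = 1e-12)
  shifted <- fold_change_ddct(rec(c(30.0, 30.2), c(25, 25)),
                              rec(c(32.1, 31.9), c(25, 25)))
  expect_equal(shifted$fold_change, ex$fold_change, tolerance = 1e-12)
  expect_error(fold_change_ddct(rec(numeric(0), numeric(0)), rec(25, 20)),
               "empty")
  expect_error(fold_change_ddct(rec(-1, 20), rec(25, 20)), "positive")
})
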