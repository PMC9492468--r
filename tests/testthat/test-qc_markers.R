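# --- QC filtering -----------------------------------------------------------

# 200 body genes + 10 mito genes; base cells carry 5 UMIs on each body gene
qc_fixture <- function() {
  genes <- c(sprintf("G%03d", 1:200), sprintf("MT-%02d", 1:10))
  base <- c(rep(5L, 200), rep(0L, 10))
  cells <- list(
    ok_boundary = base,                                   # 1000 UMIs, 200 genes
    low_umi = replace(base, 1, 4L),                       # 999 UMIs
    few_genes = replace(replace(base, 1, 0L), 2, 10L),    # 1000 UMIs, 199 genes
    mito12 = c(rep(5L, 200), rep(0L, 9), 137L),           # 137/1137 = 12.05%
    mito10 = c(rep(5L, 200), rep(0L, 9), 111L),           # 111/1111 = 9.99%
    ok2 = base * 2L, ok3 = base * 2L, ok4 = base * 3L)
  m <- do.call(cbind, cells)
  rownames(m) <- genes
  count_matrix(m)
}

test_that("cell gates follow the at-least / more-than conventions", {
  res <- filter_cells_genes(qc_fixture())
  kept <- res$cell_report$cell[res$cell_report$kept]
  expect_setequal(kept, c("ok_boundary", "mito10", "ok2", "ok3", "ok4"))
  rep <- res$cell_report
  expect_equal(rep$reason[rep$cell == "low_umi"], "low_umis")
  expect_equal(rep$reason[rep$cell == "few_genes"], "low_genes")
  expect_equal(rep$reason[rep$cell == "mito12"], "high_mito_ribo")
})

test_that("gene prevalence counts strictly more than min_cells on retained cells", {
  genes <- c(sprintf("G%03d", 1:200), "EXTRA3", "EXTRA4")
  base <- rep(5L, 202)
  # 5 identical good cells; EXTRA3 expressed in 3 of them, EXTRA4 in 4
  m <- sapply(1:5, function(i) {
    v <- base
    if (i > 3) v[201] <- 0L
    if (i > 4) v[202] <- 0L
    v
  })
  rownames(m) <- genes; colnames(m) <- paste0("c", 1:5)
  res <- filter_cells_genes(count_matrix(m))
  gr <- res$gene_report
  expect_false(gr$kept[gr$gene == "EXTRA3"])  # exactly 3 cells -> removed
  expect_true(gr$kept[gr$gene == "EXTRA4"])   # 4 cells -> kept
})

test_that("filtering is idempotent and can empty a matrix with a warning", {
  res1 <- filter_cells_genes(qc_fixture())
  res2 <- filter_cells_genes(res1$matrix)
  expect_identical(as.matrix(res2$matrix$counts), as.matrix(res1$matrix$counts))
  expect_warning(filter_cells_genes(tiny_counts()), "removed all")
})

test_that("separate mito/ribo rule differs from the joint sum", {
  genes <- c(sprintf("G%03d", 1:200), "MT-01", "RPS01")
  v <- c(rep(5L, 200), 70L, 70L)   # 6.1% each, 12.3% jointly
  m <- cbind(cellA = v); rownames(m) <- genes
  expect_warning(joint <- filter_cells_genes(count_matrix(m)), "removed all")
  sep <- filter_cells_genes(count_matrix(m),
                            qc_thresholds(min_cells_per_gene = 0L,
                                          mito_ribo_rule = "separate"))
  expect_false(joint$cell_report$kept[1])
  expect_true(sep$cell_report$kept[1])
})

# --- immunophenotype gating -------------------------------------------------

test_that("malignant gating requires all positives and no negatives", {
  genes <- c("CD38", "NCAM1", "SDC1", "CD19", "MS4A1", "OTHER")
  m <- cbind(malig = c(3L, 1L, 2L, 0L, 0L, 5L),
             cd20pos = c(3L, 1L, 2L, 0L, 4L, 5L),
             b_cell = c(1L, 1L, 1L, 2L, 3L, 0L),
             empty = c(0L, 0L, 0L, 0L, 0L, 0L))
  rownames(m) <- genes
  cm <- count_matrix(m)
  call <- gate_malignant(cm, positive = c("CD38", "NCAM1", "SDC1"),
                         negative = c("CD19", "MS4A1"))
  expect_identical(unname(call), c(TRUE, FALSE, FALSE, FALSE))
  # CD20+ relapse phenotype moves MS4A1 to the positive list
  call20 <- gate_malignant(cm, positive = c("CD38", "NCAM1", "SDC1", "MS4A1"),
                           negative = "CD19")
  expect_true(call20[["cd20pos"]])
  expect_false(call20[["empty"]])
  expect_error(gate_malignant(cm, positive = "CD138"), "absent")
})

# --- marker detection -------------------------------------------------------

test_that("rank-sum p-values match exhaustive enumeration for small groups", {
  set.seed(42)
  for (rep_i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    # integer-valued draws force ties, the hard case
    x <- sample(0:3, n1, replace = TRUE)
    y <- sample(0:4, n2, replace = TRUE)
    expect_equal(rank_sum_p(x, y), oracle_rank_sum_p(x, y), tolerance = 1e-12)
  }
})

test_that("normal-approximation path agrees with the exact path near n = 25", {
  set.seed(7)
  x <- rnorm(14); y <- rnorm(12) + 0.5
  p_exact <- rank_sum_p(x, y, exact_max = 26L)
  p_approx <- rank_sum_p(x, y, exact_max = 10L)
  expect_lt(abs(p_exact - p_approx), 0.02)
})

test_that("BH adjustment reproduces the step-up procedure on a worked vector", {
  p <- c(0.01, 0.04, 0.03, 0.005, 0.20)
  # by hand: sorted (0.005, .01, .03, .04, .20) * 5/(1..5), cummin from the top
  expect_equal(stats::p.adjust(p, "BH"),
               c(0.025, 0.05, 0.05, 0.025, 0.20))
  expect_equal(oracle_bh(p), stats::p.adjust(p, "BH"))
})

test_that("an exclusively expressed gene tops its cluster's markers", {
  cfg <- simulation_config(n_clusters = 2, cells_per_cluster = 100,
                           n_genes = 40, mito_fraction = 0, seed = 21)
  sim <- simulate_counts(cfg)
  m <- sim$matrix
  counts <- as.matrix(m$counts)
  counts["G0005", ] <- ifelse(m$cell_meta$cluster == "C1", 20L, 0L)
  m2 <- count_matrix(counts, cell_meta = m$cell_meta)
  mk <- find_markers(m2, m2$cell_meta$cluster)
  top <- mk[mk$cluster == "C1", ][1, ]
  expect_equal(top$gene, "G0005")
  expect_gt(top$logFC, 0)
  expect_lt(top$p_adj, 1e-10)
  expect_equal(top$pct_out, 0)
})

test_that("marker tables are symmetric under cluster label swap", {
  set.seed(13)
  counts <- matrix(rpois(30 * 40, 2), nrow = 30,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("c%02d", 1:40)))
  m <- count_matrix(counts)
  lab <- rep(c("A", "B"), each = 20)
  swapped <- ifelse(lab == "A", "B", "A")
  mkA <- find_markers(m, lab)
  mkB <- find_markers(m, swapped)
  a <- mkA[mkA$cluster == "A", c("gene", "logFC", "p_value")]
  b <- mkB[mkB$cluster == "B", c("gene", "logFC", "p_value")]
  expect_equal(a[order(a$gene), ], b[order(b$gene), ], ignore_attr = TRUE)
})

test_that("marker detection enforces cluster prerequisites and BH monotonicity", {
  m <- tiny_counts()
  expect_error(find_markers(m, c("A", "A", "B")), "fewer than 3")
  expect_error(find_markers(m, rep("A", 3)), ">= 2 clusters")
  cfg <- simulation_config(n_clusters = 2, cells_per_cluster = 50,
                           n_genes = 30, seed = 2)
  mk <- find_markers(simulate_counts(cfg)$matrix, "cluster")
  expect_true(all(mk$p_adj >= mk$p_value - 1e-12))
  expect_true(all(mk$pct_in >= 0 & mk$pct_in <= 1))
  # sorted by cluster then ascending p_adj
  for (cl in unique(mk$cluster)) {
    expect_false(is.unsorted(mk$p_adj[mk$cluster == cl]))
  }
})

test_that("null rank-sum p-values are calibrated at the 5% level", {
  set.seed(31)
  p <- replicate(400, rank_sum_p(rnorm(12), rnorm(12)))
  rej <- mean(p < 0.05)
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  expect_gt(mean(p), 0.35)   # roughly uniform, allowing discreteness
})
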