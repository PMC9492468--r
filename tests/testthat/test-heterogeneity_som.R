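test_that("Pi matrix reproduces the per-entry formula", {
  mk <- data.frame(gene = c("a", "b", "c", "a"),
                   cluster = c("K1", "K1", "K1", "K2"),
                   logFC = c(2, -1.5, 3, 1),
                   p_value = c(0.001, 0.02, 1, 0.5),
                   p_adj = c(0.01, 0.05, 1, 0))
  pi_mat <- compute_pi_matrix(mk)
  expect_equal(pi_mat["a", "K1"], 4)                       # -log10(.01) * 2
  expect_equal(pi_mat["b", "K1"], -log10(0.05) * -1.5)
  expect_equal(pi_mat["c", "K1"], 0)                       # p_adj = 1
  expect_equal(pi_mat["a", "K2"], 300)                     # epsilon floor
  expect_equal(pi_mat["b", "K2"], 0)                       # absent -> 0
  expect_true(all(is.finite(pi_mat)))
  expect_true(all(sign(pi_mat["b", "K1"]) == sign(-1.5)))
  # entry-by-entry oracle over every row of the table
  for (i in seq_len(nrow(mk))) {
    expect_equal(pi_mat[mk$gene[i], mk$cluster[i]],
                 -log10(max(mk$p_adj[i], 1e-300)) * mk$logFC[i])
  }
})

som_fixture <- function(seed = 2) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * 4, sd = 4), nrow = 3)
  rows <- centers[rep(1:3, each = 10), ] + matrix(rnorm(120, sd = 0.2), 30)
  rows[1, ] <- rows[2, ]   # two genes with identical Pi rows
  rownames(rows) <- sprintf("gene%02d", 1:30)
  rows
}

test_that("SOM training is deterministic, converging, and groups equal rows", {
  pi_mat <- som_fixture()
  som1 <- train_som(pi_mat, 4, 4, epochs = 20, seed = 9)
  som2 <- train_som(pi_mat, 4, 4, epochs = 20, seed = 9)
  expect_identical(som1$assignment, som2$assignment)
  expect_lte(utils::tail(som1$quantization_error, 1),
             som1$quantization_error[1])
  a <- som1$assignment
  expect_equal(a$unit[a$gene == "gene01"], a$unit[a$gene == "gene02"])
  # well-separated planted groups map to distinct units
  expect_gte(length(unique(a$unit)), 3)
})

test_that("SOM assignments are permutation-equivariant in gene order", {
  pi_mat <- som_fixture(seed = 4)
  perm <- sample(nrow(pi_mat))
  som_a <- train_som(pi_mat, 3, 3, epochs = 10, seed = 5)
  som_b <- train_som(pi_mat[perm, ], 3, 3, epochs = 10, seed = 5)
  a <- som_a$assignment[order(som_a$assignment$gene), ]
  b <- som_b$assignment[order(som_b$assignment$gene), ]
  expect_equal(a$unit, b$unit)
})

test_that("SOM guards degenerate inputs", {
  expect_error(train_som(som_fixture(), 1, 1), ">= 2 units")
  expect_error(train_som(som_fixture(), 3, 3, epochs = 0), "epochs")
  z <- matrix(0, 5, 3, dimnames = list(paste0("g", 1:5), NULL))
  expect_warning(train_som(z, 2, 2, epochs = 2, seed = 1), "trivial")
})

test_that("diversity score matches closed forms and its invariances", {
  coords <- rbind(c(0, 0), c(2, 0))
  expect_equal(diversity_score(coords, c("p", "p"))$score, 1)
  same <- matrix(1, nrow = 4, ncol = 3)
  expect_equal(diversity_score(same, rep("p", 4))$score, 0)
  set.seed(6)
  x <- matrix(rnorm(20), 10, 2)
  base <- diversity_score(x, rep("p", 10))$score
  # duplication, translation, scaling
  expect_equal(diversity_score(rbind(x, x), rep("p", 20))$score, base)
  expect_equal(diversity_score(x + 5, rep("p", 10))$score, base)
  expect_equal(diversity_score(x * 3, rep("p", 10))$score, 3 * base)
  expect_warning(out <- diversity_score(x, c(rep("p", 9), "solo")), "single")
  expect_true(is.na(out$score[out$patient == "solo"]))
})

test_that("a two-subclone patient scores higher than a matched single cluster", {
  set.seed(11)
  n <- 60
  # patient A: two well-separated subclones; patient B: one cluster with the
  # same within-cluster variance
  a <- rbind(matrix(rnorm(n / 2 * 5), ncol = 5),
             matrix(rnorm(n / 2 * 5, mean = 6), ncol = 5))
  b <- matrix(rnorm(n * 5), ncol = 5)
  coords <- rbind(a, b)
  div <- diversity_score(coords, rep(c("A", "B"), each = n))
  expect_gt(div$score[div$patient == "A"], div$score[div$patient == "B"])
})

test_that("pca embedding feeds the diversity score end to end", {
  cfg <- simulation_config(n_clusters = 2, cells_per_cluster = 40,
                           n_genes = 50, n_samples = 2, seed = 19)
  sim <- simulate_counts(cfg)
  expect_warning(emb <- pca_embedding(sim$matrix, d = 300), "reducing")
  emb <- pca_embedding(sim$matrix, d = 10)
  expect_equal(ncol(emb$coordinates), 10)
  expect_false(is.unsorted(rev(emb$explained_variance)))
  div <- diversity_score(emb, sim$matrix$cell_meta$sample)
  expect_equal(nrow(div), 2)
  expect_true(all(div$score > 0))
})
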