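random_unit <- function(g, seed) {
  set.seed(seed)
  stats::setNames(rnorm(g), sprintf("g%03d", seq_len(g)))
}

test_that("signature genes at the extreme ranks give score +1 / -1", {
  x <- stats::setNames(10:1, sprintf("g%02d", 1:10))
  top <- suppressWarnings(
    signature_score(rbind(u1 = x, u2 = x), gene_set("s", c("g01", "g02"))))
  expect_equal(top$raw, c(1, 1))
  bottom <- suppressWarnings(
    signature_score(rbind(u1 = x, u2 = x), gene_set("s", c("g09", "g10"))))
  expect_equal(bottom$raw, c(-1, -1))
})

test_that("raw scores equal an independent running-sum oracle (G <= 50)", {
  for (seed in 1:15) {
    g <- sample(10:50, 1)
    x <- random_unit(g, seed)
    members <- sample(names(x), sample(2:min(8, g - 2), 1))
    got <- signature_score(rbind(u = x), gene_set("s", members))$raw
    expect_equal(got, oracle_ks_score(x, members), tolerance = 1e-12)
  }
})

test_that("scores are invariant under strictly monotone transforms", {
  x <- random_unit(40, 99)
  s <- gene_set("s", names(x)[c(3, 17, 25)])
  base <- signature_score(rbind(u = x), s)$raw
  for (f in list(function(v) 2 * v + 7, exp, function(v) rank(v))) {
    expect_equal(signature_score(rbind(u = f(x)), s)$raw, base)
  }
  # identical rank order across units => identical raw scores
  two <- rbind(u1 = x, u2 = exp(x) * 3)
  sc <- suppressWarnings(signature_score(two, s))
  expect_equal(sc$raw[1], sc$raw[2])
})

test_that("scaled scores are an order-isomorphic min-max of raw scores", {
  set.seed(5)
  mat <- matrix(rnorm(20 * 30), nrow = 20,
                dimnames = list(paste0("u", 1:20), sprintf("g%03d", 1:30)))
  sc <- signature_score(mat, gene_set("s", sprintf("g%03d", 1:5)))
  expect_equal(min(sc$scaled), 0)
  expect_equal(max(sc$scaled), 1)
  expect_equal(sc$scaled, (sc$raw - min(sc$raw)) / diff(range(sc$raw)))
})

test_that("degenerate and empty inputs are rejected or flagged", {
  x <- stats::setNames(rep(1, 10), paste0("g", 1:10))
  expect_error(signature_score(rbind(u = x), gene_set("s", c("g1", "g2"))),
               "all-equal")
  y <- random_unit(10, 1)
  expect_error(signature_score(rbind(u = y), gene_set("s", "absent")),
               "measured")
  expect_error(signature_score(rbind(u = y), gene_set("s", names(y))),
               "none or all")
})

test_that("stemness index matches the Spearman formula and its extremes", {
  w <- gene_set("stem", sprintf("g%02d", 1:10),
                weights = stats::setNames(seq(0.1, 1, 0.1), sprintf("g%02d", 1:10)))
  aligned <- stats::setNames(1:10, sprintf("g%02d", 1:10))
  reversed <- stats::setNames(10:1, sprintf("g%02d", 1:10))
  set.seed(8)
  noise <- stats::setNames(sample(seq(1, 30)[1:10]), sprintf("g%02d", 1:10))
  mat <- rbind(aligned = aligned, reversed = reversed, noise = noise)
  st <- stemness_index(mat, w)
  expect_equal(st$raw[st$unit == "aligned"], 1)
  expect_equal(st$raw[st$unit == "reversed"], -1)
  expect_equal(st$raw[st$unit == "noise"],
               oracle_spearman(noise, seq(0.1, 1, 0.1)), tolerance = 1e-12)
  expect_equal(st$scaled[st$unit == "aligned"], 1)
  expect_equal(st$scaled[st$unit == "reversed"], 0)
  # guards
  w2 <- gene_set("w2", c("g01", "g02"), weights = c(g01 = 1, g02 = 2))
  expect_error(stemness_index(mat, w2), ">= 3")
  expect_error(stemness_index(mat, gene_set("plain", "g01")), "weights")
  expect_warning(stemness_index(mat[c(1, 1), ], w), "degenerate")
})

test_that("cell cycle scoring separates planted quiescent and cycling clusters", {
  cfg <- simulation_config(
    n_clusters = 2, cells_per_cluster = 80, n_genes = 60, seed = 17,
    marker_spec = data.frame(cluster = "C2",
                             gene = sprintf("G%04d", 1:6), fold = 6))
  sim <- simulate_counts(cfg)
  cyc <- gene_set("cycling", sprintf("G%04d", 1:6))
  sc <- cell_cycle_score(sim$matrix, cyc)
  by_cl <- tapply(sc$scaled, sim$matrix$cell_meta$cluster, mean)
  expect_gt(by_cl["C2"], by_cl["C1"] + 0.2)
  # same set scored twice -> identical output
  expect_identical(sc, cell_cycle_score(sim$matrix, cyc))
})

test_that("kde filter scores the unit on the genes above the zero mode", {
  set.seed(12)
  x <- c(stats::setNames(rnorm(30, 0, 0.01), paste0("z", 1:30)),
         stats::setNames(rnorm(20, 8), paste0("h", sprintf("%02d", 1:20))))
  s <- gene_set("s", c("h01", "h02"))
  with_f <- signature_score(rbind(u = x), s, kde_filter = TRUE)$raw
  # the two modes are separated, so the filter is equivalent to a mid cut
  manual <- signature_score(rbind(u = x[x > 4]), s)$raw
  expect_equal(with_f, manual)
})
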