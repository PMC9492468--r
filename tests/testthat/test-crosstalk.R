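# small helper: profiles object built directly, bypassing expression data,
# so the network tests control the gene lists exactly
manual_profiles <- function(lists, genes, mean_expr = NULL) {
  profs <- lapply(names(lists), function(cl) {
    me <- if (is.null(mean_expr)) {
      stats::setNames(rep(1, length(genes)), genes)
    } else mean_expr[[cl]]
    list(cluster = cl, n_cells = 100L, mean_expr = me,
         frac_expr = stats::setNames(rep(1, length(genes)), genes),
         expressed = genes, high = lists[[cl]], deg = character(),
         gene_list = lists[[cl]])
  })
  names(profs) <- names(lists)
  structure(profs, class = "cluster_profiles", genes = genes)
}

test_that("upper-tail hypergeometric matches both oracles", {
  # worked example: N = 10, K = 4, n = 4, k = 4 -> 1 / C(10, 4)
  p <- stats::phyper(3, 4, 6, 4, lower.tail = FALSE)
  expect_equal(p, 1 / choose(10, 4), tolerance = 1e-12)
  expect_equal(oracle_phyper_enum(10, 4, 4, 4), p, tolerance = 1e-12)
  # combinatorial and literal-enumeration oracles agree on a small sweep
  for (N in c(6, 9)) for (K in c(2, 4)) for (n in c(3, 5)) {
    for (k in 0:min(K, n)) {
      expect_equal(oracle_phyper_upper(N, K, n, k),
                   oracle_phyper_enum(N, K, n, k), tolerance = 1e-10)
    }
  }
})

test_that("randomized networks preserve degrees and never duplicate edges", {
  set.seed(3)
  db <- lr_database(data.frame(
    ligand = paste0("L", sample(1:12, 60, replace = TRUE)),
    receptor = paste0("R", sample(1:12, 60, replace = TRUE))))
  nets <- randomize_lr_network(db, R = 30, seed = 5)
  out0 <- table(db$pairs$ligand)
  in0 <- table(db$pairs$receptor)
  changed <- FALSE
  for (net in nets) {
    expect_equal(table(net$ligand), out0)
    expect_equal(table(net$receptor), in0)
    expect_false(any(duplicated(paste(net$ligand, net$receptor))))
    if (!identical(sort(paste(net$ligand, net$receptor)),
                   sort(paste(db$pairs$ligand, db$pairs$receptor)))) {
      changed <- TRUE
    }
  }
  expect_true(changed)
  # determinism under the seed
  nets2 <- randomize_lr_network(db, R = 30, seed = 5)
  expect_identical(nets, nets2)
})

test_that("the 2-pair graph admits exactly one rewiring", {
  db <- lr_database(data.frame(ligand = c("a", "b"), receptor = c("x", "y")))
  nets <- randomize_lr_network(db, R = 200, seed = 1)
  keys <- vapply(nets, function(n) {
    paste(sort(paste(n$ligand, n$receptor)), collapse = "|")
  }, "")
  expect_setequal(unique(keys), c("a x|b y", "a y|b x"))
})

test_that("a saturated bipartite graph is returned unchanged with a warning", {
  db <- lr_database(expand.grid(ligand = c("a", "b"), receptor = c("x", "y"),
                                stringsAsFactors = FALSE))
  expect_warning(nets <- randomize_lr_network(db, R = 3, seed = 1),
                 "no valid")
  for (net in nets) {
    expect_setequal(paste(net$ligand, net$receptor),
                    paste(db$pairs$ligand, db$pairs$receptor))
  }
  expect_error(randomize_lr_network(
    lr_database(data.frame(ligand = "a", receptor = "x"))), ">= 2")
})

test_that("hypergeometric detector records and gates follow the contract", {
  genes <- c(paste0("L", 1:10), paste0("R", 1:10))
  db <- lr_database(data.frame(ligand = paste0("L", 1:10),
                               receptor = paste0("R", 1:10)))
  # source list holds 4 ligands, target list the 4 matched receptors: k = 4
  profs <- manual_profiles(list(A = c(paste0("L", 1:4)),
                                B = c(paste0("R", 1:4))), genes)
  nets <- randomize_lr_network(db, R = 99, seed = 2)
  res <- detect_crosstalk_hyper(profs, db, nets, alpha = 0.05, bh = FALSE)
  ab <- res$pair_tests[res$pair_tests$source == "A" &
                         res$pair_tests$target == "B", ]
  expect_equal(ab[, c("N", "K", "n", "k")],
               data.frame(N = 10L, K = 4L, n = 4L, k = 4L),
               ignore_attr = TRUE)
  expect_equal(ab$p_hyper, oracle_phyper_upper(10, 4, 4, 4), tolerance = 1e-10)
  expect_gte(ab$p_empirical, 1 / 100)
  expect_true(ab$pass)
  ev <- res$events[res$events$source == "A" & res$events$target == "B", ]
  expect_setequal(paste(ev$ligand, ev$receptor),
                  paste(paste0("L", 1:4), paste0("R", 1:4)))
  # K = 0 direction: no ligand of B's list -> k = 0, p = 1, no events
  ba <- res$pair_tests[res$pair_tests$source == "B" &
                         res$pair_tests$target == "A", ]
  expect_equal(ba$k, 0L)
  expect_equal(ba$p_hyper, 1)
  expect_false(ba$pass)
})

test_that("p_hyper is monotone non-increasing in k", {
  p <- vapply(0:6, function(k) oracle_phyper_upper(20, 8, 6, k), 0)
  expect_false(is.unsorted(rev(p)))
  p2 <- vapply(0:6, function(k) {
    stats::phyper(k - 1, 8, 12, 6, lower.tail = FALSE)
  }, 0)
  expect_equal(p2, p, tolerance = 1e-12)
})

test_that("deg-match detector applies the list rule deterministically", {
  genes <- c("L1", "L2", "R1", "R2", "R3A", "R3B", "L3")
  db <- lr_database(data.frame(ligand = c("L1", "L2", "L3"),
                               receptor = c("R1", "R2", "R3"),
                               subunits = c(NA, NA, "R3A,R3B")))
  me <- list(A = stats::setNames(c(5, 4, 1, 1, 3, 2, 3), genes),
             B = stats::setNames(c(1, 1, 6, 2, 3, 1, 1), genes))
  profs <- manual_profiles(list(A = c("L1", "L3"), B = c("R1", "R3A")),
                           genes, mean_expr = me)
  ev <- detect_deg_match(profs, db)
  # L1 in A's list, R1 in B's list -> A->B event; R3 complex misses R3B
  expect_true(any(ev$source == "A" & ev$target == "B" & ev$ligand == "L1"))
  expect_false(any(ev$ligand == "L3"))
  expect_false(any(ev$ligand == "L2")) # not in any list
  expect_false(is.unsorted(rev(ev$mean_strength)))
  expect_error(detect_deg_match(profs, lr_database(
    data.frame(ligand = "X", receptor = "Y"))), "measured")
})

test_that("joint-expression detector gates on the expressed fraction", {
  set.seed(44)
  counts <- matrix(rpois(4 * 200, 3), nrow = 4,
                   dimnames = list(c("L1", "R1", "L2", "R2"), NULL))
  counts["L2", ] <- rbinom(200, 1, 0.05)  # expressed in ~5% of cells
  colnames(counts) <- paste0("c", 1:200)
  m <- count_matrix(counts)
  labels <- rep(c("A", "B"), each = 100)
  db <- lr_database(data.frame(ligand = c("L1", "L2"),
                               receptor = c("R1", "R2")))
  ev <- detect_joint_expression(m, labels, db, n_perm = 100, seed = 1)
  tests <- attr(ev, "tests")
  expect_false(any(tests$ligand == "L2"))   # below the 10% gate, never tested
  expect_true(all(tests$p_value >= 1 / 101))
})

test_that("joint-expression detector finds a planted link", {
  cfg <- simulation_config(
    n_clusters = 3, cells_per_cluster = 100, n_genes = 60, seed = 10,
    planted_links = data.frame(source = "C1", target = "C2",
                               ligand = "G0005", receptor = "G0012",
                               fold = 8))
  sim <- simulate_counts(cfg)
  db <- lr_database(data.frame(ligand = c("G0005", "G0020"),
                               receptor = c("G0012", "G0025")))
  ev <- detect_joint_expression(sim$matrix, sim$matrix$cell_meta$cluster, db,
                                n_perm = 500, seed = 7)
  expect_true(any(ev$source == "C1" & ev$target == "C2" &
                    ev$ligand == "G0005" & ev$receptor == "G0012"))
  # clusters below the size floor are excluded with a warning
  lab <- sim$matrix$cell_meta$cluster
  lab[1:2] <- "tiny"
  lab[lab == "C1"] <- "C1b"
  expect_warning(detect_joint_expression(sim$matrix, lab, db, n_perm = 100,
                                         seed = 1), "tiny")
})

test_that("consensus follows the any-two rule over all membership patterns", {
  ev <- function(on) {
    if (on) data.frame(source = "A", target = "B", ligand = "L",
                       receptor = "R", mean_strength = 1)
    else empty <- data.frame(source = character(), target = character(),
                             ligand = character(), receptor = character(),
                             mean_strength = numeric())
  }
  for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE)) for (cc in c(TRUE, FALSE)) {
    res <- consensus_events(ev(a), ev(b), ev(cc))
    n <- sum(a, b, cc)
    if (n == 0) {
      expect_equal(nrow(res), 0)
    } else {
      expect_equal(res$n_detectors, n)
      expect_identical(res$consensus, n >= 2)
    }
  }
  # symmetric in detector identity: consensus depends only on the count
  one <- consensus_events(ev(TRUE), ev(FALSE), ev(TRUE))
  two <- consensus_events(ev(FALSE), ev(TRUE), ev(TRUE))
  expect_identical(one$consensus, two$consensus)
})
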