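#' Per-cluster expression profiles for communication detection
#'
#' Builds, for every cluster, the gene lists the three communication
#' detectors share: mean normalized expression, the fraction of cells
#' expressing each gene, the expressed-gene gate (fraction >= `expressed_frac`),
#' the highly-expressed gate, and the differentially-expressed gene (DEG) set
#' taken from a marker run (`p_adj < deg_p_adj` and `logFC > deg_logfc`).
#' Gates are applied identically across clusters.
#'
#' @param m a [count_matrix()].
#' @param labels per-cell cluster ids (or a `cell_meta` column name).
#' @param markers a [find_markers()] table, or NULL to use expression gates
#'   only (empty DEG sets).
#' @param deg_p_adj,deg_logfc DEG thresholds.
#' @param expressed_frac expressed-gene gate on the detection fraction.
#' @param high_gate how "highly expressed" is defined: `"quantile"` (mean
#'   normalized expression in the cluster's top `1 - high_quantile` tail),
#'   `"fraction"` (detection fraction >= `expressed_frac`), or `"either"`.
#' @param high_quantile quantile for the expression gate (default 0.9 =
#'   top decile).
#' @param min_cells clusters smaller than this are dropped with a warning.
#' @return A list of class `cluster_profiles`; per cluster: `mean_expr`,
#'   `frac_expr`, `expressed`, `high`, `deg`, `gene_list` (DEG union high)
#'   and `n_cells`.
#' @export
cluster_profiles <- function(m, labels, markers = NULL, deg_p_adj = 0.05,
                             deg_logfc = 0.25, expressed_frac = 0.10,
                             high_gate = c("quantile", "fraction", "either"),
                             high_quantile = 0.9, min_cells = 3L) {
  stopifnot(inherits(m, "count_matrix"))
  high_gate <- match.arg(high_gate)
  if (length(labels) == 1 && !is.null(m$cell_meta) &&
      labels %in% names(m$cell_meta)) {
    labels <- m$cell_meta[[labels]]
  }
  labels <- as.character(labels)
  norm <- normalize_log_cp10k(m)
  tab <- table(labels)
  small <- names(tab)[tab < min_cells]
  if (length(small)) {
    warning("excluding cluster(s) with < ", min_cells, " cells: ",
            paste(small, collapse = ", "))
  }
  keep <- setdiff(names(tab), small)
  profs <- lapply(keep, function(cl) {
    idx <- labels == cl
    mean_expr <- rowMeans(norm[, idx, drop = FALSE])
    frac_expr <- Matrix::rowSums(m$counts[, idx, drop = FALSE] > 0) / sum(idx)
    by_frac <- names(frac_expr)[frac_expr >= expressed_frac]
    by_quant <- names(mean_expr)[mean_expr >=
                                   stats::quantile(mean_expr, high_quantile)]
    high <- switch(high_gate,
                   quantile = by_quant,
                   fraction = by_frac,
                   either = union(by_quant, by_frac))
    deg <- character()
    if (!is.null(markers)) {
      mk <- markers[markers$cluster == cl & markers$p_adj < deg_p_adj &
                      markers$logFC > deg_logfc, ]
      deg <- mk$gene
    }
    list(cluster = cl, n_cells = sum(idx), mean_expr = mean_expr,
         frac_expr = frac_expr, expressed = by_frac, high = high, deg = deg,
         gene_list = union(deg, high))
  })
  names(profs) <- keep
  structure(profs, class = "cluster_profiles", genes = m$gene_ids)
}

# value of a (possibly multi-subunit) receptor in a cluster mean profile:
# the limiting subunit (minimum) carries the complex
receptor_value <- function(mean_expr, subunits) {
  min(mean_expr[subunits])
}

db_measured <- function(db, genes) {
  subs <- receptor_subunits(db)
  ok <- db$pairs$ligand %in% genes &
    vapply(subs, function(s) all(s %in% genes), TRUE)
  list(pairs = db$pairs[ok, , drop = FALSE], subunits = subs[ok])
}

#' Joint-expression permutation detector
#'
#' The first detector: a ligand-receptor pair between an ordered cluster pair
#' is a candidate only when the ligand is expressed in at least
#' `expressed_frac` of source cells and every receptor subunit in at least
#' that fraction of target cells (joint positive expression). The statistic
#' is mean normalized ligand expression in the source plus mean receptor
#' (limiting-subunit) expression in the target; its null is the same
#' statistic under random permutations of the cluster labels, with
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param m a [count_matrix()].
#' @param labels per-cell cluster ids.
#' @param db an [lr_database()].
#' @param n_perm number of label permutations (>= 100).
#' @param alpha significance gate for emitting an event.
#' @param expressed_frac expression gate (default 10% of cells).
#' @param bh apply Benjamini-Hochberg across tested combinations before
#'   gating at `alpha` (default TRUE).
#' @param seed RNG seed for the permutations.
#' @param min_cells clusters smaller than this are excluded with a warning.
#' @return data.frame of emitted events (source, target, ligand, receptor,
#'   p_value, p_adj, mean_strength); the full test table is in
#'   `attr(, "tests")`.
#' @export
detect_joint_expression <- function(m, labels, db, n_perm = 1000L,
                                    alpha = 0.05, expressed_frac = 0.10,
                                    bh = TRUE, seed = 1L, min_cells = 3L) {
  stopifnot(inherits(m, "count_matrix"), inherits(db, "lr_database"),
            n_perm >= 100)
  if (length(labels) == 1 && !is.null(m$cell_meta) &&
      labels %in% names(m$cell_meta)) {
    labels <- m$cell_meta[[labels]]
  }
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < min_cells]
  if (length(small)) {
    warning("excluding cluster(s) with < ", min_cells, " cells: ",
            paste(small, collapse = ", "))
  }
  clusters <- setdiff(names(tab), small)
  if (length(clusters) < 2) stop("need >= 2 clusters of sufficient size")
  use <- labels %in% clusters
  norm <- normalize_log_cp10k(m)[, use, drop = FALSE]
  labels <- labels[use]

  mdb <- db_measured(db, m$gene_ids)
  genes_needed <- unique(c(mdb$pairs$ligand, unlist(mdb$subunits)))
  norm <- norm[genes_needed, , drop = FALSE]
  detected <- norm > 0

  grp <- factor(labels, levels = clusters)
  ind <- stats::model.matrix(~ 0 + grp)
  nsz <- as.numeric(table(grp))
  cl_mean <- sweep(norm %*% ind, 2, nsz, "/")
  cl_frac <- sweep(detected %*% ind, 2, nsz, "/")
  colnames(cl_mean) <- colnames(cl_frac) <- clusters

  # enumerate tested combinations (gates on the observed labels)
  combos <- list()
  for (src in clusters) for (tgt in clusters) {
    for (i in seq_len(nrow(mdb$pairs))) {
      lig <- mdb$pairs$ligand[i]; subs <- mdb$subunits[[i]]
      if (cl_frac[lig, src] >= expressed_frac &&
          all(cl_frac[subs, tgt] >= expressed_frac)) {
        combos[[length(combos) + 1L]] <-
          list(src = src, tgt = tgt, lig = lig,
               rec = mdb$pairs$receptor[i], subs = subs)
      }
    }
  }
  if (!length(combos)) {
    out <- empty_events()
    attr(out, "tests") <- empty_events()
    return(out)
  }
  lig_v <- vapply(combos, `[[`, "", "lig")
  src_v <- vapply(combos, `[[`, "", "src")
  tgt_v <- vapply(combos, `[[`, "", "tgt")
  rec_v <- vapply(combos, `[[`, "", "rec")
  rec_val <- function(M) {
    vapply(seq_along(combos), function(i) {
      receptor_value(M[, tgt_v[i]], combos[[i]]$subs)
    }, 0)
  }
  lig_obs <- cl_mean[cbind(lig_v, src_v)]
  rec_obs <- rec_val(cl_mean)
  obs <- lig_obs + rec_obs

  set.seed(seed)
  exceed <- integer(length(obs))
  for (p in seq_len(n_perm)) {
    perm <- sample(seq_along(labels))
    Mp <- sweep(norm[, perm, drop = FALSE] %*% ind, 2, nsz, "/")
    colnames(Mp) <- clusters
    null_stat <- Mp[cbind(lig_v, src_v)] + rec_val(Mp)
    exceed <- exceed + (null_stat >= obs)
  }
  pval <- (1 + exceed) / (n_perm + 1)
  tests <- data.frame(source = src_v, target = tgt_v, ligand = lig_v,
                      receptor = rec_v, statistic = obs, p_value = pval,
                      p_adj = if (bh) stats::p.adjust(pval, "BH") else pval,
                      mean_strength = (lig_obs + rec_obs) / 2,
                      row.names = NULL)
  events <- tests[tests$p_adj < alpha, , drop = FALSE]
  rownames(events) <- NULL
  attr(events, "tests") <- tests
  events
}

empty_events <- function() {
  data.frame(source = character(), target = character(), ligand = character(),
             receptor = character(), mean_strength = numeric())
}

#' Highly-expressed / DEG matching detector
#'
#' The second detector: deterministic mapping of each cluster's
#' highly-expressed and differentially-expressed genes onto the
#' ligand-receptor database. An event (source, target, L, R) is emitted
#' whenever L belongs to the source's gene list (DEG union highly expressed),
#' every subunit of R belongs to the target's list, and (L, R) is a database
#' pair. Events are ranked by `mean_strength` descending, ties broken
#' lexicographically by (source, target, ligand, receptor).
#'
#' @param profiles a [cluster_profiles()] object.
#' @param db an [lr_database()].
#' @return data.frame of events with `mean_strength`.
#' @export
detect_deg_match <- function(profiles, db) {
  stopifnot(inherits(profiles, "cluster_profiles"), inherits(db, "lr_database"))
  mdb <- db_measured(db, attr(profiles, "genes"))
  if (nrow(mdb$pairs) == 0) stop("no database pair is measured")
  out <- list()
  for (src in names(profiles)) for (tgt in names(profiles)) {
    ps <- profiles[[src]]; pt <- profiles[[tgt]]
    for (i in seq_len(nrow(mdb$pairs))) {
      lig <- mdb$pairs$ligand[i]; subs <- mdb$subunits[[i]]
      if (lig %in% ps$gene_list && all(subs %in% pt$gene_list)) {
        out[[length(out) + 1L]] <- data.frame(
          source = src, target = tgt, ligand = lig,
          receptor = mdb$pairs$receptor[i],
          mean_strength = (ps$mean_expr[lig] +
                             receptor_value(pt$mean_expr, subs)) / 2,
          row.names = NULL)
      }
    }
  }
  if (!length(out)) return(empty_events())
  res <- do.call(rbind, out)
  res <- res[order(-res$mean_strength, res$source, res$target, res$ligand,
                   res$receptor), ]
  rownames(res) <- NULL
  res
}

#' Degree-preserving randomization of the ligand-receptor network
#'
#' Generates `R` randomized replicates of the bipartite ligand -> receptor
#' graph by repeated double-edge swaps (`10 * |pairs|` attempted swaps per
#' replicate), preserving every ligand's out-degree and every receptor's
#' in-degree exactly and never creating duplicate edges. These replicates are
#' the empirical null of the network-mapping test. If the graph admits no
#' valid swap at all (e.g. a saturated bipartite graph), the original network
#' is returned unchanged with a warning.
#'
#' @param db an [lr_database()].
#' @param R number of replicates (default 1000).
#' @param seed RNG seed.
#' @return List of `R` data.frames with columns `ligand`, `receptor`.
#' @export
randomize_lr_network <- function(db, R = 1000L, seed = 1L) {
  stopifnot(inherits(db, "lr_database"))
  lig <- db$pairs$ligand; rec <- db$pairs$receptor
  n_edge <- length(lig)
  if (n_edge < 2 || length(unique(lig)) < 2 || length(unique(rec)) < 2) {
    stop("randomization needs >= 2 pairs with >= 2 distinct ligands and receptors")
  }
  edge_key <- function(l, r) paste(l, r, sep = "\r")
  has_valid_swap <- {
    found <- FALSE
    keys <- edge_key(lig, rec)
    for (i in seq_len(n_edge - 1L)) {
      for (j in (i + 1L):n_edge) {
        if (lig[i] != lig[j] && rec[i] != rec[j] &&
            !(edge_key(lig[i], rec[j]) %in% keys) &&
            !(edge_key(lig[j], rec[i]) %in% keys)) {
          found <- TRUE; break
        }
      }
      if (found) break
    }
    found
  }
  if (!has_valid_swap) {
    warning("network admits no valid double-edge swap; returning it unchanged")
    return(replicate(R, data.frame(ligand = lig, receptor = rec),
                     simplify = FALSE))
  }
  set.seed(seed)
  lapply(seq_len(R), function(rep_i) {
    # odd/even jitter of the attempt count avoids parity trapping on tiny
    # graphs where every attempted swap succeeds
    n_swap <- 10L * n_edge + sample(0:1, 1L)
    l <- lig; r <- rec
    keys <- new.env(hash = TRUE, parent = emptyenv())
    for (k in edge_key(l, r)) assign(k, TRUE, envir = keys)
    for (s in seq_len(n_swap)) {
      ij <- sample.int(n_edge, 2L)
      i <- ij[1L]; j <- ij[2L]
      if (l[i] == l[j] || r[i] == r[j]) next
      k1 <- edge_key(l[i], r[j]); k2 <- edge_key(l[j], r[i])
      if (exists(k1, envir = keys, inherits = FALSE) ||
          exists(k2, envir = keys, inherits = FALSE)) next
      rm(list = c(edge_key(l[i], r[i]), edge_key(l[j], r[j])), envir = keys)
      tmp <- r[i]; r[i] <- r[j]; r[j] <- tmp
      assign(k1, TRUE, envir = keys); assign(k2, TRUE, envir = keys)
    }
    data.frame(ligand = l, receptor = r)
  })
}

#' Hypergeometric / randomized-network communication detector
#'
#' The third detector tests, for every ordered cluster pair, whether the
#' source's gene list (DEG union highly expressed) and the target's list map
#' onto the ligand-receptor network more often than chance. With N the
#' measured database pairs, K of them having their ligand in the source list,
#' n having their receptor (every subunit) in the target list, and k
#' satisfying both, `p_hyper` is the upper-tail hypergeometric probability
#' P(X >= k) and `p_empirical` the +1-corrected fraction of degree-preserving
#' randomized networks whose mapped-pair count reaches k. A cluster pair's
#' mapped ligand-receptor events are emitted only when both gates pass at
#' `alpha`.
#'
#' @param profiles a [cluster_profiles()] object.
#' @param db an [lr_database()].
#' @param randomized list of randomized networks from
#'   [randomize_lr_network()].
#' @param alpha significance gate applied to both p-values.
#' @param bh apply Benjamini-Hochberg across cluster pairs (per p-value
#'   column) before gating (default TRUE).
#' @return List with `events` (emitted ligand-receptor events carrying both
#'   p-values and `mean_strength`) and `pair_tests` (per ordered cluster
#'   pair: N, K, n, k, p_hyper, p_empirical, pass).
#' @export
detect_crosstalk_hyper <- function(profiles, db, randomized, alpha = 0.05,
                                   bh = TRUE) {
  stopifnot(inherits(profiles, "cluster_profiles"), inherits(db, "lr_database"))
  genes <- attr(profiles, "genes")
  mdb <- db_measured(db, genes)
  N <- nrow(mdb$pairs)
  R <- length(randomized)
  clusters <- names(profiles)
  # per-cluster membership of each measured pair's ligand / receptor complex
  lig_in <- vapply(clusters, function(cl) {
    mdb$pairs$ligand %in% profiles[[cl]]$gene_list
  }, logical(N))
  rec_in <- vapply(clusters, function(cl) {
    gl <- profiles[[cl]]$gene_list
    vapply(mdb$subunits, function(s) all(s %in% gl), TRUE)
  }, logical(N))
  if (N == 1) {  # vapply drops to vector
    lig_in <- matrix(lig_in, nrow = 1, dimnames = list(NULL, clusters))
    rec_in <- matrix(rec_in, nrow = 1, dimnames = list(NULL, clusters))
  }
  rand_lig_in <- lapply(randomized, function(net) {
    vapply(clusters, function(cl) {
      net$ligand %in% profiles[[cl]]$gene_list
    }, logical(nrow(net)))
  })
  # a receptor keeps its subunit definition when the network is rewired
  sub_map <- stats::setNames(mdb$subunits, mdb$pairs$receptor)
  rand_rec_in <- lapply(randomized, function(net) {
    subs <- sub_map[net$receptor]
    subs[vapply(subs, is.null, TRUE)] <- as.list(net$receptor[
      vapply(subs, is.null, TRUE)])
    vapply(clusters, function(cl) {
      gl <- profiles[[cl]]$gene_list
      vapply(subs, function(s) all(s %in% gl), TRUE)
    }, logical(nrow(net)))
  })

  pair_tests <- list(); events <- list()
  for (src in clusters) for (tgt in clusters) {
    K <- sum(lig_in[, src]); n_ <- sum(rec_in[, tgt])
    hit <- lig_in[, src] & rec_in[, tgt]
    k <- sum(hit)
    if (K == 0 || n_ == 0) {
      p_hyper <- 1; p_emp <- 1
    } else {
      p_hyper <- stats::phyper(k - 1, K, N - K, n_, lower.tail = FALSE)
      k_rand <- vapply(seq_len(R), function(ri) {
        sum(rand_lig_in[[ri]][, src] & rand_rec_in[[ri]][, tgt])
      }, 0L)
      p_emp <- (1 + sum(k_rand >= k)) / (R + 1)
    }
    pair_tests[[paste(src, tgt)]] <- data.frame(
      source = src, target = tgt, N = N, K = K, n = n_, k = k,
      p_hyper = p_hyper, p_empirical = p_emp, row.names = NULL)
  }
  pt <- do.call(rbind, pair_tests)
  rownames(pt) <- NULL
  ph <- if (bh) stats::p.adjust(pt$p_hyper, "BH") else pt$p_hyper
  pe <- if (bh) stats::p.adjust(pt$p_empirical, "BH") else pt$p_empirical
  pt$pass <- ph < alpha & pe < alpha
  for (i in seq_len(nrow(pt))) {
    if (!pt$pass[i]) next
    src <- pt$source[i]; tgt <- pt$target[i]
    hit <- which(lig_in[, src] & rec_in[, tgt])
    for (h in hit) {
      events[[length(events) + 1L]] <- data.frame(
        source = src, target = tgt, ligand = mdb$pairs$ligand[h],
        receptor = mdb$pairs$receptor[h],
        p_hyper = pt$p_hyper[i], p_empirical = pt$p_empirical[i],
        mean_strength = (profiles[[src]]$mean_expr[mdb$pairs$ligand[h]] +
                           receptor_value(profiles[[tgt]]$mean_expr,
                                          mdb$subunits[[h]])) / 2,
        row.names = NULL)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_events()
  rownames(ev) <- NULL
  list(events = ev, pair_tests = pt)
}

#' Consensus of the three communication detectors
#'
#' Merges the event lists of the joint-expression, DEG-matching and
#' hypergeometric/randomized-network detectors by
#' (source, target, ligand, receptor) key. An event is a high-confidence
#' (consensus) intercellular communication event when at least two detectors
#' report it; consensus therefore depends only on the number of detections,
#' never on which detectors they were. Output is sorted by consensus then
#' `mean_strength`, both descending.
#'
#' @param joint,deg,hyper event data.frames from the three detectors (for
#'   `hyper`, the `$events` element).
#' @return data.frame: source, target, ligand, receptor, detected_by
#'   (comma-joined detector names), n_detectors, consensus, mean_strength.
#' @export
consensus_events <- function(joint, deg, hyper) {
  key <- function(d) {
    if (!nrow(d)) return(character())
    paste(d$source, d$target, d$ligand, d$receptor, sep = "\r")
  }
  lists <- list(joint_expression = joint, deg_match = deg,
                crosstalk_hyper = hyper)
  keys <- unique(unlist(lapply(lists, key)))
  if (!length(keys)) {
    return(cbind(empty_events(), data.frame(detected_by = character(),
                                            n_detectors = integer(),
                                            consensus = logical())))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  membership <- vapply(lists, function(d) keys %in% key(d), logical(length(keys)))
  if (length(keys) == 1) membership <- matrix(membership, nrow = 1,
                                              dimnames = list(NULL, names(lists)))
  strength <- rep(NA_real_, length(keys))
  for (d in lists) {
    if (!nrow(d) || !"mean_strength" %in% names(d)) next
    idx <- match(key(d), keys)
    strength[idx] <- ifelse(is.na(strength[idx]), d$mean_strength,
                            strength[idx])
  }
  n_det <- rowSums(membership)
  res <- data.frame(source = parts[, 1], target = parts[, 2],
                    ligand = parts[, 3], receptor = parts[, 4],
                    detected_by = apply(membership, 1, function(b) {
                      paste(names(lists)[b], collapse = ",")
                    }),
                    n_detectors = as.integer(n_det),
                    consensus = n_det >= 2,
                    mean_strength = strength, row.names = NULL)
  res <- res[order(-res$consensus, -res$mean_strength, res$source, res$target,
                   res$ligand, res$receptor), ]
  rownames(res) <- NULL
  res
}

#' Run the full three-detector consensus framework
#'
#' Convenience wrapper: computes markers (unless supplied), builds cluster
#' profiles, runs the three detectors with a shared seed, and merges them
#' with [consensus_events()].
#'
#' @param m a [count_matrix()].
#' @param labels per-cell cluster ids.
#' @param db an [lr_database()].
#' @param markers optional precomputed [find_markers()] table.
#' @param n_perm label permutations for the joint-expression detector.
#' @param n_random randomized networks for the hypergeometric detector.
#' @param alpha significance gate shared by the stochastic detectors.
#' @param bh Benjamini-Hochberg within each detector.
#' @param seed global seed; detector substreams are derived from it.
#' @param ... passed to [cluster_profiles()].
#' @return List: `consensus`, `joint`, `deg`, `hyper` (with `$pair_tests`),
#'   `profiles`, `markers`.
#' @export
run_crosstalk <- function(m, labels, db, markers = NULL, n_perm = 1000L,
                          n_random = 1000L, alpha = 0.05, bh = TRUE,
                          seed = 1L, ...) {
  if (is.null(markers)) markers <- find_markers(m, labels)
  profiles <- cluster_profiles(m, labels, markers, ...)
  joint <- detect_joint_expression(m, labels, db, n_perm = n_perm,
                                   alpha = alpha, bh = bh,
                                   seed = derive_seed(seed, "joint"))
  deg <- detect_deg_match(profiles, db)
  rand <- randomize_lr_network(db, R = n_random,
                               seed = derive_seed(seed, "network"))
  hyper <- detect_crosstalk_hyper(profiles, db, rand, alpha = alpha, bh = bh)
  list(consensus = consensus_events(joint, deg, hyper$events),
       joint = joint, deg = deg, hyper = hyper, profiles = profiles,
       markers = markers)
}
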