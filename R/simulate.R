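#' Configuration of the synthetic-data generator
#'
#' The generator emulates the statistical structure every downstream stage
#' assumes: negative-binomial UMI counts over K clusters with cluster-specific
#' marker programs, a controllable expected mitochondrial count fraction per
#' cell, planted ligand-receptor co-expression between chosen cluster pairs,
#' origin-signature abundance gradients across samples, and somatic variant
#' tables with configurable subclone sharing and substitution spectrum.
#'
#' Counts are drawn NB(mu, size = 1/nb_dispersion), i.e.
#' `var = mu + nb_dispersion * mu^2`. Per-gene baseline means are drawn
#' log-normally around `baseline_mean` (`gene_mean_sdlog` controls spread) so
#' that expression ranks differ across genes as in real data; cluster, marker,
#' planted-link and origin-gradient multipliers then scale those means.
#'
#' @param n_clusters number of cell clusters (>= 1).
#' @param cells_per_cluster integer scalar or vector of length `n_clusters`.
#' @param n_genes total genes, including the mitochondrial/ribosomal blocks.
#' @param baseline_mean expected NB mean of a baseline gene (UMI per cell).
#' @param nb_dispersion NB dispersion shared across genes (> 0).
#' @param gene_mean_sdlog sdlog of the log-normal gene-mean draw (0 = all
#'   genes share `baseline_mean`).
#' @param marker_spec data.frame(cluster, gene, fold) of planted per-cluster
#'   marker fold-ups (fold > 0).
#' @param mito_fraction target expected mitochondrial count fraction per cell,
#'   in [0, 1); scalar or per-cluster vector.
#' @param n_mito_genes,n_ribo_genes sizes of the designated mitochondrial
#'   ("MT-" prefixed) and ribosomal ("RPS" prefixed) gene blocks.
#' @param planted_links data.frame(source, target, ligand, receptor, fold):
#'   ligand fold-up in the source cluster and receptor fold-up in the target
#'   cluster.
#' @param n_samples number of samples; cells are assigned to samples in a
#'   balanced round-robin within each cluster.
#' @param origin_gradient NULL, or a list with `genes_I`, `genes_IX`
#'   (character vectors of signature genes) and `multiplier_I`,
#'   `multiplier_IX` (per-sample positive multipliers, length `n_samples`).
#' @param variant_spec list controlling [simulate_variants()]:
#'   `n_samples`, `n_subclones`, `n_shared` and `n_private` (scalar or
#'   per-sample vectors; `n_private` is per subclone), `spectrum` (named
#'   weights over the six pyrimidine-centric classes), `genome_size_mb`.
#' @param seed integer global seed; per-stage substreams are derived from it
#'   so stages can be re-run independently and reproducibly.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_clusters = 3,
                              cells_per_cluster = 200,
                              n_genes = 200,
                              baseline_mean = 2,
                              nb_dispersion = 0.5,
                              gene_mean_sdlog = 0.5,
                              marker_spec = NULL,
                              mito_fraction = 0.05,
                              n_mito_genes = 10,
                              n_ribo_genes = 0,
                              planted_links = NULL,
                              n_samples = 1,
                              origin_gradient = NULL,
                              variant_spec = list(),
                              seed = 1L) {
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  cells_per_cluster <- rep_len(as.integer(cells_per_cluster), n_clusters)
  mito_fraction <- rep_len(mito_fraction, n_clusters)
  if (any(mito_fraction < 0 | mito_fraction >= 1)) {
    stop("mito_fraction must lie in [0, 1)")
  }
  if (baseline_mean <= 0 || nb_dispersion <= 0) {
    stop("baseline_mean and nb_dispersion must be positive")
  }
  if (n_mito_genes + n_ribo_genes >= n_genes) {
    stop("flagged gene blocks must leave at least one baseline gene")
  }
  gene_ids <- c(sprintf("G%04d", seq_len(n_genes - n_mito_genes - n_ribo_genes)),
                if (n_ribo_genes) sprintf("RPS%02d", seq_len(n_ribo_genes)),
                if (n_mito_genes) sprintf("MT-G%02d", seq_len(n_mito_genes)))
  check_fold <- function(d, cols) {
    if (is.null(d)) return(NULL)
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    stopifnot(all(cols %in% names(d)))
    if (any(d$fold <= 0)) stop("all multipliers must be > 0")
    for (g in intersect(cols, c("gene", "ligand", "receptor"))) {
      if (!all(d[[g]] %in% gene_ids)) {
        stop("planted gene not among simulated genes: ",
             setdiff(d[[g]], gene_ids)[1])
      }
    }
    d
  }
  marker_spec <- check_fold(marker_spec, c("cluster", "gene", "fold"))
  planted_links <- check_fold(planted_links,
                              c("source", "target", "ligand", "receptor", "fold"))
  if (!is.null(origin_gradient)) {
    stopifnot(all(c("genes_I", "genes_IX", "multiplier_I", "multiplier_IX") %in%
                    names(origin_gradient)))
    origin_gradient$multiplier_I <-
      rep_len(origin_gradient$multiplier_I, n_samples)
    origin_gradient$multiplier_IX <-
      rep_len(origin_gradient$multiplier_IX, n_samples)
    if (any(origin_gradient$multiplier_I <= 0) ||
        any(origin_gradient$multiplier_IX <= 0)) {
      stop("all multipliers must be > 0")
    }
  }
  structure(list(n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
                 n_genes = n_genes, gene_ids = gene_ids,
                 baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
                 gene_mean_sdlog = gene_mean_sdlog, marker_spec = marker_spec,
                 mito_fraction = mito_fraction, n_mito_genes = n_mito_genes,
                 n_ribo_genes = n_ribo_genes, planted_links = planted_links,
                 n_samples = n_samples, origin_gradient = origin_gradient,
                 variant_spec = variant_spec, seed = as.integer(seed)),
            class = "simulation_config")
}

# Stable per-stage substream: fold a tag into the global seed so stages can be
# re-run independently without sharing RNG state. Kept below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Simulate a UMI count matrix with planted structure
#'
#' Draws negative-binomial counts with cluster/marker/planted-link/origin
#' multipliers applied to log-normally drawn per-gene baseline means, and
#' scales the designated mitochondrial gene block so each cell hits its
#' cluster's target mitochondrial fraction in expectation. Identical seed
#' implies identical output.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `matrix` (a [count_matrix()] whose `cell_meta`
#'   carries `cluster` and `sample`) and `truth` (a list recording the
#'   expected mean of every gene in every (cluster, sample) stratum plus the
#'   planted marker and link tables).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "counts"))
  G <- config$n_genes
  gene_ids <- config$gene_ids
  is_mito <- startsWith(gene_ids, "MT-")
  base_mean <- config$baseline_mean *
    exp(stats::rnorm(G, -config$gene_mean_sdlog^2 / 2, config$gene_mean_sdlog))
  names(base_mean) <- gene_ids

  clusters <- paste0("C", seq_len(config$n_clusters))
  # per-cluster mean profile before mito scaling
  mu_cluster <- matrix(base_mean, nrow = G, ncol = config$n_clusters,
                       dimnames = list(gene_ids, clusters))
  if (!is.null(config$marker_spec)) {
    for (i in seq_len(nrow(config$marker_spec))) {
      ms <- config$marker_spec[i, ]
      mu_cluster[ms$gene, as.character(ms$cluster)] <-
        mu_cluster[ms$gene, as.character(ms$cluster)] * ms$fold
    }
  }
  if (!is.null(config$planted_links)) {
    for (i in seq_len(nrow(config$planted_links))) {
      pl <- config$planted_links[i, ]
      mu_cluster[pl$ligand, as.character(pl$source)] <-
        mu_cluster[pl$ligand, as.character(pl$source)] * pl$fold
      mu_cluster[pl$receptor, as.character(pl$target)] <-
        mu_cluster[pl$receptor, as.character(pl$target)] * pl$fold
    }
  }
  # mito block scaled so that E[mito counts] / E[total counts] = target
  for (j in seq_len(config$n_clusters)) {
    f <- config$mito_fraction[j]
    non_mito_total <- sum(mu_cluster[!is_mito, j])
    mu_cluster[is_mito, j] <- if (f == 0 || !any(is_mito)) 0 else {
      prof <- base_mean[is_mito] / sum(base_mean[is_mito])
      prof * (f / (1 - f)) * non_mito_total
    }
  }

  samples <- paste0("S", seq_len(config$n_samples))
  cluster_of <- rep(clusters, config$cells_per_cluster)
  n_cells <- length(cluster_of)
  sample_of <- unlist(lapply(config$cells_per_cluster, function(nc) {
    samples[((seq_len(nc) - 1L) %% config$n_samples) + 1L]
  }))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))

  # per-sample origin-signature multipliers on top of the cluster profile
  og <- config$origin_gradient
  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, nrow = G, ncol = n_cells,
                   dimnames = list(gene_ids, cell_ids))
  truth_means <- list()
  for (cl in clusters) for (s in samples) {
    idx <- which(cluster_of == cl & sample_of == s)
    if (!length(idx)) next
    mu <- mu_cluster[, cl]
    if (!is.null(og)) {
      k <- match(s, samples)
      mu[og$genes_I] <- mu[og$genes_I] * og$multiplier_I[k]
      mu[og$genes_IX] <- mu[og$genes_IX] * og$multiplier_IX[k]
    }
    counts[, idx] <- stats::rnbinom(G * length(idx), mu = mu, size = size)
    truth_means[[paste(cl, s, sep = ".")]] <-
      data.frame(cluster = cl, sample = s, gene = gene_ids, mean = unname(mu))
  }

  m <- count_matrix(counts,
                    cell_meta = data.frame(sample = sample_of,
                                           cluster = cluster_of))
  list(matrix = m,
       truth = list(gene_means = do.call(rbind, c(truth_means,
                                                  make.row.names = FALSE)),
                    markers = config$marker_spec,
                    links = config$planted_links,
                    mito_genes = gene_ids[is_mito]))
}

#' Simulate somatic variant tables with subclone sharing structure
#'
#' For each sample, draws `n_shared` variants present in every subclone and
#' `n_private` variants private to each subclone; the bulk level is the union
#' of the subclone records, mirroring the convention that aspirate-level calls
#' subsume subclone-attributed calls. Substitution classes are drawn from the
#' configured pyrimidine-centric mixture; each record's reference strand is
#' chosen at random so that reverse-complement collapsing is exercised.
#'
#' @param config a [simulation_config()]; its `variant_spec` entries override
#'   the defaults (2 samples, 3 subclones, 5 shared, 3 private per subclone,
#'   uniform spectrum, 3100 Mb genome).
#' @return A list with `variants` (a [variant_set()]) and `truth` (data.frame
#'   sample, key, type in {shared, private}, subclone).
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  vs <- config$variant_spec
  spec <- utils::modifyList(
    list(n_samples = 2L, n_subclones = 3L, n_shared = 5L, n_private = 3L,
         spectrum = c("C>A" = 1, "C>G" = 1, "C>T" = 1,
                      "T>A" = 1, "T>C" = 1, "T>G" = 1),
         genome_size_mb = 3100), vs)
  if (spec$n_subclones < 1) stop("at least one subclone is required")
  set.seed(derive_seed(config$seed, "variants"))
  n_shared <- rep_len(spec$n_shared, spec$n_samples)
  n_private <- rep_len(spec$n_private, spec$n_samples)
  w <- spec$spectrum[c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")]
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("substitution spectrum has no mass")
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  recs <- list(); truth <- list()
  for (si in seq_len(spec$n_samples)) {
    smp <- paste0("P", si)
    subclones <- paste0("subclone:K", seq_len(spec$n_subclones))
    n_var <- n_shared[si] + n_private[si] * spec$n_subclones
    if (n_var == 0) next
    pos <- sample.int(1e8, n_var)
    chrom <- paste0("chr", sample(1:22, n_var, replace = TRUE))
    cls <- sample(names(w), n_var, replace = TRUE, prob = w / sum(w))
    ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
    flip <- stats::runif(n_var) < 0.5   # report on the purine strand half the time
    ref[flip] <- comp[ref[flip]]; alt[flip] <- comp[alt[flip]]
    owner <- c(rep(NA_character_, n_shared[si]),
               rep(subclones, each = n_private[si]))
    for (i in seq_len(n_var)) {
      levels <- if (is.na(owner[i])) subclones else owner[i]
      recs[[length(recs) + 1L]] <-
        data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt[i],
                   sample = smp, level = c(levels, "bulk"))
      truth[[length(truth) + 1L]] <-
        data.frame(sample = smp,
                   key = paste(chrom[i], pos[i], ref[i], alt[i], sep = ":"),
                   type = if (is.na(owner[i])) "shared" else "private",
                   subclone = if (is.na(owner[i])) NA_character_ else owner[i])
    }
  }
  list(variants = variant_set(do.call(rbind, recs), spec$genome_size_mb),
       truth = do.call(rbind, truth))
}
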