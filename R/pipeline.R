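#' Pipeline configuration
#'
#' One configuration object drives every stage. It can be built in code or
#' read from a JSON file (`read_pipeline_config()`); per-stage RNG substreams
#' are derived from the single global seed by stable hashing, so individual
#' stages can be re-run independently and reproducibly.
#'
#' @param counts_path path to the count matrix (directory for `mtx_triplet`,
#'   file for `dense_tsv`).
#' @param counts_dialect `"mtx_triplet"` or `"dense_tsv"`.
#' @param labels_path optional TSV (columns `cell`, `cluster`) with cluster
#'   labels; when NULL the `cluster` column of the cell metadata is used.
#' @param lr_db_path ligand-receptor database TSV (crosstalk stage).
#' @param variants_path variant TSV/VCF (burden stage).
#' @param out_dir output directory for stage TSVs and the run manifest.
#' @param qc a [qc_thresholds()].
#' @param crosstalk list of detector parameters (`alpha`, `n_perm`,
#'   `n_random`, `bh`, `expressed_frac`).
#' @param origin list with `type_I_cluster`, `type_IX_cluster`, `logfc_min`,
#'   `positivity`.
#' @param heterogeneity list with `d` (PCs), `grid_rows`, `grid_cols`,
#'   `epochs`.
#' @param genome_size_mb megabases of assayed genome (burden stage).
#' @param seed global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_path = NULL,
                            counts_dialect = "mtx_triplet",
                            labels_path = NULL, lr_db_path = NULL,
                            variants_path = NULL, out_dir = "clonescape_out",
                            qc = qc_thresholds(),
                            crosstalk = list(), origin = list(),
                            heterogeneity = list(),
                            genome_size_mb = NULL, seed = 1L) {
  crosstalk <- utils::modifyList(
    list(alpha = 0.05, n_perm = 1000L, n_random = 1000L, bh = TRUE,
         expressed_frac = 0.10), crosstalk)
  origin <- utils::modifyList(
    list(type_I_cluster = NULL, type_IX_cluster = NULL, logfc_min = 1,
         positivity = "cohort_median"), origin)
  heterogeneity <- utils::modifyList(
    list(d = 30L, grid_rows = 10L, grid_cols = 10L, epochs = 100L),
    heterogeneity)
  structure(list(counts_path = counts_path, counts_dialect = counts_dialect,
                 labels_path = labels_path, lr_db_path = lr_db_path,
                 variants_path = variants_path, out_dir = out_dir, qc = qc,
                 crosstalk = crosstalk, origin = origin,
                 heterogeneity = heterogeneity,
                 genome_size_mb = genome_size_mb, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$qc)) raw$qc <- do.call(qc_thresholds, raw$qc)
  do.call(pipeline_config, raw)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

log_stage <- function(stage, msg) {
  message(sprintf("[clonescape] [%s] %s", stage, msg))
}

#' Run the pipeline
#'
#' Executes the requested stages in order, writing each stage's TSV outputs
#' under `config$out_dir` plus a JSON run manifest recording the parameters,
#' the seed, md5 digests of every input file and the outputs written. Stage
#' dependencies are enforced: `markers` must precede `crosstalk`, `origin`
#' and `heterogeneity`. Rerunning with an identical configuration reproduces
#' identical outputs (stochastic stages included, through the seed).
#'
#' @param config a [pipeline_config()].
#' @param stages ordered subset of `c("qc", "markers", "crosstalk", "origin",
#'   "heterogeneity", "burden")`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("qc", "markers", "crosstalk", "origin",
                                    "heterogeneity", "burden")) {
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("qc", "markers", "crosstalk", "origin", "heterogeneity", "burden")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  needs_markers <- intersect(stages, c("crosstalk", "origin", "heterogeneity"))
  if (length(needs_markers) && !"markers" %in% stages) {
    stop("stage(s) ", paste(needs_markers, collapse = ", "),
         " require the 'markers' stage")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character()
  m <- NULL
  need_counts <- any(stages != "burden")
  if (need_counts) {
    if (is.null(config$counts_path)) stop("config field 'counts_path' is unset")
    m <- read_count_matrix(config$counts_path, config$counts_dialect)
    if (!is.null(config$labels_path)) {
      lab <- utils::read.table(config$labels_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      if (!"cell" %in% names(lab)) stop("labels file needs a 'cell' column")
      meta <- if (is.null(m$cell_meta)) {
        data.frame(row.names = m$cell_ids)
      } else m$cell_meta
      # every non-key column (cluster, sample, condition, ...) is attached
      for (col in setdiff(names(lab), "cell")) {
        meta[[col]] <- lab[[col]][match(m$cell_ids, lab$cell)]
      }
      m$cell_meta <- meta
    }
  }
  markers <- NULL
  for (stage in stages) {
    if (stage == "qc") {
      log_stage("qc", "filtering cells and genes")
      qc <- filter_cells_genes(m, config$qc)
      outputs <- c(outputs,
                   write_tsv(qc$cell_report,
                             file.path(config$out_dir, "qc_cells.tsv")),
                   write_tsv(qc$gene_report,
                             file.path(config$out_dir, "qc_genes.tsv")))
      m <- qc$matrix
      results$qc <- qc
    } else if (stage == "markers") {
      labels <- pipeline_labels(m)
      log_stage("markers", "one-vs-rest Wilcoxon marker detection")
      markers <- find_markers(m, labels)
      outputs <- c(outputs, write_tsv(markers,
                                      file.path(config$out_dir, "markers.tsv")))
      results$markers <- markers
    } else if (stage == "crosstalk") {
      if (is.null(config$lr_db_path)) stop("config field 'lr_db_path' is unset")
      db <- read_lr_database(config$lr_db_path)
      ck <- config$crosstalk
      log_stage("crosstalk", "three-detector consensus framework")
      res <- run_crosstalk(m, pipeline_labels(m), db, markers = markers,
                           n_perm = ck$n_perm, n_random = ck$n_random,
                           alpha = ck$alpha, bh = ck$bh,
                           seed = derive_seed(config$seed, "crosstalk"),
                           expressed_frac = ck$expressed_frac)
      outputs <- c(outputs,
                   write_tsv(res$consensus,
                             file.path(config$out_dir, "events.tsv")),
                   write_tsv(res$hyper$pair_tests,
                             file.path(config$out_dir, "pair_tests.tsv")))
      results$crosstalk <- res
    } else if (stage == "origin") {
      og <- config$origin
      if (is.null(og$type_I_cluster) || is.null(og$type_IX_cluster)) {
        stop("config fields origin$type_I_cluster / type_IX_cluster are unset")
      }
      log_stage("origin", "dominance scoring and four-class typing")
      sets <- extract_origin_markers(markers, og$type_I_cluster,
                                     og$type_IX_cluster,
                                     logfc_min = og$logfc_min)
      cohort <- t(pseudobulk(m, pipeline_samples(m)))
      scores <- type_origin(cohort, sets$type_I, sets$type_IX,
                            positivity = og$positivity)
      outputs <- c(outputs,
                   write_tsv(scores,
                             file.path(config$out_dir, "origin_scores.tsv")))
      results$origin <- scores
    } else if (stage == "heterogeneity") {
      ht <- config$heterogeneity
      log_stage("heterogeneity", "Pi matrix, SOM and diversity score")
      pi_mat <- compute_pi_matrix(markers)
      som <- train_som(pi_mat, ht$grid_rows, ht$grid_cols, ht$epochs,
                       seed = derive_seed(config$seed, "som"))
      emb <- pca_embedding(m, d = ht$d)
      div <- diversity_score(emb, pipeline_samples(m))
      outputs <- c(outputs,
                   write_tsv(data.frame(gene = rownames(pi_mat), pi_mat,
                                        check.names = FALSE),
                             file.path(config$out_dir, "pi_matrix.tsv")),
                   write_tsv(som$assignment,
                             file.path(config$out_dir, "som_assignments.tsv")),
                   write_tsv(div, file.path(config$out_dir, "diversity.tsv")))
      results$heterogeneity <- list(pi = pi_mat, som = som, diversity = div)
    } else if (stage == "burden") {
      if (is.null(config$variants_path)) {
        stop("config field 'variants_path' is unset")
      }
      if (is.null(config$genome_size_mb)) {
        stop("config field 'genome_size_mb' is unset")
      }
      log_stage("burden", "TMB, spectrum and sharing partition")
      v <- read_variants(config$variants_path, config$genome_size_mb)
      tmb <- compute_tmb(v)
      spec <- substitution_spectrum(v)
      outputs <- c(outputs,
                   write_tsv(tmb, file.path(config$out_dir, "tmb.tsv")),
                   write_tsv(spec, file.path(config$out_dir, "spectrum.tsv")))
      sharing <- list()
      for (smp in unique(v$records$sample)) {
        subs <- unique(v$records$level[v$records$sample == smp &
                                         startsWith(v$records$level,
                                                    "subclone:")])
        if (length(subs) >= 2) {
          part <- partition_sharing(v, smp)
          sharing[[smp]] <- part
          pres <- data.frame(variant = rownames(part$presence),
                             part$presence, check.names = FALSE)
          outputs <- c(outputs,
                       write_tsv(pres, file.path(config$out_dir,
                                                 paste0("sharing_", smp,
                                                        ".tsv"))))
        }
      }
      results$burden <- list(tmb = tmb, spectrum = spec, sharing = sharing)
    }
  }
  inputs <- Filter(Negate(is.null),
                   list(counts = config$counts_path,
                        labels = config$labels_path,
                        lr_db = config$lr_db_path,
                        variants = config$variants_path))
  file_inputs <- unlist(lapply(inputs, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE) else p
  }))
  manifest <- list(
    package = "clonescape",
    version = as.character(utils::packageVersion("clonescape")),
    stages = stages, seed = config$seed,
    parameters = config[c("qc", "crosstalk", "origin", "heterogeneity",
                          "genome_size_mb")],
    input_digests = as.list(tools::md5sum(file_inputs)),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}

pipeline_samples <- function(m) {
  if (is.null(m$cell_meta) || !"sample" %in% names(m$cell_meta)) {
    stop("sample identities required: supply a 'sample' column in the ",
         "labels file or cell metadata")
  }
  m$cell_meta$sample
}

pipeline_labels <- function(m) {
  if (is.null(m$cell_meta) || !"cluster" %in% names(m$cell_meta)) {
    stop("cluster labels required: supply labels_path or a 'cluster' ",
         "cell-metadata column")
  }
  m$cell_meta$cluster
}
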