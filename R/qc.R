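#' Cell and gene quality-control thresholds
#'
#' Defaults follow the common droplet scRNA-seq gates: a cell is kept when it
#' has at least 1000 UMIs mapped to at least 200 unique genes and at most 10%
#' of its counts on mitochondrial/ribosomal genes (strictly more than 10% is
#' removed); a gene is kept when it is expressed in more than three retained
#' cells (strict greater-than).
#'
#' @param min_umis minimum UMI total per cell (inclusive).
#' @param min_genes minimum detected genes per cell (inclusive).
#' @param min_cells_per_gene genes must be expressed in strictly more than
#'   this many retained cells.
#' @param max_mito_ribo_fraction cells with a strictly larger
#'   mitochondrial+ribosomal count fraction are removed.
#' @param mito_ribo_rule `"joint"` applies the fraction threshold to the sum
#'   of mitochondrial and ribosomal counts; `"separate"` applies it to each
#'   fraction on its own.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umis = 1000L, min_genes = 200L,
                          min_cells_per_gene = 3L,
                          max_mito_ribo_fraction = 0.10,
                          mito_ribo_rule = c("joint", "separate")) {
  stopifnot(min_umis >= 0, min_genes >= 0, min_cells_per_gene >= 0,
            max_mito_ribo_fraction >= 0, max_mito_ribo_fraction <= 1)
  structure(list(min_umis = as.integer(min_umis),
                 min_genes = as.integer(min_genes),
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 max_mito_ribo_fraction = max_mito_ribo_fraction,
                 mito_ribo_rule = match.arg(mito_ribo_rule)),
            class = "qc_thresholds")
}

#' Filter cells and genes by quality thresholds
#'
#' Cells are filtered first (UMI total, detected genes, mitochondrial/
#' ribosomal fraction); the gene-prevalence filter is then evaluated on the
#' retained cell population, so removing a failing cell can only affect other
#' cells through gene prevalence. Filtering is idempotent.
#'
#' @param m a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return A list of class `qc_result`: `matrix` (the filtered
#'   [count_matrix()]), `cell_report` (cell, n_umis, n_genes, mito_ribo_frac,
#'   kept, reason), `gene_report` (gene, n_cells_expressing, kept). An empty
#'   result after filtering raises a warning, not an error.
#' @export
filter_cells_genes <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  n_umis <- Matrix::colSums(m$counts)
  n_genes <- Matrix::colSums(m$counts > 0)
  flagged <- m$gene_flags$is_mitochondrial | m$gene_flags$is_ribosomal
  mito_frac <- Matrix::colSums(m$counts[m$gene_flags$is_mitochondrial, ,
                                        drop = FALSE]) / pmax(n_umis, 1)
  ribo_frac <- Matrix::colSums(m$counts[m$gene_flags$is_ribosomal, ,
                                        drop = FALSE]) / pmax(n_umis, 1)
  joint_frac <- Matrix::colSums(m$counts[flagged, , drop = FALSE]) /
    pmax(n_umis, 1)
  frac_fail <- if (thresholds$mito_ribo_rule == "joint") {
    joint_frac > thresholds$max_mito_ribo_fraction
  } else {
    mito_frac > thresholds$max_mito_ribo_fraction |
      ribo_frac > thresholds$max_mito_ribo_fraction
  }
  fail_umis <- n_umis < thresholds$min_umis
  fail_genes <- n_genes < thresholds$min_genes
  keep_cell <- !(fail_umis | fail_genes | frac_fail)
  reason <- mapply(function(u, g, f) {
    r <- c(if (u) "low_umis", if (g) "low_genes", if (f) "high_mito_ribo")
    if (is.null(r)) "" else paste(r, collapse = ",")
  }, fail_umis, fail_genes, frac_fail)
  cell_report <- data.frame(cell = m$cell_ids, n_umis = n_umis,
                            n_genes = n_genes, mito_ribo_frac = joint_frac,
                            kept = keep_cell, reason = reason,
                            row.names = NULL)
  kept_cells <- m$cell_ids[keep_cell]
  prevalence <- Matrix::rowSums(m$counts[, kept_cells, drop = FALSE] > 0)
  keep_gene <- prevalence > thresholds$min_cells_per_gene
  gene_report <- data.frame(gene = m$gene_ids, n_cells_expressing = prevalence,
                            kept = keep_gene, row.names = NULL)
  if (!any(keep_cell) || !any(keep_gene)) {
    warning("QC filtering removed all ",
            if (!any(keep_cell)) "cells" else "genes")
  }
  out <- subset_count_matrix(m, genes = m$gene_ids[keep_gene],
                             cells = kept_cells)
  structure(list(matrix = out, cell_report = cell_report,
                 gene_report = gene_report, thresholds = thresholds),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("qc_result: kept ", sum(x$cell_report$kept), "/",
      nrow(x$cell_report), " cells and ", sum(x$gene_report$kept), "/",
      nrow(x$gene_report), " genes\n", sep = "")
  invisible(x)
}

#' Gate malignant plasma cells by immunophenotype
#'
#' Calls a cell malignant when every positive-gate gene is expressed and every
#' negative-gate gene is silent, mirroring surface-marker gating (the default
#' myeloma gate is CD38+CD56+CD138+CD19-CD20-, i.e. positive = CD38, NCAM1,
#' SDC1 and negative = CD19, MS4A1; the CD20+ variant moves MS4A1 to the
#' positive list). Positivity defaults to raw count > 0; a normalized-
#' expression threshold can be used instead.
#'
#' @param m a [count_matrix()].
#' @param positive,negative character vectors of gate genes; all must be
#'   present in the matrix.
#' @param mode `"count"` (positive = raw count > 0) or `"normalized"`
#'   (positive = log-CP10k expression > `threshold`).
#' @param threshold numeric cutoff for `mode = "normalized"`.
#' @return A named logical vector over cells: `TRUE` = called malignant.
#' @export
gate_malignant <- function(m, positive, negative = character(),
                           mode = c("count", "normalized"), threshold = 0) {
  stopifnot(inherits(m, "count_matrix"))
  mode <- match.arg(mode)
  missing <- setdiff(c(positive, negative), m$gene_ids)
  if (length(missing)) {
    stop("gate gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  expr <- if (mode == "count") m$counts > 0 else
    normalize_log_cp10k(m) > threshold
  pos_ok <- if (length(positive)) {
    Matrix::colSums(expr[positive, , drop = FALSE]) == length(positive)
  } else rep(TRUE, length(m$cell_ids))
  neg_ok <- if (length(negative)) {
    Matrix::colSums(expr[negative, , drop = FALSE]) == 0
  } else rep(TRUE, length(m$cell_ids))
  stats::setNames(as.logical(pos_ok & neg_ok), m$cell_ids)
}
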