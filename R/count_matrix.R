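#' Gene x cell UMI count matrix with annotations
#'
#' The central container of the pipeline: a sparse gene x cell matrix of
#' non-negative integer UMI counts, together with per-cell metadata and
#' per-gene mitochondrial/ribosomal flags. All downstream stages (QC, marker
#' detection, signature scoring, crosstalk) operate on this object. Matrices
#' are always indexed by identifier, never by file order, so stage outputs are
#' stable under row shuffling of the inputs.
#'
#' @param counts gene x cell matrix (base or \pkg{Matrix} sparse) of
#'   non-negative integer counts.
#' @param gene_ids character vector of unique gene symbols (rows). Defaults to
#'   `rownames(counts)`.
#' @param cell_ids character vector of unique cell barcodes (columns).
#'   Defaults to `colnames(counts)`.
#' @param cell_meta data.frame of per-cell annotations (e.g. `sample`,
#'   `condition`, `cluster`), one row per cell. May be `NULL`.
#' @param gene_flags data.frame with logical columns `is_mitochondrial` and
#'   `is_ribosomal`, one row per gene. When `NULL`, flags are derived from
#'   `mito_prefix` / `ribo_prefix`.
#' @param mito_prefix,ribo_prefix symbol prefixes used to flag mitochondrial
#'   and ribosomal genes when `gene_flags` is not supplied. The defaults
#'   ("MT-" and "RPS"/"RPL") are the usual human annotation convention; pass
#'   explicit `gene_flags` to override for other annotations.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `gene_ids`, `cell_ids`, `cell_meta`, `gene_flags`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts), cell_meta = NULL,
                         gene_flags = NULL,
                         mito_prefix = "MT-", ribo_prefix = c("RPS", "RPL")) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (set dimnames or pass explicitly)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids)) {
    stop("counts dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match gene_ids/cell_ids lengths (",
         length(gene_ids), ", ", length(cell_ids), ")")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:3], collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicated cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)])[1:3], collapse = ", "))
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (is.null(gene_flags)) {
    gene_flags <- data.frame(
      is_mitochondrial = startsWith_any(gene_ids, mito_prefix),
      is_ribosomal = startsWith_any(gene_ids, ribo_prefix),
      row.names = gene_ids
    )
  } else {
    gene_flags <- as.data.frame(gene_flags)
    if (nrow(gene_flags) != length(gene_ids)) {
      stop("gene_flags must have one row per gene")
    }
    for (col in c("is_mitochondrial", "is_ribosomal")) {
      if (!col %in% names(gene_flags) || !is.logical(gene_flags[[col]])) {
        stop("gene_flags needs logical column '", col, "'")
      }
    }
    rownames(gene_flags) <- gene_ids
  }
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids)) {
      stop("cell_meta must have one row per cell")
    }
    rownames(cell_meta) <- cell_ids
  }
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta, gene_flags = gene_flags),
            class = "count_matrix")
}

startsWith_any <- function(x, prefixes) {
  out <- rep(FALSE, length(x))
  for (p in prefixes) out <- out | startsWith(x, p)
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", length(x$gene_ids), " genes x ", length(x$cell_ids),
      " cells (", format(Matrix::nnzero(x$counts), big.mark = ","),
      " non-zero entries)\n", sep = "")
  cat("  mitochondrial genes: ", sum(x$gene_flags$is_mitochondrial),
      "; ribosomal genes: ", sum(x$gene_flags$is_ribosomal), "\n", sep = "")
  if (!is.null(x$cell_meta)) {
    cat("  cell_meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or cell identifiers
#'
#' @param m a `count_matrix`.
#' @param genes,cells character vectors of identifiers to keep (in the given
#'   order), or `NULL` to keep all.
#' @return A `count_matrix` restricted to the requested identifiers.
#' @export
subset_count_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(genes)) genes <- m$gene_ids
  if (is.null(cells)) cells <- m$cell_ids
  if (!all(genes %in% m$gene_ids)) stop("unknown gene identifiers requested")
  if (!all(cells %in% m$cell_ids)) stop("unknown cell identifiers requested")
  count_matrix(m$counts[genes, cells, drop = FALSE],
               gene_ids = genes, cell_ids = cells,
               cell_meta = if (is.null(m$cell_meta)) NULL else
                 m$cell_meta[cells, , drop = FALSE],
               gene_flags = m$gene_flags[genes, , drop = FALSE])
}

#' Library-size normalized log expression
#'
#' Counts-per-10k followed by log1p, the dominant convention of the droplet
#' scRNA-seq toolchain. Used for marker testing, expression gates and logFC.
#'
#' @param m a `count_matrix`.
#' @param scale library-size target (default 1e4).
#' @return A dense gene x cell matrix of `log1p(count / libsize * scale)`.
#'   Cells with zero total counts are left at zero.
#' @export
normalize_log_cp10k <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  libs <- Matrix::colSums(m$counts)
  libs[libs == 0] <- 1
  out <- as.matrix(m$counts %*% Matrix::Diagonal(x = scale / libs))
  dimnames(out) <- dimnames(m$counts)
  log1p(out)
}

#' Sum counts into sample-level pseudobulk profiles
#'
#' @param m a `count_matrix`.
#' @param by per-cell grouping vector (e.g. `m$cell_meta$sample`).
#' @return A gene x group matrix of summed counts.
#' @export
pseudobulk <- function(m, by) {
  stopifnot(inherits(m, "count_matrix"), length(by) == length(m$cell_ids))
  by <- as.factor(by)
  ind <- Matrix::sparseMatrix(i = seq_along(by), j = as.integer(by), x = 1,
                              dims = c(length(by), nlevels(by)))
  out <- as.matrix(m$counts %*% ind)
  dimnames(out) <- list(m$gene_ids, levels(by))
  out
}

#' Read a count matrix from disk
#'
#' Supports the two on-disk dialects used throughout the pipeline: the 10x
#' convention (MatrixMarket coordinate file `matrix.mtx` plus `barcodes.tsv`
#' and `features.tsv`) and a dense TSV with genes as rows and cells as
#' columns.
#'
#' @param path directory (mtx_triplet) or file (dense_tsv).
#' @param dialect `"mtx_triplet"` or `"dense_tsv"`.
#' @param cell_meta optional per-cell annotation data.frame.
#' @param ... passed to [count_matrix()] (e.g. `mito_prefix`).
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, dialect = c("mtx_triplet", "dense_tsv"),
                              cell_meta = NULL, ...) {
  dialect <- match.arg(dialect)
  if (dialect == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
    for (f in c(mtx, bc, ft)) if (!file.exists(f)) stop("missing file: ", f)
    counts <- Matrix::readMM(mtx)
    barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    feats <- utils::read.table(ft, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
    # 10x features.tsv may carry (id, symbol, type); the symbol column is used
    genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
    if (nrow(counts) != length(genes)) {
      stop("matrix has ", nrow(counts), " rows but features table has ",
           length(genes))
    }
    if (ncol(counts) != length(barcodes)) {
      stop("matrix has ", ncol(counts), " columns but barcodes table has ",
           length(barcodes))
    }
    count_matrix(counts, gene_ids = genes, cell_ids = barcodes,
                 cell_meta = cell_meta, ...)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, row.names = 1)
    count_matrix(as.matrix(tab), cell_meta = cell_meta, ...)
  }
}

#' Write a count matrix to disk
#'
#' @param m a `count_matrix`.
#' @param path output directory (mtx_triplet) or file (dense_tsv).
#' @inheritParams read_count_matrix
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path,
                               dialect = c("mtx_triplet", "dense_tsv")) {
  stopifnot(inherits(m, "count_matrix"))
  dialect <- match.arg(dialect)
  if (dialect == "mtx_triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    utils::write.table(data.frame(id = m$gene_ids, symbol = m$gene_ids),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    tab <- as.matrix(m$counts)
    utils::write.table(data.frame(gene = m$gene_ids, tab, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
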