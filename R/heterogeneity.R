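#' Assemble the Pi significance-effect matrix
#'
#' For every (gene, cluster) marker statistic, `Pi = -log10(p_adj) * logFC`,
#' a signed product of significance and effect size. Genes absent from a
#' cluster's table are set to 0; `p_adj` is floored at `epsilon` before the
#' log so the matrix is always finite. Rows are genes, columns are the
#' clusters (malignant subclones or patients) of the marker run.
#'
#' @param markers a [find_markers()] table.
#' @param epsilon floor applied to `p_adj` (default 1e-300).
#' @return Numeric gene x cluster matrix.
#' @export
compute_pi_matrix <- function(markers, epsilon = 1e-300) {
  genes <- sort(unique(markers$gene))
  clusters <- sort(unique(markers$cluster))
  if (!length(clusters)) stop("marker table covers no cluster")
  pi_mat <- matrix(0, nrow = length(genes), ncol = length(clusters),
                   dimnames = list(genes, clusters))
  padj <- pmax(markers$p_adj, epsilon)
  pi_mat[cbind(match(markers$gene, genes), match(markers$cluster, clusters))] <-
    -log10(padj) * markers$logFC
  pi_mat
}

#' Train a self-organizing map on the Pi matrix
#'
#' Online Kohonen training: genes (rows of the Pi matrix) are presented in
#' random order for `epochs` passes; the best-matching unit (BMU, nearest
#' codebook vector by Euclidean distance) and its neighbours are pulled
#' toward each input with a linearly decaying learning rate and a Gaussian
#' neighbourhood of linearly decaying radius. Codebooks are initialized from
#' random input rows. Deterministic under `seed`; genes with identical rows
#' always share a unit.
#'
#' @param pi_mat numeric gene x feature matrix (from [compute_pi_matrix()]).
#' @param grid_rows,grid_cols SOM grid dimensions (default 10 x 10).
#' @param epochs training passes over the data (default 100).
#' @param alpha_range learning rate, decayed linearly from first to second
#'   element over training.
#' @param seed RNG seed.
#' @return List of class `som_model`: `codebook` (units x features), `grid`
#'   (unit_row, unit_col per unit), `assignment` (data.frame gene, unit,
#'   unit_row, unit_col), `quantization_error` (mean distance to BMU per
#'   epoch).
#' @export
train_som <- function(pi_mat, grid_rows = 10L, grid_cols = 10L, epochs = 100L,
                      alpha_range = c(0.5, 0.01), seed = 1L) {
  pi_mat <- as.matrix(pi_mat)
  n_units <- grid_rows * grid_cols
  if (n_units < 2) stop("SOM grid needs >= 2 units")
  if (epochs < 1) stop("epochs must be >= 1")
  if (all(pi_mat == 0)) warning("all-zero Pi matrix: the map is trivial")
  # canonicalize the training order (lexicographic by row values) so the
  # fitted map, and hence the assignments, never depend on input gene order
  canon <- do.call(order, c(unname(as.data.frame(pi_mat)),
                            list(method = "radix")))
  input <- pi_mat[canon, , drop = FALSE]
  set.seed(seed)
  grid <- expand.grid(unit_row = seq_len(grid_rows),
                      unit_col = seq_len(grid_cols))
  n_genes <- nrow(pi_mat)
  codebook <- input[sample.int(n_genes, n_units, replace = n_genes < n_units),
                     , drop = FALSE]
  rownames(codebook) <- NULL
  grid_d2 <- as.matrix(stats::dist(grid))^2
  total_steps <- epochs * n_genes
  radius0 <- max(grid_rows, grid_cols) / 2
  qe <- numeric(epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_genes)
    derr <- 0
    for (g in ord) {
      step <- step + 1L
      frac <- (step - 1) / total_steps
      alpha <- alpha_range[1] + (alpha_range[2] - alpha_range[1]) * frac
      radius <- max(radius0 * (1 - frac), 0.5)
      x <- input[g, ]
      d2 <- rowSums(sweep(codebook, 2, x)^2)
      bmu <- which.min(d2)
      derr <- derr + sqrt(d2[bmu])
      h <- alpha * exp(-grid_d2[bmu, ] / (2 * radius^2))
      codebook <- codebook + h * sweep(-codebook, 2, x, `+`)
    }
    qe[ep] <- derr / n_genes
  }
  d_final <- as.matrix(stats::dist(rbind(pi_mat, codebook)))[
    seq_len(n_genes), n_genes + seq_len(n_units), drop = FALSE]
  bmu <- apply(d_final, 1, which.min)
  assignment <- data.frame(gene = rownames(pi_mat), unit = bmu,
                           unit_row = grid$unit_row[bmu],
                           unit_col = grid$unit_col[bmu], row.names = NULL)
  structure(list(codebook = codebook, grid = grid, assignment = assignment,
                 quantization_error = qe,
                 meta = list(grid_rows = grid_rows, grid_cols = grid_cols,
                             epochs = epochs, alpha_range = alpha_range,
                             seed = seed)),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model: ", x$meta$grid_rows, "x", x$meta$grid_cols, " grid, ",
      nrow(x$assignment), " genes, ", x$meta$epochs,
      " epochs (final quantization error ",
      signif(utils::tail(x$quantization_error, 1), 4), ")\n", sep = "")
  invisible(x)
}

#' Principal-component embedding of cells
#'
#' PCA of log-normalized expression fitted on all cells jointly; the top `d`
#' components (default 30, reduced with a warning when fewer are available)
#' are retained for the diversity score.
#'
#' @param m a [count_matrix()] or a cells x gene numeric matrix of normalized
#'   expression.
#' @param d number of components to retain.
#' @return List of class `embedding`: `coordinates` (cells x d),
#'   `explained_variance` per retained component.
#' @export
pca_embedding <- function(m, d = 30L) {
  x <- if (inherits(m, "count_matrix")) t(normalize_log_cp10k(m)) else
    as.matrix(m)
  d_max <- min(nrow(x) - 1L, ncol(x))
  if (d > d_max) {
    warning("only ", d_max, " components available; reducing d from ", d)
    d <- d_max
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
  structure(list(coordinates = pc$x[, seq_len(d), drop = FALSE],
                 explained_variance = (pc$sdev^2)[seq_len(d)], d = d),
            class = "embedding")
}

#' Per-patient intratumor diversity score
#'
#' The diversity score of a patient is the mean Euclidean distance of the
#' patient's malignant cells to their centroid in the retained
#' principal-component space. Identical cells score 0; the score is
#' translation-invariant, scales linearly with the coordinates, and is
#' unchanged by duplicating every cell of a patient. Patients with a single
#' cell have no defined score and are reported as NA.
#'
#' @param embedding an [pca_embedding()] result, or a cells x d coordinate
#'   matrix.
#' @param patient_labels per-cell patient identifiers.
#' @return data.frame: patient, score, n_cells, d.
#' @export
diversity_score <- function(embedding, patient_labels) {
  coords <- if (inherits(embedding, "embedding")) embedding$coordinates else
    as.matrix(embedding)
  stopifnot(nrow(coords) == length(patient_labels))
  patient_labels <- as.character(patient_labels)
  out <- lapply(unique(patient_labels), function(p) {
    xs <- coords[patient_labels == p, , drop = FALSE]
    score <- if (nrow(xs) < 2) NA_real_ else {
      centroid <- colMeans(xs)
      mean(sqrt(rowSums(sweep(xs, 2, centroid)^2)))
    }
    data.frame(patient = p, score = score, n_cells = nrow(xs),
               d = ncol(coords), row.names = NULL)
  })
  res <- do.call(rbind, out)
  if (anyNA(res$score)) {
    warning("patient(s) with a single cell have no diversity score: ",
            paste(res$patient[is.na(res$score)], collapse = ", "))
  }
  res
}
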