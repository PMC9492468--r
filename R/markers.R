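#' Two-sided Wilcoxon rank-sum test p-value
#'
#' Mid-ranks are used for ties. For small pooled samples (<= `exact_max`
#' observations) the exact permutation null of the rank sum is computed by a
#' generating-function convolution over the (doubled, hence integral)
#' mid-ranks, and the two-sided p-value is `2 * min(P(W <= w), P(W >= w))`
#' capped at 1. For larger samples the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y numeric vectors, the two groups.
#' @param exact_max largest pooled sample size for the exact path.
#' @return A single p-value in (0, 1].
#' @export
rank_sum_p <- function(x, y, exact_max = 25L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_max) {
    # distribution of the doubled rank sum over all C(n, n1) subsets:
    # dp[k+1, s+1] = number of k-subsets of the doubled ranks summing to s
    r2 <- as.integer(round(2 * r))
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
    dp <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
    dp[1L, 1L] <- 1
    for (item in r2) {
      kmax <- n1
      for (k in kmax:1) {
        shift <- item
        cols <- seq_len(smax + 1L - shift)
        dp[k + 1L, cols + shift] <- dp[k + 1L, cols + shift] + dp[k, cols]
      }
    }
    pmf <- dp[n1 + 1L, ]
    total <- sum(pmf)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(pmf[seq_len(w2 + 1L)]) / total
    p_ge <- sum(pmf[(w2 + 1L):(smax + 1L)]) / total
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Per-cluster marker detection (one-vs-rest Wilcoxon)
#'
#' For every gene and cluster, tests normalized expression (log-CP10k) in the
#' cluster against all other cells with a two-sided Wilcoxon rank-sum test,
#' adjusts p-values by Benjamini-Hochberg within each cluster's tested gene
#' list, and reports `logFC = log2(mean(norm) + pseudocount)` in the cluster
#' minus the same in the rest (base-2 log with pseudocount, so conventional
#' thresholds like logFC > 1 apply).
#'
#' @param m a [count_matrix()].
#' @param labels per-cell cluster identifiers (length = number of cells), or
#'   the name of a `cell_meta` column.
#' @param mode only `"one_vs_rest"` is implemented.
#' @param pseudocount added inside the log when computing logFC.
#' @param exact_max passed to [rank_sum_p()].
#' @return data.frame of class `marker_stats`: gene, cluster, logFC, p_value,
#'   p_adj, pct_in, pct_out, significant (p_value < 0.05), sorted by cluster
#'   then ascending p_adj.
#' @export
find_markers <- function(m, labels, mode = "one_vs_rest", pseudocount = 1,
                         exact_max = 25L) {
  stopifnot(inherits(m, "count_matrix"), identical(mode, "one_vs_rest"))
  if (length(labels) == 1 && !is.null(m$cell_meta) &&
      labels %in% names(m$cell_meta)) {
    labels <- m$cell_meta[[labels]]
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == length(m$cell_ids))
  tab <- table(labels)
  if (length(tab) < 2) stop("marker detection needs >= 2 clusters")
  if (any(tab < 3)) {
    stop("cluster(s) with fewer than 3 cells: ",
         paste(names(tab)[tab < 3], collapse = ", "))
  }
  norm <- normalize_log_cp10k(m)
  n <- ncol(norm)
  detected <- m$counts > 0
  exact <- n <= exact_max

  # pooled per-gene ranks are shared by every one-vs-rest comparison
  if (!exact) {
    ranks <- t(apply(norm, 1, rank))
    tie_term <- apply(ranks, 1, function(r) {
      tt <- table(r); sum(tt^3 - tt)
    })
  }
  out <- list()
  for (cl in names(tab)) {
    in_cl <- labels == cl
    n1 <- sum(in_cl); n2 <- n - n1
    mean_in <- rowMeans(norm[, in_cl, drop = FALSE])
    mean_out <- rowMeans(norm[, !in_cl, drop = FALSE])
    logfc <- log2(mean_in + pseudocount) - log2(mean_out + pseudocount)
    if (exact) {
      p <- vapply(seq_len(nrow(norm)), function(g) {
        rank_sum_p(norm[g, in_cl], norm[g, !in_cl], exact_max = exact_max)
      }, 0)
    } else {
      w <- rowSums(ranks[, in_cl, drop = FALSE])
      mu <- n1 * (n + 1) / 2
      sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
      z <- ifelse(sigma2 > 0, (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2), 0)
      p <- pmin(1, 2 * stats::pnorm(-abs(z)))
      p[sigma2 <= 0] <- 1
    }
    out[[cl]] <- data.frame(
      gene = m$gene_ids, cluster = cl, logFC = logfc, p_value = p,
      p_adj = stats::p.adjust(p, method = "BH"),
      pct_in = Matrix::rowSums(detected[, in_cl, drop = FALSE]) / n1,
      pct_out = Matrix::rowSums(detected[, !in_cl, drop = FALSE]) / n2,
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  res$significant <- res$p_value < 0.05
  res <- res[order(res$cluster, res$p_adj, res$p_value, res$gene), ]
  rownames(res) <- NULL
  class(res) <- c("marker_stats", "data.frame")
  res
}
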