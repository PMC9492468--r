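#' Extract origin-signature marker sets from a marker table
#'
#' Builds the type-I and type-IX malignant-progenitor signatures as each
#' cluster's specific markers with `logFC > logfc_min` (strict, default 1)
#' and `p_adj < p_adj_max`. The two sets are not forced to be disjoint;
#' overlapping genes are reported in the `overlap` attribute.
#'
#' @param markers a [find_markers()] table.
#' @param type_I_cluster,type_IX_cluster cluster identifiers of the two
#'   progenitor populations.
#' @param logfc_min strict lower bound on logFC (default 1).
#' @param p_adj_max upper bound on the BH-adjusted p-value (default 0.05).
#' @return List of two `gene_set`s named `type_I` and `type_IX`, with an
#'   `overlap` attribute.
#' @export
extract_origin_markers <- function(markers, type_I_cluster, type_IX_cluster,
                                   logfc_min = 1, p_adj_max = 0.05) {
  for (cl in c(type_I_cluster, type_IX_cluster)) {
    if (!cl %in% markers$cluster) stop("cluster absent from marker table: ", cl)
  }
  pick <- function(cl) {
    g <- markers$gene[markers$cluster == cl & markers$logFC > logfc_min &
                        markers$p_adj < p_adj_max]
    if (!length(g)) {
      stop("no marker of cluster ", cl, " passes logFC > ", logfc_min,
           " and p_adj < ", p_adj_max)
    }
    g
  }
  gI <- pick(type_I_cluster); gIX <- pick(type_IX_cluster)
  out <- list(type_I = gene_set("type_I", gI),
              type_IX = gene_set("type_IX", gIX))
  attr(out, "overlap") <- intersect(gI, gIX)
  out
}

#' Malignant-origin abundance, dominance and four-class typing
#'
#' Scores every sample of a cohort for type-I and type-IX
#' malignant-progenitor abundance with the rank-based signature scorer (the
#' same engine used per cell, treating each sample as one unit), computes the
#' origin dominance score `dominance = abundance_I - abundance_IX`, flags
#' each abundance as positive against the chosen threshold, and assigns one
#' of four classes: `double_positive`, `double_negative`, `I_only`,
#' `IX_only`.
#'
#' @param cohort_expr sample x gene expression matrix (samples as rows).
#' @param set_I,set_IX `gene_set`s of the two origin signatures.
#' @param positivity `"cohort_median"` (default: abundance above the per-set
#'   cohort median), `"zero"` (raw score above 0) or `"quantile"` (above the
#'   per-set cohort quantile `q`).
#' @param q quantile for `positivity = "quantile"`.
#' @return data.frame of class `origin_scores`: sample, abundance_I,
#'   abundance_IX, dominance, positive_I, positive_IX, class. Abundances are
#'   raw signature scores (the dominance arithmetic is exact on them).
#' @export
type_origin <- function(cohort_expr, set_I, set_IX,
                        positivity = c("cohort_median", "zero", "quantile"),
                        q = 0.5) {
  positivity <- match.arg(positivity)
  sI <- signature_score(cohort_expr, set_I)
  sIX <- signature_score(cohort_expr, set_IX)
  stopifnot(identical(sI$unit, sIX$unit))
  if (positivity == "cohort_median" && length(sI$unit) < 2) {
    stop("cohort_median positivity needs >= 2 samples")
  }
  thr <- function(x) switch(positivity,
                            cohort_median = stats::median(x),
                            zero = 0,
                            quantile = stats::quantile(x, q, names = FALSE))
  pos_I <- sI$raw > thr(sI$raw)
  pos_IX <- sIX$raw > thr(sIX$raw)
  cls <- ifelse(pos_I & pos_IX, "double_positive",
                ifelse(!pos_I & !pos_IX, "double_negative",
                       ifelse(pos_I, "I_only", "IX_only")))
  res <- data.frame(sample = sI$unit, abundance_I = sI$raw,
                    abundance_IX = sIX$raw,
                    dominance = sI$raw - sIX$raw,
                    positive_I = pos_I, positive_IX = pos_IX, class = cls,
                    row.names = NULL)
  class(res) <- c("origin_scores", "data.frame")
  res
}
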