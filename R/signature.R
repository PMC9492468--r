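#' Rank-based single-sample signature score
#'
#' A non-parametric, unsupervised per-unit enrichment score in the
#' Kolmogorov-Smirnov style. For each unit (a cell, or a bulk/chip sample),
#' genes are ordered from highest to lowest expression; a running sum
#' increments by `1/|S|` at signature member genes and decrements by
#' `1/(G - |S|)` at non-members (S = members measured in the unit, G = genes
#' measured). The raw score is the deviation of maximal magnitude, signed:
#' positive means the signature sits among the unit's most highly expressed
#' genes. Raw scores are then cohort min-max normalized to [0, 1]. Because
#' the statistic depends only on within-unit expression ranks, any strictly
#' monotone transform of a unit's expression leaves the raw score unchanged.
#'
#' An optional kernel-density preprocessing step (`kde_filter = TRUE`)
#' estimates a Gaussian KDE (Silverman bandwidth) over the unit's expression
#' values and discards genes falling in the low-expression mode (below the
#' first antimode), treating the zero-inflation mode as unmeasured. This is a
#' diagnostic filter; it never reorders the remaining ranks, and it is off by
#' default.
#'
#' @param expr a [count_matrix()] (units = cells) or a numeric unit x gene
#'   matrix/data.frame (units = rows, e.g. samples of a cohort).
#' @param sets a `gene_set` or list of `gene_set`s.
#' @param kde_filter logical; apply the KDE zero-mode filter (default FALSE).
#' @return data.frame with columns unit, signature, raw, scaled (cohort
#'   min-max; 0.5 for every unit with a warning when all raw scores are
#'   equal).
#' @export
signature_score <- function(expr, sets, kde_filter = FALSE) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  mat <- unit_by_gene(expr)
  out <- list()
  for (s in sets) {
    present <- intersect(s$genes, colnames(mat))
    if (length(present) == 0) {
      stop("no gene of signature '", s$name, "' is measured")
    }
    raw <- vapply(rownames(mat), function(u) {
      ks_walk_score(mat[u, ], present, kde_filter = kde_filter)
    }, 0)
    out[[s$name]] <- data.frame(unit = rownames(mat), signature = s$name,
                                raw = unname(raw),
                                scaled = minmax_scale(unname(raw)),
                                row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

unit_by_gene <- function(expr) {
  if (inherits(expr, "count_matrix")) {
    t(as.matrix(expr$counts))
  } else {
    m <- as.matrix(expr)
    if (is.null(rownames(m))) rownames(m) <- paste0("unit", seq_len(nrow(m)))
    storage.mode(m) <- "double"
    m
  }
}

# signed KS running-sum over genes ordered from highest to lowest expression;
# ties broken by gene name so the walk is deterministic and rank-invariant
ks_walk_score <- function(x, members, kde_filter = FALSE) {
  if (length(unique(x)) < 2) {
    stop("unit has all-equal expression; rank score undefined")
  }
  if (kde_filter) x <- kde_drop_zero_mode(x)
  genes <- names(x)[order(-x, names(x))]
  is_member <- genes %in% members
  nh <- sum(is_member)
  g <- length(genes)
  if (nh == 0 || nh == g) {
    stop("signature covers none or all of the measured genes")
  }
  steps <- ifelse(is_member, 1 / nh, -1 / (g - nh))
  walk <- cumsum(steps)
  walk[which.max(abs(walk))]
}

kde_drop_zero_mode <- function(x) {
  d <- stats::density(x, bw = "nrd0")
  dy <- diff(d$y)
  antimode <- which(dy[-1] > 0 & dy[-length(dy)] <= 0)  # local minima
  if (!length(antimode)) return(x)
  cut <- d$x[antimode[1] + 1]
  if (min(x) >= cut) return(x)
  kept <- x[x >= cut]
  if (length(unique(kept)) < 2) x else kept
}

minmax_scale <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    if (length(x) >= 2) {
      warning("degenerate cohort: all raw scores equal; scaled set to 0.5")
    }
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Expression stemness index
#'
#' Applies a pre-trained stemness signature weight vector to expression
#' profiles: the raw index of a unit is the Spearman rank correlation between
#' the unit's expression of the weighted genes and the weights themselves,
#' then min-max rescaled to [0, 1] across the cohort. Training of the weight
#' vector (one-class logistic regression on stem-cell atlases) is outside the
#' scope of this package; the weights are an input.
#'
#' @param expr a [count_matrix()] or unit x gene matrix (see
#'   [signature_score()]).
#' @param w a `gene_set` carrying weights.
#' @return data.frame: unit, raw (Spearman rho in [-1, 1]), scaled in [0, 1]
#'   (0.5 for all units, with a warning, when the cohort is degenerate).
#' @export
stemness_index <- function(expr, w) {
  stopifnot(inherits(w, "gene_set"))
  if (is.null(w$weights)) stop("stemness signature must carry weights")
  mat <- unit_by_gene(expr)
  genes <- intersect(names(w$weights), colnames(mat))
  if (length(genes) < 3) {
    stop("need >= 3 weighted genes measured; found ", length(genes))
  }
  wv <- w$weights[genes]
  raw <- apply(mat[, genes, drop = FALSE], 1, function(e) {
    stats::cor(e, wv, method = "spearman")
  })
  data.frame(unit = rownames(mat), raw = unname(raw),
             scaled = minmax_scale(unname(raw)), row.names = NULL)
}

#' Cell-cycle (and other per-cell label) scoring
#'
#' Thin wrapper applying [signature_score()] to a list of cycle-phase gene
#' sets (e.g. S-phase and G2M programs), reported per cell.
#'
#' @param m a [count_matrix()].
#' @param cycle_sets list of `gene_set`s.
#' @param ... passed to [signature_score()].
#' @return The [signature_score()] table, one row per (cell, set).
#' @export
cell_cycle_score <- function(m, cycle_sets, ...) {
  stopifnot(inherits(m, "count_matrix"))
  signature_score(m, cycle_sets, ...)
}
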