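#' Tumor mutational burden per sample and level
#'
#' TMB = number of distinct somatic variant keys (chrom, pos, ref, alt) per
#' megabase of assayed genome, computed per (sample, level). The division is
#' exact: `tmb * genome_size_mb == n_variants`.
#'
#' @param v a [variant_set()].
#' @param level optional level filter (e.g. `"bulk"`); NULL computes every
#'   (sample, level) stratum present.
#' @return data.frame: sample, level, n_variants, tmb.
#' @export
compute_tmb <- function(v, level = NULL) {
  stopifnot(inherits(v, "variant_set"))
  rec <- v$records
  if (!is.null(level)) rec <- rec[rec$level %in% level, , drop = FALSE]
  strata <- unique(rec[c("sample", "level")])
  strata <- strata[order(strata$sample, strata$level), , drop = FALSE]
  n <- vapply(seq_len(nrow(strata)), function(i) {
    sel <- rec$sample == strata$sample[i] & rec$level == strata$level[i]
    length(unique(variant_key(rec[sel, ])))
  }, 0L)
  data.frame(sample = strata$sample, level = strata$level, n_variants = n,
             tmb = n / v$genome_size_mb, row.names = NULL)
}

# pyrimidine-centric collapse: a substitution reported on the purine strand
# maps to its reverse complement
SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Six-class substitution spectrum
#'
#' Classifies single-base substitutions into the six pyrimidine-centric
#' classes (C>A, C>G, C>T, T>A, T>C, T>G), collapsing purine-reference
#' records by reverse complement (G>A becomes C>T, A>G becomes T>C, ...).
#' Indels and multi-base alleles are excluded from the spectrum and counted
#' separately; records with ambiguous bases are excluded with a warning.
#'
#' @param v a [variant_set()].
#' @return data.frame of class `spectrum_table`: sample, level, class, count,
#'   fraction (fractions sum to 1 within each stratum with any SNV); the
#'   number of excluded non-SNV records is in `attr(, "n_excluded")`.
#' @export
substitution_spectrum <- function(v) {
  stopifnot(inherits(v, "variant_set"))
  rec <- v$records
  is_snv <- nchar(rec$ref) == 1 & nchar(rec$alt) == 1 &
    rec$ref %in% c("A", "C", "G", "T") & rec$alt %in% c("A", "C", "G", "T")
  ambiguous <- (nchar(rec$ref) == 1 & nchar(rec$alt) == 1) & !is_snv
  if (any(ambiguous)) {
    warning(sum(ambiguous), " record(s) with ambiguous bases excluded")
  }
  n_excluded <- sum(!is_snv)
  rec <- rec[is_snv, , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- rec$ref; alt <- rec$alt
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[rec$ref[flip]]
  alt[flip] <- comp[rec$alt[flip]]
  cls <- factor(paste0(ref, ">", alt), levels = SPECTRUM_CLASSES)
  strata <- unique(rec[c("sample", "level")])
  strata <- strata[order(strata$sample, strata$level), , drop = FALSE]
  out <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- rec$sample == strata$sample[i] & rec$level == strata$level[i]
    counts <- table(cls[sel])
    total <- sum(counts)
    data.frame(sample = strata$sample[i], level = strata$level[i],
               class = SPECTRUM_CLASSES, count = as.integer(counts),
               fraction = if (total > 0) as.numeric(counts) / total else 0,
               row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "n_excluded") <- n_excluded
  class(res) <- c("spectrum_table", "data.frame")
  res
}

#' Partition a sample's variants into shared and subclone-restricted sets
#'
#' Variants present in every malignant subclone of a sample are origin-stage
#' (shared) events; variants missing from at least one subclone are
#' evolution-stage (restricted) events, attributed to the subclones carrying
#' them. The two buckets are disjoint and together cover every
#' subclone-observed variant key exactly once.
#'
#' @param v a [variant_set()].
#' @param sample sample identifier; the sample must have >= 2 subclone
#'   levels.
#' @return List of class `sharing_partition`: `shared` (character keys),
#'   `restricted` (named list subclone -> keys carried by that subclone but
#'   not by all), `presence` (logical variant x subclone matrix).
#' @export
partition_sharing <- function(v, sample) {
  stopifnot(inherits(v, "variant_set"))
  rec <- v$records[v$records$sample == sample, , drop = FALSE]
  rec <- rec[startsWith(rec$level, "subclone:"), , drop = FALSE]
  subclones <- sort(unique(rec$level))
  if (length(subclones) < 2) {
    stop("sample ", sample, " has ", length(subclones),
         " subclone level(s); need >= 2")
  }
  keys <- sort(unique(variant_key(rec)))
  presence <- matrix(FALSE, nrow = length(keys), ncol = length(subclones),
                     dimnames = list(keys, subclones))
  presence[cbind(match(variant_key(rec), keys), match(rec$level, subclones))] <-
    TRUE
  shared <- keys[rowSums(presence) == length(subclones)]
  restricted <- lapply(subclones, function(sc) {
    setdiff(keys[presence[, sc]], shared)
  })
  names(restricted) <- subclones
  structure(list(shared = shared, restricted = restricted,
                 presence = presence, sample = sample),
            class = "sharing_partition")
}

#' @export
print.sharing_partition <- function(x, ...) {
  cat("sharing_partition of sample ", x$sample, ": ", length(x$shared),
      " shared, ", sum(rowSums(x$presence) < ncol(x$presence)),
      " subclone-restricted variants over ", ncol(x$presence),
      " subclones\n", sep = "")
  invisible(x)
}
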