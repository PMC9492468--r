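#' Somatic variant set keyed by sample and level
#'
#' Holds somatic variants for one or more samples, each record tagged with a
#' level: `"bulk"` (aspirate-level calls) or `"subclone:<id>"` (calls
#' attributed to one malignant subclone). The variant key is
#' (chrom, pos, ref, alt); positions are 1-based inclusive (VCF convention).
#' `genome_size_mb` is the assayed genome size in megabases, the denominator
#' of tumor mutational burden; no default genome is assumed.
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based integer),
#'   `ref`, `alt`, `sample`, `level`.
#' @param genome_size_mb positive real, megabases of assayed genome.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(records, genome_size_mb) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "sample", "level")
  if (!all(need %in% names(records))) {
    stop("variant records need columns: ", paste(need, collapse = ", "))
  }
  records <- records[need]
  records$pos <- as.integer(records$pos)
  if (nrow(records)) {
    if (any(records$pos < 1)) stop("variant positions must be >= 1")
    if (any(records$ref == records$alt)) stop("ref and alt alleles must differ")
    dup <- duplicated(records)
    if (any(dup)) records <- records[!dup, ]
  }
  if (!is.numeric(genome_size_mb) || length(genome_size_mb) != 1 ||
      !is.finite(genome_size_mb) || genome_size_mb <= 0) {
    stop("genome_size_mb must be a single positive number")
  }
  rownames(records) <- NULL
  structure(list(records = records, genome_size_mb = genome_size_mb),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set: ", nrow(x$records), " records, ",
      length(unique(x$records$sample)), " sample(s), genome ",
      x$genome_size_mb, " Mb\n", sep = "")
  invisible(x)
}

variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

#' Read somatic variants from TSV or minimal VCF
#'
#' TSV dialect: header with the six fields `chrom`, `pos`, `ref`, `alt`,
#' `sample`, `level`. Minimal VCF dialect: the fixed CHROM/POS/ID/REF/ALT
#' columns; the sample is taken from a `SAMPLE=` INFO key, a seventh `sample`
#' column convention is not assumed, so `sample` and `level` may instead be
#' supplied as arguments for single-sample files. Multi-allelic ALT entries
#' are split into one record per alternate allele.
#'
#' @param path file path.
#' @param genome_size_mb positive real, megabases of assayed genome.
#' @param format `"auto"` (by extension / leading `##fileformat`), `"tsv"` or
#'   `"vcf"`.
#' @param sample,level defaults applied to VCF rows that do not carry
#'   `SAMPLE=` / `LEVEL=` INFO keys.
#' @return A `variant_set`.
#' @export
read_variants <- function(path, genome_size_mb,
                          format = c("auto", "tsv", "vcf"),
                          sample = NA_character_, level = "bulk") {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE) ||
                  startsWith(first, "##fileformat")) "vcf" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    return(variant_set(tab, genome_size_mb))
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      stop("unparseable VCF row at data line ", i, ": ", substr(body[i], 1, 60))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("unparseable POS at data line ", i)
    info <- if (length(f) >= 8) f[8] else ""
    smp <- vcf_info_key(info, "SAMPLE", sample)
    lvl <- vcf_info_key(info, "LEVEL", level)
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    recs[[i]] <- data.frame(chrom = f[1], pos = pos, ref = f[4], alt = alts,
                            sample = smp, level = lvl)
  }
  variant_set(do.call(rbind, recs), genome_size_mb)
}

vcf_info_key <- function(info, key, default) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
  if (length(m) == 2) m[2] else default
}

#' Write a variant set as six-column TSV
#' @param v a `variant_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(v, path) {
  stopifnot(inherits(v, "variant_set"))
  utils::write.table(v$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
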