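#' Named gene set, optionally weighted
#'
#' A signature is a non-empty set of gene symbols; the stemness index variant
#' additionally carries one finite real weight per member gene.
#'
#' @param name identifier of the set.
#' @param genes character vector of member gene symbols (deduplicated).
#' @param weights optional numeric vector of per-gene weights, named by gene
#'   or aligned with `genes`; must cover exactly the member genes.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, weights = NULL) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("gene set '", name, "' is empty")
  if (!is.null(weights)) {
    if (is.null(names(weights))) {
      if (length(weights) != length(genes)) {
        stop("unnamed weights must align with genes")
      }
      names(weights) <- genes
    }
    if (!setequal(names(weights), genes)) {
      stop("weights must cover exactly the member genes")
    }
    weights <- weights[genes]
    if (any(!is.finite(weights))) stop("weights must be finite")
  }
  structure(list(name = as.character(name), genes = genes, weights = weights),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$genes), " genes",
      if (!is.null(x$weights)) " (weighted)", "\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file or long TSV
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Long TSV: header columns `set`, `gene` and optionally `weight`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @return A named list of `gene_set` objects.
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("empty gene-set file: ", path)
    sets <- lapply(lines, function(l) {
      parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
      gene_set(parts[1], parts[-(1:2)])
    })
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if (!all(c("set", "gene") %in% names(tab))) {
      stop("TSV gene-set file needs columns 'set' and 'gene'")
    }
    sets <- lapply(split(tab, tab$set), function(d) {
      w <- NULL
      if ("weight" %in% names(d) && !all(is.na(d$weight))) {
        w <- stats::setNames(d$weight, d$gene)
      }
      gene_set(d$set[1], d$gene, weights = w)
    })
  }
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets as long TSV
#'
#' @param sets a list of `gene_set` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    data.frame(set = s$name, gene = s$genes,
               weight = if (is.null(s$weights)) NA_real_ else
                 unname(s$weights[s$genes]))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
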