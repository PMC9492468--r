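#' Ligand-receptor interaction database
#'
#' The universe of directed ligand -> receptor gene pairs against which
#' cluster expression profiles are mapped, and from which degree-preserving
#' randomized networks are drawn. A receptor may be a multi-subunit complex;
#' such a receptor counts as expressed only when every subunit passes the
#' expression gate.
#'
#' @param pairs data.frame with character columns `ligand` and `receptor`,
#'   optionally `subunits` (comma-joined receptor subunit symbols; empty or NA
#'   means single-subunit) and `source`.
#' @return An object of class `lr_database`: the deduplicated pair table,
#'   sorted by (ligand, receptor) so row order never carries information.
#' @export
lr_database <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(pairs))) {
    stop("ligand-receptor table needs columns 'ligand' and 'receptor'")
  }
  if (nrow(pairs) == 0) stop("empty ligand-receptor database")
  if (!"subunits" %in% names(pairs)) pairs$subunits <- NA_character_
  if (!"source" %in% names(pairs)) pairs$source <- NA_character_
  pairs$subunits[!is.na(pairs$subunits) & !nzchar(pairs$subunits)] <-
    NA_character_
  pairs$source[!is.na(pairs$source) & !nzchar(pairs$source)] <- NA_character_
  pairs <- pairs[!duplicated(pairs[c("ligand", "receptor")]),
                 c("ligand", "receptor", "subunits", "source")]
  pairs <- pairs[order(pairs$ligand, pairs$receptor), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs), class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat("lr_database: ", nrow(x$pairs), " directed ligand->receptor pairs (",
      length(unique(x$pairs$ligand)), " ligands, ",
      length(unique(x$pairs$receptor)), " receptors)\n", sep = "")
  invisible(x)
}

#' Receptor subunit genes of each database record
#'
#' @param db an `lr_database`.
#' @return List of character vectors, one per pair: the receptor subunits
#'   (the receptor symbol itself when no complex is annotated).
#' @export
receptor_subunits <- function(db) {
  stopifnot(inherits(db, "lr_database"))
  mapply(function(r, s) {
    if (is.na(s)) r else strsplit(s, ",", fixed = TRUE)[[1]]
  }, db$pairs$receptor, db$pairs$subunits, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read a ligand-receptor database from TSV
#'
#' Tab-separated with header; mandatory columns `ligand` and `receptor`,
#' optional `subunits` (comma-joined) and `source`. Row order does not affect
#' the resulting set.
#'
#' @param path file path.
#' @return An `lr_database`.
#' @export
read_lr_database <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lr_database(tab)
}

#' Write a ligand-receptor database as TSV
#' @param db an `lr_database`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lr_database <- function(db, path) {
  stopifnot(inherits(db, "lr_database"))
  utils::write.table(db$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
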