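# Small deterministic fixtures built in code.

# a 4-gene x 3-cell matrix with one mito gene and simple structure
tiny_counts <- function() {
  counts <- rbind(GENE1 = c(5L, 0L, 2L),
                  GENE2 = c(0L, 3L, 1L),
                  CD38  = c(2L, 0L, 4L),
                  `MT-ND1` = c(1L, 1L, 0L))
  colnames(counts) <- c("c1", "c2", "c3")
  count_matrix(counts, cell_meta = data.frame(sample = c("S1", "S1", "S2")))
}

# a small LR database over synthetic gene names
tiny_db <- function() {
  lr_database(data.frame(
    ligand = c("L1", "L1", "L2", "L3"),
    receptor = c("R1", "R2", "R1", "R3"),
    subunits = c(NA, NA, NA, "R3A,R3B")))
}

tiny_variants <- function(genome_mb = 10) {
  variant_set(data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr2"),
    pos = c(100L, 100L, 50L, 50L, 60L),
    ref = c("C", "C", "G", "G", "T"),
    alt = c("T", "T", "A", "A", "G"),
    sample = "P1",
    level = c("subclone:K1", "subclone:K2", "subclone:K1", "subclone:K2",
              "subclone:K1")), genome_mb)
}
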