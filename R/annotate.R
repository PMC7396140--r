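# KO annotation: from alignment hit tables to paralog count matrices.

#' Assign KOs to genes from a ranked hit table
#'
#' Implements the top-hit annotation rule: each gene (query) takes its
#' first-ranked hit only — file order is the aligner's ranking — and the
#' hit's KO is assigned if and only if its e-value is strictly below
#' `e_max`. Genes whose top hit fails the cutoff remain unassigned; ties
#' and lower-ranked hits are never consulted.
#'
#' @param hits A hit-table data.frame as returned by [read_hit_table()]
#'   for one genome.
#' @param genome_id Identifier of the genome the hits belong to.
#' @param e_max E-value cutoff (default `1e-8`, strict `<`).
#' @return A data.frame with columns `genome_id`, `gene_id`, `ko_id`; at
#'   most one row per gene.
#' @export
assign_kos <- function(hits, genome_id, e_max = 1e-8) {
  stopifnot(is.data.frame(hits), is.character(genome_id),
            length(genome_id) == 1L, e_max > 0)
  if (nrow(hits) == 0L)
    return(data.frame(genome_id = character(0), gene_id = character(0),
                      ko_id = character(0), stringsAsFactors = FALSE))
  top <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  top <- top[top$evalue < e_max, , drop = FALSE]
  data.frame(genome_id = rep(genome_id, nrow(top)),
             gene_id = top$qseqid,
             ko_id = top$sseqid,
             stringsAsFactors = FALSE)
}

#' Count KO paralogs per genome
#'
#' Builds the strain-level paralog matrix: cell (genome, KO) is the number
#' of genes of that genome assigned to that KO. Genomes with no assignment
#' for a KO get 0; the column set is the union of assigned KOs.
#'
#' @param assignments A data.frame of KO assignments (rows from
#'   [assign_kos()], possibly concatenated across genomes).
#' @param genomes Character vector of all genome ids (rows of the output;
#'   may include genomes with no assignments).
#' @return An integer matrix, genomes x KOs.
#' @export
count_paralogs <- function(assignments, genomes) {
  stopifnot(is.data.frame(assignments), is.character(genomes),
            !anyDuplicated(genomes))
  unknown <- setdiff(unique(assignments$genome_id), genomes)
  if (length(unknown))
    stop("assignments reference unknown genome id(s): ",
         paste(unknown, collapse = ", "))
  kos <- sort(unique(assignments$ko_id))
  m <- matrix(0L, length(genomes), length(kos),
              dimnames = list(genomes, kos))
  if (nrow(assignments)) {
    tab <- table(factor(assignments$genome_id, levels = genomes),
                 factor(assignments$ko_id, levels = kos))
    m[] <- as.integer(tab)
  }
  m
}

#' Per-genus median paralog profiles
#'
#' Collapses a strain-level paralog matrix to genus rows by taking, for
#' each KO, the median copy number over the genus's strains. A strain
#' lacking a KO contributes a copy number of 0; with an even number of
#' strains the median is the midpoint of the two central values (so
#' half-integers are expected).
#'
#' @param strain_matrix Strain x KO paralog count matrix.
#' @param genus_map Named character vector mapping every strain (row name)
#'   to exactly one genus.
#' @return A numeric matrix, genus x KO.
#' @export
genus_median_profile <- function(strain_matrix, genus_map) {
  stopifnot(is.matrix(strain_matrix), !is.null(rownames(strain_matrix)))
  unmapped <- setdiff(rownames(strain_matrix), names(genus_map))
  if (length(unmapped))
    stop("strain(s) without a genus mapping: ",
         paste(unmapped, collapse = ", "))
  genera <- genus_map[rownames(strain_matrix)]
  levels <- unique(genera)
  out <- matrix(NA_real_, length(levels), ncol(strain_matrix),
                dimnames = list(levels, colnames(strain_matrix)))
  for (g in levels) {
    rows <- strain_matrix[genera == g, , drop = FALSE]
    if (nrow(rows) == 0L) stop("empty genus: ", g)
    out[g, ] <- apply(rows, 2L, stats::median)
  }
  out
}
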