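# 16S amplicon phylogenetics: quality trimming, dereplication, Kimura
# 2-parameter distances, neighbor-joining, outgroup rooting.

#' Quality-trim reads
#'
#' Applies, in order and per read: strip leading bases with quality below
#' `leading`; strip trailing bases with quality below `trailing`; drop the
#' read if the mean quality of what remains is below `avg_qual`; drop the
#' read if the remaining length is below `min_len`. Defaults mirror
#' single-end Trimmomatic `LEADING:17 TRAILING:17 AVGQUAL:25 MINLEN:200`.
#'
#' @param reads A [quality_reads] object.
#' @param leading,trailing Phred thresholds for end-stripping.
#' @param avg_qual Minimum mean quality of the trimmed read.
#' @param min_len Minimum length of the trimmed read.
#' @return A [quality_reads] object with surviving (possibly shortened)
#'   reads, in input order.
#' @export
trim_reads <- function(reads, leading = 17L, trailing = 17L,
                       avg_qual = 25, min_len = 200L) {
  stopifnot(inherits(reads, "quality_reads"))
  keep_id <- character(0); keep_seq <- character(0); keep_qual <- list()
  for (i in seq_along(reads$id)) {
    q <- reads$qual[[i]]
    lo <- 1L
    while (lo <= length(q) && q[lo] < leading) lo <- lo + 1L
    hi <- length(q)
    while (hi >= lo && q[hi] < trailing) hi <- hi - 1L
    if (hi < lo) next                      # fully trimmed away
    q <- q[lo:hi]
    if (mean(q) < avg_qual) next
    if (length(q) < min_len) next
    keep_id <- c(keep_id, reads$id[i])
    keep_seq <- c(keep_seq, substr(reads$seq[i], lo, hi))
    keep_qual <- c(keep_qual, list(q))
  }
  quality_reads(keep_id, keep_seq, keep_qual)
}

#' Dereplicate sequences
#'
#' Collapses exact duplicate sequences to unique representatives with
#' counts, sorted by count descending; ties are broken lexicographically
#' by sequence. Counts sum to the input size.
#'
#' @param seqs Character vector of sequences.
#' @return A data.frame with columns `sequence` and `count`.
#' @export
dereplicate <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, all(nzchar(seqs)))
  tab <- table(seqs)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Over sites where both characters are unambiguous nucleotides (pairwise
#' deletion of gaps and ambiguity codes), with P the fraction of
#' transitions (A/G, C/T) and Q the fraction of transversions:
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`. A saturated pair
#' (either log argument at or below 0) yields `Inf`.
#'
#' @param a,b Equal-length gapped sequences (character scalars).
#' @return Non-negative distance, or `Inf` for saturated pairs.
#' @export
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  nuc <- c("A", "C", "G", "T")
  ok <- av %in% nuc & bv %in% nuc
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites (all gapped or ambiguous)")
  av <- av[ok]; bv <- bv[ok]
  diff <- av != bv
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  ts <- diff & (purine[av] == purine[bv])   # A<->G, C<->T
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(Inf)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @param aln Named character vector of equal-length gapped sequences
#'   (at least 3), e.g. from [read_alignment_fasta()].
#' @param deletion `"pairwise"` (default; sites usable per pair) or
#'   `"complete"` (drop every column with any gap/ambiguity first).
#' @return Symmetric distance matrix with zero diagonal. Saturated pairs
#'   are `Inf` and raise a warning; [nj_tree()] refuses such matrices.
#' @export
k2p_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(is.character(aln), length(aln) >= 3L, !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L)
    stop("sequences must have equal length")
  if (deletion == "complete") {
    chars <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
    keep <- apply(chars, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(keep)) stop("no comparable sites after complete deletion")
    aln <- apply(chars[, keep, drop = FALSE], 1L, paste, collapse = "")
    names(aln) <- rownames(chars)
  }
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- k2p_distance(aln[[i]], aln[[j]])
    }
  }
  if (any(is.infinite(d)))
    warning("saturated pair(s) with infinite K2P distance")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]): the pair minimising the
#' Q-criterion is joined at each step. Exact on additive matrices; the
#' final 3-way join closes the unrooted tree. Negative branch lengths are
#' retained as computed unless `clamp = TRUE`.
#'
#' @param dm Symmetric distance matrix with at least 3 taxa; all entries
#'   must be finite.
#' @param clamp Set negative branch lengths to 0 (display convenience;
#'   default `FALSE`).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm, clamp = FALSE) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (any(is.infinite(dm)) || anyNA(dm)) {
    bad <- which(is.infinite(dm) | is.na(dm), arr.ind = TRUE)[1L, ]
    stop("non-finite distance between '", rownames(dm)[bad[1L]], "' and '",
         colnames(dm)[bad[2L]], "'")
  }
  tree <- ape::nj(stats::as.dist(dm))
  if (clamp) tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the edge separating the (monophyletic)
#' outgroup clade from the ingroup. A single-taxon outgroup is always
#' usable; a multi-taxon outgroup that is not monophyletic in the unrooted
#' tree is an error.
#'
#' @param tree An unrooted `phylo` tree.
#' @param outgroup Character vector of outgroup leaf labels (a proper,
#'   non-empty subset of the leaves).
#' @return A rooted `phylo` tree whose two root children separate the
#'   outgroup from the ingroup.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"), is.character(outgroup),
            length(outgroup) >= 1L)
  leaves <- tree$tip.label
  missing <- setdiff(outgroup, leaves)
  if (length(missing))
    stop("outgroup label(s) not in tree: ", paste(missing, collapse = ", "))
  if (length(outgroup) >= length(leaves))
    stop("outgroup must be a proper subset of the leaves")
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
              edgelabel = TRUE),
    error = function(e)
      stop("outgroup {", paste(outgroup, collapse = ", "),
           "} is not monophyletic in the tree: ", conditionMessage(e)))
  # ape::root puts the whole separating edge on one side of the new root;
  # split it at the midpoint
  root_node <- length(rooted$tip.label) + 1L
  root_edges <- which(rooted$edge[, 1L] == root_node)
  if (length(root_edges) == 2L) {
    total <- sum(rooted$edge.length[root_edges])
    rooted$edge.length[root_edges] <- total / 2
  }
  rooted
}
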