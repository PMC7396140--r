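#' Read a BLAST/DIAMOND tabular hit table (outfmt 6)
#'
#' Parses the standard 12-column tab-separated alignment output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Rows are returned in file order; for each query, file
#' order is the aligner's ranking (best hit first), which downstream
#' annotation relies on.
#'
#' @param path Path to a tab-separated hit table. Rows with more than 12
#'   fields are allowed; extra fields are ignored.
#' @return A data.frame with the 12 standard columns plus `rank`, the
#'   1-based per-query file-order rank. An empty file yields a 0-row frame.
#' @export
read_hit_table <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  numeric_cols <- cols[3:12]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12L), cols),
                         stringsAsFactors = FALSE)
    for (nc in numeric_cols) out[[nc]] <- numeric(0)
    out$rank <- integer(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop("malformed hit table row at line ", bad, ": expected >= 12 fields, got ",
         nf[bad])
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12L)))
  out <- data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
                    stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("malformed hit table row at line ", bad, ": non-numeric '",
           m[bad, j], "' in column ", cols[j])
    }
    out[[cols[j]]] <- v
  }
  if (any(out$evalue < 0) || any(out$bitscore < 0))
    stop("negative e-value or bit score in hit table")
  out$rank <- stats::ave(seq_len(nrow(out)), out$qseqid,
                         FUN = seq_along)
  out
}

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format. All sequences must
#' have equal (gapped) length; sequences are upper-cased.
#'
#' @param path Path to an aligned FASTA file with at least two records.
#' @return A named character vector of equal-length gapped sequences.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) < 2L) stop("alignment must contain at least 2 sequences")
  labels <- names(x)
  if (anyDuplicated(labels))
    stop("duplicate sequence labels in alignment: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1L)
    stop("alignment-shape error: sequence lengths differ (",
         paste(range(w), collapse = "-"), ")")
  stats::setNames(toupper(as.character(x)), labels)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Construct a collection of quality-scored reads
#'
#' The container used by the trimming stage: parallel vectors of read ids,
#' base strings, and a list of integer Phred quality vectors (one per read,
#' same length as the bases).
#'
#' @param id Character vector of read identifiers.
#' @param seq Character vector of base strings over A,C,G,T,N.
#' @param qual List of integer vectors of Phred scores in `[0, 93]`.
#' @return An object of class `quality_reads`.
#' @export
quality_reads <- function(id, seq, qual) {
  stopifnot(is.character(id), is.character(seq), is.list(qual),
            length(id) == length(seq), length(seq) == length(qual))
  ok <- vapply(seq_along(seq),
               function(i) nchar(seq[i]) == length(qual[[i]]), logical(1L))
  if (!all(ok))
    stop("read ", id[which(!ok)[1L]],
         ": sequence and quality lengths differ")
  qrange <- if (length(qual)) range(unlist(qual, use.names = FALSE)) else c(0, 0)
  if (length(unlist(qual)) && (qrange[1L] < 0 || qrange[2L] > 93))
    stop("Phred quality out of range [0, 93]")
  structure(list(id = id, seq = seq, qual = qual), class = "quality_reads")
}

#' @export
length.quality_reads <- function(x) length(x$id)

#' @export
print.quality_reads <- function(x, ...) {
  cat("quality_reads:", length(x$id), "reads\n")
  if (length(x$id)) {
    n <- min(3L, length(x$id))
    for (i in seq_len(n))
      cat("  ", x$id[i], " (", nchar(x$seq[i]), " bp, mean Q ",
          round(mean(x$qual[[i]]), 1), ")\n", sep = "")
    if (length(x$id) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Read a FASTQ file (Phred+33)
#'
#' Decodes 4-line-per-record FASTQ with Phred+33 quality encoding; no
#' auto-detection of other encodings is attempted.
#'
#' @param path Path to a FASTQ file.
#' @return A [quality_reads] object.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropped metadata columns on plain FASTQ; harmless
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  quals <- as(Biostrings::quality(x), "IntegerList")
  quality_reads(id = names(x),
                seq = unname(as.character(x)),
                qual = unname(as.list(quals)))
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A [quality_reads] object.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "quality_reads"))
  qstr <- vapply(reads$qual,
                 function(q) rawToChar(as.raw(q + 33L)), character(1L))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(reads$id)) {
    writeLines(c(paste0("@", reads$id[i]), reads$seq[i], "+", qstr[i]), con)
  }
  invisible(path)
}

# Newick metacharacters that force single-quoting of a label
# (']' first so the bracket expression stays well-formed)
.newick_special <- "[][(),:;'\" \t]"

.quote_newick_label <- function(lab) {
  needs <- grepl(.newick_special, lab)
  out <- lab
  out[needs] <- paste0("'", gsub("'", "''", lab[needs]), "'")
  out
}

.unquote_newick_label <- function(lab) {
  q <- grepl("^'.*'$", lab)
  out <- lab
  out[q] <- gsub("''", "'", sub("^'", "", sub("'$", "", lab[q])))
  out
}

#' Write a phylogenetic tree to a Newick file
#'
#' Serializes an `ape` phylo object with branch lengths at 10 significant
#' digits. Labels containing Newick metacharacters are single-quoted (with
#' internal quotes doubled), so that re-reading reproduces them exactly.
#'
#' @param tree A `phylo` object with at least 2 uniquely-labelled leaves.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  orig <- tree$tip.label
  # write with safe placeholders, then substitute quoted originals
  placeholders <- sprintf("MKOTIP%06d", seq_along(orig))
  tree$tip.label <- placeholders
  tree$node.label <- NULL
  s <- ape::write.tree(tree, digits = 10)
  quoted <- .quote_newick_label(orig)
  for (i in seq_along(orig))
    s <- sub(placeholders[i], quoted[i], s, fixed = TRUE)
  writeLines(s, path)
  invisible(path)
}

#' Read a Newick tree file
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object; quoted labels are unquoted.
#' @export
read_newick <- function(path) {
  s <- paste(readLines(path), collapse = "")
  # protect single-quoted labels from the parser with placeholders
  quoted <- regmatches(s, gregexpr("'(?:[^']|'')*'", s))[[1L]]
  placeholders <- sprintf("MKOLBL%06d", seq_along(quoted))
  for (i in seq_along(quoted))
    s <- sub(quoted[i], placeholders[i], s, fixed = TRUE)
  tree <- ape::read.tree(text = s)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (length(quoted)) {
    idx <- match(tree$tip.label, placeholders)
    hit <- !is.na(idx)
    tree$tip.label[hit] <- .unquote_newick_label(quoted[idx[hit]])
  }
  tree
}

#' Read a labelled numeric matrix from TSV
#'
#' Expects column labels in the first row and row labels in the first
#' column. Every cell must be numeric; missing cells are not allowed.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          fill = FALSE)
  if (anyDuplicated(colnames(df)))
    stop("duplicate column labels in matrix TSV")
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(rownames(df), colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric cell at row '", rownames(df)[bad], "', column '",
           colnames(df)[j], "': '", df[[j]][bad], "'")
    }
    m[, j] <- v
  }
  m
}

#' Write a labelled numeric matrix to TSV
#'
#' Inverse of [read_matrix_tsv()]: column labels in the first row (leading
#' empty field over the row-label column), row labels in the first column.
#' Values are written at full double precision so a round trip preserves
#' them to better than 1e-12.
#'
#' @param m Numeric matrix with unique row and column names.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have row and column names")
  if (anyDuplicated(rownames(m))) stop("duplicate row labels")
  if (anyDuplicated(colnames(m))) stop("duplicate column labels")
  df <- as.data.frame(m)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
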