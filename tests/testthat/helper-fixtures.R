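# Fixture builders shared across test files; everything is generated in
# code, nothing is stored on disk.

write_hit_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

hit_row <- function(q, s, evalue, bitscore = 300, pident = 85) {
  paste(q, s, pident, 200, 30, 0, 1, 200, 1, 200,
        format(evalue, scientific = TRUE), bitscore, sep = "\t")
}

write_fasta_lines <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

write_fastq_lines <- function(ids, seqs, quals) {
  path <- withr::local_tempfile(fileext = ".fastq",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# a small additive 4-taxon matrix: ((A,B),(C,D)) with internal edge 1
# external edges A=1, B=2, C=3, D=4
additive4 <- function() {
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  ext <- c(A = 1, B = 2, C = 3, D = 4)
  for (i in 1:3) for (j in (i + 1):4) {
    internal <- if ((i <= 2) != (j <= 2)) 1 else 0
    m[i, j] <- m[j, i] <- ext[i] + ext[j] + internal
  }
  m
}

# two-host composition config with well-separated Dirichlet weights
two_host_config <- function(n_per_host = 10, genera = 6) {
  gn <- paste0("g", seq_len(genera))
  w1 <- stats::setNames(c(100, rep(1, genera - 1)), gn)
  w2 <- stats::setNames(c(1, 100, rep(1, genera - 2)), gn)
  list(list(host = "hostA", n_samples = n_per_host, weights = w1,
            total_mean = 5000),
       list(host = "hostB", n_samples = n_per_host, weights = w2,
            total_mean = 5000))
}

# brute-force one-sided hypergeometric tail by explicit choose() sums;
# independent of phyper
hyper_tail_oracle <- function(A, B, C, D) {
  N <- A + B; K <- C + D
  xs <- C:min(A, K)
  if (length(xs) == 0L || C > min(A, K)) return(0)
  sum(choose(K, xs) * choose(N - K, A - xs)) / choose(N, A)
}
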