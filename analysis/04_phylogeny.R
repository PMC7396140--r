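#!/usr/bin/env Rscript
# Stage 4 — read trimming, dereplication and tree reconstruction.
#
# Quality-trims the synthetic reads (LEADING:17 TRAILING:17 AVGQUAL:25
# MINLEN:200 semantics), dereplicates the survivors, then estimates K2P
# distances on the stage-1 alignment, builds the neighbor-joining tree,
# roots it on a designated outgroup leaf, and compares the topology with
# the generating tree.

suppressMessages(library(microko))
indir <- "results/synthetic"
stopifnot(dir.exists(indir))

reads <- read_fastq(file.path(indir, "reads.fastq"))
trimmed <- trim_reads(reads)
message(length(trimmed), " of ", length(reads), " reads survive trimming")
if (length(trimmed)) {
  derep <- dereplicate(trimmed$seq)
  message(nrow(derep), " unique sequences; most abundant seen ",
          derep$count[1], "x")
  utils::write.table(utils::head(derep, 20), "results/dereplicated_top20.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

aln <- read_alignment_fasta(file.path(indir, "alignment.fasta"))
dm <- k2p_matrix(aln)
write_matrix_tsv(dm, "results/k2p_distances.tsv")
message(sprintf("K2P distances: %d taxa, max %.3f", nrow(dm), max(dm)))

tree <- nj_tree(dm)
outgroup <- "t1"   # stands in for the Acetobacter outgroup role
rooted <- root_with_outgroup(tree, outgroup)
write_newick(rooted, "results/nj_tree.nwk")

truth <- read_newick(file.path(indir, "true_tree.nwk"))
rf <- ape::dist.topo(ape::unroot(tree), ape::unroot(truth))
message("Robinson-Foulds distance to the generating topology: ", rf)
message("wrote results/k2p_distances.tsv, results/nj_tree.nwk")
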