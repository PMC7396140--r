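#!/usr/bin/env Rscript
# Stage 3 — genus composition across hosts.
#
# Coverage-filters the synthetic composition table (totals < 1,000 drop
# out), converts counts to per-sample relative abundances, averages them
# within host categories, collapses to the most abundant genera plus
# "others", and clusters both the host means and the per-sample profiles
# on Euclidean distances.

suppressMessages(library(microko))
indir <- "results/synthetic"
stopifnot(dir.exists(indir))

counts <- read_matrix_tsv(file.path(indir, "composition_counts.tsv"))
sh <- utils::read.delim(file.path(indir, "sample_host.tsv"), header = FALSE,
                        col.names = c("sample", "host"))
hosts <- stats::setNames(sh$host, sh$sample)

kept <- filter_low_coverage(counts)
dropped <- setdiff(rownames(counts), rownames(kept))
message(length(dropped), " low-coverage sample(s) removed: ",
        paste(dropped, collapse = ", "))

rel <- relative_abundance(kept)
hm <- host_mean_composition(rel, hosts)
write_matrix_tsv(hm, "results/host_mean_composition.tsv")
collapsed <- top_n_collapse(hm, 4)
write_matrix_tsv(collapsed, "results/host_composition_top4.tsv")
for (h in rownames(collapsed)) {
  top <- sort(collapsed[h, ], decreasing = TRUE)
  message(h, ": ", paste(sprintf("%s %.0f%%", names(top), 100 * top),
                         collapse = ", "))
}

hc <- hclust_euclidean(rel)
cut <- stats::cutree(hc, k = 2)
agree <- all(vapply(unique(hosts[rownames(rel)]), function(h)
  length(unique(cut[hosts[rownames(rel)] == h])) == 1L, logical(1)))
message("2-cluster cut reproduces the host partition: ", agree)
dend <- ape::as.phylo(hc)
write_newick(dend, "results/sample_dendrogram.nwk")
message("wrote results/host_mean_composition.tsv, ",
        "results/host_composition_top4.tsv, results/sample_dendrogram.nwk")
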