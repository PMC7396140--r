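#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study bundle.
#
# Emulates the structure of the real inputs: a strain x KO paralog count
# matrix with three functional units planted at fold-change 4 in the focal
# strain group; a genus-composition count table for two host categories
# (one dominated by a single genus, as a civet-like host would be, plus a
# diverse host) with three samples forced below the 1,000-count coverage
# threshold; a 16S-like alignment evolved under K2P on a known 8-taxon
# tree; and a batch of quality-patterned reads for the trimming stage.
# Everything is written under results/synthetic/ together with the planted
# truth, so later stages can be checked against it.

suppressMessages(library(microko))
seed <- 20150620   # collection date of the study system, used as the seed
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("KO paralog profiles: 2,000 KOs, 100 units x 20 KOs, 9 background ",
        "genera x 5 strains, 10 focal strains, 3 units planted at fold 4")
ko <- simulate_ko_profiles(seed = seed,
                           planted_units = c("M00001", "M00002", "M00003"),
                           planted_fold_change = 4)
write_matrix_tsv(ko$counts + 0, file.path(out, "ko_counts.tsv"))
writeLines(paste(names(ko$genus_map), ko$genus_map, sep = "\t"),
           file.path(out, "strain_genus.tsv"))
writeLines(vapply(names(ko$units), function(u)
  paste(u, u, paste(ko$units[[u]], collapse = ","), sep = "\t"),
  character(1)), file.path(out, "unit_map.tsv"))

message("Composition: dominated host vs diverse host, 3 low-coverage samples")
gn <- c("Gluconobacter", "Bacteroides", "Prevotella", "Lactobacillus",
        "Streptococcus", "Faecalibacterium")
comp <- simulate_composition(
  list(list(host = "civet_like", n_samples = 12,
            weights = stats::setNames(c(200, 2, 2, 2, 2, 2), gn),
            total_mean = 20000),
       list(host = "diverse", n_samples = 12,
            weights = stats::setNames(c(2, 30, 30, 20, 10, 10), gn),
            total_mean = 20000)),
  n_low_coverage = 3, seed = seed)
write_matrix_tsv(comp$counts + 0, file.path(out, "composition_counts.tsv"))
writeLines(paste(names(comp$hosts), comp$hosts, sep = "\t"),
           file.path(out, "sample_host.tsv"))

message("Sequences: 8-taxon random tree, K2P kappa = 2, 5,000 sites")
tree <- random_tree(8, seed = seed, bl_range = c(0.02, 0.25))
write_newick(tree, file.path(out, "true_tree.nwk"))
aln <- simulate_sequences(tree, 5000, kappa = 2, seed = seed)
write_fasta(aln, file.path(out, "alignment.fasta"))

message("Reads: 150 ramped-quality reads (noisy 5' end, good 3') plus 50 ",
        "uniformly mediocre reads of length 250")
good <- simulate_reads(150, 250, qual_pattern = list(lo = 12, hi = 41),
                       seed = seed)
poor <- simulate_reads(50, 250, qual_pattern = 24, seed = seed + 1)
reads <- quality_reads(id = c(paste0("ramp_", good$id),
                              paste0("flat_", poor$id)),
                       seq = c(good$seq, poor$seq),
                       qual = c(good$qual, poor$qual))
write_fastq(reads, file.path(out, "reads.fastq"))

truth <- list(seed = seed,
              planted_units = ko$truth$planted_units,
              planted_fold_change = ko$truth$planted_fold_change,
              low_coverage_samples = comp$truth$low_coverage_samples,
              tree_file = "true_tree.nwk")
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("Synthetic bundle written to ", out)
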