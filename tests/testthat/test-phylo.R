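test_that("trimming strips low-quality ends and drops failing reads", {
  reads <- quality_reads(
    id = c("lead", "avg", "short", "clean"),
    seq = c(strrep("A", 250), strrep("C", 250), strrep("G", 201),
            strrep("T", 250)),
    qual = list(c(10L, 16L, rep(40L, 248)),
                rep(24L, 250),
                c(rep(40L, 199), 16L, 15L),
                rep(40L, 250)))
  out <- trim_reads(reads)
  # leading bases below 17 stripped, rest kept
  expect_true("lead" %in% out$id)
  expect_equal(nchar(out$seq[out$id == "lead"]), 248)
  expect_equal(out$qual[[which(out$id == "lead")]][1], 40L)
  # mean quality 24 < 25: dropped
  expect_false("avg" %in% out$id)
  # trailing trim leaves 199 < 200: dropped
  expect_false("short" %in% out$id)
  expect_true("clean" %in% out$id)
})

test_that("trimming never lengthens reads and survives empty results", {
  reads <- simulate_reads(10, 250, qual_pattern = list(lo = 5, hi = 41),
                          seed = 3)
  out <- trim_reads(reads, min_len = 1, avg_qual = 0)
  expect_true(all(nchar(out$seq) <= 250))
  allbad <- simulate_reads(4, 50, qual_pattern = 5, seed = 1)
  expect_equal(length(trim_reads(allbad)), 0L)
})

test_that("dereplication counts exact duplicates with stable ordering", {
  d <- dereplicate(c("ACGT", "ACGT", "ACGA"))
  expect_equal(d$sequence, c("ACGT", "ACGA"))
  expect_equal(d$count, c(2L, 1L))
  expect_equal(sum(d$count), 3L)

  distinct <- dereplicate(c("T", "G", "A", "C"))
  expect_equal(distinct$sequence, c("A", "C", "G", "T"))
  expect_true(all(distinct$count == 1L))
  # the head of the list is the most abundant unique sequence
  pool <- c(rep("AAA", 5), rep("CCC", 3), "GGG")
  expect_equal(dereplicate(pool)$sequence[1], "AAA")
})

test_that("K2P distance matches its closed form", {
  a100 <- strrep("A", 100)
  expect_equal(k2p_distance(a100, a100), 0)
  ten_ts <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(a100, ten_ts), -0.5 * log(0.8),
               tolerance = 1e-9)
  expect_lt(abs(k2p_distance(a100, ten_ts) - 0.111572), 1e-6)
  # P = 0.25, Q = 0.25
  b <- paste0(strrep("G", 25), strrep("C", 25), strrep("A", 50))
  a <- strrep("A", 100)
  expect_equal(k2p_distance(a, b),
               -0.5 * log(0.25) - 0.25 * log(0.5), tolerance = 1e-9)
  expect_lt(abs(k2p_distance(a, b) - 0.866434), 1e-6)
})

test_that("K2P uses pairwise deletion, symmetry, and saturates to Inf", {
  a <- "ACGT-ACGTN"
  b <- "ACGTTAC-TA"
  expect_equal(k2p_distance(a, b), k2p_distance(b, a))
  expect_equal(k2p_distance(a, b), 0)   # all comparable sites identical
  expect_error(k2p_distance("----", "AAAA"), "comparable")
  expect_error(k2p_distance("AC", "ACG"), "equal length")
  # saturated: half the sites transversions
  sat_a <- strrep("A", 10)
  sat_b <- paste0(strrep("C", 6), strrep("A", 4))
  expect_equal(k2p_distance(sat_a, sat_b), Inf)
})

test_that("K2P agrees with the ape reference implementation", {
  tr <- random_tree(6, seed = 12, bl_range = c(0.02, 0.2))
  aln <- simulate_sequences(tr, 2000, kappa = 2, seed = 13)
  ours <- k2p_matrix(aln)
  bin <- ape::as.DNAbin(t(sapply(aln, function(s)
    strsplit(tolower(s), "")[[1]])))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("distance matrices are symmetric with warnings on saturation", {
  aln <- c(a = "AAAA", b = "AAAA", c = "AAAA")
  expect_equal(unname(k2p_matrix(aln)), matrix(0, 3, 3))
  sat <- c(a = strrep("A", 10),
           b = paste0(strrep("C", 6), strrep("A", 4)),
           c = strrep("A", 10))
  expect_warning(m <- k2p_matrix(sat), "saturated")
  expect_true(is.infinite(m["a", "b"]))
  expect_error(nj_tree(suppressWarnings(k2p_matrix(sat))), "non-finite")
})

test_that("NJ reproduces the 3-taxon closed form and additive matrices", {
  d <- matrix(c(0, 2, 3,
                2, 0, 4,
                3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))

  m4 <- additive4()
  t4 <- nj_tree(m4)
  co <- ape::cophenetic.phylo(t4)[rownames(m4), colnames(m4)]
  expect_equal(co, m4, tolerance = 1e-9)
})

test_that("NJ is equivariant under taxon reordering", {
  m4 <- additive4()
  t1 <- nj_tree(m4)
  perm <- c(3, 1, 4, 2)
  t2 <- nj_tree(m4[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  co1 <- ape::cophenetic.phylo(t1)
  co2 <- ape::cophenetic.phylo(t2)[rownames(co1), colnames(co1)]
  expect_equal(co1, co2, tolerance = 1e-9)
})

test_that("outgroup rooting splits the separating edge at its midpoint", {
  # unrooted 4-leaf tree; O sits on a 0.4 edge from the ingroup
  tr <- ape::read.tree(text = "(O:0.4,(A:0.1,B:0.2):0.3,C:0.5);")
  rooted <- root_with_outgroup(tr, "O")
  expect_true(ape::is.rooted(rooted))
  root_node <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[, 1] == root_node
  expect_equal(sum(kids), 2L)
  # the two root-adjacent branches each carry half the original edge
  expect_equal(sort(rooted$edge.length[kids]), c(0.2, 0.2))
  # root children partition leaves as {O} vs the rest
  splits <- lapply(rooted$edge[kids, 2], function(n)
    if (n <= length(rooted$tip.label)) rooted$tip.label[n]
    else ape::extract.clade(rooted, n)$tip.label)
  expect_true(any(vapply(splits, function(s) identical(s, "O"), logical(1))))
})

test_that("rooting then unrooting recovers the unrooted topology", {
  tr <- random_tree(7, seed = 40)
  rooted <- root_with_outgroup(tr, "t1")
  expect_equal(ape::dist.topo(ape::unroot(rooted), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
})

test_that("rooting validates the outgroup", {
  tr <- random_tree(6, seed = 41)
  expect_error(root_with_outgroup(tr, tr$tip.label), "proper subset")
  expect_error(root_with_outgroup(tr, "missing"), "not in tree")
  # a non-monophyletic pair: two leaves on opposite sides of the tree
  tr2 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  expect_error(root_with_outgroup(tr2, c("a", "c")), "monophyletic")
})
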