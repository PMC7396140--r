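test_that("KO profile simulation is deterministic and respects the design", {
  cfg <- list(seed = 11, planted = c("M00001", "M00002"))
  a <- simulate_ko_profiles(seed = cfg$seed, planted_units = cfg$planted)
  b <- simulate_ko_profiles(seed = cfg$seed, planted_units = cfg$planted)
  expect_identical(a$counts, b$counts)
  expect_identical(a$units, b$units)

  expect_equal(dim(a$counts), c(10 + 9 * 5, 2000))
  expect_equal(sum(a$genus_map == "Focal"), 10)
  expect_length(a$units, 100)
  expect_true(all(lengths(a$units) == 20))
  expect_error(simulate_ko_profiles(seed = 1, planted_units = "M99999"),
               "not generated")
})

test_that("planted fold-change shows up at the expected Poisson mean", {
  sim <- simulate_ko_profiles(seed = 5, planted_units = "M00001",
                              planted_fold_change = 4, background_mean = 1)
  focal <- sim$counts[sim$genus_map[rownames(sim$counts)] == "Focal", ]
  planted_kos <- sim$units[["M00001"]]
  x <- focal[, planted_kos]
  # mean of n Poisson(4) draws within 3 standard errors
  se <- sqrt(4 / length(x))
  expect_lt(abs(mean(x) - 4), 3 * se)
  # unplanted focal KOs stay at the background mean
  y <- focal[, setdiff(colnames(focal), planted_kos)]
  expect_lt(abs(mean(y) - 1), 3 * sqrt(1 / length(y)))
})

test_that("fold-change 1 is a genuine null", {
  sim <- simulate_ko_profiles(seed = 9, planted_units = "M00001",
                              planted_fold_change = 1)
  focal_mean <- mean(sim$counts[sim$genus_map[rownames(sim$counts)] == "Focal",
                                sim$units[["M00001"]]])
  bg_mean <- mean(sim$counts[sim$genus_map[rownames(sim$counts)] != "Focal",
                             sim$units[["M00001"]]])
  expect_lt(abs(log2(focal_mean / bg_mean)), 0.25)
})

test_that("adding background genera does not perturb focal strains", {
  small <- simulate_ko_profiles(seed = 3, n_background_genera = 5)
  big <- simulate_ko_profiles(seed = 3, n_background_genera = 9)
  focal <- paste0("Focal_s", 1:10)
  expect_identical(small$counts[focal, ], big$counts[focal, ])
})

test_that("composition simulation is deterministic with forced low coverage", {
  cfg <- two_host_config()
  a <- simulate_composition(cfg, n_low_coverage = 3, seed = 21)
  b <- simulate_composition(cfg, n_low_coverage = 3, seed = 21)
  expect_identical(a$counts, b$counts)
  expect_equal(sum(rowSums(a$counts) < 1000), 3)
  expect_setequal(a$truth$low_coverage_samples,
                  rownames(a$counts)[rowSums(a$counts) < 1000])
  expect_equal(unname(table(a$hosts)[c("hostA", "hostB")]),
               c(10L, 10L), ignore_attr = TRUE)
})

test_that("a concentrated Dirichlet host is dominated by its genus", {
  w <- stats::setNames(c(1000, 1), c("g1", "g2"))
  sim <- simulate_composition(
    list(list(host = "h", n_samples = 200, weights = w, total_mean = 5000)),
    seed = 2)
  rel <- sim$counts[, "g1"] / rowSums(sim$counts)
  expect_gte(mean(rel > 0.9), 0.99)
})

test_that("composition config validation catches mismatched genus lists", {
  bad <- list(list(host = "a", n_samples = 2,
                   weights = c(g1 = 1, g2 = 1)),
              list(host = "b", n_samples = 2,
                   weights = c(g2 = 1, g1 = 1)))
  expect_error(simulate_composition(bad, seed = 1), "same genus list")
  neg <- list(list(host = "a", n_samples = 2, weights = c(g1 = 1, g2 = 0)))
  expect_error(simulate_composition(neg, seed = 1), "positive")
})

test_that("K2P sequence simulation matches its own model", {
  # zero branch lengths: all leaves identical
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln0 <- simulate_sequences(tr0, 500, kappa = 2, seed = 4)
  expect_length(unique(aln0), 1L)
  expect_true(all(nchar(aln0) == 500))

  # at separation d the expected fractions of transitions/transversions
  # follow the closed-form K2P transition probabilities
  d <- 0.15; kappa <- 2; L <- 10000
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
  aln <- simulate_sequences(tr, L, kappa = kappa, seed = 8)
  beta <- 1 / (kappa + 2)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) -
    0.5 * exp(-2 * (kappa * beta + beta) * d)
  p_tv <- 0.5 - 0.5 * exp(-4 * beta * d)
  p_diff <- p_ts + p_tv
  obs <- mapply(function(x, y) x != y,
                strsplit(aln[[1]], "")[[1]], strsplit(aln[[2]], "")[[1]])
  se <- sqrt(p_diff * (1 - p_diff) / L)
  expect_lt(abs(mean(obs) - p_diff), 3 * se)

  expect_identical(simulate_sequences(tr, 100, seed = 1),
                   simulate_sequences(tr, 100, seed = 1))
  multi <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1,d:0.1);")
  expect_error(simulate_sequences(multi, 10, seed = 1), "binary")
})

test_that("random trees are binary, unrooted-sized and seeded", {
  expect_error(random_tree(2, seed = 1), "at least 3")
  t3 <- random_tree(3, seed = 1)
  expect_equal(length(t3$tip.label), 3L)
  for (s in 1:20) {
    tr <- random_tree(8, seed = s)
    expect_equal(length(tr$tip.label), 8L)
    expect_equal(nrow(tr$edge), 13L)   # 2n - 3 for unrooted binary
    expect_true(all(tr$edge.length >= 0.05 & tr$edge.length <= 0.5))
  }
  expect_identical(random_tree(6, seed = 5), random_tree(6, seed = 5))
})

test_that("simulated reads carry the requested quality patterns", {
  const <- simulate_reads(2, 250, qual_pattern = 40, seed = 1)
  expect_true(all(vapply(const$qual, function(q) all(q == 40), logical(1))))
  custom <- simulate_reads(1, 10, qual_pattern = c(10, 16, rep(40, 8)),
                           seed = 1)
  expect_equal(custom$qual[[1]][1:2], c(10L, 16L))
  ramp <- simulate_reads(1, 5, qual_pattern = list(lo = 0, hi = 40), seed = 1)
  expect_equal(ramp$qual[[1]], c(0L, 10L, 20L, 30L, 40L))
  expect_identical(simulate_reads(3, 50, 30, seed = 2),
                   simulate_reads(3, 50, 30, seed = 2))
})
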