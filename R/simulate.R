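# Seeded synthetic-data generators. Every generator derives per-item
# sub-seeds from the caller's seed so that enlarging a simulation (more
# strains, more samples) never perturbs items generated earlier.

# deterministic sub-seed, kept inside 32-bit integer range
.subseed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate per-strain KO paralog count profiles with planted enrichment
#'
#' Generates a strain-by-KO count matrix for one focal strain group plus a
#' set of background genera. Background counts are Poisson with a common
#' per-KO mean; in the focal strains, KOs belonging to the planted
#' functional units have their Poisson mean multiplied by
#' `planted_fold_change`. Functional units partition the first
#' `n_units * unit_size` KOs into consecutive blocks.
#'
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @param n_kos Number of KO columns (ids `K00001 ...`).
#' @param n_units Number of functional units (ids `M00001 ...`).
#' @param unit_size KOs per unit; `n_units * unit_size <= n_kos`.
#' @param n_background_genera,strains_per_genus Background design.
#' @param n_focal_strains Number of strains in the focal group.
#' @param background_mean Per-KO Poisson mean in the background (and in the
#'   focal group outside planted units).
#' @param planted_units Character vector of unit ids to enrich in the focal
#'   group (may be empty).
#' @param planted_fold_change Multiplier on the Poisson mean for planted
#'   KOs in focal strains; 1 is the null.
#' @return A list with `counts` (strain x KO integer matrix), `genus_map`
#'   (named character: strain -> genus, focal group genus `"Focal"`),
#'   `units` (named list: unit id -> member KO ids), and `truth` (planted
#'   unit ids, fold change, and the config).
#' @export
simulate_ko_profiles <- function(seed,
                                 n_kos = 2000L,
                                 n_units = 100L,
                                 unit_size = 20L,
                                 n_background_genera = 9L,
                                 strains_per_genus = 5L,
                                 n_focal_strains = 10L,
                                 background_mean = 1,
                                 planted_units = character(0),
                                 planted_fold_change = 4) {
  stopifnot(n_units * unit_size <= n_kos, background_mean > 0,
            planted_fold_change > 0, n_background_genera >= 1,
            strains_per_genus >= 1, n_focal_strains >= 1)
  kos <- sprintf("K%05d", seq_len(n_kos))
  unit_ids <- sprintf("M%05d", seq_len(n_units))
  units <- stats::setNames(
    split(kos[seq_len(n_units * unit_size)],
          rep(seq_len(n_units), each = unit_size)),
    unit_ids)
  missing_units <- setdiff(planted_units, unit_ids)
  if (length(missing_units))
    stop("planted unit id(s) not generated: ",
         paste(missing_units, collapse = ", "))

  genera <- sprintf("Genus%02d", seq_len(n_background_genera))
  bg_strains <- unlist(lapply(genera, function(g)
    paste0(g, "_s", seq_len(strains_per_genus))))
  focal_strains <- paste0("Focal_s", seq_len(n_focal_strains))
  strains <- c(focal_strains, bg_strains)
  genus_map <- stats::setNames(
    c(rep("Focal", n_focal_strains),
      rep(genera, each = strains_per_genus)),
    strains)

  planted_kos <- unlist(units[planted_units], use.names = FALSE)
  lambda_bg <- rep(background_mean, n_kos)
  lambda_focal <- lambda_bg
  lambda_focal[kos %in% planted_kos] <- background_mean * planted_fold_change

  counts <- matrix(0L, length(strains), n_kos,
                   dimnames = list(strains, kos))
  for (i in seq_along(strains)) {
    set.seed(.subseed(seed, i))
    lam <- if (genus_map[[strains[i]]] == "Focal") lambda_focal else lambda_bg
    counts[i, ] <- stats::rpois(n_kos, lam)
  }
  truth <- list(planted_units = planted_units,
                planted_kos = planted_kos,
                planted_fold_change = planted_fold_change,
                background_mean = background_mean,
                seed = seed)
  list(counts = counts, genus_map = genus_map, units = units, truth = truth)
}

#' Simulate a genus-composition count table from Dirichlet-multinomial hosts
#'
#' Each host category draws per-sample genus proportions from its own
#' Dirichlet distribution and counts from a multinomial with a
#' Poisson-distributed sequencing depth. A chosen number of samples is
#' forced below the coverage threshold (total < 1,000) to exercise the
#' coverage filter.
#'
#' @param hosts A list of host specifications, each a list with elements
#'   `host` (label), `n_samples`, `weights` (named positive Dirichlet
#'   weights over the shared genus list) and `total_mean` (mean sequencing
#'   depth; default 10000).
#' @param n_low_coverage Number of samples (chosen at random across hosts)
#'   whose totals are redrawn uniformly from 100..999.
#' @param seed Integer seed.
#' @return A list with `counts` (sample x genus integer matrix), `hosts`
#'   (named character: sample -> host label), and `truth` (host weights,
#'   indices of forced low-coverage samples).
#' @export
simulate_composition <- function(hosts, n_low_coverage = 0L, seed = 1L) {
  stopifnot(is.list(hosts), length(hosts) >= 1L)
  genus_names <- names(hosts[[1L]]$weights)
  if (is.null(genus_names) || any(!nzchar(genus_names)))
    stop("host weights must be a named vector over the genus list")
  for (h in hosts) {
    if (!identical(names(h$weights), genus_names))
      stop("all hosts must share the same genus list, in the same order")
    if (any(h$weights <= 0)) stop("dirichlet weights must be strictly positive")
  }
  n_total <- sum(vapply(hosts, function(h) as.integer(h$n_samples), integer(1L)))
  if (n_low_coverage > n_total)
    stop("n_low_coverage exceeds the number of samples")

  set.seed(.subseed(seed, 0L))
  low_idx <- if (n_low_coverage > 0L)
    sort(sample.int(n_total, n_low_coverage)) else integer(0)

  counts <- matrix(0L, n_total, length(genus_names),
                   dimnames = list(character(n_total), genus_names))
  host_lab <- character(n_total)
  i <- 0L
  for (h in hosts) {
    total_mean <- if (is.null(h$total_mean)) 10000 else h$total_mean
    for (s in seq_len(h$n_samples)) {
      i <- i + 1L
      set.seed(.subseed(seed, i))
      p <- .rdirichlet1(h$weights)
      total <- if (i %in% low_idx) sample(100:999, 1L)
               else max(1L, stats::rpois(1L, total_mean))
      counts[i, ] <- as.integer(stats::rmultinom(1L, total, p))
      rownames(counts)[i] <- sprintf("%s_%03d", h$host, s)
      host_lab[i] <- h$host
    }
  }
  names(host_lab) <- rownames(counts)
  truth <- list(weights = lapply(hosts, `[[`, "weights"),
                host_labels = vapply(hosts, `[[`, character(1L), "host"),
                low_coverage_samples = rownames(counts)[low_idx],
                seed = seed)
  list(counts = counts, hosts = host_lab, truth = truth)
}

# K2P per-branch transition probability matrix (closed form).
# Rates normalised so branch length t is the expected substitutions/site:
# alpha = kappa/(kappa+2) (transitions), beta = 1/(kappa+2) (transversions).
# Base order A, C, G, T; transitions are A<->G and C<->T.
.k2p_pmatrix <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2   # transition
  p_tv <- 0.25 - 0.25 * e1              # each of two transversions
  p_same <- 1 - p_ts - 2 * p_tv
  bases <- c("A", "C", "G", "T")
  P <- matrix(p_tv, 4, 4, dimnames = list(bases, bases))
  diag(P) <- p_same
  P["A", "G"] <- P["G", "A"] <- p_ts
  P["C", "T"] <- P["T", "C"] <- p_ts
  P
}

#' Evolve sequences on a tree under the Kimura 2-parameter model
#'
#' Simulates a gapless nucleotide alignment: the root sequence is uniform
#' over A,C,G,T per site, and each branch applies the exact K2P transition
#' probability matrix for its length (expected substitutions per site).
#' No indels are introduced.
#'
#' @param tree A binary `phylo` tree with branch lengths in expected
#'   substitutions/site.
#' @param length Number of sites.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param seed Integer seed.
#' @return A named character vector: one sequence per leaf, all of equal
#'   length.
#' @export
simulate_sequences <- function(tree, length, kappa = 2, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), length >= 1L, kappa > 0)
  if (!ape::is.binary(tree))
    stop("tree must be binary (fully bifurcating)")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  set.seed(.subseed(seed, 0L))
  states <- vector("list", ntip + nnode)
  root <- ntip + 1L
  states[[root]] <- sample.int(4L, length, replace = TRUE)
  # preorder traversal: parents before children
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    P <- .k2p_pmatrix(tree$edge.length[e], kappa)
    ps <- states[[parent]]
    cs <- integer(length)
    for (b in 1:4) {
      idx <- which(ps == b)
      if (length(idx))
        cs[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
    states[[child]] <- cs
  }
  out <- vapply(seq_len(ntip),
                function(i) paste(bases[states[[i]]], collapse = ""),
                character(1L))
  stats::setNames(out, tree$tip.label)
}

#' Generate a random unrooted binary tree
#'
#' Uniformly random binary topology by sequential random joins, with
#' branch lengths drawn uniformly from `bl_range`.
#'
#' @param n_taxa Number of leaves (>= 3), labelled `t1 ... tn`.
#' @param seed Integer seed.
#' @param bl_range Length-2 vector `(lo, hi)`, `0 < lo <= hi`.
#' @return An unrooted binary `phylo` with `2 * n_taxa - 3` edges.
#' @export
random_tree <- function(n_taxa, seed = 1L, bl_range = c(0.05, 0.5)) {
  if (n_taxa < 3L) stop("n_taxa must be at least 3")
  stopifnot(length(bl_range) == 2L, bl_range[1L] > 0,
            bl_range[1L] <= bl_range[2L])
  set.seed(.subseed(seed, 0L))
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) stats::runif(n, bl_range[1L], bl_range[2L]))
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree
}

#' Simulate reads with controlled quality profiles
#'
#' Produces reads whose quality arrays follow the requested pattern
#' exactly, with random bases: fixtures for quality-trimming behaviour.
#'
#' @param n Number of reads.
#' @param length Read length.
#' @param qual_pattern One of: a single number (constant quality), a
#'   numeric vector of length `length` (custom per-base profile), or
#'   `list(lo =, hi =)` (linear ramp from `lo` at the first base to `hi`
#'   at the last).
#' @param seed Integer seed (drives the bases only).
#' @return A [quality_reads] object.
#' @export
simulate_reads <- function(n, length, qual_pattern = 40, seed = 1L) {
  stopifnot(n >= 1L, length >= 1L)
  qual <- if (is.list(qual_pattern)) {
    round(seq(qual_pattern$lo, qual_pattern$hi, length.out = length))
  } else if (length(qual_pattern) == 1L) {
    rep(as.integer(qual_pattern), length)
  } else if (length(qual_pattern) == length) {
    as.integer(qual_pattern)
  } else {
    stop("qual_pattern must be a constant, a ramp list(lo=, hi=), or a ",
         "vector of length ", length)
  }
  bases <- c("A", "C", "G", "T")
  seqs <- character(n)
  for (i in seq_len(n)) {
    set.seed(.subseed(seed, i))
    seqs[i] <- paste(sample(bases, length, replace = TRUE), collapse = "")
  }
  quality_reads(id = sprintf("read%04d", seq_len(n)),
                seq = seqs,
                qual = rep(list(qual), n))
}
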