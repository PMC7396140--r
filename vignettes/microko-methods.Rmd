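---
title: "Methods: KO paralog enrichment, composition clustering and 16S phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KO paralog enrichment, composition clustering and 16S phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microko)
```

# The scientific problem

A fecal microbiome dominated by a single bacterial genus — the motivating
case is the civet-cat gut, overwhelmingly colonised by *Gluconobacter* —
raises two linked questions. First, *how unusual is that composition*
relative to the fecal communities of other hosts? Second, *what is the
dominant genus functionally equipped to do* that the typical gut flora is
not? `microko` implements the comparative pipeline for both questions,
plus the phylogenetic placement of the dominant organism's 16S sequences,
with seeded synthetic-data generators so that every stage can be tested
against a planted truth.

# The KO paralog enrichment model

Genomes are annotated against KEGG Orthology (KO) groups from aligner hit
tables: each gene takes its *top* hit (file order; aligners emit best
first) and is assigned that KO only when the hit's e-value is strictly
below `e_max = 1e-8`. The paralog count of KO $i$ in a genome is the
number of genes assigned to it; a genome lacking the KO has count 0.

Within each genus the per-strain counts are summarised by the **median**
(midpoint rule for even cardinality, so half-integers occur). The focal
genus is compared against $g$ background genera through the copy-number
ratio

$$ r_i = \frac{m_i}{\tfrac{1}{g}\sum_{j=1}^{g} b_{ij}}, $$

where $m_i$ is the focal median and $b_{ij}$ the median of background
genus $j$. KOs absent from every profile are dropped from the universe;
$\log_2 r_i \ge 1$ (i.e. at least a doubling of median copy number) flags
KO $i$ as over-represented. $r_i = \infty$ (focal-only KOs) qualifies;
$r_i = 0$ gives $\log_2 r_i = -\infty$ and never qualifies.

Each functional unit (KEGG module or pathway, a named KO set) is then
tested: with $A$ = unit KOs in the universe, $B$ = universe KOs outside
the unit, $C$/$D$ = over-represented KOs inside/outside, the one-sided
Fisher's exact test is run on the 2x2 table $[[C, A-C], [D, B-D]]$ — the
upper hypergeometric tail $P(X \ge C)$ with population $A+B$, successes
$C+D$ and draws $A$. Significance is declared at $p \le 0.05$ on the
*uncorrected* p-value; a Benjamini–Hochberg q-value column is emitted for
reference but deliberately never drives the flag, so results remain
comparable with the procedure the pipeline reproduces.

Design choices where the procedure was genuinely open:

* **Sidedness.** Only over-representation is of interest, so the test is
  one-sided "greater" by default; `alternative = "two.sided"` is
  available and delegates to `stats::fisher.test()`.
* **Threshold boundary.** The flag is inclusive (`log2fc >= 1`);
  `inclusive = FALSE` switches to strict, since both conventions appear
  in practice.
* **Contingency layout.** The four counts $A$–$D$ as commonly stated are
  not disjoint ($C \subseteq A$); the only standard enrichment table
  consistent with them is $[[C, A-C], [D, B-D]]$, which is what is
  tested. The "outside the unit" reading of $D$ is used — the literal
  "inside" reading would duplicate $C$.
* **Shared universe.** The background mean uses the same KO universe for
  every genus (absent = median 0) rather than per-genus universes.

# Composition processing

The 16S genus-count pipeline runs in the fixed order *filter →
normalise → host-average → collapse → cluster*:

1. samples with total aligned count **< 1,000** are removed (strict
   inequality; a 1,000-count sample is retained);
2. counts become per-sample relative abundances (rows sum to 1 within
   1e-9);
3. hosts are summarised by the unweighted mean of their samples'
   fractions — scaling any sample's counts leaves the host mean unchanged;
4. for presentation, the `n = 10` genera with the largest mean abundance
   across hosts are kept and the remainder summed into `"others"`,
   preserving row sums;
5. profiles are clustered agglomeratively on Euclidean distances.

The linkage is average (UPGMA) by default — the common choice for
abundance heatmaps, with monotone merge heights — with single, complete
and Ward (D2) available. Clustering is applied to the *full* genus
matrix, not the collapsed one; the collapse exists only for display.
16S copy-number correction is deliberately off: the pipeline consumes
genus tables produced without it, and correcting here would make the
profiles incomparable to their reference.

# Phylogenetics

Reads are quality-trimmed with single-end Trimmomatic semantics
`LEADING:17 TRAILING:17 AVGQUAL:25 MINLEN:200`, applied in that order per
read: strip 5' bases with Phred < 17, strip 3' bases with Phred < 17,
drop the read if the surviving mean quality is below 25 or the surviving
length below 200. Surviving amplicons are dereplicated exactly (counts
summing to the input size, ties broken lexicographically), so the head of
the list is each sample's most abundant unique sequence.

Distances on an aligned set use the Kimura 2-parameter estimator
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with $P$ and $Q$ the
transition and transversion fractions over comparable sites. Gap and
ambiguity handling is **pairwise deletion** by default (robust for
partially overlapping amplicon alignments); `deletion = "complete"` drops
every column containing a non-ACGT character first. A pair whose log
arguments reach 0 is saturated and reported as `Inf`; the tree builder
refuses such matrices rather than guessing.

Trees are built by neighbor-joining (Saitou–Nei, via `ape::nj()`), which
is exact on additive matrices — the property the test suite exploits.
Negative branch lengths are retained as computed (`clamp = TRUE` zeroes
them for display only), because clamping would destroy the additivity
identity the exactness tests check. Outgroup rooting places the root at
the midpoint of the edge separating a monophyletic outgroup from the
ingroup; a non-monophyletic multi-taxon outgroup is an error, not a
silent re-rooting. Byte-identical agreement with any particular GUI
implementation's trees is not claimed — tie-breaking and gap options of
such tools are not recoverable — only agreement at the level of the
algorithm's definition.

# The synthetic-data generators

The generators produce inputs with the statistical structure the analysis
assumes, plus the planted truth needed for recovery tests:

* **KO profiles** — per-strain counts are Poisson with mean
  `background_mean = 1` per KO; focal strains multiply the mean by
  `planted_fold_change` (default 4) on the KOs of the planted units. The
  default design is 2,000 KOs, 100 units x 20 KOs, 9 background genera x
  5 strains, 10 focal strains. Poisson is the minimal
  overdispersion-free count model and makes a planted fold-change
  directly interpretable as a mean ratio; real paralog counts are more
  dispersed and co-vary along operons, which this deliberately ignores.
* **Composition** — per-sample genus proportions are Dirichlet with
  host-specific weights, counts multinomial at a Poisson-distributed
  depth (default mean 10,000); `n_low_coverage` samples are forced below
  the 1,000 threshold to exercise the filter. A concentrated weight
  vector emulates a dominated, civet-like host.
* **Sequences** — evolved site-independently on a known binary tree
  under K2P with uniform base frequencies, using the closed-form
  per-branch transition matrices (exact at any branch length, unlike
  event-stepping simulation). No indels, so the output is already an
  alignment.
* **Reads** — carry exactly the requested quality pattern (constant,
  ramp, or custom vector), giving sharp trimming fixtures.

Determinism is a contract: every generator call derives per-item
sub-seeds from the caller's seed, so the same configuration reproduces
byte-identical output and enlarging one part of a design (say, adding
background genera) does not perturb the parts already generated.

Passing recovery tests on these generators shows the *procedure* is
implemented correctly under its own model assumptions. It does not show
robustness to overdispersion, compositional coupling between KOs,
chimeras, sequencing error or alignment error — none of which the
generators emulate.

# Numerical choices and problem sizes

* The exact test is computed with `stats::phyper` on the upper tail; the
  test suite checks it against an explicit `choose()`-ratio tail sum for
  every margin with $A+B \le 40$ (135,750 tables) at 1e-12.
* Enrichment results are sorted by ascending p-value with ties broken
  lexicographically by unit id; hit-table ranking is file order with no
  re-sorting; Q-criterion and clustering tie-breaks are delegated to
  `ape::nj()` and `stats::hclust()`, which are deterministic for fixed
  input order.
* Matrix TSVs are written at full double precision (round-trip within
  1e-12); Newick branch lengths at 10 significant digits (round-trip
  within 1e-9); labels with Newick metacharacters are single-quoted.
* Recovery experiments run at 100 seeds for enrichment (fold 4 planted,
  fold 1 null) and NJ topology recovery (6–10 taxa), 200 replicates for
  the K2P estimator at $d = 0.15$ (10,000 sites), and 20 seeds for the
  two-host clustering check — sizes chosen so each property is measured
  at a few-percent resolution while the whole suite stays interactive.

# Known limitations

* The annotation filter re-applies only the e-value rule; identity and
  score cutoffs are treated as properties of the upstream aligner run
  that produced the hit table.
* FASTQ is fixed to Phred+33; no encoding auto-detection.
* Fisher results are reported uncorrected by design (see above); users
  wanting FDR control should filter on the emitted q-value instead.
* The K2P estimator returns `Inf` for saturated pairs instead of a
  capped distance; downstream tree building requires finite matrices.
* No bootstrap support values; no maximum-likelihood alternative.
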