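# KO-ratio statistic and functional-unit enrichment.
#
# The statistic: for each KO i, ratio_i = m_i / b_i where m_i is the focal
# genus's median paralog count and b_i the arithmetic mean of the
# background genera's medians; log2(ratio_i) >= 1 flags the KO as
# over-represented. Each functional unit (KEGG module/pathway) is then
# tested for enrichment of over-represented KOs by a one-sided Fisher's
# exact test on [[C, A-C], [D, B-D]] where A = KOs in the unit, B = KOs
# outside it, C/D = over-represented KOs inside/outside.

#' KO copy-number ratio between a focal genus and background genera
#'
#' For every KO in the shared universe (union of columns; a missing column
#' is a median of 0), computes the focal median over the mean of the
#' background genus medians, and its log2. KOs absent from focal and all
#' background profiles are dropped from the universe.
#'
#' @param focal Named numeric vector: the focal genus's median paralog
#'   profile (one row of a genus-level matrix).
#' @param background Numeric matrix, background genera x KOs (one row per
#'   genus of median paralog counts).
#' @return A data.frame with columns `ko`, `focal_median`,
#'   `background_mean`, `ratio`, `log2fc`. `ratio` is `Inf` when the
#'   background mean is 0 and the focal median positive; `log2fc` is
#'   `-Inf` at ratio 0 and `Inf` at infinite ratio.
#' @export
ko_ratio <- function(focal, background) {
  if (is.null(dim(background)) || nrow(background) < 1L)
    stop("at least one background genus profile is required")
  if (is.null(names(focal)) || is.null(colnames(background)))
    stop("profiles must carry KO names")
  universe <- union(names(focal), colnames(background))
  f <- stats::setNames(numeric(length(universe)), universe)
  f[names(focal)] <- focal
  b <- matrix(0, nrow(background), length(universe),
              dimnames = list(rownames(background), universe))
  b[, colnames(background)] <- background
  if (any(f < 0) || any(b < 0)) stop("paralog medians must be non-negative")
  bmean <- colMeans(b)
  keep <- f > 0 | bmean > 0
  f <- f[keep]
  bmean <- bmean[keep]
  ratio <- ifelse(bmean > 0, f / bmean, ifelse(f > 0, Inf, NaN))
  data.frame(ko = names(f),
             focal_median = unname(f),
             background_mean = unname(bmean),
             ratio = unname(ratio),
             log2fc = unname(log2(ratio)),
             stringsAsFactors = FALSE)
}

#' Over-represented KO set at a log2 fold-change threshold
#'
#' @param table A KO-ratio data.frame from [ko_ratio()].
#' @param threshold log2 fold-change threshold (default 1.0).
#' @param inclusive If `TRUE` (default) the boundary qualifies
#'   (`log2fc >= threshold`); if `FALSE`, strictly greater.
#' @return Character vector of over-represented KO ids.
#' @export
overrepresented_set <- function(table, threshold = 1.0, inclusive = TRUE) {
  stopifnot(is.data.frame(table), all(c("ko", "log2fc") %in% names(table)))
  sel <- if (inclusive) table$log2fc >= threshold else table$log2fc > threshold
  table$ko[sel]
}

#' Contingency counts for one functional unit
#'
#' A = KOs of the unit present in the universe, B = universe KOs outside
#' the unit, C = over-represented KOs inside the unit, D = over-represented
#' KOs outside it. Unit members not in the universe are ignored.
#'
#' @param members Character vector of the unit's member KOs.
#' @param universe Character vector: the KO universe under test.
#' @param over Character vector of over-represented KOs (subset of
#'   `universe`).
#' @return Named integer vector `c(A=, B=, C=, D=)`, or `NULL` (with a
#'   warning) when no member survives the universe intersection.
#' @export
unit_contingency <- function(members, universe, over) {
  if (length(setdiff(over, universe)))
    stop("over-represented set must be a subset of the universe")
  inside <- intersect(members, universe)
  A <- length(inside)
  if (A == 0L) {
    warning("unit has no members in the KO universe; skipped")
    return(NULL)
  }
  B <- length(universe) - A
  C <- length(intersect(inside, over))
  D <- length(over) - C
  c(A = A, B = B, C = C, D = D)
}

#' One-sided Fisher's exact test for unit enrichment
#'
#' Exact upper-tail p-value for the 2x2 table `[[C, A-C], [D, B-D]]`:
#' the probability that a hypergeometric draw of `A` from a population of
#' `A + B` containing `C + D` successes yields at least `C` successes.
#'
#' @param A,B,C,D Contingency counts (see [unit_contingency()]).
#' @param alternative `"greater"` (default; over-representation) or
#'   `"two.sided"` (delegated to [stats::fisher.test()]).
#' @return p-value in (0, 1].
#' @export
fisher_one_sided <- function(A, B, C, D, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(C >= 0, D >= 0, C <= A, D <= B)
  if (alternative == "two.sided") {
    tab <- matrix(c(C, D, A - C, B - D), 2L)
    return(stats::fisher.test(tab)$p.value)
  }
  # P(X >= C), X ~ Hypergeom(population A+B, successes C+D, draws A)
  stats::phyper(C - 1, m = C + D, n = A + B - C - D, k = A,
                lower.tail = FALSE)
}

#' Test every functional unit for over-represented-KO enrichment
#'
#' Runs the contingency construction and exact test over a unit map,
#' flags significance at `alpha` with no multiple-testing correction (a
#' Benjamini-Hochberg q-value column is emitted for reference but never
#' drives the flag), and sorts results by ascending p-value with ties
#' broken lexicographically by unit id.
#'
#' @param units Named list: unit id -> character vector of member KOs.
#'   An optional `labels` attribute (named character) supplies display
#'   labels.
#' @param table KO-ratio data.frame from [ko_ratio()]; its `ko` column is
#'   the universe.
#' @param threshold,inclusive Passed to [overrepresented_set()].
#' @param alpha Significance level on the uncorrected p-value
#'   (default 0.05, `p <= alpha`).
#' @param alternative Passed to [fisher_one_sided()].
#' @return A data.frame with one row per tested unit: `unit_id`, `label`,
#'   `A`, `B`, `C`, `D`, `p_value`, `q_value`, `significant`,
#'   `over_kos` (comma-separated over-represented members).
#' @export
enrich_units <- function(units, table, threshold = 1.0, inclusive = TRUE,
                         alpha = 0.05, alternative = "greater") {
  if (!is.list(units) || length(units) == 0L || is.null(names(units)))
    stop("units must be a non-empty named list of KO membership vectors")
  labels <- attr(units, "labels")
  universe <- table$ko
  over <- overrepresented_set(table, threshold, inclusive)
  rows <- lapply(names(units), function(uid) {
    ct <- unit_contingency(units[[uid]], universe, over)
    if (is.null(ct)) return(NULL)
    p <- fisher_one_sided(ct["A"], ct["B"], ct["C"], ct["D"],
                          alternative = alternative)
    data.frame(unit_id = uid,
               label = if (!is.null(labels) && uid %in% names(labels))
                 labels[[uid]] else uid,
               A = ct[["A"]], B = ct[["B"]], C = ct[["C"]], D = ct[["D"]],
               p_value = p,
               over_kos = paste(intersect(intersect(units[[uid]], universe),
                                          over), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stop("no unit has members in the KO universe")
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value <= alpha
  out <- out[order(out$p_value, out$unit_id),
             c("unit_id", "label", "A", "B", "C", "D", "p_value",
               "q_value", "significant", "over_kos")]
  rownames(out) <- NULL
  out
}
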