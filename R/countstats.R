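## Exact small-count statistics for the chromosome-loss and localization
## assays.

#' Two-sided Fisher's exact test by hypergeometric enumeration
#'
#' Exact two-sided p-value for the 2x2 table \code{rbind(c(a, b), c(c, d))}
#' under fixed margins, using the probability-mass rule (the dominant
#' convention): the p-value sums the hypergeometric probabilities of every
#' table with the same margins whose probability does not exceed that of
#' the observed table, within relative tolerance 1e-7. All mass
#' computations are carried in log space. The all-zero table returns p = 1
#' by convention.
#'
#' @param a,b,c,d non-negative integer cell counts (rows = groups, columns
#'   = outcome classes).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisherExact2x2(29, 65, 3, 131)   # sectoring: bub1-null vs wild-type
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (sum(counts) == 0) return(1)
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  k <- max(0, n1 - m2):min(m1, n1)
  logp <- lchoose(m1, k) + lchoose(m2, n1 - k) - lchoose(m1 + m2, n1)
  obs <- logp[k == a]
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

#' Sectoring-rate comparisons against a reference genotype
#'
#' Fisher's exact test of each genotype's sectored/white colony counts
#' against the reference genotype, with significance stars assigned at the
#' P < 0.001 threshold used for the chromosome-loss assay.
#'
#' @param tables data.frame with columns \code{genotype}, \code{sectored},
#'   \code{white}.
#' @param reference reference genotype label (e.g. wild-type).
#' @param starThreshold p-value threshold for a star (default 0.001).
#' @return \code{tables} with added columns \code{p} and \code{starred}
#'   (reference row: \code{NA}).
#' @examples
#' sectoringSummary(data.frame(
#'   genotype = c("WT", "bub1d", "mad3d", "SCP"),
#'   sectored = c(3, 29, 5, 3), white = c(131, 65, 177, 207)), "WT")
#' @export
sectoringSummary <- function(tables, reference, starThreshold = 0.001) {
  stopifnot(all(c("genotype", "sectored", "white") %in% names(tables)))
  if (!reference %in% tables$genotype)
    stop("reference genotype ", reference, " not present")
  ref <- tables[tables$genotype == reference, ][1, ]
  tables$p <- NA_real_
  for (i in seq_len(nrow(tables))) {
    if (tables$genotype[i] == reference) next
    tables$p[i] <- fisherExact2x2(tables$sectored[i], tables$white[i],
                                  ref$sectored, ref$white)
  }
  tables$starred <- !is.na(tables$p) & tables$p < starThreshold
  tables$starred[tables$genotype == reference] <- NA
  tables
}

#' Construct localization counts for one strain
#'
#' Per-cell localization scoring: cells showing nuclear signal only,
#' kinetochore puncta only, or both compartments (cells scored in both
#' contribute to both marginal fractions); cells without scorable signal
#' are discarded upstream and carried only as a count.
#'
#' @param strain strain label.
#' @param nucleusOnly,punctaOnly,both,discarded non-negative integer counts.
#' @return One-row data.frame.
#' @export
localizationCounts <- function(strain, nucleusOnly, punctaOnly, both,
                               discarded = 0) {
  counts <- c(nucleusOnly, punctaOnly, both, discarded)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  data.frame(strain = strain, nucleus_only = nucleusOnly,
             puncta_only = punctaOnly, both = both, discarded = discarded,
             stringsAsFactors = FALSE)
}

## In/out-of-category split of scored cells: the "both" cells count toward
## either marginal category.
categoryCounts <- function(row, category = c("nucleus", "puncta")) {
  category <- match.arg(category)
  inCat <- if (category == "nucleus") row$nucleus_only + row$both
           else row$puncta_only + row$both
  total <- row$nucleus_only + row$puncta_only + row$both
  c(inCat = inCat, outCat = total - inCat, total = total)
}

#' Bootstrap confidence interval for a localization fraction
#'
#' Percentile bootstrap of a marginal category fraction: scored cells are
#' resampled with replacement, the fraction recomputed per replicate, and
#' the 2.5/97.5 percentiles reported. Deterministic given \code{seed}.
#'
#' @param counts one-row data.frame as from \code{\link{localizationCounts}}.
#' @param category \code{"nucleus"} or \code{"puncta"}.
#' @param nBoot bootstrap replicates (>= 1000).
#' @param seed integer RNG seed.
#' @param level confidence level (default 0.95).
#' @return A list with \code{fraction}, \code{lower}, \code{upper},
#'   \code{n} (scored cells).
#' @export
bootstrapFractionCI <- function(counts, category = "nucleus",
                                nBoot = 2000, seed = 1, level = 0.95) {
  if (nBoot < 1000) stop("nBoot must be at least 1000")
  cc <- categoryCounts(counts, category)
  if (cc["total"] == 0) stop("no scored cells")
  set.seed(seed)
  boots <- rbinom(nBoot, cc["total"], cc["inCat"] / cc["total"]) /
    cc["total"]
  qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  list(fraction = unname(cc["inCat"] / cc["total"]), lower = qs[1],
       upper = qs[2], n = unname(cc["total"]))
}

#' Corrected pairwise Fisher tests on localization fractions
#'
#' Every pair of strains is compared on in-category versus out-of-category
#' scored-cell counts with the exact Fisher test, and the p-values are
#' adjusted by Holm-Bonferroni (the correction is a package decision; the
#' assay's figure states only that a correction was applied). Pairs with
#' adjusted p below \code{alpha} are flagged significant.
#'
#' @param counts data.frame of localization counts, one row per strain.
#' @param category \code{"nucleus"} or \code{"puncta"}.
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.frame with one row per strain pair: \code{strain1},
#'   \code{strain2}, \code{p}, \code{p_adj}, \code{significant}.
#' @export
pairwiseFisherCorrected <- function(counts, category = "nucleus",
                                    alpha = 0.05) {
  if (nrow(counts) < 2) stop("need at least two strains")
  pairs <- utils::combn(seq_len(nrow(counts)), 2)
  rows <- apply(pairs, 2, function(ij) {
    c1 <- categoryCounts(counts[ij[1], ], category)
    c2 <- categoryCounts(counts[ij[2], ], category)
    data.frame(strain1 = counts$strain[ij[1]],
               strain2 = counts$strain[ij[2]],
               p = fisherExact2x2(c1["inCat"], c1["outCat"],
                                  c2["inCat"], c2["outCat"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "holm")
  out$significant <- out$p_adj < alpha
  out
}
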