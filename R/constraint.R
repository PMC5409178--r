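## Constraint-change analysis: map conserved regions detected in the
## pre-duplication sub-alignment onto the full alignment (which includes the
## post-duplication paralogs), then test each region for a change in
## evolutionary rate inside a flagged paralog clade with a one-rate versus
## two-rate likelihood-ratio test (chi-square, 1 df).

#' Map conserved regions into full-alignment coordinates
#'
#' Regions were decoded on the pre-duplication sub-alignment; this
#' translates their column intervals into the coordinates of the full
#' alignment through the rows the two alignments share. Shared rows must
#' contain the same ungapped sequences; their residue indices define the
#' column correspondence. All coordinates are 0-based half-open.
#'
#' @param regions data.frame with columns \code{start}, \code{end} (as from
#'   \code{\link{decodeRegions}}).
#' @param preAln,fullAln character matrices; \code{rownames(preAln)} must be
#'   a subset of \code{rownames(fullAln)}.
#' @return \code{regions} with added \code{full_start}, \code{full_end}
#'   (\code{NA} for regions that cannot be placed).
#' @export
mapRegions <- function(regions, preAln, fullAln) {
  shared <- intersect(rownames(preAln), rownames(fullAln))
  if (!length(shared)) stop("no shared rows between the alignments")
  isGap <- function(x) toupper(x) %in% GAP_CHARS
  colMap <- rep(NA_integer_, ncol(preAln))
  for (r in shared) {
    pre <- preAln[r, ]; full <- fullAln[r, ]
    preRes <- which(!isGap(pre)); fullRes <- which(!isGap(full))
    if (length(preRes) != length(fullRes) ||
        any(toupper(pre[preRes]) != toupper(full[fullRes])))
      stop("shared row ", r, " differs between the alignments")
    mapped <- rep(NA_integer_, ncol(preAln))
    mapped[preRes] <- fullRes
    conflict <- !is.na(colMap) & !is.na(mapped) & colMap != mapped
    if (any(conflict))
      stop("inconsistent column correspondence across shared rows")
    colMap[is.na(colMap)] <- mapped[is.na(colMap)]
  }
  regions$full_start <- NA_integer_
  regions$full_end <- NA_integer_
  for (i in seq_len(nrow(regions))) {
    cols <- colMap[(regions$start[i] + 1):regions$end[i]]
    cols <- cols[!is.na(cols)]
    if (length(cols)) {
      regions$full_start[i] <- min(cols) - 1L
      regions$full_end[i] <- max(cols)
    }
  }
  regions
}

## Maximised log-likelihood of the region columns under a shared rate; and
## under clade-specific rates (pre/post duplication), by golden-section
## coordinate optimisation initialised at the one-rate optimum (which
## guarantees the nested-model inequality lnL_two >= lnL_one).
regionRateFits <- function(model, idx, cladeEdges, rhoMax = 10,
                           tol = 1e-6, eig = substitutionEigen(model)) {
  nEdge <- nrow(model@tree$edge)
  ll <- function(rPre, rPost) {
    rate <- rep(rPre, nEdge)
    rate[cladeEdges] <- rPost
    sum(pruneLogLik(model, idx, rate, eig))
  }
  one <- optimize(function(r) ll(r, r), interval = c(1e-4, rhoMax),
                  maximum = TRUE, tol = tol)
  rPre <- rPost <- one$maximum
  lnL <- one$objective
  for (sweep in 1:25) {
    fPre <- optimize(function(r) ll(r, rPost), interval = c(1e-4, rhoMax),
                     maximum = TRUE, tol = tol)
    rPre <- fPre$maximum
    fPost <- optimize(function(r) ll(rPre, r), interval = c(1e-4, rhoMax),
                      maximum = TRUE, tol = tol)
    rPost <- fPost$maximum
    if (fPost$objective - lnL < 1e-9) { lnL <- max(lnL, fPost$objective); break }
    lnL <- fPost$objective
  }
  list(lnLOne = one$objective, rhoOne = one$maximum,
       lnLTwo = max(lnL, one$objective), rhoPre = rPre, rhoPost = rPost,
       atBound = max(rPre, rPost, one$maximum) > rhoMax * (1 - 1e-4))
}

#' Likelihood-ratio test for a post-duplication constraint change
#'
#' For one mapped region, compares a model with a single evolutionary-rate
#' multiplier shared by all branches against a model with one multiplier
#' outside the flagged clade (pre-duplication) and another inside it
#' (post-duplication, stem branch included). Both fits use bounded
#' golden-section optimisation (tolerance 1e-6); the statistic
#' 2(lnL2 - lnL1) is referred to chi-square with 1 df. A fitted rate at the
#' upper bound is flagged.
#'
#' @param region one-row data.frame with \code{full_start},
#'   \code{full_end} (or \code{start}, \code{end}) in full-alignment
#'   coordinates.
#' @param fullAln character matrix of the full alignment.
#' @param model a \code{\link{PhyloModel}} on the full tree.
#' @param clade node label of the tested paralog clade (default: the
#'   model's \code{cladeFlag}).
#' @param rhoMax upper bound on rate multipliers (default 10).
#' @return A one-row data.frame: interval, \code{clade}, \code{lnl_one},
#'   \code{lnl_two}, \code{rho_one}, \code{rho_pre}, \code{rho_post},
#'   \code{lrt}, \code{p}, \code{direction} (\code{relaxed} when the
#'   post-duplication rate exceeds the pre-duplication rate), and an
#'   \code{at_bound} flag.
#' @export
lrtConstraintChange <- function(region, fullAln, model,
                                clade = model@cladeFlag, rhoMax = 10) {
  start <- if (!is.null(region$full_start)) region$full_start
           else region$start
  end <- if (!is.null(region$full_end)) region$full_end else region$end
  if (is.na(start) || is.na(end)) stop("region has no mapped coordinates")
  node <- flaggedNode(model@tree, clade)
  if (is.na(node)) stop("tree has no clade labelled ", clade)
  idx <- alignmentToIndex(fullAln)[, (start + 1):end, drop = FALSE]
  fit <- regionRateFits(model, idx, cladeEdgeIndices(model@tree, node),
                        rhoMax = rhoMax)
  lrt <- max(2 * (fit$lnLTwo - fit$lnLOne), 0)
  data.frame(start = start, end = end, clade = clade,
             lnl_one = fit$lnLOne, lnl_two = fit$lnLTwo,
             rho_one = fit$rhoOne, rho_pre = fit$rhoPre,
             rho_post = fit$rhoPost, lrt = lrt,
             p = pchisq(lrt, df = 1, lower.tail = FALSE),
             direction = if (fit$rhoPost > fit$rhoPre) "relaxed"
                         else "constrained",
             at_bound = fit$atBound, stringsAsFactors = FALSE)
}

#' Scan a protein for subfunctionalized constraint changes
#'
#' The full pipeline for one protein family: decode conserved regions on the
#' pre-duplication sub-alignment, map them into the full alignment, test
#' every region against every flagged paralog clade for a rate change, and
#' adjust the resulting p-values across all region-by-clade tests
#' (Benjamini-Hochberg). Regions entirely gapped in a paralog clade are
#' flagged unalignable for that clade instead of tested. The summary labels
#' each region \code{relaxed} or \code{retained} per clade and flags the
#' complementary pattern (relaxed in exactly one paralog) that indicates
#' subfunctionalization.
#'
#' @param preAln character matrix, pre-duplication sequences (aligned).
#' @param fullAln character matrix including the paralog clades; row names
#'   of \code{preAln} must be a subset.
#' @param model \code{\link{PhyloModel}} on the full tree; the
#'   pre-duplication model is derived by pruning the tree to the
#'   pre-alignment rows.
#' @param hmm \code{\link{RateHMM}} used for decoding.
#' @param clades character vector of paralog-clade node labels to test
#'   (default: the model's flag).
#' @param minLen minimum region length for decoding.
#' @param alpha significance level on adjusted values (default 0.05).
#' @return A list with \code{regions} (decoded and mapped), \code{tests}
#'   (one row per region x clade with \code{q} added), and \code{summary}
#'   (per region: status per clade and \code{complementary} flag).
#' @export
scanProtein <- function(preAln, fullAln, model, hmm = rateHMM(),
                        clades = model@cladeFlag, minLen = 3,
                        alpha = 0.05) {
  if (any(is.na(clades)) || !length(clades))
    stop("at least one paralog clade label is required")
  preTree <- ape::keep.tip(model@tree, rownames(preAln))
  preModel <- new("PhyloModel", tree = preTree,
                  exchangeability = model@exchangeability,
                  frequencies = model@frequencies,
                  cladeFlag = NA_character_)
  dec <- decodeRegions(preAln, preModel, hmm, minLen = minLen)
  regions <- dec$regions
  emptyTests <- data.frame(region = integer(0), start = integer(0),
                           end = integer(0), clade = character(0),
                           lnl_one = numeric(0), lnl_two = numeric(0),
                           rho_one = numeric(0), rho_pre = numeric(0),
                           rho_post = numeric(0), lrt = numeric(0),
                           p = numeric(0), q = numeric(0),
                           direction = character(0),
                           at_bound = logical(0),
                           unalignable = logical(0))
  if (!nrow(regions))
    return(list(regions = regions, tests = emptyTests,
                summary = data.frame()))
  regions <- mapRegions(regions, preAln, fullAln)
  isGap <- function(x) toupper(x) %in% GAP_CHARS
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    for (cl in clades) {
      tips <- intersect(cladeTipLabels(model@tree, cl), rownames(fullAln))
      unal <- is.na(regions$full_start[i])
      if (!unal) {
        cols <- (regions$full_start[i] + 1):regions$full_end[i]
        unal <- all(isGap(fullAln[tips, cols, drop = FALSE]))
      }
      if (unal) {
        rows[[length(rows) + 1]] <- data.frame(
          region = i, start = regions$full_start[i],
          end = regions$full_end[i], clade = cl, lnl_one = NA_real_,
          lnl_two = NA_real_, rho_one = NA_real_, rho_pre = NA_real_,
          rho_post = NA_real_, lrt = NA_real_, p = NA_real_,
          direction = NA_character_, at_bound = NA,
          unalignable = TRUE, stringsAsFactors = FALSE)
      } else {
        tst <- lrtConstraintChange(regions[i, ], fullAln, model, clade = cl)
        rows[[length(rows) + 1]] <- cbind(region = i, tst,
                                          unalignable = FALSE)
      }
    }
  }
  tests <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tests$q <- p.adjust(tests$p, method = "BH")
  summary <- data.frame(region = seq_len(nrow(regions)),
                        start = regions$full_start,
                        end = regions$full_end)
  for (cl in clades) {
    st <- character(nrow(regions))
    for (i in seq_len(nrow(regions))) {
      row <- tests[tests$region == i & tests$clade == cl, ]
      st[i] <- if (isTRUE(row$unalignable[1])) "unalignable"
               else if (!is.na(row$q[1]) && row$q[1] < alpha &&
                        row$direction[1] == "relaxed") "relaxed"
               else "retained"
    }
    summary[[paste0("status_", cl)]] <- st
  }
  statusCols <- as.matrix(summary[, paste0("status_", clades), drop = FALSE])
  nRelaxed <- rowSums(statusCols == "relaxed")
  summary$complementary <- nRelaxed == 1 & length(clades) > 1
  summary$lost_in_all <- nRelaxed == length(clades) & length(clades) > 1
  list(regions = regions, tests = tests, summary = summary)
}
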