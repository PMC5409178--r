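## Synthetic-data generators. These define the study conditions the rest of
## the package is exercised under: logistic competition trajectories sampled
## binomially at 50,000 cells per timepoint (generations 20 and 40), an
## 8 x 8 all-by-all screen with fluorophore-swapped replicates, protein
## alignments evolved on a tree with conserved regions whose rate relaxes in
## a flagged post-duplication clade, and binomial colony-sectoring counts.

#' Calibrate the biological replicate noise of the competition generator
#'
#' Replicate-level noise is a single Gaussian perturbation of s per well
#' (well-level growth-condition and background-SNP effects). Its SD is
#' chosen so that the total SD of fitted s over a null screen matches the
#' published null-competition SD of 0.0017: the binomial counting variance
#' of the two-timepoint estimator,
#' \eqn{\sum_t 1/(n R_t (1-R_t)) / (t_2-t_1)^2}, is subtracted from the
#' target variance.
#'
#' @param targetSd target SD of fitted s over a null screen (default
#'   0.0017).
#' @param nCells cells counted per timepoint.
#' @param R0 initial red frequency.
#' @param timepoints the two assayed generations.
#' @return The calibrated well-level SD of s.
#' @export
calibrateBioSd <- function(targetSd = 0.0017, nCells = 50000, R0 = 0.5,
                           timepoints = c(20, 40)) {
  stopifnot(length(timepoints) == 2, targetSd > 0)
  Rt <- rep(R0, 2)  # null competition: frequency stays at R0
  samplingVar <- sum(1 / (nCells * Rt * (1 - Rt))) / diff(timepoints)^2
  if (targetSd^2 <= samplingVar)
    stop("target SD is below the binomial counting noise floor")
  sqrt(targetSd^2 - samplingVar)
}

#' Simulate one competition well
#'
#' Draws a well-level effective selection coefficient
#' \code{trueS + Normal(0, bioSd)} (one draw per well), propagates the
#' logistic trajectory from \code{R0}, and samples
#' \code{red ~ Binomial(nCells, R(t))} at each timepoint; green counts are
#' the complement. Deterministic given \code{seed}.
#'
#' @param trueS true selection coefficient of the red strain against the
#'   green strain.
#' @param R0 initial red frequency, strictly inside (0, 1).
#' @param nCells cells counted per timepoint (published assay: 50,000).
#' @param timepoints assayed generations (published assay: 20 and 40).
#' @param bioSd SD of the well-level perturbation of s (default: calibrated
#'   to the published null SD 0.0017).
#' @param seed integer RNG seed (NULL: use the current RNG state).
#' @param wellId,greenGenotype,redGenotype labels carried into the result.
#' @return A \code{\link{CompetitionCounts}}.
#' @examples
#' simulateCompetition(-0.013, seed = 1)
#' @export
simulateCompetition <- function(trueS, R0 = 0.5, nCells = 50000,
                                timepoints = c(20, 40),
                                bioSd = calibrateBioSd(),
                                seed = NULL,
                                wellId = "well1",
                                greenGenotype = NA_character_,
                                redGenotype = NA_character_) {
  if (R0 <= 0 || R0 >= 1) stop("R0 must lie strictly inside (0, 1)")
  stopifnot(nCells >= 1, bioSd >= 0, all(timepoints >= 0),
            all(diff(timepoints) > 0))
  if (!is.null(seed)) set.seed(seed)
  sEff <- trueS + if (bioSd > 0) rnorm(1, 0, bioSd) else 0
  Rt <- logisticTrajectory(R0, sEff, timepoints)
  red <- rbinom(length(timepoints), nCells, Rt)
  competitionCounts(timepoints, red = red, green = nCells - red,
                    wellId = wellId, greenGenotype = greenGenotype,
                    redGenotype = redGenotype)
}

#' All-by-all screen design
#'
#' The full cross-product of an ordered list of green-fluorophore genotypes
#' with an ordered list of red-fluorophore genotypes: 8 x 8 genotypes give
#' the published 64 competitions, with diagonal wells pairing the same
#' genotype carrying swapped fluorophores (self-competitions, an internal
#' negative control) and a block of contamination-control wells carried as a
#' count.
#'
#' @param greenGenotypes,redGenotypes character vectors of genotype labels.
#' @param controls number of contamination-control wells (default 16; the
#'   published screens do not state their content, so they are carried only
#'   as a count).
#' @return A list with \code{wells} (data.frame \code{well_id},
#'   \code{green_genotype}, \code{red_genotype}), \code{controls}, and the
#'   two genotype lists.
#' @examples
#' length(screenDesign(paste0("g", 1:8), paste0("g", 1:8))$wells$well_id)
#' @export
screenDesign <- function(greenGenotypes, redGenotypes = greenGenotypes,
                         controls = 16) {
  stopifnot(length(greenGenotypes) >= 1, length(redGenotypes) >= 1)
  grid <- expand.grid(red_genotype = redGenotypes,
                      green_genotype = greenGenotypes,
                      stringsAsFactors = FALSE)[, 2:1]
  grid$well_id <- sprintf("G%02d_R%02d",
                          match(grid$green_genotype, greenGenotypes),
                          match(grid$red_genotype, redGenotypes))
  list(wells = grid[, c("well_id", "green_genotype", "red_genotype")],
       controls = controls,
       greenGenotypes = greenGenotypes, redGenotypes = redGenotypes)
}

#' Simulate an all-by-all competition screen
#'
#' One simulated competition per well of the design. Relative fitness
#' composes additively and transitively on the s scale: the true coefficient
#' of a well (red-vs-green orientation, matching the estimator) is
#' \code{s[red] - s[green]}, so diagonal wells are true nulls by
#' construction. A subset of wells can be marked missing (competitions not
#' performed).
#'
#' @param design a \code{\link{screenDesign}} result.
#' @param classAssignment named numeric vector: true s (relative to
#'   wild-type) per genotype label.
#' @param missingWells character vector of \code{well_id}s to omit.
#' @param seed integer RNG seed; the whole screen is deterministic given it.
#' @inheritParams simulateCompetition
#' @return Long-format data.frame with columns \code{well_id},
#'   \code{green_genotype}, \code{red_genotype}, \code{generation},
#'   \code{red_count}, \code{green_count}, \code{total_count}.
#' @export
simulateScreen <- function(design, classAssignment, R0 = 0.5,
                           nCells = 50000, timepoints = c(20, 40),
                           bioSd = calibrateBioSd(), missingWells = NULL,
                           seed = NULL) {
  wells <- design$wells
  labs <- unique(c(wells$green_genotype, wells$red_genotype))
  unknown <- setdiff(labs, names(classAssignment))
  if (length(unknown))
    stop("no fitness assigned for genotype(s): ",
         paste(unknown, collapse = ", "))
  if (!is.null(missingWells))
    wells <- wells[!wells$well_id %in% missingWells, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    sWell <- classAssignment[[wells$red_genotype[i]]] -
      classAssignment[[wells$green_genotype[i]]]
    cc <- simulateCompetition(sWell, R0 = R0, nCells = nCells,
                              timepoints = timepoints, bioSd = bioSd,
                              seed = NULL, wellId = wells$well_id[i],
                              greenGenotype = wells$green_genotype[i],
                              redGenotype = wells$red_genotype[i])
    out[[i]] <- data.frame(well_id = cc@wellId,
                           green_genotype = cc@greenGenotype,
                           red_genotype = cc@redGenotype,
                           generation = cc@generations,
                           red_count = cc@red, green_count = cc@green,
                           total_count = cc@red + cc@green,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a protein alignment with rate-shifted conserved regions
#'
#' Evolves an alignment down the model's rooted tree: the root sequence is
#' drawn from the stationary frequencies and each site evolves in continuous
#' time under the substitution model, with branch lengths multiplied by the
#' site's regional rate. Sites inside \code{regions} use that region's
#' conserved multiplier (< 1); sites of regions flagged \code{shifted}
#' revert to the background multiplier 1 on every branch inside the model's
#' flagged post-duplication clade (stem branch included) — the generative
#' picture of constraint loss after duplication. Deterministic given
#' \code{seed}.
#'
#' @param model a \code{\link{PhyloModel}}; its \code{cladeFlag} names the
#'   post-duplication clade (may be \code{NA} when nothing is shifted).
#' @param length alignment length in columns.
#' @param regions data.frame with 0-based half-open columns \code{start},
#'   \code{end} and multiplier \code{rho} in (0, 1); non-overlapping.
#' @param shifted logical vector (or index vector) marking which regions
#'   lose constraint inside the flagged clade.
#' @param seed integer RNG seed.
#' @return Character matrix (tips x columns) of aligned residues, rownames =
#'   tip labels.
#' @export
simulateAlignment <- function(model, length, regions = NULL, shifted = NULL,
                              seed = NULL) {
  stopifnot(is(model, "PhyloModel"), length >= 1)
  tree <- model@tree
  if (length(tree$tip.label) < 3) stop("tree must have at least 3 leaves")
  rate <- rep(1, length)
  inRegion <- rep(FALSE, length)
  shiftSite <- rep(FALSE, length)
  if (!is.null(regions) && nrow(regions)) {
    stopifnot(all(c("start", "end", "rho") %in% names(regions)))
    if (any(regions$start < 0) || any(regions$end > length) ||
        any(regions$start >= regions$end))
      stop("region outside alignment or empty")
    if (any(regions$rho <= 0) || any(regions$rho >= 1))
      stop("conserved-rate multipliers must lie in (0, 1)")
    idx <- lapply(seq_len(nrow(regions)), function(i)
      seq(regions$start[i] + 1, regions$end[i]))
    if (anyDuplicated(unlist(idx))) stop("regions overlap")
    if (is.null(shifted)) shifted <- rep(FALSE, nrow(regions))
    if (is.numeric(shifted))
      shifted <- seq_len(nrow(regions)) %in% shifted
    for (i in seq_len(nrow(regions))) {
      rate[idx[[i]]] <- regions$rho[i]
      inRegion[idx[[i]]] <- TRUE
      if (shifted[i]) shiftSite[idx[[i]]] <- TRUE
    }
  }
  if (!is.null(seed)) set.seed(seed)
  eig <- substitutionEigen(model)
  dupNode <- if (is.na(model@cladeFlag)) NA_integer_ else
    flaggedNode(tree, model@cladeFlag)
  if (any(shiftSite) && is.na(dupNode))
    stop("shifted regions require a flagged clade on the tree")
  cladeEdges <- cladeEdgeIndices(tree, dupNode)

  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  states <- matrix(NA_integer_, nNode, length)
  root <- nTip + 1L
  states[root, ] <- sample.int(20, length, replace = TRUE,
                               prob = model@frequencies)
  ord <- rev(ape::postorder(tree))  # parents before children
  for (e in ord) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    b <- tree$edge.length[e]
    siteRate <- rate
    if (e %in% cladeEdges) siteRate[shiftSite] <- 1
    for (r in unique(siteRate)) {
      cols <- which(siteRate == r)
      P <- transitionProb(eig, b * r)
      cum <- t(apply(P, 1, cumsum))
      u <- runif(length(cols))
      pick <- cum[states[parent, cols], , drop = FALSE] >= u
      states[child, cols] <- max.col(pick, ties.method = "first")
    }
  }
  aln <- matrix(AA_ALPHABET[states[seq_len(nTip), , drop = FALSE]],
                nTip, length)
  rownames(aln) <- tree$tip.label
  aln
}

#' Simulate a colony-sectoring assay
#'
#' Each plated colony independently loses the marker chromosome with
#' probability \code{lossProb} and then grows a visible red sector.
#'
#' @param lossProb per-colony loss probability in [0, 1].
#' @param nColonies colonies plated.
#' @param seed integer RNG seed.
#' @return A list with integer \code{sectored} and \code{white} counts.
#' @examples
#' simulateSectoring(29 / 94, 94, seed = 1)
#' @export
simulateSectoring <- function(lossProb, nColonies, seed = NULL) {
  stopifnot(lossProb >= 0, lossProb <= 1, nColonies >= 0)
  if (!is.null(seed)) set.seed(seed)
  sectored <- rbinom(1, nColonies, lossProb)
  list(sectored = as.integer(sectored),
       white = as.integer(nColonies - sectored))
}
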