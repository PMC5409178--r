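#' Construct competition counts for one well
#'
#' @param generations numeric vector of assayed generations.
#' @param red,green integer vectors of per-timepoint channel counts.
#' @param wellId optional well identifier.
#' @param greenGenotype,redGenotype optional genotype labels.
#' @return A \code{\link{CompetitionCounts}} object.
#' @examples
#' competitionCounts(c(20, 40), red = c(100, 200), green = c(100, 100))
#' @export
competitionCounts <- function(generations, red, green,
                              wellId = NA_character_,
                              greenGenotype = NA_character_,
                              redGenotype = NA_character_) {
  new("CompetitionCounts", wellId = as.character(wellId),
      greenGenotype = as.character(greenGenotype),
      redGenotype = as.character(redGenotype),
      generations = as.numeric(generations),
      red = as.integer(round(red)), green = as.integer(round(green)))
}

#' Construct an assay configuration
#'
#' Defaults reproduce the published assay constants: censoring floors of 50
#' cells per channel and in total, a measurable-|s| bound of 0.3, a detection
#' denominator of 50,000 cells, a 0.005 call threshold and a 1024-fold daily
#' dilution.
#'
#' @param minChannelCount,minTotalCount,maxMagnitude,detectDenominator
#'   censoring and detection constants.
#' @param callThreshold absolute-s threshold for effect calls.
#' @param dilutionFactor per-cycle dilution factor.
#' @param Ne informational effective population size.
#' @return An \code{\link{AssayConfig}} object.
#' @export
assayConfig <- function(minChannelCount = 50, minTotalCount = 50,
                        maxMagnitude = 0.3, detectDenominator = 50000,
                        callThreshold = 0.005, dilutionFactor = 1024,
                        Ne = 3.44e5) {
  new("AssayConfig", minChannelCount = minChannelCount,
      minTotalCount = minTotalCount, maxMagnitude = maxMagnitude,
      detectDenominator = detectDenominator, callThreshold = callThreshold,
      dilutionFactor = dilutionFactor, Ne = Ne)
}

#' Construct an allele specification
#'
#' @param elements character vector, subset of
#'   \code{KEN1, KEN2, TPR, ABBA1, ABBA2, GLEBS, MAD1B, KINASE}.
#' @param promoter \code{"BUB1pr"} or \code{"MAD3pr"}.
#' @param provenance \code{"SCP"}, \code{"extant_Bub1"} or
#'   \code{"extant_Mad3"}.
#' @return An \code{\link{AlleleSpec}} object.
#' @examples
#' alleleSpec(c("KEN1", "KEN2", "TPR", "KINASE"), promoter = "BUB1pr")
#' @export
alleleSpec <- function(elements, promoter = "BUB1pr", provenance = "SCP") {
  new("AlleleSpec", elements = sort(unique(as.character(elements))),
      promoter = promoter, provenance = provenance)
}

#' Construct a genotype specification
#'
#' @param label unique genotype identifier.
#' @param bub1,mad3 \code{AlleleSpec} at each locus, or \code{NULL} when the
#'   locus is unoccupied.
#' @return A \code{\link{GenotypeSpec}} object.
#' @export
genotypeSpec <- function(label, bub1 = NULL, mad3 = NULL) {
  new("GenotypeSpec", bub1 = bub1, mad3 = mad3, label = as.character(label))
}

#' The full-element single-copy protein allele
#'
#' The bi-functional single-copy protein carries the whole element universe;
#' element subsets model degenerative losses.
#'
#' @param drop character vector of elements to remove (degenerations).
#' @param promoter promoter driving the allele.
#' @return An \code{AlleleSpec}.
#' @export
scpAllele <- function(drop = character(0), promoter = "BUB1pr") {
  alleleSpec(setdiff(ELEMENT_UNIVERSE, drop), promoter = promoter,
             provenance = "SCP")
}

#' Construct a rate HMM
#'
#' @param rhoConserved conserved-state rate multiplier in (0,1).
#' @param selfConserved,selfBackground self-transition probabilities.
#' @param initial initial state distribution (conserved, background).
#' @return A \code{\link{RateHMM}} object.
#' @export
rateHMM <- function(rhoConserved = 0.2, selfConserved = 0.95,
                    selfBackground = 0.95, initial = c(0.5, 0.5)) {
  new("RateHMM", rhoConserved = rhoConserved,
      transitions = matrix(c(selfConserved, 1 - selfConserved,
                             1 - selfBackground, selfBackground),
                           2, 2, byrow = TRUE,
                           dimnames = list(c("conserved", "background"),
                                           c("conserved", "background"))),
      initial = initial / sum(initial))
}

#' @describeIn CompetitionCounts-class display summary
#' @param object a \code{CompetitionCounts}.
#' @export
setMethod("show", "CompetitionCounts", function(object) {
  cat("CompetitionCounts well", object@wellId, "\n")
  if (!is.na(object@greenGenotype) || !is.na(object@redGenotype))
    cat("  green:", object@greenGenotype, " red:", object@redGenotype, "\n")
  for (i in seq_along(object@generations))
    cat(sprintf("  gen %g: red %d, green %d\n", object@generations[i],
                object@red[i], object@green[i]))
})

#' @describeIn SelectionEstimate-class display summary
#' @param object a \code{SelectionEstimate}.
#' @export
setMethod("show", "SelectionEstimate", function(object) {
  lab <- switch(object@status,
                measured = sprintf("s = %.5f (se %.2g)", object@s, object@se),
                censored_low = sprintf("s %s %.1f (censored)",
                                       if (object@s < 0) "<" else ">",
                                       object@s),
                equally_lethal = "s = 0 (equally lethal)")
  cat("SelectionEstimate:", lab, "\n")
  if (object@status == "measured")
    cat(sprintf("  R0 = %.4f, converged: %s\n", object@R0Hat,
                object@converged))
})

#' @describeIn GenotypeSpec-class display summary
#' @param object a \code{GenotypeSpec}.
#' @export
setMethod("show", "GenotypeSpec", function(object) {
  fmtLocus <- function(a)
    if (is.null(a)) "absent"
    else paste0(a@provenance, "[", paste(a@elements, collapse = ","), "]@",
                a@promoter)
  cat("GenotypeSpec", object@label, "\n")
  cat("  BUB1 locus:", fmtLocus(object@bub1), "\n")
  cat("  MAD3 locus:", fmtLocus(object@mad3), "\n")
})

#' @describeIn FitnessLandscape-class display summary
#' @param object a \code{FitnessLandscape}.
#' @export
setMethod("show", "FitnessLandscape", function(object) {
  cat("FitnessLandscape with", length(object@genotypes), "genotypes and",
      nrow(object@edges), "single-step edges\n")
  if (nrow(object@edges)) {
    cat("  events:",
        paste(names(table(object@edges$event)),
              table(object@edges$event), collapse = ", "), "\n")
    if ("call" %in% names(object@edges))
      cat("  calls:",
          paste(names(table(object@edges$call)),
                table(object@edges$call), collapse = ", "), "\n")
  }
})

#' @describeIn PhyloModel-class display summary
#' @param object a \code{PhyloModel}.
#' @export
setMethod("show", "PhyloModel", function(object) {
  cat("PhyloModel:", length(object@tree$tip.label), "tips,",
      "tree depth", format(max(ape::node.depth.edgelength(object@tree)),
                           digits = 3), "subst/site\n")
  if (!is.na(object@cladeFlag))
    cat("  post-duplication clade flag:", object@cladeFlag, "\n")
})

#' @describeIn RateHMM-class display summary
#' @param object a \code{RateHMM}.
#' @export
setMethod("show", "RateHMM", function(object) {
  cat(sprintf("RateHMM: rho_conserved = %.3f, self-transitions %.3f/%.3f\n",
              object@rhoConserved, object@transitions[1, 1],
              object@transitions[2, 2]))
})

## -- accessors -------------------------------------------------------------

#' Accessors for core classes
#'
#' @param object a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wellId", function(object) standardGeneric("wellId"))
#' @rdname accessors
#' @export
setMethod("wellId", "CompetitionCounts", function(object) object@wellId)
#' @rdname accessors
#' @export
setMethod("wellId", "SelectionEstimate", function(object) object@wellId)

#' @rdname accessors
#' @export
setGeneric("generations", function(object) standardGeneric("generations"))
#' @rdname accessors
#' @export
setMethod("generations", "CompetitionCounts",
          function(object) object@generations)

#' @rdname accessors
#' @export
setGeneric("redCounts", function(object) standardGeneric("redCounts"))
#' @rdname accessors
#' @export
setMethod("redCounts", "CompetitionCounts", function(object) object@red)

#' @rdname accessors
#' @export
setGeneric("greenCounts", function(object) standardGeneric("greenCounts"))
#' @rdname accessors
#' @export
setMethod("greenCounts", "CompetitionCounts", function(object) object@green)

#' @rdname accessors
#' @export
setGeneric("totalCounts", function(object) standardGeneric("totalCounts"))
#' @rdname accessors
#' @export
setMethod("totalCounts", "CompetitionCounts",
          function(object) object@red + object@green)

#' @rdname accessors
#' @export
setGeneric("selectionCoef", function(object) standardGeneric("selectionCoef"))
#' @rdname accessors
#' @export
setMethod("selectionCoef", "SelectionEstimate", function(object) object@s)

#' @rdname accessors
#' @export
setGeneric("estimateStatus",
           function(object) standardGeneric("estimateStatus"))
#' @rdname accessors
#' @export
setMethod("estimateStatus", "SelectionEstimate",
          function(object) object@status)

#' @rdname accessors
#' @export
setGeneric("landscapeEdges",
           function(object) standardGeneric("landscapeEdges"))
#' @rdname accessors
#' @export
setMethod("landscapeEdges", "FitnessLandscape",
          function(object) object@edges)

#' @rdname accessors
#' @export
setGeneric("landscapeGenotypes",
           function(object) standardGeneric("landscapeGenotypes"))
#' @rdname accessors
#' @export
setMethod("landscapeGenotypes", "FitnessLandscape",
          function(object) object@genotypes)
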