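#' @import methods
#' @importFrom stats setNames optimize rbinom rnorm runif sd quantile
#'   p.adjust pchisq plogis qlogis glm glm.control binomial coef dbinom
#'   hclust cutree as.dist vcov
#' @importFrom utils read.delim write.table
NULL

## Universe of discrete functional elements carried by a Bub1/Mad3-family
## allele (KEN boxes, TPR domain, ABBA motifs, GLEBS, Mad1-binding region,
## kinase domain).
ELEMENT_UNIVERSE <- c("KEN1", "KEN2", "TPR", "ABBA1", "ABBA2", "GLEBS",
                      "MAD1B", "KINASE")

PROMOTERS <- c("BUB1pr", "MAD3pr")
PROVENANCES <- c("SCP", "extant_Bub1", "extant_Mad3")

#' Competition count data for one well
#'
#' Red/green cell counts from a two-fluorophore competitive fitness assay,
#' taken at a set of assayed generations. The total analysed per timepoint is
#' fixed by the cytometer settings (50,000 cells in the assay this package
#' models), so \code{red + green} must equal the per-timepoint total.
#'
#' @slot wellId character(1), well identifier.
#' @slot greenGenotype,redGenotype character(1), genotype labels of the two
#'   competitors (may be \code{NA} for bare count data).
#' @slot generations numeric, assayed generations (non-negative, increasing).
#' @slot red,green integer, cells counted in each channel per timepoint.
#' @export
setClass("CompetitionCounts",
  representation(wellId = "character",
                 greenGenotype = "character",
                 redGenotype = "character",
                 generations = "numeric",
                 red = "integer",
                 green = "integer"),
  prototype(wellId = NA_character_, greenGenotype = NA_character_,
            redGenotype = NA_character_))

setValidity("CompetitionCounts", function(object) {
  msg <- character(0)
  nt <- length(object@generations)
  if (length(object@red) != nt || length(object@green) != nt)
    msg <- c(msg, "red, green and generations must have equal length")
  if (any(object@generations < 0)) msg <- c(msg, "generations must be >= 0")
  if (nt > 1 && any(diff(object@generations) <= 0))
    msg <- c(msg, "generations must be strictly increasing")
  if (any(object@red < 0) || any(object@green < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Fitted selection coefficient for one competition
#'
#' The result of selection-coefficient estimation or censoring for one well.
#' \code{status} is one of \code{"measured"}, \code{"censored_low"} (the
#' magnitude exceeds the assay's measurable bound, reported as s < -0.3) or
#' \code{"equally_lethal"} (both competitors below countable abundance,
#' reported as s = 0).
#'
#' @slot s numeric(1), selection coefficient per generation (for censored
#'   estimates, the signed censoring bound).
#' @slot R0Hat numeric(1), fitted initial red-cell frequency (NA if censored).
#' @slot status character(1), estimation status.
#' @slot se numeric(1), delta-method standard error (informational; NA when
#'   censored).
#' @slot converged logical(1), optimizer convergence flag.
#' @slot wellId character(1), well identifier carried over from the counts.
#' @export
setClass("SelectionEstimate",
  representation(s = "numeric", R0Hat = "numeric", status = "character",
                 se = "numeric", converged = "logical", wellId = "character"),
  prototype(R0Hat = NA_real_, se = NA_real_, converged = TRUE,
            wellId = NA_character_))

setValidity("SelectionEstimate", function(object) {
  msg <- character(0)
  if (!object@status %in% c("measured", "censored_low", "equally_lethal"))
    msg <- c(msg, "invalid status")
  if (object@status == "measured" && !is.finite(object@s))
    msg <- c(msg, "measured estimate must have finite s")
  if (object@status == "censored_low" && abs(abs(object@s) - 0.3) > 1e-12)
    msg <- c(msg, "censored_low estimates carry the bound |s| = 0.3")
  if (length(msg)) msg else TRUE
})

#' Assay configuration
#'
#' Thresholds and constants of the competitive fitness assay: per-channel and
#' total count floors below which estimates are censored, the censoring bound
#' on |s|, the detection denominator (1 cell out of \code{detectDenominator}),
#' the per-cycle dilution factor and an informational effective population
#' size.
#'
#' @slot minChannelCount numeric(1), per-strain count floor (default 50).
#' @slot minTotalCount numeric(1), combined floor (default 50).
#' @slot maxMagnitude numeric(1), censoring bound on |s| (default 0.3).
#' @slot detectDenominator numeric(1), detection denominator (default 50000).
#' @slot callThreshold numeric(1), |s| threshold for effect calls (default
#'   0.005).
#' @slot dilutionFactor numeric(1), per-cycle dilution (default 1024).
#' @slot Ne numeric(1), effective population size estimate (informational).
#' @export
setClass("AssayConfig",
  representation(minChannelCount = "numeric", minTotalCount = "numeric",
                 maxMagnitude = "numeric", detectDenominator = "numeric",
                 callThreshold = "numeric", dilutionFactor = "numeric",
                 Ne = "numeric"),
  prototype(minChannelCount = 50, minTotalCount = 50, maxMagnitude = 0.3,
            detectDenominator = 50000, callThreshold = 0.005,
            dilutionFactor = 1024, Ne = 3.44e5))

setValidity("AssayConfig", function(object) {
  vals <- c(object@minChannelCount, object@minTotalCount, object@maxMagnitude,
            object@detectDenominator, object@callThreshold,
            object@dilutionFactor, object@Ne)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all configuration values must be positive and finite" else TRUE
})

#' Allele specification
#'
#' One allele at one locus, described as a subset of discrete functional
#' elements (\code{KEN1, KEN2, TPR, ABBA1, ABBA2, GLEBS, MAD1B, KINASE}), the
#' promoter driving it and its provenance (the bi-functional single-copy
#' protein, or an extant paralog).
#'
#' @slot elements character, subset of the element universe.
#' @slot promoter character(1), \code{"BUB1pr"} or \code{"MAD3pr"}.
#' @slot provenance character(1), one of \code{"SCP"}, \code{"extant_Bub1"},
#'   \code{"extant_Mad3"}.
#' @export
setClass("AlleleSpec",
  representation(elements = "character", promoter = "character",
                 provenance = "character"),
  prototype(promoter = "BUB1pr", provenance = "SCP"))

setValidity("AlleleSpec", function(object) {
  msg <- character(0)
  if (!all(object@elements %in% ELEMENT_UNIVERSE))
    msg <- c(msg, paste("elements must be a subset of",
                        paste(ELEMENT_UNIVERSE, collapse = ", ")))
  if (anyDuplicated(object@elements)) msg <- c(msg, "duplicate elements")
  if (!object@promoter %in% PROMOTERS) msg <- c(msg, "invalid promoter")
  if (!object@provenance %in% PROVENANCES) msg <- c(msg, "invalid provenance")
  if (object@provenance == "extant_Bub1" &&
      ("KEN1" %in% object@elements || !"KINASE" %in% object@elements))
    msg <- c(msg, "an extant Bub1 allele lacks KEN1 and carries KINASE")
  if (object@provenance == "extant_Mad3" &&
      (!all(c("KEN1", "KEN2") %in% object@elements) ||
       "KINASE" %in% object@elements))
    msg <- c(msg, "an extant Mad3 allele carries KEN1/KEN2 and lacks KINASE")
  if (length(msg)) msg else TRUE
})

setClassUnion("AlleleSpecOrNULL", c("AlleleSpec", "NULL"))

#' Genotype specification
#'
#' A genotype described by the allele present at each of the two loci
#' (\emph{BUB1} and \emph{MAD3}); an unoccupied locus is \code{NULL}. One
#' node of the DDC fitness landscape.
#'
#' @slot bub1,mad3 \code{AlleleSpec} or \code{NULL}.
#' @slot label character(1), unique genotype identifier.
#' @export
setClass("GenotypeSpec",
  representation(bub1 = "AlleleSpecOrNULL", mad3 = "AlleleSpecOrNULL",
                 label = "character"))

setValidity("GenotypeSpec", function(object) {
  if (length(object@label) != 1L || is.na(object@label) ||
      !nzchar(object@label)) return("label must be a non-empty string")
  TRUE
})

#' DDC fitness landscape
#'
#' A directed acyclic graph over genotypes in which an edge joins a parent to
#' a child separated by exactly one evolutionary event: a duplication (the
#' occupied allele is copied into the empty locus), the loss of a single
#' functional element, or the loss of a whole gene. No event re-creates an
#' element, so the graph has no cycles. Edges optionally carry replicate
#' selection-coefficient contrasts and a fitness-effect call filled in by
#' \code{\link{classifyEdges}}.
#'
#' @slot genotypes named list of \code{GenotypeSpec} (names = labels).
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{event} and, once classified, \code{s_rep1}, \code{s_rep2},
#'   \code{call}.
#' @slot nodeClass named character, fitness class per genotype (optional).
#' @export
setClass("FitnessLandscape",
  representation(genotypes = "list", edges = "data.frame",
                 nodeClass = "character"),
  prototype(nodeClass = character(0)))

setValidity("FitnessLandscape", function(object) {
  msg <- character(0)
  labs <- names(object@genotypes)
  if (anyDuplicated(labs)) msg <- c(msg, "duplicate genotype labels")
  if (nrow(object@edges)) {
    if (!all(c("parent", "child", "event") %in% names(object@edges)))
      msg <- c(msg, "edges need parent, child, event columns")
    else {
      if (!all(object@edges$parent %in% labs) ||
          !all(object@edges$child %in% labs))
        msg <- c(msg, "edge endpoints must be landscape genotypes")
      if (!all(object@edges$event %in%
               c("duplication", "element_loss", "gene_loss")))
        msg <- c(msg, "invalid edge event type")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Phylogenetic substitution model
#'
#' A reversible amino-acid substitution model (symmetric exchangeabilities
#' composed with stationary frequencies, normalised to one expected
#' substitution per site per unit branch length) on a rooted tree. The tree
#' may carry a node label (\code{"DUP"} by convention) marking the
#' post-duplication clade.
#'
#' @slot tree an \code{ape::phylo} rooted tree with branch lengths.
#' @slot exchangeability symmetric 20x20 matrix of exchangeabilities.
#' @slot frequencies numeric(20), stationary amino-acid frequencies (sum 1).
#' @slot cladeFlag character(1), node label marking the post-duplication
#'   clade (\code{NA} if none).
#' @export
setClass("PhyloModel",
  representation(tree = "ANY", exchangeability = "matrix",
                 frequencies = "numeric", cladeFlag = "character"),
  prototype(cladeFlag = NA_character_))

setValidity("PhyloModel", function(object) {
  msg <- character(0)
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
  else if (is.null(object@tree$edge.length) ||
           any(object@tree$edge.length < 0))
    msg <- c(msg, "tree needs non-negative branch lengths")
  if (!all(dim(object@exchangeability) == c(20, 20)) ||
      max(abs(object@exchangeability - t(object@exchangeability))) > 1e-8)
    msg <- c(msg, "exchangeability must be a symmetric 20x20 matrix")
  if (length(object@frequencies) != 20 ||
      abs(sum(object@frequencies) - 1) > 1e-6 ||
      any(object@frequencies <= 0))
    msg <- c(msg, "frequencies must be 20 positive values summing to 1")
  if (length(msg)) msg else TRUE
})

#' Two-state evolutionary-rate HMM
#'
#' Hidden Markov model over alignment columns with states
#' \code{conserved} (rate multiplier \code{rhoConserved} < 1) and
#' \code{background} (multiplier 1). Emissions are phylogenetic column
#' likelihoods under the \code{PhyloModel} with branch lengths scaled by the
#' state's multiplier.
#'
#' @slot rhoConserved numeric(1), conserved-state rate multiplier in (0,1).
#' @slot transitions 2x2 row-stochastic matrix, order (conserved, background).
#' @slot initial numeric(2), initial state distribution.
#' @export
setClass("RateHMM",
  representation(rhoConserved = "numeric", transitions = "matrix",
                 initial = "numeric"),
  prototype(rhoConserved = 0.2,
            transitions = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2,
                                 byrow = TRUE),
            initial = c(0.5, 0.5)))

setValidity("RateHMM", function(object) {
  msg <- character(0)
  if (object@rhoConserved <= 0 || object@rhoConserved >= 1)
    msg <- c(msg, "rhoConserved must lie in (0, 1)")
  if (!all(dim(object@transitions) == c(2, 2)) ||
      any(object@transitions < 0) ||
      max(abs(rowSums(object@transitions) - 1)) > 1e-8)
    msg <- c(msg, "transitions must be 2x2 row-stochastic")
  if (length(object@initial) != 2 || any(object@initial < 0) ||
      abs(sum(object@initial) - 1) > 1e-8)
    msg <- c(msg, "initial must be a length-2 distribution")
  if (length(msg)) msg else TRUE
})
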