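## DDC fitness-landscape analysis: the single-mutational-step genotype
## graph, fitness-class clustering of the all-by-all screen matrix, edge
## effect calls, neutral-path enumeration and the absorbing-state test.

alleleEqual <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  setequal(a@elements, b@elements) && a@promoter == b@promoter &&
    a@provenance == b@provenance
}

## Classify the single evolutionary event separating parent -> child at one
## locus pair, or NA if they are not one step apart. Events never add an
## element (reversions are not modelled).
singleStepEvent <- function(parent, child) {
  pb <- parent@bub1; pm <- parent@mad3
  cb <- child@bub1; cm <- child@mad3
  sameB <- alleleEqual(pb, cb); sameM <- alleleEqual(pm, cm)
  if (sameB && sameM) return(NA_character_)
  ## duplication: the occupied allele is copied into the empty locus; the
  ## copy keeps its elements and provenance but runs under the new locus's
  ## promoter (the promoter change is part of the duplication event).
  dupCopy <- function(a, promoter) {
    b <- a; b@promoter <- promoter; b
  }
  if (is.null(pm) && !is.null(pb) && sameB && !is.null(cm) &&
      alleleEqual(cm, dupCopy(pb, cm@promoter)))
    return("duplication")
  if (is.null(pb) && !is.null(pm) && sameM && !is.null(cb) &&
      alleleEqual(cb, dupCopy(pm, cb@promoter)))
    return("duplication")
  ## gene loss: one locus becomes absent, the other untouched.
  if (!is.null(pb) && is.null(cb) && sameM) return("gene_loss")
  if (!is.null(pm) && is.null(cm) && sameB) return("gene_loss")
  ## element loss: one locus loses exactly one element.
  oneLoss <- function(p, c) {
    !is.null(p) && !is.null(c) && p@promoter == c@promoter &&
      p@provenance == c@provenance &&
      length(setdiff(p@elements, c@elements)) == 1 &&
      length(setdiff(c@elements, p@elements)) == 0
  }
  if (sameM && oneLoss(pb, cb)) return("element_loss")
  if (sameB && oneLoss(pm, cm)) return("element_loss")
  NA_character_
}

#' Build the single-step fitness landscape
#'
#' Directed graph over the supplied genotypes with an edge from parent to
#' child whenever the two differ by exactly one evolutionary event: a
#' duplication filling the empty locus, the loss of a single functional
#' element, or the loss of a whole gene. No event adds an element, so the
#' graph is acyclic. Edges carry no fitness information until
#' \code{\link{classifyEdges}} is applied.
#'
#' @param genotypes list of \code{\link{GenotypeSpec}} with unique labels.
#' @return A \code{\link{FitnessLandscape}}.
#' @export
buildLandscape <- function(genotypes) {
  labs <- vapply(genotypes, function(g) g@label, character(1))
  if (anyDuplicated(labs)) stop("duplicate genotype labels")
  names(genotypes) <- labs
  edges <- data.frame(parent = character(0), child = character(0),
                      event = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(genotypes)) for (j in seq_along(genotypes)) {
    if (i == j) next
    ev <- singleStepEvent(genotypes[[i]], genotypes[[j]])
    if (!is.na(ev))
      edges <- rbind(edges, data.frame(parent = labs[i], child = labs[j],
                                       event = ev,
                                       stringsAsFactors = FALSE))
  }
  new("FitnessLandscape", genotypes = genotypes, edges = edges)
}

#' Cluster an all-by-all fitness matrix into fitness classes
#'
#' Agglomerative average-linkage clustering of the genotype-by-genotype
#' selection-coefficient matrix using pairwise-complete Euclidean distance
#' (each pair's squared distance over the coordinates both rows observe,
#' rescaled by \code{p / p_observed} before the square root, so missing
#' competitions do not shrink distances). Flat classes are obtained by
#' cutting the dendrogram at the height \code{sqrt(p) * callThreshold}:
#' two groups form distinct fitness classes when their average profile
#' distance exceeds the distance implied by a just-callable fitness
#' difference in every competition. (A largest-gap cut cannot work here:
#' fitness plateaus are nested — the wild-type/mad3-like split is an order
#' of magnitude finer than the bub1-like split — so the dominant gap always
#' absorbs the finer, still well-resolved class.) The class count is capped
#' at \code{maxK}. Each class reports its mean selection coefficient
#' against the wild-type column.
#'
#' @param sMatrix numeric matrix, rows and columns indexed by genotype
#'   label; entry (g, h) is the selection coefficient of g relative to h
#'   (censored entries substituted at the +-0.3 bound upstream); \code{NA}
#'   for competitions not performed.
#' @param wildType label of the wild-type reference column (default: first
#'   column).
#' @param callThreshold just-callable per-competition fitness difference
#'   setting the dendrogram cut height (default 0.005, the assay's call
#'   threshold).
#' @param maxK cap on the number of flat classes (default 6).
#' @return A list with \code{classes} (named integer vector, class ids
#'   numbered by decreasing class mean s), \code{k}, \code{classMeanS}
#'   (mean s vs wild-type per class) and the \code{hclust} object.
#' @export
clusterFitnessClasses <- function(sMatrix, wildType = colnames(sMatrix)[1],
                                  callThreshold = 0.005, maxK = 6) {
  stopifnot(is.matrix(sMatrix), !is.null(rownames(sMatrix)))
  if (any(rowSums(!is.na(sMatrix)) == 0))
    stop("row(s) with no observed entries: ",
         paste(rownames(sMatrix)[rowSums(!is.na(sMatrix)) == 0],
               collapse = ", "))
  ## deterministic tie-breaking: order rows lexicographically before
  ## agglomeration so equal-distance merges resolve by label
  ord <- order(rownames(sMatrix))
  X <- sMatrix[ord, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    obs <- !is.na(X[i, ]) & !is.na(X[j, ])
    if (!any(obs))
      stop("rows ", rownames(X)[i], " and ", rownames(X)[j],
           " share no observed entries")
    D[i, j] <- D[j, i] <-
      sqrt(sum((X[i, obs] - X[j, obs])^2) * p / sum(obs))
  }
  dimnames(D) <- list(rownames(X), rownames(X))
  if (n == 1) {
    cl <- setNames(1L, rownames(X))
    return(list(classes = cl, k = 1L,
                classMeanS = setNames(X[1, wildType], "1"), hclust = NULL))
  }
  hc <- hclust(as.dist(D), method = "average")
  ## flat classes: cut where the average profile distance exceeds the
  ## distance a just-callable fitness difference (callThreshold in every
  ## competition) would produce; merges below that height are measurement
  ## noise, every merge above it joins genuinely distinct classes
  cutHeight <- sqrt(p) * callThreshold
  k <- min(1L + sum(hc$height > cutHeight), maxK, n)
  classes <- cutree(hc, k = k)
  wt <- sMatrix[, wildType]
  classMeanS <- vapply(split(names(classes), classes), function(g)
    mean(wt[g], na.rm = TRUE), numeric(1))
  ## renumber classes by decreasing mean s (class 1 = most fit)
  newId <- rank(-classMeanS, ties.method = "first")
  classes <- setNames(as.integer(newId[as.character(classes)]),
                      names(classes))
  classMeanS <- setNames(classMeanS[order(newId)], sort(newId))
  ## restore the caller's row order
  classes <- classes[rownames(sMatrix)]
  list(classes = classes, k = as.integer(k), classMeanS = classMeanS,
       hclust = hc)
}

#' Assemble the screen selection-coefficient matrix
#'
#' Converts per-well estimates into the genotype-by-genotype matrix used for
#' clustering: entry (g, h) is the selection coefficient of the green
#' genotype g relative to the red genotype h, i.e. the negated fitted
#' red-vs-green coefficient. Censored wells contribute the signed bound
#' (+-0.3); equally-lethal wells contribute 0; missing wells stay \code{NA}.
#'
#' @param estimates data.frame from \code{\link{fitScreen}}.
#' @param genotypes optional label ordering.
#' @return Numeric matrix with genotype dimnames.
#' @export
screenMatrix <- function(estimates, genotypes = NULL) {
  if (is.null(genotypes))
    genotypes <- unique(c(estimates$green_genotype,
                          estimates$red_genotype))
  M <- matrix(NA_real_, length(genotypes), length(genotypes),
              dimnames = list(genotypes, genotypes))
  for (i in seq_len(nrow(estimates))) {
    g <- estimates$green_genotype[i]; r <- estimates$red_genotype[i]
    M[g, r] <- -estimates$s[i]
  }
  M
}

#' Attach fitness-effect calls to landscape edges
#'
#' Labels every edge with the fitness effect of the child relative to the
#' parent, using replicated estimates against a common wild-type reference:
#' when no direct competition exists, the contrast composes as
#' \code{s(child, parent) = s(child, WT) - s(parent, WT)} per replicate
#' (fitness is treated as transitive on the s scale). A child censored at
#' the bound makes the contrast censored. Edges with no estimable contrast
#' are labelled \code{"unknown"}, never silently neutral.
#'
#' @param landscape a \code{\link{FitnessLandscape}}.
#' @param estimatesVsWT data.frame with columns \code{genotype},
#'   \code{replicate}, \code{s}, \code{status}: replicated
#'   (fluorophore-swapped) selection coefficients of each genotype against
#'   wild-type, already sign-aligned to the genotype-vs-WT orientation.
#' @param config an \code{\link{AssayConfig}} supplying the call threshold.
#' @return The landscape with edge columns \code{s_rep1}, \code{s_rep2},
#'   \code{call}.
#' @export
classifyEdges <- function(landscape, estimatesVsWT,
                          config = assayConfig()) {
  ed <- landscape@edges
  ed$s_rep1 <- NA_real_; ed$s_rep2 <- NA_real_
  ed$call <- "unknown"
  getReps <- function(lab) {
    rows <- estimatesVsWT[estimatesVsWT$genotype == lab, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    rows[order(rows$replicate), , drop = FALSE]
  }
  for (i in seq_len(nrow(ed))) {
    pa <- getReps(ed$parent[i]); ch <- getReps(ed$child[i])
    if (is.null(pa) || is.null(ch) || nrow(pa) < 2 || nrow(ch) < 2) next
    nRep <- min(nrow(pa), nrow(ch))
    s <- ch$s[seq_len(nRep)] - pa$s[seq_len(nRep)]
    censored <- ch$status[seq_len(nRep)] == "censored_low" &
      ch$s[seq_len(nRep)] < 0
    ed$s_rep1[i] <- s[1]; ed$s_rep2[i] <- s[2]
    ed$call[i] <- if (any(censored)) "deleterious"
                  else callEffect(s, config)
  }
  landscape@edges <- ed
  landscape
}

#' Enumerate neutral evolutionary paths
#'
#' Exhaustive depth-first enumeration of all directed paths from
#' \code{source} to \code{target} whose every edge is non-deleterious (call
#' \code{no_detectable_effect} or \code{beneficial}); the landscape is
#' acyclic by construction so the search terminates. A path that would
#' traverse an unclassified edge is reported with the
#' \code{indeterminate} flag instead of being silently dropped.
#'
#' @param landscape a classified \code{\link{FitnessLandscape}}.
#' @param source,target genotype labels.
#' @return A list of paths; each path is a list with \code{nodes},
#'   \code{events}, \code{degenerations} (number of element-loss events) and
#'   \code{indeterminate}. \code{source == target} yields the single
#'   zero-length path.
#' @export
findNeutralPaths <- function(landscape, source, target) {
  ed <- landscape@edges
  if (!"call" %in% names(ed)) stop("classify edges first")
  stopifnot(source %in% names(landscape@genotypes),
            target %in% names(landscape@genotypes))
  passable <- ed[ed$call %in%
                 c("no_detectable_effect", "beneficial", "unknown"), ,
                 drop = FALSE]
  paths <- list()
  walk <- function(node, nodes, events, indet) {
    if (node == target) {
      paths[[length(paths) + 1]] <<- list(
        nodes = nodes, events = events,
        degenerations = sum(events == "element_loss"),
        indeterminate = indet)
      return(invisible())
    }
    out <- passable[passable$parent == node, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      if (out$child[i] %in% nodes) next  # acyclic guard
      walk(out$child[i], c(nodes, out$child[i]),
           c(events, out$event[i]),
           indet || out$call[i] == "unknown")
    }
  }
  walk(source, source, character(0), FALSE)
  paths
}

#' Is a genotype an absorbing state?
#'
#' Under the no-valley-crossing rule a genotype is absorbing when no neutral
#' or beneficial forward step leaves it: every outgoing single-step edge is
#' deleterious. A sink with no outgoing edges is vacuously absorbing
#' (documented convention). Unclassified outgoing edges are an error, never
#' a silent answer.
#'
#' @param landscape a classified \code{\link{FitnessLandscape}}.
#' @param node genotype label.
#' @return Logical.
#' @export
isAbsorbing <- function(landscape, node) {
  ed <- landscape@edges
  if (!"call" %in% names(ed)) stop("classify edges first")
  out <- ed[ed$parent == node, , drop = FALSE]
  if (!nrow(out)) return(TRUE)
  if (any(out$call == "unknown"))
    stop("unclassified outgoing edge(s) at ", node)
  all(out$call == "deleterious")
}

#' Fig 5-consistent synthetic genotype set
#'
#' A reconstruction (synthetic, not ground truth: the published work gives
#' no complete table of assayed element compositions) of the landscape
#' genotypes: the single-copy bi-functional protein, its duplication, the
#' degeneration series to the extant-like Bub1/Mad3 pair, and the
#' deleterious neighbours of the extant-like node (function-destroying
#' element losses and whole-gene losses).
#'
#' @return Named list of \code{\link{GenotypeSpec}}.
#' @export
ddcGenotypeSet <- function() {
  g <- list(
    genotypeSpec("scp_single", bub1 = scpAllele()),
    genotypeSpec("scp_double", bub1 = scpAllele(),
                 mad3 = scpAllele(promoter = "MAD3pr")),
    genotypeSpec("dKEN1_scp", bub1 = scpAllele(drop = "KEN1"),
                 mad3 = scpAllele(promoter = "MAD3pr")),
    genotypeSpec("dKEN1_dKINASE", bub1 = scpAllele(drop = "KEN1"),
                 mad3 = scpAllele(drop = "KINASE", promoter = "MAD3pr")),
    genotypeSpec("dKEN1dABBA1_dKINASE",
                 bub1 = scpAllele(drop = c("KEN1", "ABBA1")),
                 mad3 = scpAllele(drop = "KINASE", promoter = "MAD3pr")),
    genotypeSpec("extant_like",
                 bub1 = scpAllele(drop = c("KEN1", "ABBA1")),
                 mad3 = scpAllele(drop = c("KINASE", "MAD1B"),
                                  promoter = "MAD3pr")),
    ## deleterious exits from the extant-like node
    genotypeSpec("extant_dKEN1mad3",
                 bub1 = scpAllele(drop = c("KEN1", "ABBA1")),
                 mad3 = scpAllele(drop = c("KINASE", "MAD1B", "KEN1"),
                                  promoter = "MAD3pr")),
    genotypeSpec("extant_dKINASEbub1",
                 bub1 = scpAllele(drop = c("KEN1", "ABBA1", "KINASE")),
                 mad3 = scpAllele(drop = c("KINASE", "MAD1B"),
                                  promoter = "MAD3pr")),
    genotypeSpec("extant_lossMAD3",
                 bub1 = scpAllele(drop = c("KEN1", "ABBA1"))),
    genotypeSpec("extant_lossBUB1",
                 mad3 = scpAllele(drop = c("KINASE", "MAD1B"),
                                  promoter = "MAD3pr")))
  names(g) <- vapply(g, function(x) x@label, character(1))
  g
}

#' True fitness classes for synthetic landscape genotypes
#'
#' Rule-based class assignment used by the generator: the Mad3-side
#' checkpoint function requires a KEN1 box at some locus, the Bub1-side
#' function a kinase domain at some locus. Genotypes with both functions
#' are wild-type-like (s = 0); loss of the Mad3-side function costs
#' \code{sMad3Like}; loss of the Bub1-side function costs
#' \code{sBub1Like} (beyond the assay's measurable bound).
#'
#' @param genotypes list of \code{GenotypeSpec}.
#' @param sMad3Like,sBub1Like true class selection coefficients (defaults
#'   -0.015 and -0.35).
#' @return Named numeric vector of true s relative to wild-type.
#' @export
trueClassAssignment <- function(genotypes, sMad3Like = -0.015,
                                sBub1Like = -0.35) {
  hasEl <- function(g, el) {
    (!is.null(g@bub1) && el %in% g@bub1@elements) ||
      (!is.null(g@mad3) && el %in% g@mad3@elements)
  }
  vapply(genotypes, function(g) {
    if (!hasEl(g, "KINASE")) sBub1Like
    else if (!hasEl(g, "KEN1")) sMad3Like
    else 0
  }, numeric(1))
}
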