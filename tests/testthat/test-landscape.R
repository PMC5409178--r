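test_that("allele and genotype validity rules hold", {
  expect_error(alleleSpec("NOPE"), "subset")
  expect_error(alleleSpec(c("KEN1", "KINASE"), provenance = "extant_Bub1"),
               "Bub1")
  expect_error(alleleSpec(c("KEN1", "KEN2", "KINASE"),
                          provenance = "extant_Mad3"), "Mad3")
  ok <- alleleSpec(c("KEN2", "TPR", "KINASE"), provenance = "extant_Bub1")
  expect_s4_class(ok, "AlleleSpec")
})

test_that("single-step edges are exactly the one-event relation", {
  single <- genotypeSpec("single", bub1 = scpAllele())
  double <- genotypeSpec("double", bub1 = scpAllele(),
                         mad3 = scpAllele(promoter = "MAD3pr"))
  lost1 <- genotypeSpec("lost1", bub1 = scpAllele(drop = "KEN1"),
                        mad3 = scpAllele(promoter = "MAD3pr"))
  lost2 <- genotypeSpec("lost2", bub1 = scpAllele(drop = c("KEN1", "KEN2")),
                        mad3 = scpAllele(promoter = "MAD3pr"))
  L <- buildLandscape(list(single, double, lost1, lost2))
  ed <- landscapeEdges(L)
  key <- paste(ed$parent, ed$child, ed$event)
  # duplication fills the empty locus (under the new locus promoter)
  expect_true("single double duplication" %in% key)
  # one element loss per edge; two-element jumps are absent
  expect_true("double lost1 element_loss" %in% key)
  expect_true("lost1 lost2 element_loss" %in% key)
  expect_false(any(ed$parent == "double" & ed$child == "lost2"))
  # gene loss runs opposite to duplication, and losses are irreversible
  expect_true("double single gene_loss" %in% key)
  expect_false(any(ed$parent == "lost1" & ed$child == "double"))
  expect_error(buildLandscape(list(single, single)), "duplicate")
})

test_that("edge set equals brute-force pairwise comparison and forms a DAG", {
  genotypes <- ddcGenotypeSet()
  L <- buildLandscape(genotypes)
  ed <- landscapeEdges(L)
  # brute force: every ordered pair, via the event classifier itself --
  # checks buildLandscape misses nothing relative to pairwise comparison
  nEdges <- 0L
  for (p in names(genotypes)) for (ch in names(genotypes)) {
    if (p == ch) next
    ev <- ddcquant:::singleStepEvent(genotypes[[p]], genotypes[[ch]])
    if (!is.na(ev)) {
      nEdges <- nEdges + 1L
      expect_true(any(ed$parent == p & ed$child == ch & ed$event == ev))
    }
  }
  expect_identical(nrow(ed), nEdges)
  # degenerations are irreversible: the graph restricted to element- and
  # gene-loss edges is acyclic; the only reversible step is the duplication
  # itself (undone by whole-gene loss), so any cycle must pass through a
  # duplication edge
  lossOnly <- ed[ed$event != "duplication", c("parent", "child")]
  expect_true(igraph::is_dag(igraph::graph_from_data_frame(lossOnly)))
  full <- igraph::graph_from_data_frame(ed[, c("parent", "child")])
  dupRemoved <- igraph::delete_edges(full, which(ed$event == "duplication"))
  expect_true(igraph::is_dag(dupRemoved))
  # element-loss edges drop exactly one element
  countEl <- function(lab) {
    gt <- genotypes[[lab]]
    length(if (is.null(gt@bub1)) NULL else gt@bub1@elements) +
      length(if (is.null(gt@mad3)) NULL else gt@mad3@elements)
  }
  el <- ed[ed$event == "element_loss", ]
  for (i in seq_len(nrow(el)))
    expect_identical(countEl(el$parent[i]) - countEl(el$child[i]), 1L)
})

test_that("fitness-class clustering recovers the generative classes", {
  M <- simulateClassScreen(seed = 1401)
  cl <- clusterFitnessClasses(M, wildType = "extant_like")
  expect_identical(cl$k, 3L)
  truth <- as.integer(factor(
    -trueClassAssignment(ddcGenotypeSet())[rownames(M)]))
  expect_equal(partitionAgreement(cl$classes, truth), 1)
  # class means sit near the generative values (wt 0, mad3-like -0.015,
  # censored bub1-like at the -0.3 bound)
  expect_lt(abs(cl$classMeanS[1]), 0.004)
  expect_lt(abs(cl$classMeanS[2] + 0.015), 0.004)
  expect_lt(abs(cl$classMeanS[3] + 0.3), 0.01)
})

test_that("clustering is permutation- and shift-invariant and handles trivia", {
  M <- simulateClassScreen(seed = 77)
  cl <- clusterFitnessClasses(M, wildType = "extant_like")
  perm <- sample(nrow(M))
  clPerm <- clusterFitnessClasses(M[perm, perm], wildType = "extant_like")
  expect_identical(cl$classes[rownames(M)], clPerm$classes[rownames(M)])
  clShift <- clusterFitnessClasses(M + 0.05, wildType = "extant_like")
  expect_identical(cl$classes, clShift$classes)
  # all-zero matrix: a single class
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_identical(clusterFitnessClasses(Z)$k, 1L)
  # rows with no observations are refused
  M2 <- M; M2["scp_double", ] <- NA
  expect_error(clusterFitnessClasses(M2, wildType = "extant_like"),
               "no observed")
})

test_that("clustering tolerates missing wells via pairwise-complete rescaling", {
  M <- simulateClassScreen(seed = 4242)
  # knock out a sprinkling of competitions (not performed)
  set.seed(9)
  M[sample(length(M), 8)] <- NA
  diag(M) <- diag(simulateClassScreen(seed = 4242))  # keep diagonal
  cl <- clusterFitnessClasses(M, wildType = "extant_like")
  truth <- as.integer(factor(
    -trueClassAssignment(ddcGenotypeSet())[rownames(M)]))
  expect_identical(cl$k, 3L)
  expect_equal(partitionAgreement(cl$classes, truth), 1)
})

test_that("edge classification composes contrasts through the wild-type reference", {
  landscape <- ddcquant:::classifiedSyntheticLandscape(seed = 2024)
  ed <- landscapeEdges(landscape)
  expect_true(all(ed$call != "unknown"))
  # neutral backbone: duplication and the four complementary degenerations
  backbone <- ed[ed$parent == "scp_single" & ed$child == "scp_double", ]
  expect_identical(backbone$call, "no_detectable_effect")
  # wt-like parent with mad3-like child is deleterious
  exit <- ed[ed$parent == "extant_like" & ed$child == "extant_dKEN1mad3", ]
  expect_identical(exit$call, "deleterious")
  # bub1-function loss goes through a censored replicate, still deleterious
  lethal <- ed[ed$parent == "extant_like" &
               ed$child == "extant_dKINASEbub1", ]
  expect_identical(lethal$call, "deleterious")
})

test_that("neutral-path search equals brute-force enumeration and flags unknowns", {
  landscape <- ddcquant:::classifiedSyntheticLandscape(seed = 11)
  paths <- findNeutralPaths(landscape, "scp_single", "extant_like")
  ok <- paths[!vapply(paths, `[[`, logical(1), "indeterminate")]
  expect_gte(length(ok), 1)
  expect_true(all(vapply(ok, `[[`, numeric(1), "degenerations") >= 3))
  # independent oracle: igraph simple-path enumeration on the subgraph of
  # non-deleterious edges
  ed <- landscapeEdges(landscape)
  passable <- ed[ed$call %in% c("no_detectable_effect", "beneficial"), ]
  g <- igraph::graph_from_data_frame(passable[, c("parent", "child")],
    vertices = names(landscapeGenotypes(landscape)))
  ref <- igraph::all_simple_paths(g, "scp_single", "extant_like",
                                  mode = "out")
  expect_identical(length(ok), length(ref))
  refNodes <- sort(vapply(ref, function(p)
    paste(names(p), collapse = ">"), character(1)))
  gotNodes <- sort(vapply(ok, function(p)
    paste(p$nodes, collapse = ">"), character(1)))
  expect_identical(gotNodes, refNodes)
  # source equal to target: the single zero-length path
  self <- findNeutralPaths(landscape, "extant_like", "extant_like")
  expect_identical(length(self), 1L)
  expect_identical(self[[1]]$degenerations, 0L)
  # all-deleterious landscape yields no paths
  allDel <- landscape
  allDel@edges$call <- "deleterious"
  expect_identical(length(findNeutralPaths(allDel, "scp_single",
                                           "extant_like")), 0L)
})

test_that("absorbing-state test follows the no-valley-crossing rule", {
  landscape <- ddcquant:::classifiedSyntheticLandscape(seed = 31)
  expect_true(isAbsorbing(landscape, "extant_like"))
  # a node with a neutral outgoing edge is not absorbing
  expect_false(isAbsorbing(landscape, "scp_single"))
  # vacuous sink: no outgoing edges at all
  expect_true(isAbsorbing(landscape, "extant_lossBUB1"))
  # unclassified edges are an error, not a silent answer
  broken <- landscape
  broken@edges$call[broken@edges$parent == "extant_like"][1] <- "unknown"
  expect_error(isAbsorbing(broken, "extant_like"), "unclassified")
})
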