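# Shared fixtures, built in code.

# Balanced 8-taxon tree; E-H form the flagged post-duplication clade.
treeEight <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2):0.1,",
    "((E:0.2,F:0.2):0.2,(G:0.2,H:0.2):0.2)DUP:0.1);"))
}

# Rooted 3-taxon tree for exhaustive-enumeration oracles.
treeThree <- function()
  ape::read.tree(text = "((A:0.3,B:0.4):0.2,C:0.5);")

wagModel <- function(tree) phyloModel(tree)

# Independent brute-force column likelihood on the rooted 3-leaf tree
# ((A,B):b_int, C): sum over all 20^2 internal/root state assignments.
bruteColumnLik3 <- function(column, model, rate = 1) {
  tree <- model@tree
  eig <- ddcquant:::substitutionEigen(model)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    ddcquant:::transitionProb(eig, tree$edge.length[e] * rate))
  tipIdx <- match(toupper(column[tree$tip.label]), ddcquant:::AA_ALPHABET)
  # gap leaves contribute a factor of one (missing data)
  pTip <- function(P, from, tip)
    if (is.na(tipIdx[tip])) 1 else P[from, tipIdx[tip]]
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  inner <- setdiff(unique(tree$edge[, 1]), root)
  edgeTo <- function(node) which(tree$edge[, 2] == node)
  kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  lik <- 0
  for (r in 1:20) for (i in 1:20) {
    term <- model@frequencies[r]
    for (child in kids(root)) {
      pc <- P[[edgeTo(child)]]
      term <- term * if (child == inner) pc[r, i] else pTip(pc, r, child)
    }
    for (child in kids(inner))
      term <- term * pTip(P[[edgeTo(child)]], i, child)
    lik <- lik + term
  }
  log(unname(lik))
}

# Brute-force 2-state HMM likelihood: sum over all state paths.
bruteHMMLik <- function(hmm, logE) {
  C <- ncol(logE)
  paths <- as.matrix(expand.grid(rep(list(1:2), C)))
  tot <- -Inf
  for (p in seq_len(nrow(paths))) {
    st <- paths[p, ]
    lp <- log(hmm@initial[st[1]]) + logE[st[1], 1]
    if (C > 1) for (t in 2:C)
      lp <- lp + log(hmm@transitions[st[t - 1], st[t]]) + logE[st[t], t]
    tot <- max(tot, lp) + log1p(exp(min(tot, lp) - max(tot, lp)))
  }
  tot
}

# The standard screen: 8 genotypes from the synthetic landscape spanning the
# three fitness classes, extant_like as the wild-type-like reference.
screenLabels <- function()
  c("extant_like", "scp_double", "dKEN1_dKINASE", "dKEN1dABBA1_dKINASE",
    "extant_dKEN1mad3", "extant_lossMAD3", "extant_dKINASEbub1",
    "extant_lossBUB1")

simulateClassScreen <- function(seed, labs = screenLabels()) {
  trueS <- trueClassAssignment(ddcGenotypeSet())
  counts <- simulateScreen(screenDesign(labs, labs), trueS[labs],
                           seed = seed)
  screenMatrix(fitScreen(counts), labs)
}

# Best-permutation agreement between a clustering and the true labels.
partitionAgreement <- function(pred, truth)
  ddcquant:::labelAgreement(pred, truth)
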