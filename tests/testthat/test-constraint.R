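test_that("column likelihood matches trivial cases and exhaustive enumeration", {
  m3 <- wagModel(treeThree())
  pi <- m3@frequencies
  # two identical residues at (near) zero distance collapse to log pi_a
  tiny <- treeThree(); tiny$edge.length[] <- 1e-12
  mTiny <- phyloModel(tiny, cladeFlag = NA)
  expect_equal(columnLikelihood(c(A = "W", B = "W", C = "W"), mTiny),
               log(pi[["W"]]), tolerance = 1e-6)
  # gaps are missing data: an all-gap column has likelihood 1
  expect_equal(columnLikelihood(c(A = "-", B = "-", C = "-"), m3), 0)
  # exhaustive sum over all 20^2 internal-state assignments
  for (col in list(c(A = "M", B = "M", C = "L"),
                   c(A = "A", B = "R", C = "N"),
                   c(A = "K", B = "-", C = "K"))) {
    expect_equal(columnLikelihood(col, m3), bruteColumnLik3(col, m3),
                 tolerance = 1e-10)
    expect_equal(columnLikelihood(col, m3, rate = 0.25),
                 bruteColumnLik3(col, m3, rate = 0.25), tolerance = 1e-10)
  }
  expect_error(columnLikelihood(c(A = "1", B = "A", C = "A"), m3),
               "alphabet")
})

test_that("column likelihood is invariant to re-rooting the reversible model", {
  m <- wagModel(treeEight())
  aln <- simulateAlignment(m, 6, seed = 21)
  ll <- ddcquant:::pruneLogLik(m, ddcquant:::alignmentToIndex(aln), 1)
  rerooted <- phyloModel(ape::root(ape::unroot(m@tree), outgroup = "C",
                                   resolve.root = TRUE), cladeFlag = NA)
  ll2 <- ddcquant:::pruneLogLik(rerooted,
                                ddcquant:::alignmentToIndex(aln), 1)
  expect_equal(ll, ll2, tolerance = 1e-8)
})

test_that("forward-backward likelihood equals brute-force path enumeration", {
  m <- wagModel(treeEight())
  aln <- simulateAlignment(m, 5, regions = data.frame(start = 0, end = 2,
                                                      rho = 0.1), seed = 9)
  idx <- ddcquant:::alignmentToIndex(aln)
  hmm <- rateHMM(rhoConserved = 0.15, selfConserved = 0.9,
                 selfBackground = 0.85)
  logE <- ddcquant:::hmmEmissions(m, idx, hmm)
  fb <- ddcquant:::forwardBackward(hmm, logE)
  expect_equal(fb$logLik, bruteHMMLik(hmm, logE), tolerance = 1e-8)
  # posteriors are proper distributions per column
  expect_equal(colSums(fb$posterior), rep(1, 5), tolerance = 1e-10)
})

test_that("degenerate HMM with equal rates decodes nothing", {
  m <- wagModel(treeEight())
  aln <- simulateAlignment(m, 30, seed = 14)
  idx <- ddcquant:::alignmentToIndex(aln)
  # force both states to the background rate: emissions identical, the
  # posterior equals the chain's marginal state distribution
  bg <- ddcquant:::pruneLogLik(m, idx, 1)
  hmm <- rateHMM(0.5, 0.9, 0.9, initial = c(0.5, 0.5))
  fb <- ddcquant:::forwardBackward(hmm, rbind(bg, bg))
  expect_equal(fb$posterior[1, ], rep(0.5, 30), tolerance = 1e-10)
})

test_that("decoder recovers a planted conserved region", {
  # 4-taxon tree of depth ~1 substitution/site; one 30-column region at a
  # tenth of the background rate inside 200 columns
  m4 <- phyloModel(ape::read.tree(
    text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);"), cladeFlag = NA)
  hits <- 0
  set.seed(33)
  seeds <- sample.int(1e8, 50)
  for (s in seeds) {
    aln <- simulateAlignment(m4, 200,
                             regions = data.frame(start = 100, end = 130,
                                                  rho = 0.1), seed = s)
    dec <- decodeRegions(aln, m4, rateHMM(rhoConserved = 0.1))
    ok <- nrow(dec$regions) > 0 && any(abs(dec$regions$start - 100) <= 3 &
                                       abs(dec$regions$end - 130) <= 3)
    hits <- hits + ok
  }
  expect_gte(hits / length(seeds), 0.9)
})

test_that("region mapping shifts through insertions and flags unalignable paralogs", {
  pre <- rbind(A = strsplit("MKLVNQWERT", "")[[1]],
               B = strsplit("MKLVNQWERT", "")[[1]])
  regions <- data.frame(start = 4, end = 8)
  # identity when no extra columns exist
  same <- mapRegions(regions, pre, pre)
  expect_identical(same$full_start, 4L)
  expect_identical(same$full_end, 8L)
  # a 5-column insertion before the region shifts it by +5
  ins <- cbind(pre[, 1:3], matrix("-", 2, 5), pre[, 4:10])
  full <- rbind(ins, X = c(strsplit("MKL", "")[[1]],
                           strsplit("AAAAA", "")[[1]],
                           strsplit("VNQWERT", "")[[1]]))
  shifted <- mapRegions(regions, pre, full)
  expect_identical(shifted$full_start, 9L)
  expect_identical(shifted$full_end, 13L)
  # altered shared-row content is an error
  bad <- pre; bad["A", 2] <- "W"
  expect_error(mapRegions(regions, bad, pre), "differs")
})

test_that("constraint LRT detects a planted relaxation and respects nesting", {
  m <- wagModel(treeEight())
  regions <- data.frame(start = 10, end = 40, rho = 0.1)
  # relaxed inside the flagged clade: strong statistic expected
  lrts <- vapply(1:12, function(s) {
    aln <- simulateAlignment(m, 60, regions, shifted = TRUE, seed = s)
    lrtConstraintChange(data.frame(start = 10, end = 40), aln, m)$lrt
  }, numeric(1))
  expect_gt(median(lrts), 3.84)
  # the same data without a shift: small statistics, and the nested-model
  # inequality holds every time
  tsts <- lapply(1:12, function(s) {
    aln <- simulateAlignment(m, 60, regions, shifted = FALSE, seed = s)
    lrtConstraintChange(data.frame(start = 10, end = 40), aln, m)
  })
  expect_true(all(vapply(tsts, function(t)
    t$lnl_two >= t$lnl_one - 1e-6, logical(1))))
  expect_true(all(vapply(tsts, `[[`, numeric(1), "lrt") >= 0))
  # direction is reported from the fitted rates
  relaxed <- lrtConstraintChange(
    data.frame(start = 10, end = 40),
    simulateAlignment(m, 60, regions, shifted = TRUE, seed = 4), m)
  expect_identical(relaxed$direction, "relaxed")
  expect_gt(relaxed$rho_post, relaxed$rho_pre)
})

test_that("scanProtein reports complementary relaxation patterns", {
  # two paralog clades; two regions relaxed in clade P1 only, two in P2 only
  tree <- ape::read.tree(text = paste0(
    "((O1:0.3,O2:0.3):0.15,((P1a:0.25,P1b:0.25)CLADE1:0.2,",
    "(P2a:0.25,P2b:0.25)CLADE2:0.2)DUP:0.1);"))
  m <- phyloModel(tree, cladeFlag = "DUP")
  regions <- data.frame(start = c(20, 60, 100, 140),
                        end = c(20, 60, 100, 140) + 25, rho = 0.08)
  # simulate the two shift patterns with separate clade flags, then splice:
  # regions 1-2 lose constraint in clade 1, regions 3-4 in clade 2
  m1 <- phyloModel(tree, cladeFlag = "CLADE1")
  m2 <- phyloModel(tree, cladeFlag = "CLADE2")
  a1 <- simulateAlignment(m1, 180, regions, shifted = c(TRUE, TRUE, FALSE,
                                                        FALSE), seed = 5)
  a2 <- simulateAlignment(m2, 180, regions, shifted = c(FALSE, FALSE, TRUE,
                                                        TRUE), seed = 5)
  full <- a1
  full[, 81:180] <- a2[, 81:180]
  pre <- full[c("O1", "O2"), , drop = FALSE]
  scan <- scanProtein(pre, full, m, rateHMM(),
                      clades = c("CLADE1", "CLADE2"))
  expect_gte(nrow(scan$regions), 4)
  # the planted complementary partition is recovered: at least one region
  # relaxed in each clade alone, none lost in both
  expect_gte(sum(scan$summary$complementary), 2)
  expect_identical(sum(scan$summary$lost_in_all), 0L)
  # BH with a single test leaves p unchanged
  one <- scan$tests[1, ]
  expect_equal(p.adjust(one$p, "BH"), one$p)
})

test_that("scanProtein on an unconserved alignment returns an empty table", {
  m <- wagModel(treeEight())
  aln <- simulateAlignment(m, 50, seed = 61)
  pre <- aln[c("A", "B", "C", "D"), ]
  scan <- scanProtein(pre, aln, m, rateHMM())
  expect_identical(nrow(scan$tests), 0L)
})

test_that("EM fitting moves the conserved rate toward the generative value", {
  m4 <- phyloModel(ape::read.tree(
    text = "((A:0.25,B:0.25):0.25,(C:0.25,D:0.25):0.25);"), cladeFlag = NA)
  aln <- simulateAlignment(m4, 240,
                           regions = data.frame(start = c(40, 160),
                                                end = c(90, 210),
                                                rho = 0.1), seed = 8)
  fit <- fitHMM(aln, m4, nRestarts = 3, maxIter = 25)
  expect_lt(fit$hmm@rhoConserved, 0.5)
  # the fitted model should decode the planted regions
  dec <- decodeRegions(aln, m4, fit$hmm)
  expect_gte(nrow(dec$regions), 2)
})
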