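## Pipeline orchestration: flat key=value configuration, stage-granular
## logging with seeds echoed, atomic output writes, and a manifest of
## inputs, seeds and output digests. The synthetic end-to-end rerun
## (syntheticRerun) drives every stage on generated data and juxtaposes the
## computed quantities with the published reference values.

#' Read a flat key=value pipeline configuration
#'
#' One \code{key = value} pair per line; blank lines and \code{#} comments
#' ignored. Every randomized stage requires an explicit \code{seed} key.
#'
#' @param path config file.
#' @return Named list of character values.
#' @export
readPipelineConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed config line(s)")
  setNames(lapply(kv, function(x) trimws(x[2])),
           vapply(kv, function(x) trimws(x[1]), character(1)))
}

writeAtomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order — selection-coefficient fitting
#' (+ resolution summary from diagonal null wells), landscape construction
#' and classification, the constraint scan, and sectoring statistics — each
#' reading and writing only declared files. Missing optional inputs skip
#' their stage with a logged notice; outputs are written atomically and a
#' manifest records package version, seed, input digests and output
#' digests. Re-running an identical config reproduces byte-identical
#' outputs for deterministic stages.
#'
#' @param config named list or path to a key=value file. Recognised keys:
#'   \code{out_dir} (required), \code{seed}, \code{counts} (counts TSV),
#'   \code{wild_type} (reference genotype label), \code{genotypes}
#'   (genotype table TSV), \code{pre_alignment}, \code{full_alignment},
#'   \code{tree}, \code{matrix} (constraint-scan inputs), \code{clades}
#'   (comma-separated clade labels), \code{sectoring} (sectoring TSV),
#'   \code{sectoring_ref}.
#' @param verbose log stage progress (default TRUE).
#' @return Invisible list of stage results.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (is.character(config) && length(config) == 1)
    config <- readPipelineConfig(config)
  if (is.null(config$out_dir)) stop("config needs out_dir")
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (verbose) message("[ddcquant] ", ...)
  results <- list()
  inputs <- character(0)
  outputs <- character(0)

  if (!is.null(config$counts)) {
    note("stage fit-s: counts = ", config$counts)
    inputs <- c(inputs, config$counts)
    counts <- readCompetitionCounts(config$counts)
    est <- fitScreen(counts)
    p <- file.path(outDir, "estimates.tsv")
    writeAtomic(function(f) writeEstimates(est, f), p)
    outputs <- c(outputs, p)
    results$estimates <- est
    diag <- est[est$green_genotype == est$red_genotype &
                est$status == "measured", , drop = FALSE]
    if (nrow(diag) >= 2) {
      res <- estimateResolution(diag$s)
      p <- file.path(outDir, "resolution.tsv")
      writeAtomic(function(f) write.table(
        data.frame(mean_s = res$meanS, sd_s = res$sdS,
                   resolution = res$resolution,
                   call_threshold = res$callThreshold, n = res$n),
        f, sep = "\t", quote = FALSE, row.names = FALSE), p)
      outputs <- c(outputs, p)
      results$resolution <- res
    }
  } else note("stage fit-s skipped: no counts input")

  if (!is.null(config$genotypes) && !is.null(results$estimates) &&
      !is.null(config$wild_type)) {
    note("stage landscape: genotypes = ", config$genotypes)
    inputs <- c(inputs, config$genotypes)
    genotypes <- readGenotypeTable(config$genotypes)
    landscape <- buildLandscape(genotypes)
    vsWT <- estimatesVsWildType(results$estimates, config$wild_type)
    landscape <- classifyEdges(landscape, vsWT)
    p1 <- file.path(outDir, "landscape.tsv")
    p2 <- file.path(outDir, "landscape.dot")
    writeAtomic(function(f) writeLandscapeTable(landscape, f), p1)
    writeAtomic(function(f) writeLandscapeDot(landscape, f), p2)
    outputs <- c(outputs, p1, p2)
    results$landscape <- landscape
  } else note("stage landscape skipped: needs genotypes, estimates and ",
              "wild_type")

  if (!is.null(config$pre_alignment) && !is.null(config$full_alignment) &&
      !is.null(config$tree)) {
    note("stage constraint-scan: tree = ", config$tree)
    inputs <- c(inputs, config$pre_alignment, config$full_alignment,
                config$tree)
    mat <- if (!is.null(config$matrix)) {
      inputs <- c(inputs, config$matrix)
      parseRateMatrix(config$matrix)
    } else wagMatrix()
    clades <- if (!is.null(config$clades))
      trimws(strsplit(config$clades, ",")[[1]]) else "DUP"
    tree <- readAnnotatedTree(config$tree, flag = clades[1])
    model <- phyloModel(tree, mat, cladeFlag = clades[1])
    scan <- scanProtein(readAlignmentFasta(config$pre_alignment),
                        readAlignmentFasta(config$full_alignment),
                        model, clades = clades)
    p <- file.path(outDir, "constraint_tests.tsv")
    writeAtomic(function(f) write.table(scan$tests, f, sep = "\t",
                                        quote = FALSE, row.names = FALSE), p)
    outputs <- c(outputs, p)
    results$constraint <- scan
  } else note("stage constraint-scan skipped: alignment/tree inputs absent")

  if (!is.null(config$sectoring) && !is.null(config$sectoring_ref)) {
    note("stage count-stats: sectoring = ", config$sectoring)
    inputs <- c(inputs, config$sectoring)
    tab <- read.delim(config$sectoring, stringsAsFactors = FALSE)
    summ <- sectoringSummary(tab, config$sectoring_ref)
    p <- file.path(outDir, "sectoring.tsv")
    writeAtomic(function(f) write.table(summ, f, sep = "\t", quote = FALSE,
                                        row.names = FALSE), p)
    outputs <- c(outputs, p)
    results$sectoring <- summ
  } else note("stage count-stats skipped: no sectoring input")

  manifest <- c(
    paste0("package_version = ", as.character(utils::packageVersion("ddcquant"))),
    paste0("seed = ", if (is.null(config$seed)) "NA" else config$seed),
    paste0("input ", inputs, " md5 = ", unname(tools::md5sum(inputs))),
    paste0("output ", outputs, " md5 = ", unname(tools::md5sum(outputs))))
  writeAtomic(function(f) writeLines(manifest, f),
              file.path(outDir, "manifest.txt"))
  invisible(results)
}

#' Sign-aligned per-genotype estimates against wild-type
#'
#' Collects, for each non-reference genotype, the replicate estimates of
#' its selection coefficient relative to the wild-type reference from both
#' fluorophore orientations of the screen: wells with the genotype in the
#' red channel contribute the fitted s directly, wells with the genotype in
#' the green channel contribute the negated fit. Censoring status is
#' carried through the sign flip.
#'
#' @param estimates data.frame from \code{\link{fitScreen}}.
#' @param wildType reference genotype label.
#' @return data.frame with columns \code{genotype}, \code{replicate},
#'   \code{s}, \code{status}.
#' @export
estimatesVsWildType <- function(estimates, wildType) {
  rows <- list()
  for (i in seq_len(nrow(estimates))) {
    g <- estimates$green_genotype[i]; r <- estimates$red_genotype[i]
    if (g == wildType && r == wildType) {
      ## self-competition: the reference's own (null) contrast
      rows[[length(rows) + 1]] <- data.frame(
        genotype = wildType, s = estimates$s[i],
        status = estimates$status[i], stringsAsFactors = FALSE)
      next
    }
    if (g == wildType && r != wildType)
      rows[[length(rows) + 1]] <- data.frame(
        genotype = r, s = estimates$s[i], status = estimates$status[i],
        stringsAsFactors = FALSE)
    if (r == wildType && g != wildType)
      rows[[length(rows) + 1]] <- data.frame(
        genotype = g, s = -estimates$s[i], status = estimates$status[i],
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$replicate <- stats::ave(seq_len(nrow(out)), out$genotype,
                              FUN = seq_along)
  out[, c("genotype", "replicate", "s", "status")]
}

#' Synthetic end-to-end rerun
#'
#' Drives every stage of the pipeline on synthetic data generated under the
#' published study conditions — a 64-well null screen for assay resolution,
#' an 8-genotype all-by-all screen over the three fitness classes for
#' clustering, wild-type-referenced replicates for landscape edge calls and
#' neutral-path analysis, the printed sectoring tables for the exact tests,
#' plus the detection-limit and effective-population-size arithmetic — and
#' reports each computed quantity next to the published reference value.
#'
#' @param seed integer seed controlling all randomness.
#' @param nAgreementSeeds screens simulated for the class-recovery rate
#'   (default 100).
#' @return A list with components \code{resolution}, \code{clustering},
#'   \code{landscape}, \code{paths}, \code{sectoring}, \code{constants} and
#'   a \code{report} data.frame (columns \code{quantity}, \code{computed},
#'   \code{reference}).
#' @export
syntheticRerun <- function(seed = 1, nAgreementSeeds = 100) {
  set.seed(seed)
  stageSeeds <- sample.int(.Machine$integer.max - 1, 4)

  ## -- null screen: assay resolution ---------------------------------------
  nullDesign <- screenDesign(paste0("wt_g", 1:8), paste0("wt_r", 1:8))
  nullS <- setNames(rep(0, 16), c(paste0("wt_g", 1:8), paste0("wt_r", 1:8)))
  nullCounts <- simulateScreen(nullDesign, nullS, seed = stageSeeds[1])
  nullEst <- fitScreen(nullCounts)
  resolution <- estimateResolution(nullEst$s[nullEst$status == "measured"])

  ## -- three-class screen: clustering --------------------------------------
  genotypes <- ddcGenotypeSet()
  trueS <- trueClassAssignment(genotypes)
  screenLabs <- c("extant_like", "scp_double", "dKEN1_dKINASE",
                  "dKEN1dABBA1_dKINASE", "extant_dKEN1mad3",
                  "extant_lossMAD3", "extant_dKINASEbub1",
                  "extant_lossBUB1")
  cluster <- clusterScreenOnce(screenLabs, trueS, stageSeeds[2])
  agree <- classRecoveryRate(screenLabs, trueS, nAgreementSeeds,
                             seed = stageSeeds[3])

  ## -- landscape: edge calls, neutral paths, absorbing state ---------------
  landscape <- classifiedSyntheticLandscape(genotypes, trueS,
                                            seed = stageSeeds[4])
  paths <- findNeutralPaths(landscape, "scp_single", "extant_like")
  ok <- !vapply(paths, `[[`, logical(1), "indeterminate")
  degen <- vapply(paths[ok], `[[`, numeric(1), "degenerations")
  absorbing <- isAbsorbing(landscape, "extant_like")

  ## -- sectoring tables (published counts as inputs) -----------------------
  sectoring <- sectoringSummary(data.frame(
    genotype = c("WT", "bub1d", "mad3d", "SCP"),
    sectored = c(3, 29, 5, 3), white = c(131, 65, 177, 207),
    stringsAsFactors = FALSE), "WT")

  ## -- assay constants ------------------------------------------------------
  constants <- list(
    wells = nrow(nullDesign$wells),
    doublings_per_day = estimateNe(2e8, 0.32, 1024)$generations,
    detection_limit = detectionLimit(),
    ne = estimateNe(2e8, 0.32, 1024)$Ne)

  report <- data.frame(
    quantity = c("null screen mean s", "null screen sd s",
                 "resolution (1.96 sd)", "fitness classes",
                 "class recovery agreement", "mad3-like class mean s",
                 "neutral paths (>=3 degenerations)",
                 "extant node absorbing", "bub1-null sectoring p",
                 "mad3-null sectoring p", "screen wells",
                 "doublings per day", "detection limit s"),
    computed = c(resolution$meanS, resolution$sdS, resolution$resolution,
                 cluster$k, agree,
                 cluster$classMeanS[which.min(abs(cluster$classMeanS +
                                                  0.015))],
                 sum(degen >= 3), as.numeric(absorbing),
                 sectoring$p[sectoring$genotype == "bub1d"],
                 sectoring$p[sectoring$genotype == "mad3d"],
                 nrow(nullDesign$wells), constants$doublings_per_day,
                 constants$detection_limit),
    reference = c(0.00069, 0.0017, 0.0033, 3, NA, -0.015, 1, 1, 1e-4,
                  NA, 64, 10, -0.3),
    stringsAsFactors = FALSE)
  list(resolution = resolution, clustering = cluster,
       agreement = agree, landscape = landscape, paths = paths,
       absorbing = absorbing, sectoring = sectoring,
       constants = constants, report = report)
}

## Simulate one all-by-all screen over the given genotypes and cluster it.
clusterScreenOnce <- function(labels, trueS, seed,
                              wildType = "extant_like") {
  design <- screenDesign(labels, labels)
  counts <- simulateScreen(design, trueS[labels], seed = seed)
  est <- fitScreen(counts)
  M <- screenMatrix(est, labels)
  clusterFitnessClasses(M, wildType = wildType)
}

## Proportion of screens (over `n` seeds) whose clustering recovers the
## true class partition, scored as best-permutation label agreement.
classRecoveryRate <- function(labels, trueS, n, seed,
                              wildType = "extant_like") {
  trueClass <- as.integer(factor(trueS[labels]))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, n)
  rates <- vapply(seq_len(n), function(i) {
    cl <- clusterScreenOnce(labels, trueS, seeds[i], wildType)
    labelAgreement(cl$classes[labels], trueClass)
  }, numeric(1))
  mean(rates)
}

## Best agreement between two labelings over all permutations of cluster
## identities.
labelAgreement <- function(pred, truth) {
  ks <- unique(pred)
  perms <- permutationsOf(length(ks))
  best <- 0
  for (p in seq_len(nrow(perms))) {
    mapped <- perms[p, ][match(pred, ks)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

permutationsOf <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutationsOf(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

## Build the synthetic landscape, simulate wild-type-referenced replicate
## competitions for every genotype (both fluorophore orientations, each
## assayed in `nTech` technical-replicate wells that are averaged into one
## biological replicate — key genotypes in the assayed study were likewise
## re-assayed technically), and classify the edges.
classifiedSyntheticLandscape <- function(genotypes = ddcGenotypeSet(),
                                         trueS = trueClassAssignment(genotypes),
                                         seed = 1,
                                         wildType = "extant_like",
                                         nTech = 2) {
  landscape <- buildLandscape(genotypes)
  labs <- setdiff(names(genotypes), wildType)
  one <- data.frame(
    well_id = c(paste0("A_", labs), paste0("B_", labs), "SA", "SB"),
    green_genotype = c(rep(wildType, length(labs)), labs, wildType,
                       wildType),
    red_genotype = c(labs, rep(wildType, length(labs)), wildType,
                     wildType),
    stringsAsFactors = FALSE)
  wells <- do.call(rbind, lapply(seq_len(nTech), function(tech) {
    w <- one
    w$well_id <- paste0(w$well_id, "_t", tech)
    w
  }))
  counts <- simulateScreen(list(wells = wells, controls = 0), trueS,
                           seed = seed)
  est <- fitScreen(counts)
  vsWT <- estimatesVsWildType(est, wildType)
  ## average technical wells within each (genotype, fluorophore
  ## orientation): replicates 1..nTech share an orientation by construction
  vsWT$orientation <- (vsWT$replicate - 1) %% 2
  agg <- do.call(rbind, lapply(split(vsWT, vsWT[c("genotype",
                                                  "orientation")]),
    function(d) data.frame(
      genotype = d$genotype[1], replicate = d$orientation[1] + 1,
      s = mean(d$s),
      status = if (any(d$status == "censored_low")) "censored_low"
               else if (all(d$status == "equally_lethal")) "equally_lethal"
               else "measured",
      stringsAsFactors = FALSE)))
  classifyEdges(landscape, agg)
}
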