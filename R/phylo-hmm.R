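## Phylogenetic HMM machinery: Felsenstein-pruning column likelihoods
## (vectorised over alignment columns), the two-state rate HMM
## forward-backward decoder, and EM fitting of the HMM parameters.

GAP_CHARS <- c("-", ".", "?", "*", "X", "B", "Z", "J", "U", "O")

## Character alignment matrix -> integer indices into AA_ALPHABET; gaps and
## ambiguity codes become NA (missing data).
alignmentToIndex <- function(aln) {
  if (!is.matrix(aln)) stop("alignment must be a character matrix")
  idx <- match(toupper(aln), AA_ALPHABET)
  bad <- is.na(idx) & !(toupper(aln) %in% GAP_CHARS)
  if (any(bad))
    stop("residues outside the amino-acid alphabet: ",
         paste(unique(aln[bad]), collapse = " "))
  matrix(idx, nrow(aln), ncol(aln), dimnames = dimnames(aln))
}

## Column log-likelihoods for all columns of an indexed alignment under the
## model with branch lengths multiplied by `rate` (scalar, or one multiplier
## per tree edge for clade-specific rates). Felsenstein pruning, vectorised
## over columns; gap leaves carry partial-likelihood vectors of ones. `eig`
## lets callers cache the spectral decomposition.
pruneLogLik <- function(model, idx, rate, eig = substitutionEigen(model)) {
  tree <- model@tree
  rate <- if (length(rate) == 1L) rep(rate, nrow(tree$edge)) else rate
  if (length(rate) != nrow(tree$edge))
    stop("rate must be scalar or one value per edge")
  tips <- tree$tip.label
  if (!all(tips %in% rownames(idx)))
    stop("alignment lacks rows for tree tips: ",
         paste(setdiff(tips, rownames(idx)), collapse = ", "))
  idx <- idx[tips, , drop = FALSE]
  nTip <- length(tips)
  nCol <- ncol(idx)
  edges <- ape::postorder(tree)
  parentOf <- tree$edge[, 1]; childOf <- tree$edge[, 2]
  partial <- vector("list", nTip + tree$Nnode)
  scaleLog <- numeric(nCol)
  leafMat <- function(row) {
    L <- matrix(0, 20, nCol)
    obs <- which(!is.na(row))
    L[cbind(row[obs], obs)] <- 1
    if (length(obs) < nCol) L[, setdiff(seq_len(nCol), obs)] <- 1
    L
  }
  for (e in edges) {
    ch <- childOf[e]; pa <- parentOf[e]
    Lc <- if (ch <= nTip) leafMat(idx[ch, ]) else partial[[ch]]
    contrib <- transitionProb(eig, tree$edge.length[e] * rate[e]) %*% Lc
    partial[[pa]] <- if (is.null(partial[[pa]])) contrib
                     else partial[[pa]] * contrib
    sc <- .colSums(partial[[pa]], 20, nCol)
    if (min(sc) < 1e-150) {
      partial[[pa]] <- partial[[pa]] / rep(sc, each = 20)
      scaleLog <- scaleLog + log(sc)
    }
  }
  root <- nTip + 1L
  log(.colSums(partial[[root]] * model@frequencies, 20, nCol)) + scaleLog
}

#' Phylogenetic log-likelihood of one alignment column
#'
#' Felsenstein-pruning likelihood of a single aligned column under the
#' substitution model, with all branch lengths multiplied by \code{rate};
#' gaps are treated as missing data.
#'
#' @param column named character vector, one residue (or gap) per tree leaf.
#' @param model a \code{\link{PhyloModel}}.
#' @param rate positive branch-length multiplier.
#' @return Log-likelihood of the column.
#' @export
columnLikelihood <- function(column, model, rate = 1) {
  stopifnot(rate > 0)
  aln <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  pruneLogLik(model, alignmentToIndex(aln), rate)
}

## Emission log-likelihood matrix (2 x columns) for the rate HMM: row 1 the
## conserved state (multiplier rho), row 2 background (multiplier 1).
hmmEmissions <- function(model, idx, hmm, eig = substitutionEigen(model)) {
  rbind(conserved = pruneLogLik(model, idx, hmm@rhoConserved, eig),
        background = pruneLogLik(model, idx, 1, eig))
}

## Scaled forward-backward for the 2-state HMM. Returns per-column
## posteriors (2 x C), the forward log-likelihood, and the expected
## transition-count matrix (for EM).
forwardBackward <- function(hmm, logE) {
  C <- ncol(logE)
  m <- apply(logE, 2, max)
  E <- exp(sweep(logE, 2, m))
  A <- hmm@transitions
  alpha <- matrix(0, 2, C); beta <- matrix(0, 2, C)
  cs <- numeric(C)
  a <- hmm@initial * E[, 1]
  cs[1] <- sum(a); alpha[, 1] <- a / cs[1]
  if (C > 1) for (t in 2:C) {
    a <- (crossprod(A, alpha[, t - 1])) * E[, t]
    cs[t] <- sum(a); alpha[, t] <- a / cs[t]
  }
  beta[, C] <- 1
  if (C > 1) for (t in (C - 1):1)
    beta[, t] <- (A %*% (E[, t + 1] * beta[, t + 1])) / cs[t + 1]
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  xi <- matrix(0, 2, 2)
  if (C > 1) for (t in 2:C)
    xi <- xi + (alpha[, t - 1] %o% (E[, t] * beta[, t])) * A / cs[t]
  list(posterior = gamma, logLik = sum(log(cs)) + sum(m), xi = xi)
}

#' Decode conserved regions with the phylo-HMM
#'
#' Runs the two-state rate HMM over the alignment columns: emissions are
#' phylogenetic column likelihoods at the conserved and background rate
#' multipliers, the forward-backward posteriors are computed per column, and
#' maximal runs of columns with conserved posterior > 0.5 of length at least
#' \code{minLen} are reported as conserved regions. Each region's rate is
#' re-fitted by bounded one-dimensional likelihood maximisation over its
#' columns.
#'
#' @param aln character matrix of aligned residues (rows = tree tips).
#' @param model a \code{\link{PhyloModel}}.
#' @param hmm a \code{\link{RateHMM}}.
#' @param minLen minimum region length in columns (default 3, favouring
#'   short-motif sensitivity).
#' @return A list with \code{regions} (data.frame \code{start}, \code{end}
#'   0-based half-open, \code{mean_posterior}, \code{rho_hat}),
#'   \code{posterior} (2 x columns matrix) and the forward \code{logLik}.
#' @export
decodeRegions <- function(aln, model, hmm = rateHMM(), minLen = 3) {
  idx <- alignmentToIndex(aln)
  if (ncol(idx) < 1) stop("empty alignment")
  eig <- substitutionEigen(model)
  fb <- forwardBackward(hmm, hmmEmissions(model, idx, hmm, eig))
  post <- fb$posterior[1, ]
  r <- rle(post > 0.5)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= minLen)
  regions <- data.frame(start = integer(0), end = integer(0),
                        mean_posterior = numeric(0), rho_hat = numeric(0))
  for (k in keep) {
    cols <- starts[k]:ends[k]
    fit <- optimize(function(r) sum(pruneLogLik(model,
                      idx[, cols, drop = FALSE], r, eig)),
                    interval = c(1e-4, 10), maximum = TRUE, tol = 1e-6)
    regions <- rbind(regions,
                     data.frame(start = starts[k] - 1L, end = ends[k],
                                mean_posterior = mean(post[cols]),
                                rho_hat = fit$maximum))
  }
  list(regions = regions, posterior = fb$posterior, logLik = fb$logLik)
}

#' Fit rate-HMM parameters by expectation-maximisation
#'
#' Baum-Welch updates for the transition matrix and initial distribution,
#' with the conserved-state rate multiplier re-estimated each iteration by
#' bounded maximisation of its posterior-weighted emission likelihood.
#' Multiple random restarts guard against local optima; the best-likelihood
#' fit is returned.
#'
#' @inheritParams decodeRegions
#' @param init starting \code{\link{RateHMM}} (default: rho 0.2,
#'   self-transitions 0.95).
#' @param nRestarts random restarts (default 10).
#' @param maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed integer seed for the restart jitter.
#' @return A list with the fitted \code{hmm} and its \code{logLik}.
#' @export
fitHMM <- function(aln, model, init = rateHMM(), nRestarts = 10,
                   maxIter = 50, tol = 1e-6, seed = 1) {
  idx <- alignmentToIndex(aln)
  eig <- substitutionEigen(model)
  bgLL <- pruneLogLik(model, idx, 1, eig)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    rho <- if (r == 1) init@rhoConserved else runif(1, 0.02, 0.9)
    selfC <- if (r == 1) init@transitions[1, 1] else runif(1, 0.7, 0.99)
    selfB <- if (r == 1) init@transitions[2, 2] else runif(1, 0.7, 0.99)
    hmm <- rateHMM(rho, selfC, selfB, init@initial)
    prev <- -Inf
    for (it in seq_len(maxIter)) {
      logE <- rbind(pruneLogLik(model, idx, hmm@rhoConserved, eig), bgLL)
      fb <- forwardBackward(hmm, logE)
      if (abs(fb$logLik - prev) < tol) break
      prev <- fb$logLik
      A <- fb$xi / pmax(rowSums(fb$xi), .Machine$double.eps)
      w <- fb$posterior[1, ]
      rhoFit <- optimize(function(rr)
        sum(w * pruneLogLik(model, idx, rr, eig)),
        interval = c(1e-3, 0.999), maximum = TRUE, tol = 1e-4)$maximum
      hmm <- new("RateHMM", rhoConserved = rhoFit, transitions = A,
                 initial = fb$posterior[, 1])
    }
    if (is.null(best) || prev > best$logLik)
      best <- list(hmm = hmm, logLik = prev)
  }
  best
}
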