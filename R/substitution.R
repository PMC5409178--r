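## Reversible amino-acid substitution model: symmetric exchangeabilities S
## composed with stationary frequencies pi give the rate matrix
## Q_ij = S_ij pi_j (i != j), rows summing to zero, normalised so that
## -sum_i pi_i Q_ii = 1 expected substitution per site per unit branch
## length. Transition probabilities P(t) = exp(Qt) come from the spectral
## decomposition of the pi-symmetrised rate matrix.

#' Read an exchangeability matrix in PAML-style format
#'
#' The dialect: optional comment lines starting with \code{#}; 19 rows of
#' whitespace-separated numbers forming the strict lower triangle of the
#' symmetric 20x20 exchangeability matrix in residue order
#' \code{ARNDCQEGHILKMFPSTWYV}; then a line of 20 stationary frequencies.
#' Frequencies are renormalised to sum exactly to 1.
#'
#' @param path file path.
#' @return A list with \code{exchangeability} (symmetric 20x20 matrix,
#'   dimnames = residues) and \code{frequencies} (named numeric(20)).
#' @export
parseRateMatrix <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nums <- lapply(strsplit(lines, "\\s+"), as.numeric)
  if (any(vapply(nums, function(x) any(is.na(x)), logical(1))))
    stop("non-numeric content in rate-matrix file")
  flat <- unlist(nums)
  if (length(flat) < 190 + 20)
    stop("rate-matrix file must hold 190 exchangeabilities + 20 frequencies")
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  k <- 0
  for (i in 2:20) {           # row-wise strict lower triangle
    S[i, 1:(i - 1)] <- flat[k + 1:(i - 1)]
    k <- k + i - 1
  }
  S <- S + t(S)
  freqs <- flat[k + 1:20]
  if (any(freqs <= 0)) stop("frequencies must be positive")
  freqs <- freqs / sum(freqs)
  names(freqs) <- AA_ALPHABET
  list(exchangeability = S, frequencies = freqs)
}

#' The packaged WAG amino-acid model
#'
#' The published WAG empirical exchangeabilities and stationary frequencies
#' (Whelan & Goldman 2001), shipped as a plain-text file and used as the
#' default emission model throughout the constraint scanner.
#'
#' @return As \code{\link{parseRateMatrix}}.
#' @export
wagMatrix <- function() {
  parseRateMatrix(system.file("extdata", "wag.dat", package = "ddcquant",
                              mustWork = TRUE))
}

#' Construct a phylogenetic substitution model
#'
#' @param tree rooted \code{ape::phylo} with branch lengths; may carry a
#'   node label flagging the post-duplication clade.
#' @param matrix a list as returned by \code{\link{parseRateMatrix}}
#'   (default: the packaged WAG model).
#' @param cladeFlag node label marking the post-duplication clade
#'   (\code{NA} when the tree has none).
#' @return A \code{\link{PhyloModel}}.
#' @export
phyloModel <- function(tree, matrix = wagMatrix(), cladeFlag = "DUP") {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  cladeFlag <- as.character(cladeFlag)
  if (!is.na(cladeFlag) && is.na(flaggedNode(tree, cladeFlag)))
    cladeFlag <- NA_character_
  new("PhyloModel", tree = tree, exchangeability = matrix$exchangeability,
      frequencies = matrix$frequencies, cladeFlag = cladeFlag)
}

## Spectral decomposition of the normalised rate matrix. Returns U, Uinv and
## eigenvalues lambda with P(t) = U diag(exp(lambda t)) Uinv.
substitutionEigen <- function(model) {
  pi <- model@frequencies
  Q <- model@exchangeability * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  d <- sqrt(pi)
  B <- Q * (d / rep(d, each = 20))      # D^{1/2} Q D^{-1/2}, symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / d, Uinv = t(e$vectors) * rep(d, each = 20),
       lambda = e$values)
}

## P(t) = exp(Qt) from a cached spectral decomposition; tiny negative
## entries from roundoff are clamped and rows renormalised.
transitionProb <- function(eig, t) {
  P <- (eig$U * rep(exp(eig$lambda * t), each = 20)) %*% eig$Uinv
  P[P < 0] <- 0
  P / rowSums(P)
}
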