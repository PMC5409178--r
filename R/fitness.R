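## Selection-coefficient inference from competitive flow-cytometry counts.
##
## Model: deterministic logistic competition dR/dt = s R G with G = 1 - R,
## whose solution is linear on the log-odds scale,
##   logit R(t) = logit R(0) + s t,
## observed through binomial sampling of n cells per timepoint. The MLE of
## (R0, s) is therefore a binomial logistic regression of red counts on
## generations.

#' Logistic competition trajectory
#'
#' Expected red-cell frequency after \code{t} generations of competition at
#' selection coefficient \code{s}, starting from frequency \code{R0}:
#' \deqn{R(t) = \frac{R_0 e^{st}}{(1 - R_0) + R_0 e^{st}}}
#' computed on the log-odds scale for numerical safety.
#'
#' @param R0 initial red frequency, in (0, 1).
#' @param s selection coefficient per generation.
#' @param t generations (non-negative; vectorised).
#' @return Red-cell frequency R(t) in (0, 1).
#' @examples
#' logisticTrajectory(0.5, log(2) / 20, 20)  # odds double: 2/3
#' @export
logisticTrajectory <- function(R0, s, t) {
  if (any(R0 <= 0) || any(R0 >= 1))
    stop("R0 must lie strictly inside (0, 1)")
  if (any(t < 0)) stop("t must be non-negative")
  plogis(qlogis(R0) + s * t)
}

#' Binomial log-likelihood of competition counts
#'
#' Sum over timepoints of the binomial log-probability of the observed red
#' count given the logistic trajectory, including the combinatorial
#' constants (so values are comparable across calls).
#'
#' @param counts a \code{\link{CompetitionCounts}}.
#' @param R0 initial red frequency in (0, 1).
#' @param s selection coefficient.
#' @return Log-likelihood value.
#' @export
competitionLogLik <- function(counts, R0, s) {
  stopifnot(is(counts, "CompetitionCounts"))
  n <- totalCounts(counts)
  Rt <- logisticTrajectory(R0, s, counts@generations)
  sum(dbinom(counts@red, n, Rt, log = TRUE))
}

#' Closed-form selection-coefficient estimate for two timepoints
#'
#' With exactly two timepoints the maximum-likelihood estimate is the
#' log-odds-ratio slope
#' \deqn{\hat s = \frac{\log(r_2/g_2) - \log(r_1/g_1)}{t_2 - t_1}}
#' and the fitted initial frequency is the back-extrapolation of the fitted
#' log-odds line to generation zero. All four counts must be positive;
#' apply \code{\link{censorCompetition}} first.
#'
#' @param counts a \code{\link{CompetitionCounts}} with exactly two
#'   timepoints.
#' @return A \code{\link{SelectionEstimate}} with status \code{"measured"}.
#' @examples
#' estimateSClosedForm(
#'   competitionCounts(c(20, 40), red = c(100, 200), green = c(100, 100)))
#' @export
estimateSClosedForm <- function(counts) {
  stopifnot(is(counts, "CompetitionCounts"))
  if (length(counts@generations) != 2L)
    stop("closed form requires exactly two timepoints")
  if (any(counts@red < 1) || any(counts@green < 1))
    stop("zero count in a channel: apply censoring first")
  t <- counts@generations
  lo <- log(counts@red / counts@green)
  s <- (lo[2] - lo[1]) / (t[2] - t[1])
  R0 <- plogis(lo[1] - s * t[1])
  se <- sqrt(sum(1 / counts@red + 1 / counts@green)) / (t[2] - t[1])
  new("SelectionEstimate", s = s, R0Hat = R0, status = "measured", se = se,
      converged = TRUE, wellId = counts@wellId)
}

#' Maximum-likelihood selection-coefficient estimate
#'
#' Joint maximum-likelihood fit of (R0, s) under the binomial logistic-growth
#' likelihood, for two or more timepoints, by iteratively reweighted least
#' squares (binomial logistic regression of red counts on generations;
#' convergence when the deviance change falls below 1e-10, at most 200
#' iterations). For exactly two timepoints this equals
#' \code{\link{estimateSClosedForm}} to well below 1e-8.
#'
#' @param counts a \code{\link{CompetitionCounts}} with >= 2 timepoints and
#'   positive counts.
#' @return A \code{\link{SelectionEstimate}}; non-convergence is flagged in
#'   the \code{converged} slot, never silent.
#' @export
estimateSMLE <- function(counts) {
  stopifnot(is(counts, "CompetitionCounts"))
  if (length(counts@generations) < 2L)
    stop("estimation requires at least two timepoints")
  if (any(counts@red < 1) || any(counts@green < 1))
    stop("zero count in a channel: apply censoring first")
  t <- counts@generations
  fit <- glm(cbind(counts@red, counts@green) ~ t, family = binomial("logit"),
             control = glm.control(epsilon = 1e-10, maxit = 200))
  s <- unname(coef(fit)[2])
  R0 <- plogis(unname(coef(fit)[1]))
  se <- sqrt(vcov(fit)[2, 2])
  if (!fit$converged)
    warning("IRLS did not converge for well ", counts@wellId)
  new("SelectionEstimate", s = s, R0Hat = R0, status = "measured", se = se,
      converged = fit$converged, wellId = counts@wellId)
}

#' Apply censoring rules to competition counts
#'
#' Reporting conventions for competitions that leave the measurable range:
#' if the total count at any timepoint is below \code{minTotalCount}, both
#' competitors are below countable abundance and the competition is reported
#' as \code{equally_lethal} (s = 0); otherwise, if either channel falls below
#' \code{minChannelCount} at any assayed timepoint (strongly depleted strains
#' can already be undetectable at generation 20), the estimate is censored at
#' the measurable bound, signed against the depleted channel (a depleted red
#' channel is reported as s < -0.3). Otherwise the counts pass through
#' unchanged for estimation. Equal lethality takes precedence over channel
#' censoring, so no estimator ever sees a zero count.
#'
#' @param counts a \code{\link{CompetitionCounts}}.
#' @param config an \code{\link{AssayConfig}}.
#' @return A \code{\link{SelectionEstimate}} for censored wells, or the
#'   input \code{CompetitionCounts} (pass-through) when measurable.
#' @examples
#' censorCompetition(
#'   competitionCounts(c(20, 40), red = c(200, 20), green = c(49800, 49980)))
#' @export
censorCompetition <- function(counts, config = assayConfig()) {
  stopifnot(is(counts, "CompetitionCounts"), is(config, "AssayConfig"))
  n <- totalCounts(counts)
  if (any(n < config@minTotalCount))
    return(new("SelectionEstimate", s = 0, status = "equally_lethal",
               wellId = counts@wellId))
  redLow <- any(counts@red < config@minChannelCount)
  greenLow <- any(counts@green < config@minChannelCount)
  if (redLow || greenLow) {
    sign <- if (redLow) -1 else 1
    return(new("SelectionEstimate", s = sign * config@maxMagnitude,
               status = "censored_low", wellId = counts@wellId))
  }
  counts
}

#' Censor-then-estimate convenience wrapper
#'
#' @inheritParams censorCompetition
#' @param method \code{"closed_form"} (two timepoints) or \code{"mle"}.
#' @return A \code{\link{SelectionEstimate}}.
#' @export
estimateSelection <- function(counts, config = assayConfig(),
                              method = c("closed_form", "mle")) {
  method <- match.arg(method)
  out <- censorCompetition(counts, config)
  if (is(out, "SelectionEstimate")) return(out)
  if (method == "closed_form" && length(counts@generations) == 2L)
    estimateSClosedForm(out) else estimateSMLE(out)
}

#' Detection limit of the assay
#'
#' The selection coefficient at which the expected minority frequency first
#' falls below 1/\code{detectDenominator} at the final assayed generation,
#' found by bisection on the logistic trajectory to |delta s| < 1e-6. For
#' the published design (R0 = 0.5, 40 generations, 1 cell in 50,000) the
#' root is s = -0.27049.
#'
#' @param config an \code{\link{AssayConfig}}.
#' @param R0 initial red frequency.
#' @param tFinal final assayed generation.
#' @return The limiting selection coefficient (negative: the red strain is
#'   the depleted minority).
#' @export
detectionLimit <- function(config = assayConfig(), R0 = 0.5, tFinal = 40) {
  stopifnot(is(config, "AssayConfig"), R0 > 0, R0 < 1, tFinal > 0)
  target <- 1 / config@detectDenominator
  f <- function(s) logisticTrajectory(R0, s, tFinal) - target
  lo <- -10; hi <- 10
  if (f(lo) > 0 || f(hi) < 0) stop("no root in bracket [-10, 10]")
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Assay resolution from null competitions
#'
#' Mean and sample standard deviation (n - 1 denominator) of
#' selection-coefficient estimates from competitions of genetically identical
#' strains, and the implied resolution 1.96 x SD: the smallest |s| the assay
#' can distinguish from measurement noise at the 5\% level.
#'
#' @param nullEstimates numeric vector of fitted s values (>= 2), or a list
#'   of \code{SelectionEstimate}s (censored entries excluded).
#' @param callThreshold reported call threshold (default 0.005; must not be
#'   below the resolution).
#' @return A list with \code{meanS}, \code{sdS}, \code{resolution} (=
#'   1.96 * sdS), \code{callThreshold} and \code{n}.
#' @examples
#' estimateResolution(c(-0.001, 0.001))
#' @export
estimateResolution <- function(nullEstimates, callThreshold = 0.005) {
  if (is.list(nullEstimates)) {
    keep <- vapply(nullEstimates, function(e)
      estimateStatus(e) == "measured", logical(1))
    nullEstimates <- vapply(nullEstimates[keep], selectionCoef, numeric(1))
  }
  if (length(nullEstimates) < 2)
    stop("need at least two null estimates")
  sdS <- sd(nullEstimates)
  res <- 1.96 * sdS
  if (callThreshold < res)
    warning("call threshold ", callThreshold,
            " is below the measured resolution ", signif(res, 3))
  list(meanS = mean(nullEstimates), sdS = sdS, resolution = res,
       callThreshold = callThreshold, n = length(nullEstimates))
}

#' Call the fitness effect of a genotype contrast
#'
#' Replicated (fluorophore-swapped) estimates of the same genotype contrast,
#' sign-aligned by the caller, are called \code{deleterious} when every
#' replicate is at or below -\code{callThreshold}, \code{beneficial} when
#' every replicate is at or above +\code{callThreshold},
#' \code{inconsistent} when the replicates disagree in sign with at least
#' one exceeding the threshold, and \code{no_detectable_effect} otherwise.
#' A replicate censored at s < -0.3 forces a \code{deleterious} call.
#'
#' @param replicates numeric vector (>= 2) of replicate s values, or a list
#'   of \code{SelectionEstimate}s.
#' @param config an \code{\link{AssayConfig}} supplying the call threshold.
#' @return One of \code{"deleterious"}, \code{"beneficial"},
#'   \code{"no_detectable_effect"}, \code{"inconsistent"}.
#' @examples
#' callEffect(c(-0.013, -0.015))   # deleterious
#' callEffect(c(0.002, -0.001))    # no_detectable_effect
#' @export
callEffect <- function(replicates, config = assayConfig()) {
  if (is.list(replicates)) {
    status <- vapply(replicates, estimateStatus, character(1))
    s <- vapply(replicates, selectionCoef, numeric(1))
    if (any(status == "censored_low" & s < 0)) {
      if (length(replicates) < 2) stop("at least two replicates required")
      return("deleterious")
    }
  } else {
    s <- as.numeric(replicates)
  }
  if (length(s) < 2) stop("at least two replicates required")
  thr <- config@callThreshold
  if (all(s <= -thr)) return("deleterious")
  if (all(s >= thr)) return("beneficial")
  if (min(s) < 0 && max(s) > 0 && any(abs(s) >= thr)) return("inconsistent")
  "no_detectable_effect"
}

#' Effective population size of the serial-dilution assay
#'
#' Harmonic-mean effective size over one growth cycle of a serially diluted
#' culture: with bottleneck size \eqn{N_b} (saturation density x volume /
#' dilution factor) and \eqn{g = \log_2(\mathrm{dilution})} doublings per
#' cycle,
#' \deqn{N_e = g \Big/ \sum_{i=0}^{g-1} \frac{1}{N_b 2^i}.}
#'
#' @param saturationDensity cells/mL at saturation (published estimate
#'   2e8).
#' @param cultureVolume culture volume in mL.
#' @param dilutionFactor per-cycle dilution (published design 1024).
#' @param generationsPerCycle doublings per cycle; defaults to
#'   \code{log2(dilutionFactor)}.
#' @return A list with \code{Ne}, \code{nBottleneck} and
#'   \code{generations}.
#' @examples
#' estimateNe(2e8, 0.32, 1024)
#' @export
estimateNe <- function(saturationDensity, cultureVolume,
                       dilutionFactor = 1024,
                       generationsPerCycle = NULL) {
  stopifnot(saturationDensity > 0, cultureVolume > 0, dilutionFactor > 0)
  g <- log2(dilutionFactor)
  if (abs(g - round(g)) > 1e-9)
    warning("dilution factor is not a power of two; using g = log2")
  else g <- round(g)
  if (!is.null(generationsPerCycle)) g <- generationsPerCycle
  nb <- saturationDensity * cultureVolume / dilutionFactor
  ne <- g / sum(1 / (nb * 2^(seq_len(g) - 1)))
  list(Ne = ne, nBottleneck = nb, generations = g)
}

#' Fit selection coefficients for a whole screen
#'
#' Applies censoring and estimation to every well of a long-format count
#' table (schema of \code{\link{writeCompetitionCounts}}).
#'
#' @param countsTable data.frame with columns \code{well_id},
#'   \code{green_genotype}, \code{red_genotype}, \code{generation},
#'   \code{red_count}, \code{green_count}.
#' @param config an \code{\link{AssayConfig}}.
#' @param method estimation method, see \code{\link{estimateSelection}}.
#' @return data.frame with one row per well: \code{well_id},
#'   \code{green_genotype}, \code{red_genotype}, \code{s}, \code{R0_hat},
#'   \code{status}, \code{se}.
#' @export
fitScreen <- function(countsTable, config = assayConfig(),
                      method = "closed_form") {
  stopifnot(all(c("well_id", "generation", "red_count", "green_count") %in%
                names(countsTable)))
  wells <- split(countsTable, countsTable$well_id)
  rows <- lapply(wells, function(w) {
    w <- w[order(w$generation), ]
    cc <- competitionCounts(w$generation, w$red_count, w$green_count,
                            wellId = w$well_id[1],
                            greenGenotype = w$green_genotype[1],
                            redGenotype = w$red_genotype[1])
    est <- estimateSelection(cc, config, method)
    data.frame(well_id = w$well_id[1],
               green_genotype = w$green_genotype[1],
               red_genotype = w$red_genotype[1],
               s = selectionCoef(est), R0_hat = est@R0Hat,
               status = estimateStatus(est), se = est@se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[match(unique(countsTable$well_id), out$well_id), , drop = FALSE]
}
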