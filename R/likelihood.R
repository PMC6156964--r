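## Monte-Carlo approximate composite likelihood of a bSFS table.
##
## The probability of a blockwise configuration k given an ARG's class
## lengths t is a product over mutation classes of Poisson probabilities
## with rate theta * t_i; classes with t_i = 0 contribute 1 when k_i = 0 and
## annihilate the product otherwise (the zero-branch convention). Lumped
## "> k_max" entries use the upper Poisson tail so that probabilities over a
## lumped enumeration sum to one. The approximate probability of k under the
## model is the arithmetic mean of these products over sampled ARGs, and the
## composite log-likelihood weights each configuration's log-probability by
## its block count.

#' Settings for Monte-Carlo likelihood evaluation
#'
#' @param numArgs number of ARGs sampled per evaluation.
#' @param seed optional integer seed for the draws.
#' @param reuseDraws logical; when TRUE the same seed (hence the same ARG
#'   draws) is used at every evaluation -- common random numbers, useful for
#'   variance-reduced optimization. Default FALSE: fresh draws each call.
#' @param floor probability assigned to configurations observed in the data
#'   but given zero Monte-Carlo mass; default \code{1/(10 * numArgs)}.
#' @return A list of settings.
#' @export
likelihoodSettings <- function(numArgs = 1000, seed = NULL,
                               reuseDraws = FALSE, floor = NULL) {
  stopifnot(numArgs >= 1)
  if (is.null(floor)) floor <- 1 / (10 * numArgs)
  stopifnot(floor > 0, floor < 1)
  list(numArgs = as.integer(numArgs), seed = seed,
       reuseDraws = isTRUE(reuseDraws), floor = floor)
}

.kernelKmax <- function(kmax) if (is.na(kmax)) -1L else as.integer(kmax)

#' Configuration probability given fixed branch-class lengths
#'
#' The product over mutation classes of Poisson probabilities
#' \eqn{p(k_i | \theta t_i)}; entries of \code{-1} in \code{k} denote the
#' lumped \dQuote{more than kmax} class and take the upper tail mass.
#'
#' @param k integer vector of per-class mutation counts (\code{-1} lumped).
#' @param t numeric vector of class lengths (an ARG summary).
#' @param theta block-scaled mutation rate.
#' @param kmax lumping cap (needed only when \code{k} has lumped entries).
#' @return The probability.
#' @examples
#' configProbGivenLengths(0, 2, theta = 1)  # exp(-2)
#' @export
configProbGivenLengths <- function(k, t, theta, kmax = NA) {
  stopifnot(length(k) == length(t), theta >= 0)
  .bsfsProbKernel(matrix(as.numeric(t), 1), matrix(as.integer(k), 1),
                  theta, .kernelKmax(kmax))[1]
}

#' Approximate configuration probabilities and composite log-likelihood
#'
#' Samples ARGs under the model and averages, per configuration in the
#' table, the Poisson-product probability over the draws; every draw
#' contributes to every configuration. Configurations left with zero
#' Monte-Carlo mass are floored at \code{settings$floor} and counted. The
#' composite log-likelihood is
#' \eqn{\sum_j n_{k_j} \log \hat p(k_j)}.
#'
#' @param table a \code{\link{bsfsTable}}.
#' @param model a \code{\link{demographicModel}} for the table's layout.
#' @param settings a \code{\link{likelihoodSettings}}.
#' @param draws optional precomputed class-length matrix from
#'   \code{\link{sampleArgs}} (bypasses sampling; used for fixed-genealogy
#'   checks and common-random-number schemes).
#' @return List of class \code{"likelihoodResult"}: \code{loglik},
#'   \code{perConfig}, \code{zeroMassConfigs}, \code{argsUsed},
#'   \code{thetaBlock}.
#' @export
approximateConfigProbs <- function(table, model, settings =
                                     likelihoodSettings(), draws = NULL) {
  layout <- tableLayout(table)
  if (is.null(draws)) {
    ## with reuseDraws the stored seed makes every evaluation see the same
    ## ARGs (common random numbers); otherwise the caller's RNG stream (or a
    ## one-off seed) governs the draws
    draws <- sampleArgs(model, layout, settings$numArgs,
                        seed = settings$seed)
  } else if (ncol(draws) != numSiteTypes(layout)) {
    stop("draws have ", ncol(draws), " class columns but the table layout ",
         "defines ", numSiteTypes(layout))
  }
  theta <- attr(draws, "thetaBlock")
  if (is.null(theta))
    theta <- 4 * referenceSize(model) * mutationRate(model) *
      effectiveLength(layout)
  K <- configMatrix(table)
  p <- .bsfsProbKernel(draws, K, theta, .kernelKmax(kMax(table)))
  zero <- p == 0
  p[zero] <- settings$floor
  res <- list(loglik = sum(table@counts * log(p)),
              perConfig = setNames(p, .configLabels(K)),
              zeroMassConfigs = sum(zero & table@counts > 0),
              argsUsed = nrow(draws), thetaBlock = theta)
  class(res) <- "likelihoodResult"
  res
}

#' @export
print.likelihoodResult <- function(x, ...) {
  cat("Composite log-likelihood:", x$loglik, "\n")
  cat("  configurations:", length(x$perConfig),
      " ARGs:", x$argsUsed, " theta_block:", signif(x$thetaBlock, 5), "\n")
  if (x$zeroMassConfigs > 0)
    cat("  WARNING:", x$zeroMassConfigs,
        "observed configuration(s) had zero Monte-Carlo mass (floored)\n")
  invisible(x)
}

#' Composite log-likelihood of a bSFS table under a model
#'
#' Convenience wrapper around \code{\link{approximateConfigProbs}} returning
#' the scalar composite log-likelihood.
#'
#' @inheritParams approximateConfigProbs
#' @return Numeric log-likelihood.
#' @export
blockLoglik <- function(table, model, settings = likelihoodSettings()) {
  approximateConfigProbs(table, model, settings)$loglik
}

#' Probabilities over a lumped enumeration given fixed class lengths
#'
#' For a single ARG summary (or matrix of summaries, averaged), the
#' probabilities over the full lumped configuration enumeration. These sum
#' to one exactly for each single ARG, and hence for the average.
#'
#' @param t class-length vector or matrix of draws (columns = classes).
#' @param layout a \code{\link{sampleLayout}}.
#' @param kmax per-class lumping cap.
#' @param theta block-scaled mutation rate.
#' @param noRecombination passed to \code{\link{enumerateConfigurations}}.
#' @return Named probability vector over the enumeration.
#' @export
lumpedProbsGivenLengths <- function(t, layout, kmax, theta,
                                    noRecombination = FALSE) {
  if (is.null(dim(t))) t <- matrix(t, 1)
  enum <- enumerateConfigurations(layout, kmax, noRecombination)
  K <- configMatrix(enum)
  setNames(.bsfsProbKernel(t, K, theta, as.integer(kmax)),
           .configLabels(K))
}

#' Exhaustive lumped probabilities under a model
#'
#' Monte-Carlo average of \code{\link{lumpedProbsGivenLengths}} over sampled
#' ARGs: the approximated bSFS over the full lumped enumeration, summing to
#' one.
#'
#' @param model a \code{\link{demographicModel}}.
#' @param layout a \code{\link{sampleLayout}}.
#' @param kmax per-class lumping cap.
#' @param settings a \code{\link{likelihoodSettings}}.
#' @param noRecombination exclude single-genealogy-incompatible
#'   configurations from the enumeration.
#' @return Named probability vector.
#' @export
exhaustiveLumpedProbs <- function(model, layout, kmax,
                                  settings = likelihoodSettings(),
                                  noRecombination = FALSE) {
  draws <- sampleArgs(model, layout, settings$numArgs,
                      seed = settings$seed)
  lumpedProbsGivenLengths(draws, layout, kmax, attr(draws, "thetaBlock"),
                          noRecombination)
}

#' Watterson's theta per population from a bSFS table
#'
#' The mean per-block count of sites segregating within each population
#' divided by the harmonic number \eqn{a_{b_x}}; used to seed search bounds
#' on population sizes.
#'
#' @param table a \code{\link{bsfsTable}}.
#' @return Numeric vector, per-block Watterson's theta per population.
#' @export
wattersonTheta <- function(table) {
  layout <- tableLayout(table)
  b <- sampleSizes(layout)
  classes <- mutationClasses(layout)
  K <- configMatrix(table)
  km <- kMax(table)
  Kc <- K
  if (any(Kc < 0)) Kc[Kc < 0] <- km + 1 # lumped entries: lower bound
  vapply(seq_along(b), function(x) {
    seg <- classes[, x] > 0 & classes[, x] < b[x]
    if (!isPolarized(layout)) {
      comp <- sweep(-classes, 2, b, "+") # complements also realize the class
      seg <- seg | (comp[, x] > 0 & comp[, x] < b[x])
    }
    S <- sum(table@counts * (Kc[, seg, drop = FALSE] %*% rep(1, sum(seg))))
    S / totalBlocks(table) / sum(1 / seq_len(b[x] - 1))
  }, 0)
}
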