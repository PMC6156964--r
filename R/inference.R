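## Two-stage noisy maximum composite likelihood search: a population-based
## controlled random search within broad bounds, followed by replicated
## simplex (Nelder-Mead) refinements inside bounds narrowed around the
## global-stage bests. Gradients are never used: the Monte-Carlo likelihood
## surface is noisy, so only direct-search methods are reliable.

#' Specification of one search stage
#'
#' @param stage \code{"global"} or \code{"local"}.
#' @param argsPerEval ARGs sampled per likelihood evaluation at this stage.
#' @param replicates independent restarts.
#' @param evalBudget maximum likelihood evaluations per replicate.
#' @param reltol relative parameter movement below which a replicate stops.
#' @param logliktol log-likelihood movement below which a replicate stops.
#' @param reuseDraws use common random numbers within a replicate (the same
#'   ARG draws at every evaluation), making the stage's surface
#'   deterministic; fresh draws are taken between replicates.
#' @param seed integer seed for the stage.
#' @return A list of class \code{"searchSpec"}.
#' @export
searchSpec <- function(stage = c("global", "local"), argsPerEval = 1000,
                       replicates = 3, evalBudget = 200 , reltol = 1e-3,
                       logliktol = 0.5, reuseDraws = TRUE, seed = 1) {
  stage <- match.arg(stage)
  stopifnot(argsPerEval >= 1, replicates >= 1, evalBudget >= 2)
  structure(list(stage = stage, argsPerEval = as.integer(argsPerEval),
                 replicates = as.integer(replicates),
                 evalBudget = as.integer(evalBudget), reltol = reltol,
                 logliktol = logliktol, reuseDraws = isTRUE(reuseDraws),
                 seed = as.integer(seed)),
            class = "searchSpec")
}

## transform free parameters to the search scale (log for positive
## parameters, linear for signed ones)
.toSearch <- function(p, map) ifelse(map@logScale, log(p), p)
.fromSearch <- function(z, map) {
  p <- ifelse(map@logScale, exp(z), z)
  names(p) <- map@names
  p
}

.makeObjective <- function(table, template, map, argsPerEval, reuseDraws,
                           evalSeed, objective = NULL) {
  if (!is.null(objective)) {
    return(function(p) {
      m <- buildModel(p, map, template)
      if (isInfeasible(m)) -Inf else objective(freeParameters(m))
    })
  }
  settings <- likelihoodSettings(argsPerEval,
                                 seed = if (reuseDraws) evalSeed else NULL)
  function(p) {
    m <- buildModel(p, map, template)
    if (isInfeasible(m)) return(-Inf)
    approximateConfigProbs(table, m, settings)$loglik
  }
}

.resultFromTrace <- function(trace, map, finalArgs) {
  best <- trace[which.max(trace$loglik), , drop = FALSE]
  bp <- as.numeric(best[map@names])
  names(bp) <- map@names
  structure(list(bestParams = bp, bestLoglik = best$loglik, trace = trace,
                 finalArgs = finalArgs), class = "searchResult")
}

#' @export
print.searchResult <- function(x, ...) {
  cat("Maximum composite likelihood estimate (", nrow(x$trace),
      " replicate(s), final ARGs per evaluation ", x$finalArgs, ")\n",
      sep = "")
  print(signif(x$bestParams, 5))
  cat("log-likelihood:", x$bestLoglik, "\n")
  invisible(x)
}

## controlled random search (CRS2 with local mutation) maximizing fn over a
## box in transformed space; fn returns -Inf at infeasible points
.crs <- function(fn, lower, upper, budget, reltol, logliktol) {
  d <- length(lower)
  npop <- max(10 * (d + 1), 20)
  P <- matrix(0, npop, d)
  for (j in seq_len(d)) P[, j] <- runif(npop, lower[j], upper[j])
  f <- apply(P, 1, fn)
  used <- npop
  if (all(!is.finite(f)))
    stop("every point evaluated in the global stage was infeasible; ",
         "check the parameter bounds and ordering constraints")
  while (used < budget) {
    ix <- sample.int(npop, d + 1)
    simplex <- P[ix, , drop = FALSE]
    centroid <- colMeans(simplex[-(d + 1), , drop = FALSE])
    trial <- 2 * centroid - simplex[d + 1, ]
    worst <- which.min(f)
    if (all(trial >= lower & trial <= upper)) {
      ft <- fn(trial); used <- used + 1
      if (is.finite(ft) && ft > f[worst]) {
        P[worst, ] <- trial; f[worst] <- ft
      } else {
        ## local mutation: contract towards the current best point
        bestIx <- which.max(f)
        mut <- P[bestIx, ] + runif(d) * (trial - P[bestIx, ]) / 2
        mut <- pmin(pmax(mut, lower), upper)
        fm <- fn(mut); used <- used + 1
        if (is.finite(fm) && fm > f[worst]) { P[worst, ] <- mut; f[worst] <- fm }
      }
    }
    fin <- f[is.finite(f)]
    spread <- apply(P[is.finite(f), , drop = FALSE], 2,
                    function(z) diff(range(z)))
    if (length(fin) == npop &&
        max(fin) - min(fin) < logliktol &&
        all(spread < reltol * pmax(abs(upper - lower), 1e-12))) break
  }
  best <- which.max(f)
  list(par = P[best, ], value = f[best], evaluations = used)
}

#' Global stage: population-based controlled random search
#'
#' Runs \code{spec$replicates} independent controlled-random-search
#' maximizations of the Monte-Carlo composite likelihood within the map's
#' bounds (positive parameters are searched on log scale). Infeasible
#' points (outside bounds or violating ordering constraints) are rejected
#' without stopping the search.
#'
#' @param table a \code{\link{bsfsTable}}.
#' @param template,map a model template and \code{\link{parameterMap}}
#'   (e.g. from \code{\link{modelTemplate}}).
#' @param spec a \code{\link{searchSpec}} with \code{stage = "global"}.
#' @param objective optional replacement objective
#'   \code{function(namedParams) -> loglik} (for surrogate and diagnostic
#'   runs); infeasible points are still rejected first.
#' @return A \code{"searchResult"}: \code{bestParams}, \code{bestLoglik},
#'   per-replicate \code{trace}, and \code{finalArgs}.
#' @export
globalSearch <- function(table, template, map, spec, objective = NULL) {
  stopifnot(spec$stage == "global")
  lower <- .toSearch(map@lower, map)
  upper <- .toSearch(map@upper, map)
  rows <- withr::with_seed(spec$seed, lapply(seq_len(spec$replicates),
    function(rep) {
      fn <- .makeObjective(table, template, map, spec$argsPerEval,
                           spec$reuseDraws, evalSeed = spec$seed + 7919L * rep,
                           objective = objective)
      r <- .crs(function(z) fn(.fromSearch(z, map)), lower, upper,
                spec$evalBudget, spec$reltol, spec$logliktol)
      c(as.list(.fromSearch(r$par, map)), loglik = r$value,
        evaluations = r$evaluations, replicate = rep)
    }))
  trace <- do.call(rbind, lapply(rows, as.data.frame))
  .resultFromTrace(trace, map, spec$argsPerEval)
}

#' Local stage: replicated simplex refinement
#'
#' Nelder-Mead refinements (in transformed space) from random start points
#' inside \code{startBox}, with infeasible points penalized. Intended to run
#' inside bounds narrowed around the global-stage bests.
#'
#' @inheritParams globalSearch
#' @param spec a \code{\link{searchSpec}} with \code{stage = "local"}.
#' @param startBox list with \code{lower}, \code{upper} (natural scale)
#'   bounding the start points; defaults to the map bounds. A box collapsed
#'   to a point evaluates that point.
#' @return A \code{"searchResult"}.
#' @export
localSearch <- function(table, template, map, spec, startBox = NULL,
                        objective = NULL) {
  stopifnot(spec$stage == "local")
  if (is.null(startBox)) startBox <- list(lower = map@lower,
                                          upper = map@upper)
  lo <- .toSearch(pmax(startBox$lower, map@lower), map)
  hi <- .toSearch(pmin(startBox$upper, map@upper), map)
  rows <- withr::with_seed(spec$seed, lapply(seq_len(spec$replicates),
    function(rep) {
      fn <- .makeObjective(table, template, map, spec$argsPerEval,
                           spec$reuseDraws, evalSeed = spec$seed + 104729L * rep,
                           objective = objective)
      z0 <- runif(length(lo), lo, hi)
      neg <- function(z) {
        v <- fn(.fromSearch(z, map))
        if (!is.finite(v)) 1e12 else -v
      }
      if (all(hi - lo < 1e-12)) {
        z <- lo
        val <- -neg(z)
        ev <- 1L
      } else if (length(lo) == 1) {
        opt <- stats::optim(z0, neg, method = "Brent",
                            lower = .toSearch(map@lower, map),
                            upper = .toSearch(map@upper, map),
                            control = list(maxit = spec$evalBudget))
        z <- opt$par; val <- -opt$value; ev <- opt$counts[1]
      } else {
        opt <- stats::optim(z0, neg, method = "Nelder-Mead",
                            control = list(maxit = spec$evalBudget,
                                           reltol = 1e-8))
        z <- opt$par; val <- -opt$value; ev <- opt$counts[1]
      }
      c(as.list(.fromSearch(z, map)), loglik = val,
        evaluations = unname(ev), replicate = rep)
    }))
  trace <- do.call(rbind, lapply(rows, as.data.frame))
  .resultFromTrace(trace, map, spec$argsPerEval)
}

## bounds narrowed to the envelope of replicate bests, expanded 25% in log
## space for log-scale parameters and by 25% of the span otherwise
.narrowBounds <- function(trace, map) {
  lo <- up <- numeric(length(map@names))
  for (i in seq_along(map@names)) {
    v <- trace[[map@names[i]]]
    if (map@logScale[i]) {
      r <- range(log(v))
      pad <- 0.25 * max(diff(r), 0.1)
      lo[i] <- max(exp(r[1] - pad), map@lower[i])
      up[i] <- min(exp(r[2] + pad), map@upper[i])
    } else {
      r <- range(v)
      pad <- 0.25 * max(diff(r), 1e-3 * (map@upper[i] - map@lower[i]))
      lo[i] <- max(r[1] - pad, map@lower[i])
      up[i] <- min(r[2] + pad, map@upper[i])
    }
  }
  list(lower = lo, upper = up)
}

#' Two-stage maximum composite likelihood search
#'
#' Chains a global controlled-random-search stage and a local simplex stage,
#' narrowing the parameter bounds between them to the envelope of the
#' global replicate bests (expanded by 25 percent in log space for positive
#' parameters), then re-evaluates the best point at \code{finalArgs} ARGs.
#' When the local replicates disagree by more than the stage's
#' log-likelihood tolerance a second local round is run inside a box
#' narrowed around the local bests.
#'
#' @inheritParams globalSearch
#' @param schedule list of \code{\link{searchSpec}}s, global stages before
#'   local ones; defaults to a two-stage schedule scaled by \code{scale}.
#' @param scale multiplier applied to the default ARGs-per-evaluation
#'   schedule (50,000 global / 500,000 local / 1,000,000 final).
#' @param finalArgs ARGs used for the final re-evaluation.
#' @param seed integer seed.
#' @param secondRound allow a second local round on disagreement.
#' @return A \code{"searchResult"} with provenance (\code{stages}).
#' @export
fit <- function(table, template, map = NULL, schedule = NULL, scale = 1,
                finalArgs = NULL, seed = 1, objective = NULL,
                secondRound = TRUE) {
  if (is.null(map) && is.list(template) && !is.null(template$map)) {
    map <- template$map
    template <- template$template
  }
  if (is.null(schedule)) {
    schedule <- list(
      searchSpec("global", argsPerEval = max(1, ceiling(50000 * scale)),
                 replicates = 10, evalBudget = 120 * length(map@names),
                 seed = seed),
      searchSpec("local", argsPerEval = max(1, ceiling(500000 * scale)),
                 replicates = 20, evalBudget = 200 * length(map@names),
                 seed = seed + 1L))
  }
  if (is.null(finalArgs))
    finalArgs <- max(1, ceiling(1e6 * scale))
  stopifnot(length(schedule) >= 1)
  stages <- list()
  box <- list(lower = map@lower, upper = map@upper)
  res <- NULL
  for (s in schedule) {
    if (s$stage == "global") {
      res <- globalSearch(table, template, map, s, objective = objective)
    } else {
      res <- localSearch(table, template, map, s, startBox = box,
                         objective = objective)
      spread <- diff(range(res$trace$loglik))
      if (secondRound && nrow(res$trace) > 1 && spread > s$logliktol) {
        box2 <- .narrowBounds(res$trace[order(-res$trace$loglik), ][
          seq_len(max(2, ceiling(nrow(res$trace) / 2))), ], map)
        s2 <- s; s2$seed <- s$seed + 555L
        res2 <- localSearch(table, template, map, s2, startBox = box2,
                            objective = objective)
        if (res2$bestLoglik > res$bestLoglik) res <- res2
        stages[[length(stages) + 1]] <- res2
      }
    }
    stages[[length(stages) + 1]] <- res
    box <- .narrowBounds(res$trace, map)
  }
  ## final re-evaluation of the best point at the stated ARG count
  best <- res$bestParams
  finalLoglik <- res$bestLoglik
  if (is.null(objective)) {
    m <- buildModel(best, map, template)
    finalLoglik <- withr::with_seed(seed + 999L,
      approximateConfigProbs(table, m,
        likelihoodSettings(finalArgs))$loglik)
  }
  structure(list(bestParams = best, bestLoglik = finalLoglik,
                 trace = res$trace, finalArgs = finalArgs,
                 stages = stages, seed = seed),
            class = "searchResult")
}

#' Seed size bounds from Watterson's theta
#'
#' Suggests an upper bound for effective population sizes from the
#' per-population Watterson's theta of a table:
#' \eqn{N \le \theta_W / (4 \mu E)} times a slack factor. Never applied
#' silently; callers pass the result to their own
#' \code{\link{parameterMap}}.
#'
#' @param table a \code{\link{bsfsTable}}.
#' @param mu per-site mutation rate.
#' @param slack multiplicative slack on the bound.
#' @return Named numeric vector of suggested per-population upper bounds.
#' @export
wattersonSizeBound <- function(table, mu = 2e-8, slack = 5) {
  thw <- wattersonTheta(table)
  E <- effectiveLength(tableLayout(table))
  setNames(slack * thw / (4 * mu * E),
           paste0("pop", seq_along(thw)))
}
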