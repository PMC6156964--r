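## Blockwise simulation with known truth: unlinked blocks for power
## studies, contiguous stretches cut into consecutive blocks for the
## parametric bootstrap (which deliberately induces the between-block
## correlation the composite likelihood ignores), and the experiment
## drivers built on them.

#' Specification of a blockwise simulation
#'
#' @param model the true \code{\link{demographicModel}}.
#' @param layout a \code{\link{sampleLayout}}.
#' @param numBlocks number of blocks to simulate.
#' @param linkage \code{"unlinked"} (one independent ARG per block) or
#'   \code{"stretches"} (one ARG per contiguous stretch, cut into
#'   consecutive blocks).
#' @param stretchLength stretch length in bp, a multiple of the block
#'   length (\code{"stretches"} only).
#' @param seed integer seed.
#' @return A list of class \code{"simulationSpec"}.
#' @export
simulationSpec <- function(model, layout, numBlocks,
                           linkage = c("unlinked", "stretches"),
                           stretchLength = NULL, seed = 1) {
  linkage <- match.arg(linkage)
  stopifnot(numBlocks >= 1)
  if (linkage == "stretches") {
    if (is.null(stretchLength))
      stop("stretches linkage needs a stretchLength")
    if (stretchLength %% blockLength(layout) != 0)
      stop("stretchLength must be a multiple of the block length")
  }
  structure(list(model = model, layout = layout,
                 numBlocks = as.integer(numBlocks), linkage = linkage,
                 stretchLength = stretchLength, seed = as.integer(seed)),
            class = "simulationSpec")
}

## per-block class-length draws under the spec (rows = blocks, unfolded
## classes); stretches are simulated as one ARG over the stretch
.simulateClassLengths <- function(spec) {
  layout <- spec$layout
  model <- spec$model
  sc <- .scaledArgs(model, layout)
  X <- length(sc$sizeRel)
  if (spec$linkage == "unlinked") {
    res <- .simArgs(sampleSizes(layout), sc$sizeRel, sc$growthScaled,
                    matrix(0, X, X), sc$events, sc$rhoBlock, c(0, 1),
                    spec$numBlocks, 0L)
    res$tA
  } else {
    nb <- as.integer(spec$stretchLength / blockLength(layout))
    nstretch <- ceiling(spec$numBlocks / nb)
    rhoStretch <- 4 * referenceSize(model) * recombinationRate(model) *
      (spec$stretchLength - 1)
    res <- .simArgs(sampleSizes(layout), sc$sizeRel, sc$growthScaled,
                    matrix(0, X, X), sc$events, rhoStretch,
                    seq(0, 1, length.out = nb + 1), nstretch, 0L)
    res$tA[seq_len(spec$numBlocks), , drop = FALSE]
  }
}

#' Simulate a blockwise dataset under a known model
#'
#' Samples per-block ARGs under the model (independently per block, or one
#' ARG per contiguous stretch cut into consecutive blocks) and drops
#' mutations on them as a Poisson process under infinite sites.
#' \code{output = "table"} returns the bSFS directly;
#' \code{output = "records"} returns per-block 0/1 site-by-genome matrices
#' (positions drawn uniformly over the callable bases, distinct within a
#' block) suitable for \code{\link{tabulateBlocks}} and
#' \code{\link{buildCbsfs}}.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @param output \code{"table"} or \code{"records"}.
#' @param kmax optional per-class cap for the returned table.
#' @return A \code{\link{bsfsTable}}, or a list with elements \code{blocks}
#'   and \code{layout}.
#' @export
simulateDataset <- function(spec, output = c("table", "records"),
                            kmax = NA) {
  output <- match.arg(output)
  layout <- spec$layout
  theta <- 4 * referenceSize(spec$model) * mutationRate(spec$model) *
    effectiveLength(layout)
  if (output == "table") {
    return(withr::with_seed(spec$seed, {
      T <- .foldLengths(.simulateClassLengths(spec), layout)
      C <- ncol(T)
      kmat <- matrix(rpois(length(T), theta * T), nrow(T), C)
      if (!is.na(kmax)) kmat[kmat > kmax] <- -1L
      .tallyConfigs(kmat, layout, kmax)
    }))
  }
  withr::with_seed(spec$seed, .simulateRecords(spec, theta))
}

.simulateRecords <- function(spec, theta) {
  layout <- spec$layout
  model <- spec$model
  sc <- .scaledArgs(model, layout)
  X <- length(sc$sizeRel)
  nsam <- sum(sampleSizes(layout))
  E <- effectiveLength(layout)
  if (spec$linkage == "unlinked") {
    nb <- 1L
    nreps <- spec$numBlocks
    rho <- sc$rhoBlock
  } else {
    nb <- as.integer(spec$stretchLength / blockLength(layout))
    nreps <- as.integer(ceiling(spec$numBlocks / nb))
    rho <- 4 * referenceSize(model) * recombinationRate(model) *
      (spec$stretchLength - 1)
  }
  res <- .simArgs(sampleSizes(layout), sc$sizeRel, sc$growthScaled,
                  matrix(0, X, X), sc$events, rho, c(0, 1), nreps, 2L)
  blocks <- vector("list", spec$numBlocks)
  for (rep in seq_len(nreps)) {
    rec <- res$detail[[rep]]
    if (!nrow(rec)) next
    ## expected mutations per record: theta_block * branch length * the
    ## fraction of the simulated unit (block or stretch) it covers
    lam <- theta * rec[, "len"] * (rec[, "b"] - rec[, "a"]) * nb
    nm <- rpois(length(lam), lam)
    tot <- sum(nm)
    if (!tot) next
    masks <- rep(rec[, "mask"], nm)
    ## site position: which block within the stretch, uniform over extent
    u <- runif(tot, rep(rec[, "a"], nm), rep(rec[, "b"], nm))
    blkIdx <- pmin(floor(u * nb), nb - 1) + (rep - 1L) * nb + 1L
    for (bl in unique(blkIdx)) {
      if (bl > spec$numBlocks) next
      mk <- masks[blkIdx == bl]
      n <- length(mk)
      if (n > E) stop("more mutations than callable sites in block ", bl,
                      "; infinite sites cannot be honoured")
      pos <- sort(sample.int(E, n))
      g <- matrix(0L, n, nsam)
      for (s in seq_len(n))
        g[s, ] <- as.integer(floor(mk[s] / 2^(seq_len(nsam) - 1)) %% 2)
      attr(g, "positions") <- pos
      blocks[[bl]] <- g
    }
  }
  list(blocks = blocks, layout = layout)
}

#' Parametric bootstrap around a fitted point
#'
#' Simulates replicate datasets at the fitted parameter values, re-fits each
#' with a local search started inside a box around the fitted point, and
#' summarizes the spread: per-parameter standard deviation (n-1 denominator)
#' and the MCLE plus/minus two standard deviations interval.
#'
#' @param params named fitted parameter vector (the MCLE).
#' @param template,map model template and \code{\link{parameterMap}} (or a
#'   \code{\link{modelTemplate}} list as \code{template}).
#' @param layout a \code{\link{sampleLayout}}.
#' @param numBlocks blocks per replicate dataset.
#' @param replicates bootstrap replicates (>= 2).
#' @param localSpec a \code{\link{searchSpec}} with \code{stage = "local"}.
#' @param linkage,stretchLength passed to \code{\link{simulationSpec}};
#'   stretch linkage reproduces the conservative fully linked design.
#' @param startBox start box for the local searches; defaults to the fitted
#'   point expanded by 50 percent in log space (or of the bound span for
#'   linear parameters).
#' @param seed integer seed; per-replicate seeds are derived from it and
#'   recorded.
#' @param objective optional surrogate objective (see
#'   \code{\link{globalSearch}}).
#' @return A list of class \code{"bootstrapResult"}: \code{estimates} (one
#'   row per replicate), \code{sd}, \code{ci} (rows lower/upper),
#'   \code{center}, \code{seeds}.
#' @export
parametricBootstrap <- function(params, template, map = NULL, layout,
                                numBlocks, replicates, localSpec,
                                linkage = "unlinked", stretchLength = NULL,
                                startBox = NULL, seed = 1,
                                objective = NULL) {
  stopifnot(replicates >= 2)
  if (is.null(map) && is.list(template) && !is.null(template$map)) {
    map <- template$map
    template <- template$template
  }
  if (is.null(startBox)) {
    pad <- ifelse(map@logScale, 0.5, 0.25 * (map@upper - map@lower))
    lo <- ifelse(map@logScale, params * exp(-pad), params - pad)
    hi <- ifelse(map@logScale, params * exp(pad), params + pad)
    startBox <- list(lower = pmax(lo, map@lower),
                     upper = pmin(hi, map@upper))
  }
  seeds <- seed + 1000L * seq_len(replicates)
  est <- matrix(NA_real_, replicates, length(map@names),
                dimnames = list(NULL, map@names))
  for (r in seq_len(replicates)) {
    model <- buildModel(params, map, template)
    if (isInfeasible(model)) stop("fitted point is infeasible: ",
                                  model$message)
    tab <- if (is.null(objective)) {
      simulateDataset(simulationSpec(model, layout, numBlocks,
                                     linkage = linkage,
                                     stretchLength = stretchLength,
                                     seed = seeds[r]))
    } else NULL
    spec_r <- localSpec
    spec_r$seed <- seeds[r] + 1L
    res <- localSearch(tab, template, map, spec_r, startBox = startBox,
                       objective = objective)
    est[r, ] <- res$bestParams
  }
  sds <- apply(est, 2, sd)
  ci <- rbind(lower = params[map@names] - 2 * sds,
              upper = params[map@names] + 2 * sds)
  structure(list(estimates = as.data.frame(est), sd = sds, ci = ci,
                 center = params[map@names], seeds = seeds,
                 replicates = replicates),
            class = "bootstrapResult")
}

#' @export
print.bootstrapResult <- function(x, ...) {
  cat("Parametric bootstrap,", x$replicates, "replicate(s)\n")
  out <- rbind(MCLE = x$center, SD = x$sd, x$ci)
  print(signif(out, 4))
  invisible(x)
}

#' Nested-model misspecification experiment
#'
#' Simulates datasets under each true model and evaluates the composite
#' log-likelihood under each candidate model, either at supplied parameter
#' values (point evaluation, including \dQuote{R-variant} candidates whose
#' split time is replaced by the true admixture time) or by a full
#' \code{\link{fit}}.
#'
#' @param trueModels named list; each element a list with \code{template}
#'   (a \code{\link{modelTemplate}} list) and \code{params} (named truth).
#' @param fitModels named list; each element a list with \code{template}
#'   and either \code{params} (point evaluation) or \code{schedule}
#'   (fitting).
#' @param datasetsPerModel simulated datasets per true model.
#' @param layout a \code{\link{sampleLayout}}.
#' @param numBlocks blocks per dataset.
#' @param settings \code{\link{likelihoodSettings}} for point evaluations.
#' @param seed integer seed.
#' @return data.frame with columns \code{true}, \code{candidate},
#'   \code{dataset}, \code{loglik}.
#' @export
misspecificationExperiment <- function(trueModels, fitModels,
                                       datasetsPerModel, layout, numBlocks,
                                       settings = likelihoodSettings(),
                                       seed = 1) {
  rows <- list()
  for (tn in names(trueModels)) {
    tm <- trueModels[[tn]]
    truth <- buildModel(tm$params, tm$template$map, tm$template$template)
    if (isInfeasible(truth)) stop("true model '", tn, "' infeasible")
    for (d in seq_len(datasetsPerModel)) {
      dseed <- seed + 100000L * match(tn, names(trueModels)) + d
      tab <- simulateDataset(simulationSpec(truth, layout, numBlocks,
                                            seed = dseed))
      for (fn in names(fitModels)) {
        fm <- fitModels[[fn]]
        ll <- if (!is.null(fm$params)) {
          cand <- buildModel(fm$params, fm$template$map,
                             fm$template$template)
          if (isInfeasible(cand)) NA_real_ else withr::with_seed(
            dseed + 17L, blockLoglik(tab, cand, settings))
        } else {
          fit(tab, fm$template, schedule = fm$schedule,
              seed = dseed + 31L)$bestLoglik
        }
        rows[[length(rows) + 1]] <- data.frame(
          true = tn, candidate = fn, dataset = d, loglik = ll)
      }
    }
  }
  do.call(rbind, rows)
}
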