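## Sampling blockwise ARGs and reducing them to branch lengths per
## joint-SFS mutation class -- the only genealogical information the
## composite likelihood needs.

.scaledArgs <- function(model, layout) {
  sc <- toScaledUnits(model, blockLength(layout), effectiveLength(layout))
  X <- length(sc$sizeRel)
  if (length(sampleSizes(layout)) > X)
    stop("layout samples more populations than the model declares")
  sc
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Sample blockwise ARGs reduced to mutation-class branch lengths
#'
#' Draws \code{count} independent blockwise ancestral recombination graphs
#' under the model and returns, for each, the span-weighted average total
#' branch length per mutation class,
#' \eqn{t_{i,A} = (1/L) \sum_p w_p t_{i,p}}, in units of
#' \code{4 * referenceSize} generations. With a block-scaled recombination
#' rate of zero every ARG is a single genealogy spanning the block.
#'
#' @param model a \code{\link{demographicModel}}.
#' @param layout a \code{\link{sampleLayout}}; class columns are folded when
#'   the layout is unpolarized.
#' @param count number of ARGs to draw.
#' @param seed optional integer seed (draws are reproducible given it).
#' @param singleTree if TRUE, assert that the model has no recombination and
#'   sample plain single genealogies (the rho = 0 path).
#' @return Numeric matrix (\code{count} rows, one column per mutation class,
#'   labelled) with attributes \code{"thetaBlock"} and \code{"rhoBlock"}.
#' @examples
#' m <- imModel(T = 1.2, M = 0.5)
#' t <- sampleArgs(m, sampleLayout(c(2, 2)), count = 100, seed = 1)
#' colMeans(t)
#' @export
sampleArgs <- function(model, layout, count, seed = NULL,
                       singleTree = FALSE) {
  sc <- .scaledArgs(model, layout)
  rho <- sc$rhoBlock
  if (singleTree && rho > 0)
    stop("single-tree sampling requires a recombination rate of zero")
  X <- length(sc$sizeRel)
  res <- .withSeed(seed, tryCatch(
    .simArgs(sampleSizes(layout), sc$sizeRel, sc$growthScaled,
             matrix(0, X, X), sc$events, rho, c(0, 1), as.integer(count),
             0L),
    error = function(e) {
      stop("ARG simulation failed: ", conditionMessage(e),
           "\nscaled event list:\n",
           paste(utils::capture.output(print(sc$events)), collapse = "\n"),
           call. = FALSE)
    }))
  t <- .foldLengths(res$tA, layout)
  colnames(t) <- rownames(mutationClasses(layout))
  attr(t, "thetaBlock") <- sc$thetaBlock
  attr(t, "rhoBlock") <- sc$rhoBlock
  t
}

#' Sample ARGs with per-marginal-segment detail
#'
#' Like \code{\link{sampleArgs}} but returns, for every replicate, the
#' recombination breakpoints, per-segment spans (bp) and the class-length
#' matrix of every marginal genealogy, plus the raw branch records
#' (genomic interval, genome mask, length) for independent recounts.
#'
#' @inheritParams sampleArgs
#' @return List of length \code{count}; each element has \code{spans},
#'   \code{classLengths} (segments x classes), \code{breakpoints} (bp) and
#'   \code{records}.
#' @export
sampleMarginals <- function(model, layout, count, seed = NULL) {
  sc <- .scaledArgs(model, layout)
  X <- length(sc$sizeRel)
  res <- .withSeed(seed,
    .simArgs(sampleSizes(layout), sc$sizeRel, sc$growthScaled,
             matrix(0, X, X), sc$events, sc$rhoBlock, c(0, 1),
             as.integer(count), 1L))
  L <- blockLength(layout)
  classes <- mutationClasses(layout)
  lapply(seq_len(count), function(rep) {
    det <- res$detail[[rep]]
    bounds <- c(0, det$breakpoints, 1)
    S <- length(bounds) - 1
    rec <- det$records
    unfC <- nrow(.unfoldedClassVectors(sampleSizes(layout)))
    seg <- matrix(0, S, unfC)
    if (nrow(rec)) {
      ci <- .maskClassIndex(rec[, "mask"], layout)
      mid <- (bounds[-1] + bounds[-length(bounds)]) / 2
      for (r in seq_len(nrow(rec))) {
        inside <- mid > rec[r, "a"] & mid < rec[r, "b"]
        seg[inside, ci[r]] <- seg[inside, ci[r]] + rec[r, "len"]
      }
    }
    segF <- .foldLengths(seg, layout)
    colnames(segF) <- rownames(classes)
    list(spans = diff(bounds) * L, classLengths = segF,
         breakpoints = det$breakpoints * L, records = rec)
  })
}

## unfolded class index of a genome bitmask (R-side mirror of the C++
## indexing; masks come back as doubles)
.maskClassIndex <- function(mask, layout) {
  b <- sampleSizes(layout)
  n <- sum(b)
  popOf <- rep(seq_along(b), b)
  w <- rev(cumprod(rev(c(b[-1] + 1, 1)))) # lex weights, i_1 most significant
  vapply(mask, function(m) {
    bits <- which(floor(m / 2^(seq_len(n) - 1)) %% 2 == 1)
    cnt <- tabulate(popOf[bits], length(b))
    ## mixed-radix lex code; the 1-based unfolded class index equals it
    as.integer(sum(cnt * w))
  }, 0L)
}

#' Span-weighted reduction of marginal genealogies to an ARG summary
#'
#' Computes \eqn{t_{i,A} = (1/L) \sum_p w_p t_{i,p}} from per-segment spans
#' and class lengths. The spans must tile the block exactly.
#'
#' @param spans segment spans in bp, summing to the block length.
#' @param classLengths matrix (segments x classes) of per-segment total
#'   branch length per mutation class.
#' @param layout a \code{\link{sampleLayout}}.
#' @return Named numeric vector of span-weighted average class lengths.
#' @examples
#' lay <- sampleLayout(2, blockLength = 1000)
#' reduceToClasses(c(600, 400), matrix(c(1, 2), 2, 1), lay)  # 1.4
#' @export
reduceToClasses <- function(spans, classLengths, layout) {
  if (!isTRUE(all.equal(sum(spans), blockLength(layout))))
    stop("segment spans sum to ", sum(spans), " but the block length is ",
         blockLength(layout))
  if (NROW(classLengths) != length(spans))
    stop("one row of class lengths per segment is required")
  out <- colSums(spans * classLengths) / blockLength(layout)
  if (!is.null(colnames(classLengths))) names(out) <- colnames(classLengths)
  out
}

#' Mutation classes present on an ARG
#'
#' Returns the set of mutation classes with positive branch length in an ARG
#' summary. For a non-recombining two-population sample of two genomes each,
#' a genealogy is incongruent with the population split exactly when the
#' shared-polymorphism class (one lineage from each population) is present.
#'
#' @param summary a named class-length vector (one row of
#'   \code{\link{sampleArgs}} output).
#' @return Character vector of class labels with positive length.
#' @export
classifyTopology <- function(summary) {
  names(summary)[summary > 0]
}

#' Dump sampled ARG summaries to a columnar text file
#'
#' One row per ARG, one column per mutation class; useful for debugging and
#' for convergence experiments.
#'
#' @param summaries matrix from \code{\link{sampleArgs}}.
#' @param path output file.
#' @export
dumpArgSummaries <- function(summaries, path) {
  write.table(summaries, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
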