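## Mutation-class combinatorics and bSFS/cbSFS tabulation.
##
## Class conventions (shared with the C++ sampler):
##  * unfolded classes are the count vectors (i_1,...,i_X) with
##    0 <= i_x <= b_x, in lexicographic order with i_1 most significant,
##    excluding the all-zero and all-b vectors;
##  * folded classes merge each vector with its complement (b - i); the
##    canonical representative is the lexicographically smaller of the two,
##    and folded classes are listed in lexicographic order of their
##    canonical representatives.

.unfoldedClassVectors <- function(b) {
  X <- length(b)
  grid <- expand.grid(rev(lapply(b, function(n) 0:n)))[, X:1, drop = FALSE]
  m <- as.matrix(grid)
  dimnames(m) <- NULL
  keep <- rowSums(m) > 0 & apply(m, 1, function(v) any(v < b))
  m[keep, , drop = FALSE]
}

.lexLess <- function(u, v) {
  d <- u - v
  nz <- which(d != 0)
  if (!length(nz)) FALSE else d[nz[1]] < 0
}

#' Mutation classes of a sample layout
#'
#' Returns the joint-SFS mutation (branch) classes for a layout: one row per
#' class giving the per-population derived-lineage count vector. For folded
#' (unpolarized) layouts each class is represented by the lexicographically
#' smaller of the vector and its complement, and the \code{"fold"} attribute
#' maps each folded class to the one or two unfolded class indices it pools.
#'
#' @param layout a \code{\link{sampleLayout}}.
#' @return Integer matrix (classes x populations) with row labels; folded
#'   layouts carry a \code{"fold"} attribute.
#' @examples
#' mutationClasses(sampleLayout(c(2, 2)))  # 4 folded classes
#' @export
mutationClasses <- function(layout) {
  b <- sampleSizes(layout)
  unf <- .unfoldedClassVectors(b)
  if (isPolarized(layout)) {
    rownames(unf) <- apply(unf, 1, paste, collapse = "-")
    return(unf)
  }
  canon <- unf
  for (r in seq_len(nrow(unf))) {
    w <- b - unf[r, ]
    if (.lexLess(w, unf[r, ])) canon[r, ] <- w
  }
  key <- apply(canon, 1, paste, collapse = "-")
  reps <- !duplicated(key)
  folded <- canon[reps, , drop = FALSE]
  ord <- do.call(order, as.data.frame(folded))
  folded <- folded[ord, , drop = FALSE]
  rownames(folded) <- apply(folded, 1, paste, collapse = "-")
  fold <- lapply(rownames(folded), function(k) which(key == k))
  names(fold) <- rownames(folded)
  attr(folded, "fold") <- fold
  folded
}

#' Number of joint-SFS site types
#'
#' For a polarized sample the count is \code{prod(b + 1) - 2}; for folded
#' data it is the number of classes remaining after merging each class with
#' its complement.
#'
#' @param layout a \code{\link{sampleLayout}}.
#' @return Integer count of mutation classes.
#' @examples
#' numSiteTypes(sampleLayout(c(2, 2), polarized = TRUE))  # 7
#' numSiteTypes(sampleLayout(c(2, 2)))                    # 4
#' @export
numSiteTypes <- function(layout) nrow(mutationClasses(layout))

## fold an unfolded class-length matrix (columns = unfolded classes) into
## the folded class space of the layout
.foldLengths <- function(T, layout) {
  if (isPolarized(layout)) return(T)
  fold <- attr(mutationClasses(layout), "fold")
  out <- matrix(0, nrow(T), length(fold))
  for (j in seq_along(fold))
    out[, j] <- rowSums(T[, fold[[j]], drop = FALSE])
  colnames(out) <- names(fold)
  out
}

## All labeled rooted binary topologies for a sample, as sets of mutation
## classes their branches can carry. Used to exclude configurations that no
## single (non-recombining) genealogy can produce.
.topologyClassSets <- function(layout) {
  b <- sampleSizes(layout)
  n <- sum(b)
  if (n > 7)
    stop("single-genealogy compatibility is enumerated exhaustively and is ",
         "limited to samples of at most 7 genomes")
  classes <- mutationClasses(layout)
  key <- rownames(classes)
  popOf <- rep(seq_along(b), b)
  classOfMask <- function(mask) {
    cnt <- vapply(seq_along(b), function(x)
      sum(bitwAnd(mask, bitwShiftL(1L, which(popOf == x) - 1L)) > 0L), 0L)
    if (sum(cnt) == 0L || all(cnt == b)) return(NA_integer_)
    if (!isPolarized(layout)) {
      w <- b - cnt
      if (.lexLess(w, cnt)) cnt <- w
    }
    match(paste(cnt, collapse = "-"), key)
  }
  seen <- new.env(hash = TRUE)
  results <- list()
  recurse <- function(masks, clades) {
    if (length(masks) == 1L) {
      ids <- sort(unique(stats::na.omit(vapply(clades, classOfMask, 0L))))
      k <- paste(ids, collapse = ",")
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        results[[length(results) + 1L]] <<- ids
      }
      return(invisible(NULL))
    }
    m <- length(masks)
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      merged <- bitwOr(masks[i], masks[j])
      recurse(c(masks[-c(i, j)], merged), c(clades, merged))
    }
    invisible(NULL)
  }
  leafMasks <- bitwShiftL(1L, seq_len(n) - 1L)
  recurse(leafMasks, as.list(leafMasks))
  ## keep only maximal sets
  results <- unique(results)
  maximal <- vapply(seq_along(results), function(i)
    !any(vapply(seq_along(results), function(j)
      j != i && all(results[[i]] %in% results[[j]]), TRUE)), TRUE)
  results[maximal]
}

#' Enumerate lumped bSFS configurations
#'
#' Lists every configuration with each mutation class taking a value in
#' \code{0:kmax} or the lumped \dQuote{more than kmax} marker (encoded
#' \code{-1}). With \code{noRecombination = TRUE}, configurations whose set
#' of non-zero classes cannot co-occur on any single genealogy (established
#' by exhaustive enumeration of labeled topologies) are excluded; for a
#' folded two-plus-two sample this removes exactly the configurations that
#' combine a shared polymorphism with a fixed difference.
#'
#' @param layout a \code{\link{sampleLayout}}.
#' @param kmax per-class cap (>= 0).
#' @param noRecombination logical; exclude single-genealogy-incompatible
#'   configurations.
#' @return A \code{\link{bsfsTable}} with zero counts, one row per
#'   configuration.
#' @examples
#' nrow(configMatrix(enumerateConfigurations(sampleLayout(c(2, 2)), 4,
#'                                           noRecombination = TRUE)))  # 396
#' @export
enumerateConfigurations <- function(layout, kmax, noRecombination = FALSE) {
  stopifnot(kmax >= 0)
  C <- numSiteTypes(layout)
  vals <- c(0:kmax, -1L)
  K <- as.matrix(expand.grid(rev(rep(list(vals), C)))[, C:1, drop = FALSE])
  dimnames(K) <- NULL
  if (noRecombination) {
    sets <- .topologyClassSets(layout)
    pos <- K != 0L
    ok <- vapply(seq_len(nrow(K)), function(r) {
      p <- which(pos[r, ])
      any(vapply(sets, function(s) all(p %in% s), TRUE))
    }, TRUE)
    K <- K[ok, , drop = FALSE]
  }
  bsfsTable(layout, K, rep(0, nrow(K)), kmax = kmax)
}

## classify one site (0/1 genotype vector across genomes) into a class index;
## NA for non-segregating sites
.siteClass <- function(g, b, classKey, polarized) {
  cnt <- vapply(split(g, rep(seq_along(b), b)), sum, 0)
  if (sum(cnt) == 0 || all(cnt == b)) return(NA_integer_)
  if (!polarized) {
    w <- b - cnt
    if (.lexLess(w, cnt)) cnt <- w
  }
  match(paste(cnt, collapse = "-"), classKey)
}

#' Tabulate per-block variant records into a bSFS table
#'
#' Each block record is a 0/1 matrix (sites by genomes, genome columns
#' ordered by population as in the layout; 1 = derived or alternate allele).
#' Sites with missing entries and multi-allelic sites (entries outside 0/1)
#' are dropped and counted; monomorphic blocks fall into the
#' all-zero configuration k_0.
#'
#' @param blocks list of per-block site-by-genome 0/1 matrices (a block with
#'   no variants may be an empty matrix or NULL).
#' @param layout a \code{\link{sampleLayout}}.
#' @param kmax optional per-class cap; counts above it are lumped into the
#'   \code{> kmax} marker.
#' @return A \code{\link{bsfsTable}}; attribute \code{"droppedSites"} records
#'   the number of sites removed (missing or multi-allelic).
#' @export
tabulateBlocks <- function(blocks, layout, kmax = NA) {
  b <- sampleSizes(layout)
  classes <- mutationClasses(layout)
  classKey <- rownames(classes)
  C <- nrow(classes)
  nsam <- sum(b)
  dropped <- 0L
  kmat <- matrix(0L, length(blocks), C)
  for (j in seq_along(blocks)) {
    g <- blocks[[j]]
    if (is.null(g) || !length(g)) next
    if (ncol(g) != nsam)
      stop("block ", j, " has ", ncol(g), " genome columns; layout expects ",
           nsam)
    bad <- apply(g, 1, function(r) anyNA(r) || any(r != 0 & r != 1))
    dropped <- dropped + sum(bad)
    g <- g[!bad, , drop = FALSE]
    if (!nrow(g)) next
    ci <- apply(g, 1, .siteClass, b = b, classKey = classKey,
                polarized = isPolarized(layout))
    ci <- ci[!is.na(ci)]
    if (length(ci)) kmat[j, ] <- tabulate(ci, nbins = C)
  }
  if (!is.na(kmax)) kmat[kmat > kmax] <- -1L
  tab <- .tallyConfigs(kmat, layout, kmax)
  attr(tab, "droppedSites") <- dropped
  tab
}

## tally a blocks-by-classes count matrix into a BsfsTable
.tallyConfigs <- function(kmat, layout, kmax = NA) {
  keys <- apply(kmat, 1, paste, collapse = ",")
  tt <- table(keys)
  K <- do.call(rbind, lapply(names(tt), function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]])))
  if (is.null(K)) K <- matrix(0L, 0, ncol(kmat))
  bsfsTable(layout, K, as.numeric(tt), kmax = kmax)
}

#' Subsampling schemes for the composite bSFS
#'
#' Defines which genome subsets are pooled into a cbSFS. Genomes are grouped
#' into consecutive units of \code{unitSize} columns per population (units
#' correspond to diploid individuals for \code{unitSize = 2}).
#' \code{"consecutive"} takes the i-th unit of every population as the i-th
#' subsample (up to the smallest per-population unit count);
#' \code{"all_subsets"} takes every combination of \code{unitsPerSubsample}
#' units per population, crossed over populations; \code{"explicit"} uses the
#' column index sets supplied in \code{subsamples}.
#'
#' @param layout the full-sample \code{\link{sampleLayout}}.
#' @param grouping one of \code{"consecutive"}, \code{"all_subsets"},
#'   \code{"explicit"}.
#' @param unitSize genomes per subsampling unit (2 for diploids).
#' @param unitsPerSubsample units drawn per population
#'   (\code{"all_subsets"} only).
#' @param subsamples list of genome-column index vectors
#'   (\code{"explicit"} only).
#' @return List with elements \code{subsamples} (list of column index
#'   vectors) and \code{layout} (the per-subsample \code{SampleLayout}).
#' @examples
#' # 5 diploids per population, all subsets of 2 diploids: 100 subsamples
#' s <- subsamplingScheme(sampleLayout(c(10, 10)), "all_subsets",
#'                        unitSize = 2, unitsPerSubsample = 2)
#' length(s$subsamples)
#' @export
subsamplingScheme <- function(layout,
                              grouping = c("consecutive", "all_subsets",
                                           "explicit"),
                              unitSize = 2, unitsPerSubsample = 1,
                              subsamples = NULL) {
  grouping <- match.arg(grouping)
  b <- sampleSizes(layout)
  offsets <- c(0, cumsum(b))[seq_along(b)]
  popUnits <- lapply(seq_along(b), function(x) {
    nu <- b[x] %/% unitSize
    lapply(seq_len(nu), function(u)
      offsets[x] + ((u - 1) * unitSize + 1):(u * unitSize))
  })
  if (grouping == "consecutive") {
    nsub <- min(lengths(popUnits))
    if (nsub < 1) stop("no complete subsampling unit in some population")
    subs <- lapply(seq_len(nsub), function(i)
      unlist(lapply(popUnits, `[[`, i)))
    subSizes <- rep(unitSize, length(b))
  } else if (grouping == "all_subsets") {
    perPop <- lapply(popUnits, function(units) {
      cmb <- utils::combn(length(units), unitsPerSubsample, simplify = FALSE)
      lapply(cmb, function(ix) unlist(units[ix]))
    })
    grid <- expand.grid(lapply(perPop, seq_along))
    subs <- lapply(seq_len(nrow(grid)), function(r)
      unlist(lapply(seq_along(perPop), function(x)
        perPop[[x]][[grid[r, x]]])))
    subSizes <- rep(unitSize * unitsPerSubsample, length(b))
  } else {
    if (is.null(subsamples)) stop("explicit grouping needs 'subsamples'")
    subs <- lapply(subsamples, as.integer)
    if (any(unlist(subs) < 1) || any(unlist(subs) > sum(b)))
      stop("subsample indices out of range")
    popOf <- rep(seq_along(b), b)
    sz <- lapply(subs, function(s) tabulate(popOf[s], length(b)))
    if (length(unique(vapply(sz, paste, "", collapse = ","))) != 1)
      stop("all subsamples must have identical per-population sizes")
    subSizes <- sz[[1]]
  }
  list(subsamples = subs,
       layout = sampleLayout(subSizes, polarized = isPolarized(layout),
                             blockLength = blockLength(layout),
                             effectiveLength = effectiveLength(layout)))
}

#' Build a composite bSFS (cbSFS) by pooling subsamples
#'
#' For every block and every subsample in the scheme, the subsample's
#' configuration is computed and added to one pooled table in the subsample
#' layout; the pooled total block count is (number of blocks) x (number of
#' subsamples). A scheme containing exactly the full sample reproduces
#' \code{\link{tabulateBlocks}}.
#'
#' @param blocks list of per-block 0/1 site-by-genome matrices.
#' @param scheme a \code{\link{subsamplingScheme}}.
#' @param layout the full-sample \code{\link{sampleLayout}}.
#' @param kmax optional per-class cap.
#' @return A \code{\link{bsfsTable}} in the subsample layout.
#' @export
buildCbsfs <- function(blocks, scheme, layout, kmax = NA) {
  nsam <- sum(sampleSizes(layout))
  if (any(unlist(scheme$subsamples) > nsam))
    stop("subsampling scheme refers to genomes absent from the layout")
  subLayout <- scheme$layout
  b <- sampleSizes(subLayout)
  classes <- mutationClasses(subLayout)
  classKey <- rownames(classes)
  C <- nrow(classes)
  nsub <- length(scheme$subsamples)
  kmat <- matrix(0L, length(blocks) * nsub, C)
  row <- 0L
  for (j in seq_along(blocks)) {
    g <- blocks[[j]]
    if (!is.null(g) && length(g)) {
      bad <- apply(g, 1, function(r) anyNA(r) || any(r != 0 & r != 1))
      g <- g[!bad, , drop = FALSE]
    }
    for (s in scheme$subsamples) {
      row <- row + 1L
      if (is.null(g) || !nrow(g)) next
      gs <- g[, s, drop = FALSE]
      ci <- apply(gs, 1, .siteClass, b = b, classKey = classKey,
                  polarized = isPolarized(subLayout))
      ci <- ci[!is.na(ci)]
      if (length(ci)) kmat[row, ] <- tabulate(ci, nbins = C)
    }
  }
  if (!is.na(kmax)) kmat[kmat > kmax] <- -1L
  .tallyConfigs(kmat, subLayout, kmax)
}

#' Read and write bSFS tables
#'
#' Plain-text format: a commented header recording the layout and lumping,
#' then one tab-separated line per configuration (one entry per mutation
#' class, \code{">k"} marking a lumped entry) ending with the block count.
#' \code{writeBsfsTable} followed by \code{readBsfsTable} is the identity.
#'
#' @param table a \code{\link{bsfsTable}}.
#' @param path file path.
#' @return \code{readBsfsTable}: a \code{BsfsTable}.
#' @export
writeBsfsTable <- function(table, path) {
  lay <- tableLayout(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# bSFS table v1",
    paste0("# sample_sizes: ", paste(sampleSizes(lay), collapse = ",")),
    paste0("# polarized: ", isPolarized(lay)),
    paste0("# block_length: ", format(blockLength(lay), digits = 15)),
    paste0("# effective_length: ", format(effectiveLength(lay), digits = 15)),
    paste0("# kmax: ", kMax(table)),
    paste0("# classes: ", paste(rownames(mutationClasses(lay)),
                                collapse = " "))), con)
  K <- configMatrix(table)
  km <- kMax(table)
  for (r in seq_len(nrow(K))) {
    ent <- ifelse(K[r, ] < 0, paste0(">", km), K[r, ])
    writeLines(paste(c(ent, format(table@counts[r], digits = 15)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeBsfsTable
#' @export
readBsfsTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    v <- sub(paste0("^# ", key, ": "), "",
             grep(paste0("^# ", key, ":"), hdr, value = TRUE))
    if (!length(v)) stop("bSFS table header is missing '", key, "'")
    v
  }
  b <- as.integer(strsplit(get("sample_sizes"), ",")[[1]])
  layout <- sampleLayout(b, polarized = as.logical(get("polarized")),
                         blockLength = as.numeric(get("block_length")),
                         effectiveLength = as.numeric(get("effective_length")))
  kmaxStr <- get("kmax")
  kmax <- if (kmaxStr == "NA") NA_integer_ else as.integer(kmaxStr)
  C <- numSiteTypes(layout)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  K <- matrix(0L, length(body), C)
  counts <- numeric(length(body))
  for (i in seq_along(body)) {
    ln <- body[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != C + 1)
      stop("malformed bSFS table line ", ln, ": expected ", C + 1,
           " fields, found ", length(f))
    lumped <- grepl("^>", f[1:C])
    vals <- suppressWarnings(as.integer(f[1:C]))
    if (any(is.na(vals) & !lumped))
      stop("malformed bSFS table line ", ln, ": non-integer count")
    vals[lumped] <- -1L
    K[i, ] <- vals
    counts[i] <- as.numeric(f[C + 1])
    if (is.na(counts[i]))
      stop("malformed bSFS table line ", ln, ": bad block count")
  }
  bsfsTable(layout, K, counts, kmax = kmax)
}
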