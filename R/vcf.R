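## bSFS tabulation from a VCF plus a BED mask of callable sites.
##
## Blocks are half-open 0-based [start, start + L) windows on each contig.
## A block is retained iff at least q*L callable bases fall in it, and
## exactly the first q*L passing bases are used, so that every retained
## block contributes the same effective length q*L to the block-scaled
## mutation rate.

#' Tabulate a bSFS table from a VCF and a callable-sites mask
#'
#' Splits each contig into fixed-length blocks, keeps blocks where at least
#' \code{minCallableFraction * blockLength} bases are callable in all
#' individuals (taking exactly the first that many callable bases), assigns
#' variants to blocks, and tallies blockwise configurations. Diploid
#' genotypes contribute two genomes per sample; phase is ignored.
#' Multi-allelic sites are dropped and counted; sites with missing
#' genotypes are dropped at tabulation. Polarized tabulation requires the
#' ancestral allele \code{AA} INFO field and refuses to guess without it.
#'
#' @param vcfPath path to a VCF (plain or bgzipped).
#' @param bedPath path to a BED file (0-based half-open intervals) of bases
#'   callable in every individual.
#' @param popMap named character vector mapping VCF sample names to
#'   population labels; column order is populations in first-appearance
#'   order, samples within a population in map order.
#' @param blockLength block length L in bp.
#' @param minCallableFraction minimum callable fraction q (default 0.8).
#' @param polarized use the AA INFO field to polarize; otherwise folded.
#' @param kmax optional per-class cap.
#' @return A \code{\link{bsfsTable}} with attributes \code{"blocksRetained"},
#'   \code{"blocksSeen"}, \code{"droppedMultiallelic"},
#'   \code{"droppedSites"}.
#' @export
tabulateVcf <- function(vcfPath, bedPath, popMap, blockLength = 2000,
                        minCallableFraction = 0.8, polarized = FALSE,
                        kmax = NA) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("tabulateVcf requires the vcfR package")
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf)
  samples <- colnames(gt)
  if (!all(samples %in% names(popMap)))
    stop("popMap is missing samples: ",
         paste(setdiff(samples, names(popMap)), collapse = ", "))
  popLabels <- unique(popMap[names(popMap) %in% samples])
  sampleOrder <- unlist(lapply(popLabels, function(p)
    names(popMap)[popMap == p & names(popMap) %in% samples]))
  ploidy <- 2L
  b <- vapply(popLabels, function(p)
    ploidy * sum(popMap[sampleOrder] == p), 0L)
  E <- as.integer(round(minCallableFraction * blockLength))
  layout <- sampleLayout(b, polarized = polarized,
                         blockLength = blockLength, effectiveLength = E)

  bed <- read.table(bedPath, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")

  pos <- as.numeric(fix$POS)
  chrom <- fix$CHROM
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  droppedMulti <- sum(multi)

  ## derived-allele orientation
  flip <- rep(FALSE, nrow(fix))
  dropAA <- rep(FALSE, nrow(fix))
  if (polarized) {
    aa <- sub(".*AA=([^;]+).*", "\\1", fix$INFO)
    noAA <- !grepl("AA=", fix$INFO)
    if (all(noAA))
      stop("polarized tabulation requires the AA INFO field; none found")
    aa <- toupper(aa)
    flip <- !noAA & aa == toupper(fix$ALT)
    dropAA <- noAA | (aa != toupper(fix$REF) & aa != toupper(fix$ALT))
  }

  blocksSeen <- 0L
  blocksRetained <- 0L
  blocks <- list()
  for (ch in unique(bed$chrom)) {
    ivs <- bed[bed$chrom == ch, , drop = FALSE]
    ivs <- ivs[order(ivs$start), , drop = FALSE]
    maxEnd <- max(ivs$end, if (any(chrom == ch)) max(pos[chrom == ch]) else 0)
    nblock <- ceiling(maxEnd / blockLength)
    blocksSeen <- blocksSeen + nblock
    for (bi in seq_len(nblock)) {
      b0 <- (bi - 1) * blockLength
      b1 <- bi * blockLength
      s <- pmax(ivs$start, b0); e <- pmin(ivs$end, b1)
      keep <- e > s
      if (!any(keep)) next
      s <- s[keep]; e <- e[keep]
      if (sum(e - s) < E) next
      ## the first E callable bases of the block
      cum <- cumsum(e - s)
      lastIv <- which(cum >= E)[1]
      eTrunc <- e
      eTrunc[lastIv] <- e[lastIv] - (cum[lastIv] - E)
      if (lastIv < length(s)) eTrunc[(lastIv + 1):length(s)] <- s[(lastIv + 1):length(s)]
      blocksRetained <- blocksRetained + 1L
      inBlock <- which(chrom == ch & pos > b0 & pos <= b1 & !multi & !dropAA)
      ## keep variants inside the retained callable prefix (VCF POS is
      ## 1-based; BED is 0-based half-open)
      inPrefix <- inBlock[vapply(pos[inBlock], function(p)
        any(p - 1 >= s & p - 1 < eTrunc), TRUE)]
      if (!length(inPrefix)) {
        length(blocks) <- length(blocks) + 1L # monomorphic block -> k_0
        next
      }
      g <- matrix(NA_integer_, length(inPrefix), sum(b))
      for (vi in seq_along(inPrefix)) {
        row <- inPrefix[vi]
        alleles <- unlist(lapply(sampleOrder, function(smp) {
          a <- strsplit(gt[row, smp], "[/|]")[[1]]
          if (length(a) != ploidy) rep(NA_integer_, ploidy)
          else suppressWarnings(as.integer(a))
        }))
        if (flip[row]) alleles <- 1L - alleles
        g[vi, ] <- alleles
      }
      blocks[[length(blocks) + 1]] <- g
    }
  }
  tab <- tabulateBlocks(blocks, layout, kmax = kmax)
  attr(tab, "blocksRetained") <- blocksRetained
  attr(tab, "blocksSeen") <- blocksSeen
  attr(tab, "droppedMultiallelic") <- droppedMulti
  tab
}
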