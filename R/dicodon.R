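#' P/A-site codon-pair pause matrix
#'
#' Computes per-gene pause scores (the per-gene occupancy normalisation)
#' for each replicate and attributes each included position i (with
#' i >= trim + 1 so its P-site codon also lies inside the trimmed window)
#' to the cell (codon at i-1, codon at i).  Cell value = instance-weighted
#' mean pause score over all contributing positions, averaged across
#' replicates; the occurrence count of each pair is reported alongside.
#' Stop codons are excluded from both axes.
#'
#' Genes must pass the coverage filter in every replicate so all
#' replicates contribute the same instance set.
#'
#' @param occList list of \code{\linkS4class{CodonOccupancy}} objects
#'   (replicates of one genotype).
#' @param minCoverage coverage filter passed to \code{\link{pauseScores}}.
#' @param lowSupport cells with fewer contributing instances are flagged
#'   in the \code{lowSupport} attribute of the mean matrix.
#' @return a \code{\linkS4class{DicodonMatrix}}.
#' @export
dicodonPause <- function(occList, minCoverage = 0.1, lowSupport = 5L) {
  sc <- senseCodons()
  tabs <- lapply(occList, pauseScores, minCoverage = minCoverage)
  genes <- Reduce(intersect, lapply(tabs, function(t) unique(t$gene)))
  trim <- occList[[1]]@trim
  sums <- matrix(0, 61, 61, dimnames = list(sc, sc))
  cnts <- matrix(0, 61, 61, dimnames = list(sc, sc))
  for (t in tabs) {
    t <- t[t$gene %in% genes, , drop = FALSE]
    ## within-gene consecutive included positions: P-site codon = previous row
    prevGene <- c("", t$gene[-nrow(t)])
    prevPos <- c(-1L, t$pos[-nrow(t)])
    prevCodon <- c("", t$codon[-nrow(t)])
    use <- t$gene == prevGene & t$pos == prevPos + 1L &
      t$pos >= trim + 1L & prevCodon %in% sc & t$codon %in% sc
    pi <- match(prevCodon[use], sc)
    ai <- match(t$codon[use], sc)
    idx <- cbind(pi, ai)
    flat <- (ai - 1L) * 61L + pi
    ssum <- rowsum(t$score[use], flat)
    scnt <- rowsum(rep(1, sum(use)), flat)
    ii <- as.integer(rownames(ssum))
    sums[ii] <- sums[ii] + ssum[, 1]
    cnts[ii] <- cnts[ii] + scnt[, 1]
  }
  nrep <- length(tabs)
  mean <- ifelse(cnts > 0, sums / cnts, NA_real_)
  count <- cnts / nrep
  attr(mean, "lowSupport") <- count > 0 & count < lowSupport
  new("DicodonMatrix", mean = mean, count = count,
      clamped = matrix(NA_real_, 61, 61, dimnames = list(sc, sc)))
}

#' Mutant/wild-type codon-pair ratio matrix
#'
#' Cell-wise ratio of mean codon-pair pause scores, mutant over wild type.
#' A display copy clamps ratios at \code{clamp} (ratios >= 2 are shown as
#' 2); the raw ratio is preserved for statistics.  Cells empty in either
#' genotype are undefined (NA).
#'
#' @param matMut,matWt \code{DicodonMatrix} objects from identically
#'   processed genotypes.
#' @param clamp display ceiling (default 2).
#' @return a \code{DicodonMatrix}: \code{mean} = raw ratio, \code{clamped}
#'   = display copy, \code{count} = wild-type occurrence count.
#' @export
dicodonRatio <- function(matMut, matWt, clamp = 2) {
  ratio <- matMut@mean / matWt@mean
  ratio[matWt@count == 0 | matMut@count == 0] <- NA_real_
  new("DicodonMatrix", mean = ratio, count = matWt@count,
      clamped = pmin(ratio, clamp))
}

#' Extract the NNN-a_codon slice of a pair matrix
#'
#' Raw (unclamped) values of all P-site codons paired with a fixed A-site
#' codon.
#'
#' @param mat a \code{DicodonMatrix} (typically a ratio matrix).
#' @param aCodon a sense codon (DNA or RNA spelling).
#' @return named numeric vector of length 61 (P-site codons; NA where the
#'   pair has no support).
#' @export
slicePairs <- function(mat, aCodon) {
  aCodon <- normalizeCodon(aCodon)
  if (!aCodon %in% senseCodons()) stop(aCodon, " is not a sense codon")
  mat@mean[, aCodon]
}

#' Occurrence-count quantile categories of a pair matrix
#'
#' Bins the per-pair occurrence counts into \code{n} quantile categories
#' (mirroring dot sizes in a di-codon plot).
#'
#' @param mat a \code{DicodonMatrix}.
#' @param n number of quantile categories.
#' @return integer matrix of categories (NA for empty cells).
#' @export
dicodonCountQuantiles <- function(mat, n = 4L) {
  cnt <- mat@count
  pos <- cnt[cnt > 0]
  br <- unique(quantile(pos, probs = seq(0, 1, length.out = n + 1L)))
  cat <- matrix(NA_integer_, nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  cat[cnt > 0] <- as.integer(cut(pos, breaks = br, include.lowest = TRUE))
  cat
}
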