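#' Read-based codon decoding-speed comparison
#'
#' For each library, the frequency of each sense codon in the ribosomal A
#' site (pooled over the transcriptome, 15 codons trimmed at both CDS ends)
#' is normalised to its mean frequency at the +1, +2 and +3 downstream
#' sites; the log2 mutant/wild-type ratio of these normalised rates,
#' median-centred over the 61 codons, is the relative decoding slowdown.
#' Significance is a one-sided Welch's t-test across replicates
#' (alternative: slower in the mutant), flagged at P < \code{alpha} and
#' centred log2 fold change > \code{lfcThreshold}.
#'
#' Per-replicate log2 rates are median-centred before testing, so two
#' identical libraries give exactly zero everywhere.
#'
#' @param fpMut,fpWt lists of footprint data.frames (replicates).
#' @param ts a \code{\linkS4class{TranscriptSet}}.
#' @param offsets an \code{\linkS4class{OffsetTable}}.
#' @param excludeEnds trimmed codons at each CDS end.
#' @param alpha significance level of the Welch test.
#' @param lfcThreshold minimum centred log2 fold change to flag.
#' @return data.frame(codon, lfc, p, significant, missing) with exactly 61
#'   rows; the median of defined \code{lfc} values is 0.
#' @export
readBasedSpeed <- function(fpMut, fpWt, ts, offsets = defaultOffsets(),
                           excludeEnds = 15L, alpha = 0.05,
                           lfcThreshold = 0.1) {
  sc <- senseCodons()
  codonL <- cdsCodonList(ts)
  lens <- cdsLengthCodons(ts)
  codAll <- unlist(codonL, use.names = FALSE)
  offBase <- c(0L, cumsum(lens))[seq_along(lens)]
  libRates <- function(fp) {
    fp <- selectFootprints(fp[fp$fraction == "monosome", , drop = FALSE],
                           ts, offsets)
    k <- assignASite(fp, ts, offsets)
    l <- lens[fp$transcript_id]
    ok <- !is.na(k) & k >= excludeEnds & k < l - excludeEnds
    fp <- fp[ok, , drop = FALSE]; k <- k[ok]
    freq <- matrix(0, length(sc), 4L, dimnames = list(sc, 0:3))
    gi <- match(fp$transcript_id, transcriptIds(ts))
    for (j in 0:3) {
      kk <- k + j
      inside <- kk < lens[gi]
      cod <- codAll[offBase[gi[inside]] + kk[inside] + 1L]
      agg <- rowsum(fp$count[inside], cod)
      hit <- intersect(rownames(agg), sc)
      freq[hit, j + 1L] <- agg[hit, 1]
    }
    freq <- sweep(freq, 2L, colSums(freq), "/")
    freq[, 1] / rowMeans(freq[, 2:4, drop = FALSE])
  }
  ## log2 rates, centred per library so identical libraries cancel exactly
  center <- function(x) {
    lx <- log2(x)
    lx - median(lx[is.finite(lx)])
  }
  a <- vapply(fpMut, function(f) center(libRates(f)), numeric(length(sc)))
  b <- vapply(fpWt, function(f) center(libRates(f)), numeric(length(sc)))
  lfc <- rowMeans(a) - rowMeans(b)
  lfc <- lfc - median(lfc, na.rm = TRUE)
  p <- rowWelchGreater(a, b)
  missing <- !is.finite(lfc)
  data.frame(codon = sc, lfc = lfc, p = p,
             significant = !missing & !is.na(p) & p < alpha &
               lfc > lfcThreshold,
             missing = missing, row.names = NULL)
}

#' Decile enrichment of codons by vulnerability rank
#'
#' Ranks codon instances by vulnerability score, splits them into
#' \code{bins} equal-size groups (bin 1 = lowest scores; any remainder
#' goes to the lower bins) and reports, per codon and bin, the frequency
#' of the codon in the bin relative to its overall frequency.
#'
#' @param vuln vulnerability table from \code{\link{vulnerabilityScores}}.
#' @param bins number of rank bins (default 10).
#' @return matrix codons x bins of enrichment values (NA for codons never
#'   observed).
#' @export
decileEnrichment <- function(vuln, bins = 10L) {
  n <- nrow(vuln)
  if (n < bins) stop("need at least ", bins, " scored instances")
  ord <- order(vuln$score)
  sizes <- rep(n %/% bins, bins)
  extra <- n %% bins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(n)
  bin[ord] <- rep(seq_len(bins), times = sizes)
  sc <- senseCodons()
  overall <- table(factor(vuln$codon, levels = sc)) / n
  enr <- matrix(NA_real_, length(sc), bins,
                dimnames = list(sc, paste0("bin", seq_len(bins))))
  for (b in seq_len(bins)) {
    fb <- table(factor(vuln$codon[bin == b], levels = sc)) / sizes[b]
    enr[, b] <- as.numeric(fb) / as.numeric(overall)
  }
  enr[overall == 0, ] <- NA_real_
  enr
}

#' Positional residue enrichment upstream of vulnerable codons
#'
#' Compares the amino-acid composition at each of the \code{window} codon
#' positions upstream of the top-ranked vulnerable codon instances against
#' the same positions upstream of a background instance set (e.g. from a
#' wild-type-vs-wild-type control contrast).  Each (position, residue)
#' cell is a two-sided binomial test of the top-set residue count against
#' the background frequency, Bonferroni-corrected over all positions x
#' residues; cells are significant at corrected P < 0.01.
#'
#' Instances with fewer than \code{window} upstream codons inside the CDS
#' are skipped; the number skipped is recorded in the \code{skipped}
#' attribute.
#'
#' @param top ranked instance table (columns gene, pos, score), highest
#'   scores used first.
#' @param background instance table for the control contrast.
#' @param ts a \code{\linkS4class{TranscriptSet}}.
#' @param nTop number of top instances analysed (default 1000).
#' @param window upstream codons examined (default 30).
#' @param alpha corrected significance threshold.
#' @return data.frame(position, residue, freqTop, freqBg, p, pBonf,
#'   significant, direction); positions run -window..-1.
#' @export
positionalResidueEnrichment <- function(top, background, ts, nTop = 1000L,
                                        window = 30L, alpha = 0.01) {
  if (!nrow(background)) stop("empty background instance set")
  codonL <- cdsCodonList(ts)
  gi <- function(x) match(x$gene, transcriptIds(ts))
  upstreamAA <- function(inst) {
    ok <- inst$pos >= window
    skipped <- sum(!ok)
    inst <- inst[ok, , drop = FALSE]
    g <- gi(inst)
    aa <- matrix(NA_character_, nrow(inst), window)
    for (i in seq_len(nrow(inst))) {
      cods <- codonL[[g[i]]][(inst$pos[i] - window + 1L):inst$pos[i]]
      ## columns are positions -window..-1 relative to the site
      aa[i, ] <- codonToAA(cods[seq_len(window)])
    }
    attr(aa, "skipped") <- skipped
    aa
  }
  top <- top[order(-top$score), , drop = FALSE]
  top <- head(top, nTop)
  aaTop <- upstreamAA(top)
  aaBg <- upstreamAA(background)
  residues <- sort(unique(unname(Biostrings::GENETIC_CODE)))
  residues <- setdiff(residues, "*")
  res <- expand.grid(position = -(window:1), residue = residues,
                     stringsAsFactors = FALSE)
  res <- res[order(res$position, res$residue), ]
  nT <- nrow(aaTop); nB <- nrow(aaBg)
  out <- lapply(seq_len(nrow(res)), function(i) {
    colIdx <- res$position[i] + window + 1L
    x <- sum(aaTop[, colIdx] == res$residue[i], na.rm = TRUE)
    bg <- sum(aaBg[, colIdx] == res$residue[i], na.rm = TRUE) / nB
    p0 <- min(max(bg, 0.5 / nB), 1 - 0.5 / nB)
    pv <- binom.test(x, nT, p = p0)$p.value
    c(freqTop = x / nT, freqBg = bg, p = pv)
  })
  out <- do.call(rbind, out)
  res <- cbind(res, out)
  res$pBonf <- pmin(res$p * nrow(res), 1)
  res$significant <- res$pBonf < alpha
  res$direction <- ifelse(res$freqTop > res$freqBg, "enriched", "depleted")
  attr(res, "skipped") <- c(top = attr(aaTop, "skipped"),
                            background = attr(aaBg, "skipped"))
  rownames(res) <- NULL
  res
}
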