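#' Build per-codon A-site occupancy
#'
#' Accumulates selected monosome footprint counts per (gene, codon
#' position) after A-site assignment.  All CDS positions are materialised
#' (zeros included); positions within \code{excludeEnds} codons of either
#' CDS end are retained but flagged \code{included = FALSE} so that context
#' profiles can still see them.
#'
#' @param fp selected monosome footprint data.frame (one library).
#' @param ts a \code{\linkS4class{TranscriptSet}}.
#' @param offsets an \code{\linkS4class{OffsetTable}}.
#' @param excludeEnds codons excluded at both CDS ends (default 15).
#' @return a \code{\linkS4class{CodonOccupancy}}.
#' @export
buildOccupancy <- function(fp, ts, offsets = defaultOffsets(),
                           excludeEnds = 15L) {
  lens <- cdsLengthCodons(ts)
  ids <- transcriptIds(ts)
  gene <- rep.int(seq_along(ids), lens)
  pos <- unlist(lapply(lens, function(l) seq_len(l) - 1L), use.names = FALSE)
  codon <- unlist(cdsCodonList(ts), use.names = FALSE)
  count <- numeric(length(gene))
  if (nrow(fp)) {
    fp <- fp[fp$fraction == "monosome", , drop = FALSE]
    k <- assignASite(fp, ts, offsets)
    ok <- !is.na(k)
    gi <- match(fp$transcript_id, ids)
    offBase <- c(0L, cumsum(lens))[seq_along(ids)]
    idx <- offBase[gi[ok]] + k[ok] + 1L
    agg <- rowsum(fp$count[ok], idx)
    count[as.integer(rownames(agg))] <- agg[, 1]
  }
  l <- lens[gene]
  dat <- data.frame(gene = ids[gene], pos = pos, codon = codon,
                    count = count,
                    included = pos >= excludeEnds & pos < l - excludeEnds,
                    stringsAsFactors = FALSE)
  new("CodonOccupancy", data = dat, trim = as.integer(excludeEnds),
      cdsLen = setNames(as.integer(lens), ids))
}

#' Pause scores (per-gene occupancy normalisation)
#'
#' For each gene passing the coverage filter, the pause score of codon i is
#' its A-site read count divided by the mean read count over the included
#' positions (15..l-16, i.e. the CDS minus 15 codons at each end), so the
#' per-gene mean pause score over included positions is exactly 1.  Genes
#' whose read coverage (total A-site reads over the CDS divided by its
#' length in codons) falls below \code{minCoverage} (default 0.1 reads per
#' codon) are dropped.
#'
#' @param occ a \code{\linkS4class{CodonOccupancy}}.
#' @param minCoverage minimum reads per codon of CDS.
#' @param pseudocount added to every position before scoring (0 here; the
#'   vulnerability-score pipeline uses 1).
#' @return data.frame(gene, pos, codon, count, score) over included
#'   positions of retained genes.
#' @export
pauseScores <- function(occ, minCoverage = 0.1, pseudocount = 0) {
  ## coverage = total A-site reads over the whole CDS / CDS length (codons)
  tot <- tapply(occ@data$count, occ@data$gene, sum)
  cov <- tot / occ@cdsLen[names(tot)]
  keepGenes <- names(cov)[cov >= minCoverage]
  d <- occ@data[occ@data$included, , drop = FALSE]
  d <- d[d$gene %in% keepGenes, , drop = FALSE]
  cnt <- d$count + pseudocount
  denom <- ave(cnt, d$gene, FUN = mean)
  zero <- unique(d$gene[denom == 0])
  if (length(zero)) {
    warning("gene(s) with zero included reads dropped: ",
            paste(head(zero, 5), collapse = ", "))
    keep <- !d$gene %in% zero
    d <- d[keep, , drop = FALSE]
    cnt <- cnt[keep]; denom <- denom[keep]
  }
  data.frame(gene = d$gene, pos = d$pos, codon = d$codon, count = d$count,
             score = cnt / denom, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Vulnerability scores (mutant/wild-type pause-score ratios)
#'
#' Recomputes pause scores on counts + 1 (the pseudocount guards against
#' division by zero) for every replicate of both genotypes, forms the
#' per-codon-instance ratio mutant/wild type for every mutant x wild-type
#' replicate pair, and reports the median across pairs together with a
#' two-sample Student's t-test of the per-replicate pause scores.
#'
#' Genes must pass the raw-count coverage filter (\code{minCoverage} mean
#' reads per included codon) in every replicate of both genotypes.
#'
#' @param occMut,occWt lists of \code{CodonOccupancy} objects (replicates).
#' @param pseudocount added before pause scoring (default 1).
#' @param minCoverage coverage filter on raw counts.
#' @return data.frame(gene, pos, codon, score, p).
#' @export
vulnerabilityScores <- function(occMut, occWt, pseudocount = 1,
                                minCoverage = 0.1) {
  scoreMat <- function(occList) {
    tabs <- lapply(occList, pauseScores, minCoverage = minCoverage,
                   pseudocount = pseudocount)
    genes <- Reduce(intersect, lapply(tabs, function(t) unique(t$gene)))
    tabs <- lapply(tabs, function(t) t[t$gene %in% genes, , drop = FALSE])
    key <- paste(tabs[[1]]$gene, tabs[[1]]$pos)
    m <- vapply(tabs, function(t) {
      stopifnot(identical(paste(t$gene, t$pos), key))
      t$score
    }, numeric(nrow(tabs[[1]])))
    list(key = tabs[[1]][c("gene", "pos", "codon")], scores = m)
  }
  sm <- scoreMat(occMut)
  sw <- scoreMat(occWt)
  common <- intersect(unique(sm$key$gene), unique(sw$key$gene))
  if (!length(common))
    stop("no genes pass the coverage filter in both genotypes")
  im <- sm$key$gene %in% common
  iw <- sw$key$gene %in% common
  km <- sm$key[im, , drop = FALSE]
  kw <- sw$key[iw, , drop = FALSE]
  if (!identical(paste(km$gene, km$pos), paste(kw$gene, kw$pos)))
    stop("mutant and wild-type position sets do not align; offending ",
         "genes: ", paste(head(setdiff(unique(km$gene), unique(kw$gene)), 5),
                          collapse = ", "))
  a <- sm$scores[im, , drop = FALSE]
  b <- sw$scores[iw, , drop = FALSE]
  ## median over all mutant x wild-type replicate pair ratios
  ratios <- matrix(NA_real_, nrow(a), ncol(a) * ncol(b))
  c0 <- 0L
  for (j in seq_len(ncol(a))) for (k in seq_len(ncol(b))) {
    c0 <- c0 + 1L
    ratios[, c0] <- a[, j] / b[, k]
  }
  med <- if (ncol(ratios) == 1L) ratios[, 1] else
    apply(ratios, 1L, median)
  p <- rowStudentT(a, b)
  data.frame(gene = km$gene, pos = km$pos, codon = km$codon,
             score = med, p = p, stringsAsFactors = FALSE,
             row.names = NULL)
}
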