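#' Gene-level footprint counting
#'
#' Sums footprint counts per gene x (fraction, genotype, replicate) for
#' footprints overlapping the CDS; footprints lying entirely in the
#' flanking regions are excluded.
#'
#' @param fp footprint data.frame (monosome and disome records).
#' @param ts a \code{\linkS4class{TranscriptSet}}.
#' @return a \code{SummarizedExperiment} (assay \code{counts}; colData
#'   \code{genotype}, \code{fraction}, \code{replicate}).
#' @export
countGeneFootprints <- function(fp, ts) {
  fp <- checkFootprints(fp, ts)
  cs <- cdsStart(ts)[fp$transcript_id]
  ce <- cdsEnd(ts)[fp$transcript_id]
  inCds <- fp$five_prime_pos < ce & fp$five_prime_pos + fp$length > cs
  fp <- fp[inCds, , drop = FALSE]
  sample <- paste(fp$genotype, fp$fraction, fp$replicate, sep = "_")
  samples <- sort(unique(sample))
  genes <- transcriptIds(ts)
  counts <- matrix(0L, length(genes), length(samples),
                   dimnames = list(genes, samples))
  agg <- rowsum(fp$count, paste(fp$transcript_id, sample, sep = "\r"))
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  counts[cbind(match(parts[, 1], genes), match(parts[, 2], samples))] <-
    as.integer(agg[, 1])
  meta <- do.call(rbind, strsplit(samples, "_"))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(genotype = meta[, 1],
                                   fraction = meta[, 2],
                                   replicate = meta[, 3],
                                   row.names = samples))
}

#' RQC-target / RQC-refractory classification
#'
#' Applies the two-contrast rule: a gene is an \code{RQC_target} when its
#' disome enrichment is significantly up in the first contrast (e.g.
#' modification mutant vs wild type) and significantly down in the second
#' (e.g. triple mutant lacking the collision sensor vs the double mutant);
#' an \code{RRT} (RQC-refractory transcript) shows the sign-mirrored
#' pattern; everything else is \code{neither}.  Significance is adjusted
#' P < \code{alpha} in each contrast.
#'
#' @param deMutVsWt,deTripleVsDouble results from
#'   \code{\link{interactionDE}} for the two contrasts.
#' @param alpha adjusted-P threshold (default 0.05).
#' @return data.frame(gene, label) over the genes tested in both
#'   contrasts; labels are mutually exclusive and exhaustive.
#' @export
classifyRQC <- function(deMutVsWt, deTripleVsDouble, alpha = 0.05) {
  m <- merge(deMutVsWt[c("gene", "lfc", "padj")],
             deTripleVsDouble[c("gene", "lfc", "padj")],
             by = "gene", suffixes = c("1", "2"))
  up1 <- !is.na(m$padj1) & m$padj1 < alpha & m$lfc1 > 0
  dn1 <- !is.na(m$padj1) & m$padj1 < alpha & m$lfc1 < 0
  up2 <- !is.na(m$padj2) & m$padj2 < alpha & m$lfc2 > 0
  dn2 <- !is.na(m$padj2) & m$padj2 < alpha & m$lfc2 < 0
  label <- rep("neither", nrow(m))
  label[up1 & dn2] <- "RQC_target"
  label[dn1 & up2] <- "RRT"
  data.frame(gene = m$gene, label = label, stringsAsFactors = FALSE)
}

#' One-sided Kolmogorov-Smirnov comparison of log2 fold changes
#'
#' Two-sample KS test between two sets of log2 fold changes; the
#' directional alternatives follow \code{stats::ks.test} ("less": the CDF
#' of x lies below that of y, i.e. x tends to larger values).
#'
#' @param lfc1,lfc2 numeric vectors (non-empty).
#' @param alternative "two.sided", "less" or "greater".
#' @return list(statistic, p.value).
#' @export
compareLogFC <- function(lfc1, lfc2,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(lfc1) || !length(lfc2)) stop("both sets must be non-empty")
  kt <- suppressWarnings(ks.test(lfc1, lfc2, alternative = alternative))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Aggregation-propensity cross-tabulation
#'
#' Cross-tabulates aggregation behaviour (fold change > \code{up} =
#' aggregation-prone, < \code{down} = non-aggregating; both strict) against
#' the RQC_target/RRT labels and applies a two-sided Fisher's exact test.
#' The reported odds ratio is the sample odds ratio (ad/bc).
#'
#' @param labels data.frame(gene, label) from \code{\link{classifyRQC}}.
#' @param aggregateFC named numeric vector of linear-scale aggregate
#'   fold changes.
#' @param up,down strict thresholds on the linear fold change.
#' @return list(table, oddsRatio, p.value); the test is skipped (p NA)
#'   when a category is empty.
#' @export
aggregationCrosstab <- function(labels, aggregateFC, up = 2, down = 0.5) {
  fc <- aggregateFC[labels$gene]
  cat <- ifelse(is.na(fc), NA,
                ifelse(fc > up, "aggregation_prone",
                       ifelse(fc < down, "non_aggregating", NA)))
  use <- !is.na(cat) & labels$label %in% c("RQC_target", "RRT")
  tab <- table(factor(cat[use],
                      levels = c("aggregation_prone", "non_aggregating")),
               factor(labels$label[use], levels = c("RQC_target", "RRT")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("empty category; Fisher's test skipped")
    return(list(table = tab, oddsRatio = NA_real_, p.value = NA_real_))
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, oddsRatio = unname(or),
       p.value = fisher.test(tab)$p.value)
}

#' Codon/codon-pair content comparison between gene sets
#'
#' Computes, per gene, the density of a set of codons or "P-A" codon pairs
#' per codon of CDS and compares RQC_target against RRT genes with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param labels data.frame(gene, label).
#' @param ts a \code{\linkS4class{TranscriptSet}}.
#' @param codonSet character vector of codons and/or "P-A" pairs.
#' @param alternative passed to \code{wilcox.test}.
#' @return list(perGene, statistic, p.value).
#' @export
codonContentEnrichment <- function(labels, ts, codonSet,
                                   alternative = "two.sided") {
  genes <- labels$gene[labels$label %in% c("RQC_target", "RRT")]
  if (!length(genes)) stop("both label groups must be non-empty")
  codonL <- cdsCodonList(ts)
  dens <- vapply(genes, function(g) {
    cc <- codonL[[g]]
    total <- 0L
    for (q in codonSet) {
      parts <- normalizeCodon(strsplit(q, "-", fixed = TRUE)[[1]])
      if (length(parts) == 1L) total <- total + sum(cc == parts)
      else total <- total +
        sum(cc[-length(cc)] == parts[1] & cc[-1] == parts[2])
    }
    total / length(cc)
  }, numeric(1))
  perGene <- data.frame(gene = genes,
                        label = labels$label[match(genes, labels$gene)],
                        density = dens, row.names = NULL)
  x <- perGene$density[perGene$label == "RQC_target"]
  y <- perGene$density[perGene$label == "RRT"]
  if (!length(x) || !length(y)) stop("both label groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative))
  list(perGene = perGene, statistic = unname(wt$statistic),
       p.value = wt$p.value)
}
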