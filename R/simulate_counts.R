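#' Simulate gene-level monosome/disome count tables
#'
#' Draws negative-binomial counts for a genotype x fraction x replicate
#' design in which the disome/monosome ratio of a gene changes by a planted
#' interaction effect per genotype.  Truth labels drive the effect pattern:
#' an \code{RQC_target} gains disome enrichment of \code{+lfc} (log2) in
#' the second genotype relative to the first and loses it again
#' (\code{-lfc}) in the third genotype relative to the second (the RQC-
#' rescue pattern); an \code{RRT} is sign-mirrored; \code{null} genes carry
#' no interaction.  With two genotypes only the first contrast is planted.
#'
#' @param nGenes number of genes.
#' @param genotypes genotype labels (2 or 3; first = reference).
#' @param fractions fraction labels, first = monosome (reference).
#' @param replicates libraries per genotype x fraction.
#' @param nbMean location of the per-gene base-mean distribution
#'   (log-normal around \code{nbMean} with \code{meanSdLog} log-sd).
#' @param nbDispersion negative-binomial dispersion (must be > 0).
#' @param plantedEffects data.frame(gene, label, lfc); \code{gene} is an
#'   index into 1..nGenes, \code{label} in \{RQC_target, RRT, null\}.
#' @param disomeRatio expected disome/monosome count ratio at baseline.
#' @param meanSdLog log-sd of base means (0 gives a constant mean).
#' @param seed RNG seed.
#' @return a \code{SummarizedExperiment}: assay \code{counts}, colData
#'   \code{genotype}/\code{fraction}/\code{replicate}, rowData with the
#'   truth label and planted lfc.
#' @export
simulateGeneCounts <- function(nGenes, genotypes = c("wt", "mut"),
    fractions = c("monosome", "disome"), replicates = 3L,
    nbMean = 200, nbDispersion = 0.05, plantedEffects = NULL,
    disomeRatio = 0.3, meanSdLog = 1, seed = 1L) {
  if (nbDispersion <= 0) stop("nbDispersion must be > 0")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(nGenes))
  label <- rep("null", nGenes)
  lfc <- rep(0, nGenes)
  if (!is.null(plantedEffects)) {
    label[plantedEffects$gene] <- plantedEffects$label
    lfc[plantedEffects$gene] <- plantedEffects$lfc
  }
  ## per-genotype disome-enrichment offsets (log2), reference genotype = 0
  sgn <- ifelse(label == "RQC_target", 1, ifelse(label == "RRT", -1, 0))
  eff <- matrix(0, nGenes, length(genotypes))
  if (length(genotypes) >= 2L) eff[, 2L] <- sgn * lfc
  if (length(genotypes) >= 3L) eff[, 3L] <- 0   # +lfc then -lfc cancels
  base <- if (meanSdLog > 0)
    rlnorm(nGenes, meanlog = log(nbMean), sdlog = meanSdLog)
  else rep(nbMean, nGenes)
  design <- expand.grid(replicate = paste0("rep", seq_len(replicates)),
                        fraction = fractions, genotype = genotypes,
                        stringsAsFactors = FALSE)
  counts <- matrix(0L, nGenes, nrow(design))
  for (j in seq_len(nrow(design))) {
    gidx <- match(design$genotype[j], genotypes)
    mu <- base
    if (design$fraction[j] != fractions[1L])
      mu <- mu * disomeRatio * 2^eff[, gidx]
    counts[, j] <- rnbinom(nGenes, mu = mu, size = 1 / nbDispersion)
  }
  rownames(counts) <- genes
  colnames(counts) <- paste(design$genotype, design$fraction,
                            design$replicate, sep = "_")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(design, row.names = colnames(counts)),
    rowData = S4Vectors::DataFrame(label = label, lfc = lfc,
                                   row.names = genes))
}
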