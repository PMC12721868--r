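test_that("gene-level counting sums CDS-overlapping footprints only", {
  ts <- toyTranscript(toyCds(40))
  cs <- unname(cdsStart(ts))
  fp <- data.frame(transcript_id = "g1",
                   five_prime_pos = c(cs, cs + 10L, 2L),
                   length = 28L, count = c(3L, 4L, 5L),
                   fraction = "monosome", genotype = "wt",
                   replicate = "rep1")
  # the footprint at position 2 spans into the CDS (2+28 > 21): included;
  # push it fully into the flank to see it excluded
  se <- countGeneFootprints(fp, ts)
  expect_equal(unname(SummarizedExperiment::assay(se)["g1", 1]), 12L)
  fp$five_prime_pos[3] <- 150L   # 3' flank only (CDS ends at 141)
  fp$length[3] <- 10L            # keep it short of the CDS... not valid len
  fp$length[3] <- 28L
  fp$five_prime_pos[3] <- 141L
  se2 <- countGeneFootprints(fp, ts)
  expect_equal(unname(SummarizedExperiment::assay(se2)["g1", 1]), 7L)
})

test_that("counting reproduces the simulator's library totals", {
  cfg <- simulationConfig(seed = 61, nGenes = 10,
                          cdsLengthRange = c(80, 120), readDepth = 5e3,
                          replicates = 2)
  ts <- simulateTranscriptome(cfg)
  fp <- simulateFootprints(ts, cfg)
  se <- countGeneFootprints(fp, ts)
  truth <- tapply(fp$count, paste(fp$genotype, fp$fraction, fp$replicate,
                                  sep = "_"), sum)
  expect_equal(unname(colSums(SummarizedExperiment::assay(se))[names(truth)]),
               as.numeric(truth))
})

test_that("the interaction test is calibrated near its nominal level and scale-stable", {
  se <- simulateGeneCounts(400, replicates = 2, nbMean = 200,
                           nbDispersion = 0.05, meanSdLog = 1, seed = 71)
  res <- interactionDE(se, c("wt", "mut"))
  # loose unit-level calibration check (the full-size one runs elsewhere)
  expect_gt(mean(res$pvalue < 0.05), 0.01)
  expect_lt(mean(res$pvalue < 0.05), 0.10)
  expect_true(all(diff(res$padj[order(res$pvalue)]) >= -1e-12))
  # doubling one sample's counts is absorbed by normalisation
  se2 <- se
  SummarizedExperiment::assay(se2)[, 3] <-
    2L * SummarizedExperiment::assay(se2)[, 3]
  res2 <- interactionDE(se2, c("wt", "mut"))
  expect_gt(cor(res$lfc, res2$lfc), 0.98)
  expect_lt(median(abs(res$lfc - res2$lfc)), 0.05)
})

test_that("interaction p-values agree with an independent DESeq2 run", {
  skip_if_not_installed("DESeq2")
  pe <- data.frame(gene = 1:30, label = "RQC_target", lfc = 1)
  se <- simulateGeneCounts(200, replicates = 3, nbMean = 300,
                           nbDispersion = 0.05, meanSdLog = 0.5,
                           plantedEffects = pe, seed = 73)
  res <- interactionDE(se, c("wt", "mut"))
  cnt <- SummarizedExperiment::assay(se)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  cd$sampleType <- factor(cd$fraction, levels = c("monosome", "disome"))
  cd$condition <- factor(cd$genotype, levels = c("wt", "mut"))
  dds <- DESeq2::DESeqDataSetFromMatrix(cnt, cd,
    ~ sampleType + condition + condition:sampleType)
  dds <- DESeq2::DESeq(dds, test = "LRT",
                       reduced = ~ sampleType + condition, quiet = TRUE)
  ref <- as.data.frame(DESeq2::results(dds))
  m <- match(res$gene, rownames(ref))
  expect_gt(cor(res$lfc, ref$log2FoldChange[m]), 0.95)
  expect_gt(cor(-log10(res$pvalue), -log10(ref$pvalue[m]),
                method = "spearman"), 0.9)
})

test_that("the two-contrast rule labels genes exclusively and exhaustively", {
  mk <- function(lfc, padj) data.frame(gene = paste0("g", seq_along(lfc)),
                                       lfc = lfc, padj = padj)
  d1 <- mk(c(2, -2, 2, 2, 0.5), c(0.001, 0.001, 0.001, 0.2, 0.001))
  d2 <- mk(c(-2, 2, 2, -2, -0.5), c(0.001, 0.001, 0.001, 0.001, 0.2))
  lab <- classifyRQC(d1, d2)
  expect_identical(lab$label,
                   c("RQC_target", "RRT", "neither", "neither", "neither"))
  expect_true(all(lab$label %in% c("RQC_target", "RRT", "neither")))
})

test_that("strongly planted labels are recovered with near-zero false discovery", {
  pe <- data.frame(gene = 1:120,
                   label = rep(c("RQC_target", "RRT"), each = 60),
                   lfc = 2)
  se <- simulateGeneCounts(800, genotypes = c("wt", "dbl", "tpl"),
                           replicates = 3, nbMean = 500,
                           nbDispersion = 0.05, meanSdLog = 0,
                           disomeRatio = 1, plantedEffects = pe, seed = 77)
  r1 <- interactionDE(se, c("wt", "dbl"))
  r2 <- interactionDE(se, c("dbl", "tpl"))
  lab <- classifyRQC(r1, r2)
  truth <- setNames(as.character(SummarizedExperiment::rowData(se)$label),
                    rownames(se))
  for (L in c("RQC_target", "RRT")) {
    called <- lab$gene[lab$label == L]
    tp <- sum(truth[called] == L)
    expect_gte(tp / 60, 0.9)                       # recovery
    expect_lte((length(called) - tp) / max(length(called), 1), 0.1)  # FDP
  }
})

test_that("KS comparison and its limiting cases behave", {
  x <- rnorm(100)
  r <- compareLogFC(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  set.seed(2)
  a <- rnorm(4000); b <- a - 1
  expect_gt(compareLogFC(a, b)$statistic, 0.3)
  # a downward mRNA shift in RQC targets is detected at n = 150/group
  set.seed(3)
  t1 <- rnorm(150, mean = -0.5, sd = 1); t2 <- rnorm(150, 0, 1)
  expect_lt(compareLogFC(t1, t2, alternative = "greater")$p.value, 0.05)
  expect_error(compareLogFC(numeric(), x), "non-empty")
})

test_that("the aggregation crosstab matches the hypergeometric oracle", {
  labels <- data.frame(gene = paste0("g", 1:30),
                       label = rep(c("RQC_target", "RRT"), each = 15))
  # engineer the 2x2 table [[10,5],[5,10]]
  fc <- c(rep(3, 10), rep(0.2, 5), rep(3, 5), rep(0.2, 10))
  names(fc) <- labels$gene
  res <- aggregationCrosstab(labels, fc)
  expect_equal(unname(as.vector(res$table)), c(10, 5, 5, 10))
  expect_equal(res$oddsRatio, 4.0)
  # hypergeometric enumeration oracle for the two-sided Fisher p-value
  m <- 15; n <- 15; k <- 15
  probs <- dhyper(0:15, m, n, k)
  pOracle <- sum(probs[probs <= dhyper(10, m, n, k) * (1 + 1e-7)])
  expect_equal(res$p.value, pOracle, tolerance = 1e-12)
  # strict thresholds: fold change exactly 2 is not aggregation-prone
  fc2 <- fc; fc2[1] <- 2
  res2 <- aggregationCrosstab(labels, fc2)
  expect_equal(unname(as.vector(res2$table)), c(9, 5, 5, 10))
  # empty category: test skipped
  expect_message(r0 <- aggregationCrosstab(labels, setNames(rep(1, 30),
                                                            labels$gene)),
                 "skipped")
  expect_true(is.na(r0$p.value))
})

test_that("codon-content comparison sees planted pair-rich targets", {
  rich <- toyCds(120)
  rich[seq(31, 89, by = 2)] <- "CAA"; rich[seq(30, 88, by = 2)] <- "GCA"
  poor <- toyCds(120, fill = "GAT")
  seqs <- c(
    setNames(paste0(strrep("A", 21), paste(rich, collapse = ""),
                    strrep("A", 21)), "t1"),
    setNames(paste0(strrep("A", 21), paste(poor, collapse = ""),
                    strrep("A", 21)), "t2"),
    setNames(paste0(strrep("A", 21), paste(rich, collapse = ""),
                    strrep("A", 21)), "t3"),
    setNames(paste0(strrep("A", 21), paste(poor, collapse = ""),
                    strrep("A", 21)), "t4"))
  ts <- TranscriptSet(seqs, rep(21L, 4), rep(21L + 360L, 4))
  labels <- data.frame(gene = c("t1", "t3", "t2", "t4"),
                       label = c("RQC_target", "RQC_target", "RRT", "RRT"))
  res <- codonContentEnrichment(labels, ts, c("GCA-CAA"))
  expect_true(all(res$perGene$density[res$perGene$label == "RQC_target"] >
                  res$perGene$density[res$perGene$label == "RRT"]))
  # absent pair -> zero density everywhere and no signal
  res0 <- codonContentEnrichment(labels, ts, c("TGG-TGG"))
  expect_true(all(res0$perGene$density == 0))
  # identical composition in both groups -> no significance
  seqs2 <- setNames(rep(unname(seqs[c(1, 2)]), 2), c("u1", "u2", "u3", "u4"))
  ts2 <- TranscriptSet(seqs2, rep(21L, 4), rep(21L + 360L, 4))
  labels2 <- data.frame(gene = c("u1", "u2", "u3", "u4"),
                        label = c("RQC_target", "RQC_target", "RRT", "RRT"))
  res2 <- codonContentEnrichment(labels2, ts2, "GCA-CAA")
  expect_true(is.na(res2$p.value) || res2$p.value > 0.5)
})
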