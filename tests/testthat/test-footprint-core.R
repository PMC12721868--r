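test_that("annotation and footprint tables round-trip through disk", {
  cfg <- simulationConfig(seed = 2, nGenes = 3, cdsLengthRange = c(40, 60),
                          readDepth = 500, replicates = 1)
  ts <- simulateTranscriptome(cfg)
  fp <- simulateFootprints(ts, cfg)
  annP <- tempfile(fileext = ".tsv"); fasP <- tempfile(fileext = ".fa")
  fpP <- tempfile(fileext = ".tsv")
  writeAnnotation(ts, annP, fasP)
  writeFootprints(fp, fpP)
  ts2 <- readAnnotation(annP, fasP)
  expect_identical(as.character(ts2@sequences), as.character(ts@sequences))
  expect_identical(cdsStart(ts2), cdsStart(ts))
  fp2 <- readFootprints(fpP, ts2)
  cols <- c("transcript_id", "five_prime_pos", "length", "count",
            "fraction", "genotype", "replicate")
  rt <- fp[cols]; rownames(rt) <- NULL
  expect_identical(fp2, rt)
})

test_that("malformed inputs are rejected with informative errors", {
  ts <- toyTranscript(toyCds(40))
  annP <- tempfile(); fasP <- tempfile()
  writeAnnotation(ts, annP, fasP)
  # CDS length 100 nt is not divisible by 3
  bad <- data.frame(transcript_id = "g1", cds_start = 21, cds_end = 121)
  badP <- tempfile()
  write.table(bad, badP, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readAnnotation(badP, fasP), "multiple of 3")
  # negative count
  fp <- toyFootprints(ts, rep(1, 40))
  fp$count[3] <- -1L
  fpP <- tempfile()
  write.table(fp, fpP, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readFootprints(fpP), "negative count")
  # unknown transcript id
  fp$count[3] <- 1L
  fp$transcript_id[2] <- "nope"
  write.table(fp, fpP, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readFootprints(fpP, ts), "unknown transcript")
})

test_that("frame classification follows the codon-position rule", {
  ts <- toyTranscript(toyCds(40))
  cs <- unname(cdsStart(ts))
  fp <- data.frame(transcript_id = "g1",
                   five_prime_pos = cs + c(0L, 4L, -3L, 2L),
                   length = 28L, count = 1L, fraction = "monosome",
                   genotype = "wt", replicate = "rep1")
  expect_identical(classifyFrame(fp, ts), c(0L, 1L, 0L, 2L))
})

test_that("selection keeps only offset-table monosomes and 56-64 nt disomes", {
  ts <- toyTranscript(toyCds(40))
  cs <- unname(cdsStart(ts))
  fp <- data.frame(transcript_id = "g1",
                   five_prime_pos = cs + c(0L, 1L, 0L, 2L, 0L, 0L, 0L),
                   length = c(28L, 28L, 29L, 29L, 57L, 55L, 64L),
                   count = 1L,
                   fraction = c(rep("monosome", 4), rep("disome", 3)),
                   genotype = "wt", replicate = "rep1")
  sel <- selectFootprints(fp, ts)
  expect_identical(sel$length, c(28L, 29L, 29L, 57L, 64L))
  # 28-nt frame-1 dropped, both 29-nt frames kept, 55-nt disome dropped
  expect_identical(classifyFrame(sel, ts)[1:3], c(0L, 0L, 2L))
})

test_that("A-site assignment follows the offset arithmetic", {
  ts <- toyTranscript(toyCds(60))
  cs <- unname(cdsStart(ts))
  fp <- data.frame(transcript_id = "g1",
                   five_prime_pos = c(cs + 30L, cs + 0L),
                   length = c(28L, 60L), count = 1L,
                   fraction = c("monosome", "disome"),
                   genotype = "wt", replicate = "rep1")
  # 28-nt frame-0 at cds_start+30: A-site nt +46 -> codon 15
  # disome at cds_start: lead A site 45 nt downstream -> codon 15
  expect_identical(assignASite(fp, ts), c(15L, 15L))
  # missing offset key names the key
  fp$five_prime_pos[1] <- cs + 31L   # frame 1, not in the table
  expect_error(assignASite(fp, ts), "28 1")
  # outside the CDS -> NA marker
  fp2 <- data.frame(transcript_id = "g1", five_prime_pos = cs - 30L,
                    length = 28L, count = 1L, fraction = "monosome",
                    genotype = "wt", replicate = "rep1")
  expect_true(is.na(assignASite(fp2, ts)))
})

test_that("flat simulations are pure frame 0 and have no spurious metagene peaks", {
  cfg <- simulationConfig(seed = 17, nGenes = 40,
                          cdsLengthRange = c(100, 150), readDepth = 5e4,
                          lengthDistribution = c("28" = 1),
                          genotypes = "wt", replicates = 1)
  ts <- simulateTranscriptome(cfg)
  fp <- simulateFootprints(ts, cfg)
  sel <- selectFootprints(fp, ts)
  expect_true(all(classifyFrame(sel, ts) == 0L))
  expect_equal(sum(sel$count), sum(fp$count))  # nothing dropped
  mp <- metageneProfile(fp, ts, "stop", window = c(-50L, -25L))
  p <- profileTable(mp)
  internal <- p$value[p$value > 0]
  expect_lt(max(internal), 3 * median(internal))
})

test_that("termination geometry yields the stop-anchored -18/-48 peak pair", {
  cfg <- simulationConfig(seed = 19, nGenes = 30,
                          cdsLengthRange = c(100, 150), readDepth = 2e4,
                          terminationReads = 2e4, genotypes = "wt",
                          replicates = 1)
  ts <- simulateTranscriptome(cfg)
  fp <- simulateFootprints(ts, cfg)
  mp <- metageneProfile(fp, ts, "stop")
  term <- profilePeak(mp)
  expect_identical(term, -18L)
  expect_identical(profilePeak(mp, range = c(-60L, term - 28L)), -48L)
})

test_that("initiating-ribosome reads peak at the configured start offset", {
  cfg <- simulationConfig(seed = 23, nGenes = 20,
                          cdsLengthRange = c(80, 120), readDepth = 0,
                          initiationReads = 5e3, genotypes = "wt",
                          replicates = 1)
  ts <- simulateTranscriptome(cfg)
  fp <- simulateFootprints(ts, cfg)
  mp <- metageneProfile(fp, ts, "start")
  expect_identical(profilePeak(mp), -12L)
})
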