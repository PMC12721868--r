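#' Simulation configuration
#'
#' Parameters of the synthetic footprint generator.  The generator encodes
#' the stalling/collision model used throughout the package: per-codon
#' dwell times, multiplicative P/A-site codon-pair dwell factors,
#' stall-induced ribosome queues with a fixed 30-nt (10-codon) 5'-to-5'
#' spacing, monosome (28/29 nt) and disome (56-64 nt) footprint geometry,
#' and termination geometry (terminating footprints 18 nt upstream of the
#' stop-anchored origin, their queued partners at 48 nt).
#'
#' @slot seed integer RNG seed; the same seed yields bit-identical output.
#' @slot nGenes number of genes.
#' @slot cdsLengthRange CDS length range in codons (start and stop codon
#'   included).
#' @slot codonUsage named probability vector over the 61 sense codons
#'   (must sum to 1 within 1e-9).
#' @slot baseDwell named per-codon relative dwell time (baseline 1).
#' @slot pairDwell data.frame(p_codon, a_codon, multiplier) of codon-pair
#'   dwell factors applied on top of \code{baseDwell}.
#' @slot stallSites data.frame(gene, codon, depth, reads, disomeReads
#'   [, genotype]) of explicit stalls; \code{depth} is the total number of
#'   stacked ribosomes (lead included), \code{reads}/\code{disomeReads} the
#'   footprint count emitted per stack member / adjacent collided pair.
#' @slot queueSpacingNt inter-ribosome 5'-to-5' spacing, default 30 nt.
#' @slot readDepth elongation footprints per library.
#' @slot lengthDistribution probability over monosome lengths, names
#'   "28"/"29"; 29-nt reads are split evenly between frames 0 and 2.
#' @slot disomeLengthRange nt range of disome footprint lengths.
#' @slot genotypes genotype labels.
#' @slot dwellOverrides named list (per genotype) of \code{baseDwell} /
#'   \code{pairDwell} overrides, e.g. a slow codon only in the mutant.
#' @slot replicates libraries per genotype.
#' @slot abundance per-gene transcript abundance (uniform if empty).
#' @slot terminationReads termination events per library (0 disables).
#' @slot termQueueProb probability that a terminating ribosome has a
#'   directly collided upstream partner.
#' @slot initiationReads initiation footprints per library (0 disables).
#' @slot initiationOffsetNt 5'-end offset of initiating-ribosome reads
#'   upstream of the start codon.
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nGenes = "integer",
    cdsLengthRange = "integer", codonUsage = "numeric",
    baseDwell = "numeric", pairDwell = "data.frame",
    stallSites = "data.frame", queueSpacingNt = "integer",
    readDepth = "numeric", lengthDistribution = "numeric",
    disomeLengthRange = "integer", genotypes = "character",
    dwellOverrides = "list", replicates = "integer",
    abundance = "numeric", terminationReads = "numeric",
    termQueueProb = "numeric", initiationReads = "numeric",
    initiationOffsetNt = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (abs(sum(object@codonUsage) - 1) > 1e-9)
    msgs <- c(msgs, "codonUsage must sum to 1 (tolerance 1e-9)")
  if (!setequal(names(object@codonUsage), senseCodons()))
    msgs <- c(msgs, "codonUsage must be named by the 61 sense codons")
  if (any(object@codonUsage < 0))
    msgs <- c(msgs, "codonUsage must be non-negative")
  if (any(object@baseDwell <= 0))
    msgs <- c(msgs, "all dwell factors must be > 0")
  if (nrow(object@pairDwell) && any(object@pairDwell$multiplier <= 0))
    msgs <- c(msgs, "pair dwell multipliers must be > 0")
  if (object@nGenes < 1L) msgs <- c(msgs, "nGenes must be >= 1")
  if (object@cdsLengthRange[1] < 5L ||
      object@cdsLengthRange[2] < object@cdsLengthRange[1])
    msgs <- c(msgs, "invalid cdsLengthRange")
  if (object@queueSpacingNt < 1L)
    msgs <- c(msgs, "queueSpacingNt must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SimulationConfig constructor with the package defaults.
#' @param seed,nGenes,cdsLengthRange,codonUsage,baseDwell,pairDwell,stallSites
#'   see slots.
#' @param queueSpacingNt,readDepth,lengthDistribution,disomeLengthRange see
#'   slots.
#' @param genotypes,dwellOverrides,replicates,abundance see slots.
#' @param terminationReads,termQueueProb,initiationReads,initiationOffsetNt
#'   see slots.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 50L,
    cdsLengthRange = c(120L, 400L),
    codonUsage = NULL, baseDwell = NULL,
    pairDwell = data.frame(p_codon = character(), a_codon = character(),
                           multiplier = numeric()),
    stallSites = data.frame(),
    queueSpacingNt = 30L, readDepth = 1e5,
    lengthDistribution = c("28" = 0.7, "29" = 0.3),
    disomeLengthRange = c(56L, 64L),
    genotypes = c("wt", "mut"), dwellOverrides = list(),
    replicates = 3L, abundance = numeric(),
    terminationReads = 0, termQueueProb = 0.5,
    initiationReads = 0, initiationOffsetNt = 12L) {
  sc <- senseCodons()
  if (is.null(codonUsage))
    codonUsage <- setNames(rep(1 / 61, 61), sc)
  else {
    names(codonUsage) <- normalizeCodon(names(codonUsage))
    if (!setequal(names(codonUsage), sc))
      stop("codonUsage must cover exactly the 61 sense codons")
    codonUsage <- codonUsage[sc]
  }
  if (is.null(baseDwell)) baseDwell <- setNames(rep(1, 61), sc)
  else {
    names(baseDwell) <- normalizeCodon(names(baseDwell))
    baseDwell <- baseDwell[sc]
    baseDwell[is.na(baseDwell)] <- 1
    names(baseDwell) <- sc
  }
  if (nrow(pairDwell)) {
    pairDwell$p_codon <- normalizeCodon(pairDwell$p_codon)
    pairDwell$a_codon <- normalizeCodon(pairDwell$a_codon)
  }
  lengthDistribution <- lengthDistribution / sum(lengthDistribution)
  new("SimulationConfig", seed = as.integer(seed),
      nGenes = as.integer(nGenes),
      cdsLengthRange = as.integer(cdsLengthRange),
      codonUsage = codonUsage, baseDwell = baseDwell,
      pairDwell = pairDwell, stallSites = as.data.frame(stallSites),
      queueSpacingNt = as.integer(queueSpacingNt),
      readDepth = readDepth, lengthDistribution = lengthDistribution,
      disomeLengthRange = as.integer(disomeLengthRange),
      genotypes = genotypes, dwellOverrides = dwellOverrides,
      replicates = as.integer(replicates), abundance = abundance,
      terminationReads = terminationReads, termQueueProb = termQueueProb,
      initiationReads = initiationReads,
      initiationOffsetNt = as.integer(initiationOffsetNt))
}

#' Generate a synthetic transcriptome
#'
#' Each CDS starts with ATG, ends with one stop codon drawn uniformly from
#' \{TAA, TAG, TGA\}, and has internal codons drawn i.i.d. from
#' \code{codonUsage}; 21-nt random flanks are added on both sides
#' (mirroring the +/-21 nt ORF extension).  Output is deterministic for a
#' given \code{seed}.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return a \code{\linkS4class{TranscriptSet}}.
#' @export
simulateTranscriptome <- function(config) {
  set.seed(config@seed)
  sc <- senseCodons()
  n <- config@nGenes
  lenPool <- seq(config@cdsLengthRange[1], config@cdsLengthRange[2])
  lens <- if (length(lenPool) == 1L) rep(lenPool, n)
          else sample(lenPool, n, replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    internal <- sample(sc, lens[i] - 2L, replace = TRUE,
                       prob = config@codonUsage)
    stopc <- sample(stopCodons(), 1L)
    flank5 <- paste(sample(c("A", "C", "G", "T"), 21L, replace = TRUE),
                    collapse = "")
    flank3 <- paste(sample(c("A", "C", "G", "T"), 21L, replace = TRUE),
                    collapse = "")
    seqs[i] <- paste0(flank5, "ATG", paste(internal, collapse = ""),
                      stopc, flank3)
  }
  names(seqs) <- sprintf("g%04d", seq_len(n))
  TranscriptSet(seqs, rep(21L, n), 21L + 3L * lens)
}

## Merge base dwell/pair tables with per-genotype overrides.
genotypeDwell <- function(config, genotype) {
  bd <- config@baseDwell
  pd <- config@pairDwell
  ov <- config@dwellOverrides[[genotype]]
  if (!is.null(ov)) {
    if (!is.null(ov$baseDwell)) {
      nm <- normalizeCodon(names(ov$baseDwell))
      bd[nm] <- ov$baseDwell
    }
    if (!is.null(ov$pairDwell)) {
      op <- ov$pairDwell
      op$p_codon <- normalizeCodon(op$p_codon)
      op$a_codon <- normalizeCodon(op$a_codon)
      pd <- rbind(pd[!(paste(pd$p_codon, pd$a_codon) %in%
                       paste(op$p_codon, op$a_codon)), , drop = FALSE], op)
    }
  }
  list(baseDwell = bd, pairDwell = pd)
}

#' Simulate footprint libraries
#'
#' Emits monosome and disome footprint records per genotype x replicate.
#' Elongation footprints are sampled multinomially over (gene, codon) cells
#' with probability proportional to transcript abundance x codon dwell x
#' codon-pair dwell factor; each sampled A-site codon is emitted at the 5'
#' position in the configured frame that the offset rule maps back to that
#' codon.  Explicit stall sites additionally emit a ribosome stack (lead +
#' queued members 30 nt apart) and a disome for each adjacent collided
#' pair, 45 nt upstream of the leading ribosome's A site.  Termination
#' geometry emits terminating footprints at stop-anchored position -18 and
#' queued partners at -48.
#'
#' The returned table carries two provenance columns beyond the canonical
#' footprint format: \code{origin} (elongation, stall_lead, stall_queued,
#' termination, term_queue, initiation, disome) and \code{source_codon},
#' the A-site codon each footprint was emitted from (for disomes, the lead
#' ribosome of the collided pair).  \code{\link{writeFootprints}} drops
#' them.
#'
#' RNG consumption order is fixed: genotypes in configuration order,
#' replicates within genotype; within a library, the elongation multinomial
#' is drawn first, then the length/frame split, termination counts, the
#' termination-queue binomial, and disome length assignments.
#'
#' @param ts a \code{\linkS4class{TranscriptSet}} (typically from
#'   \code{\link{simulateTranscriptome}}).
#' @param config a \code{SimulationConfig}.
#' @param geometry geometry constants from \code{\link{riboGeometry}}.
#' @return data.frame of footprint records with provenance columns.
#' @export
simulateFootprints <- function(ts, config,
                               geometry = riboGeometry(config@queueSpacingNt)) {
  set.seed(config@seed)
  ids <- transcriptIds(ts)
  n <- length(ids)
  lens <- cdsLengthCodons(ts)
  cs <- cdsStart(ts)
  ce <- cdsEnd(ts)
  abund <- if (length(config@abundance)) config@abundance else rep(1, n)
  if (length(abund) != n) stop("abundance length must equal nGenes")
  codonL <- cdsCodonList(ts)
  spacing <- geometry$queueSpacingNt
  disOff <- geometry$disomeOffsetNt

  ## (gene, codon) elongation cells: codons 0..l-2 (stop decoded only at
  ## termination)
  cellGene <- rep.int(seq_len(n), lens - 1L)
  cellCodon <- unlist(lapply(lens - 1L, function(m) seq_len(m) - 1L),
                      use.names = FALSE)
  cellId <- unlist(lapply(codonL, function(cc) cc[-length(cc)]),
                   use.names = FALSE)
  cellPrev <- unlist(lapply(codonL, function(cc)
    c(NA_character_, cc[-c(length(cc) - 1L, length(cc))])),
    use.names = FALSE)

  st <- config@stallSites
  if (nrow(st)) {
    if (!all(c("gene", "codon", "depth") %in% names(st)))
      stop("stallSites needs columns gene, codon, depth")
    if (is.character(st$gene)) {
      st$gene <- match(st$gene, ids)
      if (anyNA(st$gene)) stop("stall site on unknown transcript id")
    }
    if (is.null(st$reads)) st$reads <- 100L
    if (is.null(st$disomeReads)) st$disomeReads <- st$reads
    if (is.null(st$genotype)) st$genotype <- NA_character_
    gl <- lens[st$gene]
    if (anyNA(gl) || any(st$codon < 0L | st$codon >= gl))
      stop("stall site outside CDS")
    minFp <- cs[st$gene] + 3L * st$codon - 15L - (st$depth - 1L) * spacing
    minDi <- cs[st$gene] + 3L * st$codon - disOff -
      pmax(st$depth - 2L, 0L) * spacing
    if (any(pmin(minFp, ifelse(st$depth > 1L, minDi, minFp)) < 0L))
      stop("stall site outside CDS: queued footprints would fall off the ",
           "transcript 5' end")
  }

  ld <- config@lengthDistribution
  p28 <- if ("28" %in% names(ld)) ld[["28"]] else 0
  out <- vector("list", 0L)
  emit <- function(gene, p5, len, count, fraction, origin, src,
                   genotype, replicate) {
    nn <- length(count)
    gene <- rep_len(gene, nn); p5 <- rep_len(p5, nn)
    len <- rep_len(len, nn); origin <- rep_len(origin, nn)
    src <- rep_len(src, nn)
    keep <- count > 0L
    if (!any(keep)) return(NULL)
    data.frame(transcript_id = ids[gene][keep],
               five_prime_pos = as.integer(p5[keep]),
               length = as.integer(len[keep]),
               count = as.integer(count[keep]),
               fraction = fraction, genotype = genotype,
               replicate = replicate,
               origin = origin[keep], source_codon = as.integer(src[keep]),
               stringsAsFactors = FALSE)
  }

  for (g in config@genotypes) {
    dw <- genotypeDwell(config, g)
    w <- abund[cellGene] * dw$baseDwell[cellId]
    if (nrow(dw$pairDwell)) {
      pk <- paste(dw$pairDwell$p_codon, dw$pairDwell$a_codon)
      m <- match(paste(cellPrev, cellId), pk)
      w <- w * ifelse(is.na(m), 1, dw$pairDwell$multiplier[m])
    }
    stG <- if (nrow(st))
      st[is.na(st$genotype) | st$genotype == g, , drop = FALSE]
    else st
    for (r in seq_len(config@replicates)) {
      rep_id <- paste0("rep", r)
      lib <- list()
      if (config@readDepth > 0) {
        cnt <- as.integer(rmultinom(1L, config@readDepth, w))
        nz <- which(cnt > 0L)
        n28 <- rbinom(length(nz), cnt[nz], p28)
        rest <- cnt[nz] - n28
        n29f2 <- rbinom(length(nz), rest, 0.5)
        n29f0 <- rest - n29f2
        gene <- cellGene[nz]; k <- cellCodon[nz]
        lib$el28 <- emit(gene, emitFivePrime(cs[gene], k, 0L, 16L), 28L,
                         n28, "monosome", "elongation", k, g, rep_id)
        lib$el29a <- emit(gene, emitFivePrime(cs[gene], k, 0L, 16L), 29L,
                          n29f0, "monosome", "elongation", k, g, rep_id)
        lib$el29b <- emit(gene, emitFivePrime(cs[gene], k, 2L, 17L), 29L,
                          n29f2, "monosome", "elongation", k, g, rep_id)
      }
      if (config@terminationReads > 0) {
        tg <- as.integer(rmultinom(1L, config@terminationReads,
                                   abund / sum(abund)))
        qg <- rbinom(n, tg, config@termQueueProb)
        gene <- seq_len(n)
        lib$term <- emit(gene, ce - geometry$termFivePrimeNt, 28L, tg,
                         "monosome", "termination", lens - 1L, g, rep_id)
        lib$termq <- emit(gene,
                          ce - geometry$termFivePrimeNt - spacing, 28L, qg,
                          "monosome", "term_queue",
                          lens - 1L - spacing %/% 3L, g, rep_id)
      }
      if (config@initiationReads > 0) {
        ig <- as.integer(rmultinom(1L, config@initiationReads,
                                   abund / sum(abund)))
        lib$init <- emit(seq_len(n), cs - config@initiationOffsetNt, 28L,
                         ig, "monosome", "initiation", 0L, g, rep_id)
      }
      if (nrow(stG)) {
        for (s in seq_len(nrow(stG))) {
          gi <- stG$gene[s]; k <- stG$codon[s]; d <- stG$depth[s]
          m <- seq_len(d) - 1L
          lead5 <- emitFivePrime(cs[gi], k, 0L, 16L)
          lib[[paste0("st", s)]] <- emit(
            rep(gi, d), lead5 - m * spacing, 28L,
            rep(stG$reads[s], d), "monosome",
            ifelse(m == 0L, "stall_lead", "stall_queued"),
            k - (m * spacing) %/% 3L, g, rep_id)
          if (d > 1L && stG$disomeReads[s] > 0L) {
            dlens <- seq(config@disomeLengthRange[1],
                         config@disomeLengthRange[2])
            for (mm in seq_len(d - 1L)) {
              dl <- as.integer(rmultinom(1L, stG$disomeReads[s],
                                         rep(1, length(dlens))))
              lib[[paste0("di", s, "_", mm)]] <- emit(
                rep(gi, length(dlens)),
                rep(cs[gi] + 3L * k - disOff - (mm - 1L) * spacing,
                    length(dlens)),
                dlens, dl, "disome", "disome",
                rep(k - ((mm - 1L) * spacing) %/% 3L, length(dlens)),
                g, rep_id)
            }
          }
        }
      }
      out[[length(out) + 1L]] <- do.call(rbind, lib)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
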