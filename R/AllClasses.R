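#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet GENETIC_CODE
#' @importFrom stats median optimize optim pt p.adjust rbinom rmultinom
#'   rnbinom rlnorm pchisq binom.test fisher.test ks.test wilcox.test
#'   setNames quantile dnbinom mad sd ave glm Gamma coef dnorm
#' @importFrom utils read.delim write.table head
NULL

#' Transcript models with CDS coordinates
#'
#' A set of transcript sequences together with 0-based, half-open CDS
#' coordinates in transcript space.  The CDS includes the stop codon and its
#' length must be divisible by 3; at least 21 nt of flanking sequence is
#' required on both sides so that footprints around start and stop codons
#' (the +/-21 nt ORF extension used during alignment) stay inside the
#' transcript.
#'
#' @slot sequences \code{DNAStringSet} of transcript sequences, named by
#'   transcript id.
#' @slot cdsStart integer vector, 0-based first nt of the CDS per transcript.
#' @slot cdsEnd integer vector, 0-based position one past the last CDS nt.
#' @export
setClass("TranscriptSet",
  representation(sequences = "DNAStringSet",
                 cdsStart = "integer",
                 cdsEnd = "integer"))

setValidity("TranscriptSet", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "sequences must have unique names (transcript ids)")
  if (length(object@cdsStart) != n || length(object@cdsEnd) != n)
    msgs <- c(msgs, "cdsStart/cdsEnd length must match number of sequences")
  else {
    len <- object@cdsEnd - object@cdsStart
    bad <- which(len %% 3L != 0L | len <= 0L)
    if (length(bad))
      msgs <- c(msgs, paste0("CDS length not a positive multiple of 3 for: ",
                             paste(ids[head(bad, 5)], collapse = ", ")))
    bad <- which(object@cdsStart < 21L |
                 Biostrings::width(object@sequences) < object@cdsEnd + 21L)
    if (length(bad))
      msgs <- c(msgs, paste0("less than 21 nt flank around the CDS for: ",
                             paste(ids[head(bad, 5)], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TranscriptSet constructor.
#' @param sequences named \code{DNAStringSet} (or character vector).
#' @param cdsStart,cdsEnd integer CDS bounds (0-based, half-open).
#' @export
TranscriptSet <- function(sequences, cdsStart, cdsEnd) {
  if (!is(sequences, "DNAStringSet")) sequences <- DNAStringSet(sequences)
  new("TranscriptSet", sequences = sequences,
      cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
}

#' @describeIn TranscriptSet transcript identifiers.
#' @param x a \code{TranscriptSet}.
#' @export
transcriptIds <- function(x) names(x@sequences)

#' @describeIn TranscriptSet named vector of CDS start positions.
#' @export
cdsStart <- function(x) setNames(x@cdsStart, transcriptIds(x))

#' @describeIn TranscriptSet named vector of CDS end positions.
#' @export
cdsEnd <- function(x) setNames(x@cdsEnd, transcriptIds(x))

#' @describeIn TranscriptSet named vector of CDS lengths in codons
#'   (stop codon included).
#' @export
cdsLengthCodons <- function(x)
  setNames((x@cdsEnd - x@cdsStart) %/% 3L, transcriptIds(x))

setMethod("show", "TranscriptSet", function(object) {
  n <- length(object@sequences)
  l <- cdsLengthCodons(object)
  cat("TranscriptSet with", n, "transcripts\n")
  if (n) cat("  CDS length (codons): ", min(l), "-", max(l), "\n", sep = "")
})

#' A-site offset table
#'
#' Maps (footprint length, reading frame) to the nt offset from the 5' end of
#' a monosome footprint to the ribosomal A site, plus the fixed 5'-to-lead-
#' A-site offset for disome footprints.  Defaults are the empirically chosen
#' monosome offsets {(28,0)->16, (29,0)->16, (29,2)->17} and a disome offset
#' of 45 nt.
#'
#' @slot entries data.frame with columns \code{length}, \code{frame},
#'   \code{offset}.
#' @slot disomeOffset integer, nt from disome 5' end to the lead ribosome's
#'   A site.
#' @export
setClass("OffsetTable",
  representation(entries = "data.frame", disomeOffset = "integer"))

setValidity("OffsetTable", function(object) {
  e <- object@entries
  if (!all(c("length", "frame", "offset") %in% names(e)))
    return("entries needs columns length, frame, offset")
  if (anyDuplicated(e[c("length", "frame")]))
    return("duplicate (length, frame) keys")
  if (!all(e$frame %in% 0:2)) return("frame must be in {0,1,2}")
  TRUE
})

setMethod("show", "OffsetTable", function(object) {
  cat("OffsetTable:", nrow(object@entries), "monosome keys; disome offset",
      object@disomeOffset, "nt\n")
  print(object@entries, row.names = FALSE)
})

#' Metagene profile of footprint 5' ends
#'
#' Footprint 5'-end density relative to a common anchor across transcripts.
#' Anchor conventions: \code{"start"} puts the A of the AUG at position 0;
#' \code{"stop"} puts the last nucleotide of the stop codon at position -1.
#'
#' @slot profile data.frame with columns \code{position}, \code{value} and
#'   optionally \code{length}, \code{frame}.
#' @slot anchor \code{"start"} or \code{"stop"}.
#' @export
setClass("MetaProfile",
  representation(profile = "data.frame", anchor = "character"))

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile anchored at the", object@anchor, "codon;",
      nrow(object@profile), "rows\n")
  p <- object@profile
  top <- p[order(-p$value), , drop = FALSE]
  cat("  top positions:",
      paste(head(top$position, 3), collapse = ", "), "\n")
})

#' @describeIn MetaProfile profile table accessor.
#' @param x a \code{MetaProfile} or \code{SiteProfile}.
#' @export
profileTable <- function(x) x@profile

#' Site-aligned occupancy profile
#'
#' Mean occupancy (pause score or footprint density) at codon positions
#' relative to a set of aligned sites; position 0 is the A-site codon of the
#' (first stalled) ribosome at the site of interest.  The band columns hold
#' the across-replicate dispersion (min/max by default).
#'
#' @slot profile data.frame with columns \code{position}, \code{mean},
#'   \code{lo}, \code{hi}.
#' @slot nSites number of aligned site instances.
#' @export
setClass("SiteProfile",
  representation(profile = "data.frame", nSites = "integer"))

setMethod("show", "SiteProfile", function(object) {
  cat("SiteProfile over", object@nSites, "site instances;",
      nrow(object@profile), "positions\n")
})

#' Per-gene, per-codon-position A-site occupancy
#'
#' Long-format A-site read counts per (gene, codon position), with the codon
#' identity at each position and an inclusion flag for the trimmed analysis
#' window (15 codons excluded at both CDS ends by default).  Zero-count
#' positions are materialised so per-gene vectors are complete.
#'
#' @slot data data.frame with columns \code{gene}, \code{pos}, \code{codon},
#'   \code{count}, \code{included}.
#' @slot trim integer, codons excluded at each CDS end.
#' @slot cdsLen named integer vector, CDS length in codons per gene.
#' @export
setClass("CodonOccupancy",
  representation(data = "data.frame", trim = "integer", cdsLen = "integer"))

setMethod("show", "CodonOccupancy", function(object) {
  cat("CodonOccupancy:", length(object@cdsLen), "genes,",
      sum(object@data$count), "assigned reads, trim", object@trim, "\n")
})

#' @describeIn CodonOccupancy long-format occupancy table accessor.
#' @param x a \code{CodonOccupancy}.
#' @export
occupancyTable <- function(x) x@data

#' P-site x A-site codon-pair matrix
#'
#' 61 x 61 grid over sense codons, rows = P-site codon, columns = A-site
#' codon.  Holds the mean pause score (or mutant/wild-type ratio) per pair,
#' the number of contributing codon-pair instances, and a display copy
#' clamped at a ceiling (ratios >= 2 are shown as 2).
#'
#' @slot mean numeric 61x61 matrix (NA where no instance exists).
#' @slot count numeric 61x61 matrix of contributing instances.
#' @slot clamped numeric 61x61 display copy (NA if not a ratio matrix).
#' @export
setClass("DicodonMatrix",
  representation(mean = "matrix", count = "matrix", clamped = "matrix"))

setMethod("show", "DicodonMatrix", function(object) {
  def <- sum(!is.na(object@mean))
  cat("DicodonMatrix: 61 x 61,", def, "populated cells\n")
})
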