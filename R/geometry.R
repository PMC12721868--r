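#' Default A-site offset table
#'
#' The monosome selection used throughout the package: 28-nt frame-0 reads
#' (A-site offset 16 nt), 29-nt frame-0 reads (offset 16 nt) and 29-nt
#' frame-2 reads (offset 17 nt).  Disome footprints are assigned 45 nt
#' downstream of their 5' end (the lead, stalled ribosome's A site).
#'
#' The A-site nucleotide of a footprint is \code{five_prime_pos + offset};
#' the codon index is \code{floor((a_site_nt - cds_start)/3)}, so the offset
#' need not point at a codon boundary.
#'
#' @param disomeOffset nt from disome 5' end to the lead A site (default 45).
#' @return an \code{\linkS4class{OffsetTable}}.
#' @export
defaultOffsets <- function(disomeOffset = 45L) {
  new("OffsetTable",
      entries = data.frame(length = c(28L, 29L, 29L),
                           frame = c(0L, 0L, 2L),
                           offset = c(16L, 16L, 17L)),
      disomeOffset = as.integer(disomeOffset))
}

#' Ribosome footprint geometry model
#'
#' The fixed geometric constants of the stalling/collision model:
#' \itemize{
#'   \item \code{queueSpacingNt}: 5'-to-5' distance between collided
#'     ribosomes, 30 nt = one 28-nt footprint + a 2-nt gap (the stop-codon
#'     arithmetic 48 = 28 + 2 + 18), i.e. 10 codons.
#'   \item \code{disomeOffsetNt}: 45 nt from a disome 5' end to the lead
#'     ribosome's A site.
#'   \item \code{terminationASiteNt}: a terminating ribosome accommodates
#'     4 nt in its A site during stop-codon recognition, shifting its
#'     footprint 5' end by +1 nt relative to elongation geometry.
#'   \item \code{termFivePrimeNt}: resulting distance from the terminating
#'     footprint 5' end to the stop-anchored origin, 18 nt (a queued partner
#'     sits one spacing further at 48 nt).
#' }
#'
#' @param queueSpacingNt inter-ribosome 5'-to-5' spacing in nt.
#' @param offsets an \code{\linkS4class{OffsetTable}}.
#' @return a list with the geometry constants.
#' @export
riboGeometry <- function(queueSpacingNt = 30L, offsets = defaultOffsets()) {
  list(offsets = offsets,
       queueSpacingNt = as.integer(queueSpacingNt),
       disomeOffsetNt = offsets@disomeOffset,
       terminationASiteNt = 4L,
       termFivePrimeNt = 18L)
}

## 5' position emitting a footprint whose A site is codon k of gene,
## for a given (length, frame, offset): the unique position p with
## (p - cds_start) %% 3 == frame and floor((p + offset - cds_start)/3) == k.
emitFivePrime <- function(cdsStart, codon, frame, offset) {
  base <- cdsStart + 3L * codon - offset
  base + (frame - (base - cdsStart)) %% 3L
}
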