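#' Reading-frame classification
#'
#' A footprint is in frame 0/1/2 if its 5' end maps to the first/second/
#' third nucleotide of a codon; positions upstream of the CDS use the same
#' modulus extended leftward.
#'
#' @param fp footprint data.frame.
#' @param ts a \code{\linkS4class{TranscriptSet}}.
#' @return integer vector of frames in \{0,1,2\}.
#' @export
classifyFrame <- function(fp, ts) {
  cs <- cdsStart(ts)[fp$transcript_id]
  as.integer((fp$five_prime_pos - cs) %% 3L)
}

#' Footprint selection
#'
#' Keeps monosome records whose (length, frame) is a key of the offset table
#' and disome records whose length lies in the disome selection range
#' (56-64 nt by default); counts are unchanged.
#'
#' @param fp footprint data.frame.
#' @param ts a \code{TranscriptSet}.
#' @param offsets an \code{\linkS4class{OffsetTable}}.
#' @param disomeRange nt range of disome lengths to keep.
#' @return the filtered footprint data.frame.
#' @export
selectFootprints <- function(fp, ts, offsets = defaultOffsets(),
                             disomeRange = c(56L, 64L)) {
  frame <- classifyFrame(fp, ts)
  key <- paste(fp$length, frame)
  monoKeys <- paste(offsets@entries$length, offsets@entries$frame)
  keep <- ifelse(fp$fraction == "monosome",
                 key %in% monoKeys,
                 fp$length >= disomeRange[1] & fp$length <= disomeRange[2])
  out <- fp[keep, , drop = FALSE]
  if (!nrow(out)) warning("no footprints survive selection")
  out
}

#' A-site assignment
#'
#' Monosome footprints: A-site nucleotide = 5' end + offset(length, frame);
#' disome footprints: 5' end + the fixed disome offset (45 nt), pointing at
#' the lead (stalled) ribosome's A site.  The codon index is
#' \code{floor((a_site_nt - cds_start)/3)}; positions outside \code{[0, l)}
#' are returned as \code{NA}.
#'
#' @param fp footprint data.frame.
#' @param ts a \code{TranscriptSet}.
#' @param offsets an \code{OffsetTable}.
#' @return integer vector of 0-based codon indices (NA outside the CDS).
#' @export
assignASite <- function(fp, ts, offsets = defaultOffsets()) {
  frame <- classifyFrame(fp, ts)
  e <- offsets@entries
  key <- paste(fp$length, frame)
  monoKeys <- paste(e$length, e$frame)
  off <- integer(nrow(fp))
  mono <- fp$fraction == "monosome"
  idx <- match(key[mono], monoKeys)
  if (anyNA(idx)) {
    missing <- unique(key[mono][is.na(idx)])
    stop("no A-site offset for monosome (length frame) key(s): ",
         paste(missing, collapse = "; "))
  }
  off[mono] <- e$offset[idx]
  off[!mono] <- offsets@disomeOffset
  cs <- cdsStart(ts)[fp$transcript_id]
  codon <- (fp$five_prime_pos + off - cs) %/% 3L
  l <- cdsLengthCodons(ts)[fp$transcript_id]
  codon[codon < 0L | codon >= l] <- NA_integer_
  as.integer(codon)
}

#' Metagene profile of 5' ends
#'
#' Sums footprint counts per 5'-end position relative to a common anchor:
#' \code{"start"} aligns the A of the AUG at 0; \code{"stop"} aligns the
#' last stop-codon nucleotide at -1.  With \code{byLengthFrame = TRUE} the
#' profile is stratified per (length, frame) to expose the termination
#' frame behaviour.
#'
#' @param fp footprint data.frame (typically unselected raw records).
#' @param ts a \code{TranscriptSet}.
#' @param anchor \code{"start"} or \code{"stop"}.
#' @param byLengthFrame stratify by (length, frame)?
#' @param window integer c(min, max) relative positions retained.
#' @return a \code{\linkS4class{MetaProfile}}.
#' @export
metageneProfile <- function(fp, ts, anchor = c("start", "stop"),
                            byLengthFrame = FALSE, window = c(-60L, 60L)) {
  anchor <- match.arg(anchor)
  ref <- if (anchor == "start") cdsStart(ts) else cdsEnd(ts)
  rel <- fp$five_prime_pos - ref[fp$transcript_id]
  keep <- rel >= window[1] & rel <= window[2]
  rel <- rel[keep]
  cnt <- fp$count[keep]
  if (byLengthFrame) {
    frame <- classifyFrame(fp, ts)[keep]
    len <- fp$length[keep]
    key <- paste(rel, len, frame)
    agg <- rowsum(cnt, key)
    parts <- do.call(rbind, strsplit(rownames(agg), " "))
    prof <- data.frame(position = as.integer(parts[, 1]),
                       value = as.numeric(agg[, 1]),
                       length = as.integer(parts[, 2]),
                       frame = as.integer(parts[, 3]))
    prof <- prof[order(prof$length, prof$frame, prof$position), ]
  } else {
    agg <- rowsum(cnt, rel)
    prof <- data.frame(position = as.integer(rownames(agg)),
                       value = as.numeric(agg[, 1]))
    prof <- prof[order(prof$position), ]
  }
  rownames(prof) <- NULL
  new("MetaProfile", profile = prof, anchor = anchor)
}

#' Peak of a metagene profile
#'
#' Position of the maximum profile value, optionally restricted to a
#' position range; ties are resolved toward the position closest to the
#' anchor (smallest absolute position).
#'
#' @param profile a \code{MetaProfile}.
#' @param range optional c(min, max) restriction on positions.
#' @return the peak position (integer), or NA on an empty profile.
#' @export
profilePeak <- function(profile, range = NULL) {
  p <- profileTable(profile)
  if (!is.null(range))
    p <- p[p$position >= range[1] & p$position <= range[2], , drop = FALSE]
  if (!nrow(p)) return(NA_integer_)
  top <- p[p$value == max(p$value), , drop = FALSE]
  top$position[which.min(abs(top$position))]
}
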