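#' Read transcript annotation and sequences
#'
#' Reads a tab-separated annotation (columns \code{transcript_id},
#' \code{cds_start}, \code{cds_end}; 0-based, half-open transcript
#' coordinates) together with a transcript FASTA and returns a validated
#' \code{\linkS4class{TranscriptSet}}.  Violations (CDS length not divisible
#' by 3, missing flanks, ids absent from the FASTA) are reported with the
#' offending annotation line numbers.
#'
#' @param annotationPath path to the annotation TSV (with header).
#' @param fastaPath path to the transcript FASTA.
#' @return a \code{TranscriptSet}.
#' @export
readAnnotation <- function(annotationPath, fastaPath) {
  ann <- read.delim(annotationPath, stringsAsFactors = FALSE)
  req <- c("transcript_id", "cds_start", "cds_end")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("annotation: missing columns: ", paste(miss, collapse = ", "))
  seqs <- readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- which(!ann$transcript_id %in% names(seqs))
  if (length(bad))
    stop("annotation line(s) ", paste(head(bad, 5), collapse = ", "),
         ": transcript id not in FASTA")
  len <- ann$cds_end - ann$cds_start
  bad <- which(len %% 3L != 0L | len <= 0L)
  if (length(bad))
    stop("annotation line(s) ", paste(head(bad, 5), collapse = ", "),
         ": CDS length not a positive multiple of 3")
  seqs <- seqs[ann$transcript_id]
  TranscriptSet(seqs, ann$cds_start, ann$cds_end)
}

#' @describeIn readAnnotation write the annotation TSV and FASTA for a
#'   \code{TranscriptSet}.
#' @param ts a \code{TranscriptSet}.
#' @export
writeAnnotation <- function(ts, annotationPath, fastaPath) {
  ann <- data.frame(transcript_id = transcriptIds(ts),
                    cds_start = ts@cdsStart, cds_end = ts@cdsEnd)
  write.table(ann, annotationPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeXStringSet(ts@sequences, fastaPath)
  invisible(annotationPath)
}

#' Read and write footprint tables
#'
#' Footprint records are tab-separated with columns \code{transcript_id},
#' \code{five_prime_pos} (0-based transcript coordinate of the 5' end),
#' \code{length}, \code{count}, \code{fraction} (monosome/disome),
#' \code{genotype}, \code{replicate}.  All invariants (non-negative counts,
#' raw length ranges, known transcript ids) are validated on load and
#' violations reported with row numbers.
#'
#' @param path file path.
#' @param ts optional \code{TranscriptSet} to validate transcript ids
#'   against.
#' @return data.frame of footprint records.
#' @export
readFootprints <- function(path, ts = NULL) {
  fp <- read.delim(path, stringsAsFactors = FALSE)
  fp$replicate <- as.character(fp$replicate)
  checkFootprints(fp, ts, where = path)
}

#' @describeIn readFootprints write a footprint table (canonical columns
#'   only; simulator provenance columns are dropped).
#' @param fp footprint data.frame.
#' @export
writeFootprints <- function(fp, path) {
  cols <- c("transcript_id", "five_prime_pos", "length", "count",
            "fraction", "genotype", "replicate")
  write.table(fp[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn readFootprints write a metagene or site-aligned profile as a
#'   tab-separated table.
#' @param profile a \code{MetaProfile} or \code{SiteProfile}.
#' @export
writeProfile <- function(profile, path) {
  write.table(profileTable(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
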