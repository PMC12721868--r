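#' The 61 sense codons
#'
#' DNA-alphabet sense codons in lexicographic order; stop codons (TAA, TAG,
#' TGA) are excluded everywhere codon identities are tabulated.
#'
#' @return character vector of length 61.
#' @export
senseCodons <- function() {
  codons <- sort(names(Biostrings::GENETIC_CODE))
  setdiff(codons, stopCodons())
}

#' @describeIn senseCodons the three stop codons.
#' @export
stopCodons <- function() c("TAA", "TAG", "TGA")

## Accept RNA-style codon spellings (AUG) transparently.
normalizeCodon <- function(x) chartr("Uu", "Tt", toupper(x))

## Translate a codon vector to one-letter amino acids.
codonToAA <- function(codon) {
  unname(Biostrings::GENETIC_CODE[normalizeCodon(codon)])
}

## Per-gene character vectors of CDS codons (stop included as last codon).
cdsCodonList <- function(ts) {
  seqs <- as.character(ts@sequences)
  ids <- transcriptIds(ts)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    cds <- substr(seqs[i], ts@cdsStart[i] + 1L, ts@cdsEnd[i])
    starts <- seq(1L, nchar(cds), by = 3L)
    out[[i]] <- substring(cds, starts, starts + 2L)
  }
  out
}

## Validate a footprint data.frame; `where` names the source for messages.
## Returns the frame with canonical column types.
checkFootprints <- function(fp, ts = NULL, where = "footprints") {
  req <- c("transcript_id", "five_prime_pos", "length", "count", "fraction",
           "genotype", "replicate")
  miss <- setdiff(req, names(fp))
  if (length(miss))
    stop(where, ": missing columns: ", paste(miss, collapse = ", "))
  fp$transcript_id <- as.character(fp$transcript_id)
  fp$five_prime_pos <- as.integer(fp$five_prime_pos)
  fp$length <- as.integer(fp$length)
  fp$count <- as.integer(fp$count)
  bad <- which(fp$count < 0L)
  if (length(bad))
    stop(where, ": negative count at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(!fp$fraction %in% c("monosome", "disome"))
  if (length(bad))
    stop(where, ": fraction must be monosome/disome at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  mono <- fp$fraction == "monosome"
  bad <- which((mono & (fp$length < 25L | fp$length > 35L)) |
               (!mono & (fp$length < 50L | fp$length > 70L)))
  if (length(bad))
    stop(where, ": footprint length outside the raw monosome [25,35] / ",
         "disome [50,70] range at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  if (!is.null(ts)) {
    bad <- which(!fp$transcript_id %in% transcriptIds(ts))
    if (length(bad))
      stop(where, ": unknown transcript id at row(s) ",
           paste(head(bad, 5), collapse = ", "))
  }
  fp
}

## Vectorised two-sample Student t-test (rows of matrices a, b).
rowStudentT <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L) return(rep(NA_real_, nrow(a)))
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  sp <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  p <- 2 * pt(-abs(tt), df = n1 + n2 - 2L)
  p[!is.finite(tt)] <- NA_real_
  p
}

## Vectorised Welch t-test, one-sided alternative "a greater than b".
rowWelchGreater <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L) return(rep(NA_real_, nrow(a)))
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- pt(tt, df = df, lower.tail = FALSE)
  p[!is.finite(tt)] <- NA_real_
  p
}
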