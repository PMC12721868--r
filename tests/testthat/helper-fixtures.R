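# In-code fixtures: tiny transcripts and footprint tables built from scratch.

# One transcript of `codons` (character vector incl. ATG.. stop), 21-nt
# A-flanks, id `id`.
toyTranscript <- function(codons, id = "g1") {
  seqs <- paste0(strrep("A", 21), paste(codons, collapse = ""),
                 strrep("A", 21))
  TranscriptSet(setNames(seqs, id), 21L, 21L + 3L * length(codons))
}

# A CDS of l codons: ATG, internal `fill` codons, TAA; optional substitutions
# at 0-based codon positions via `at` (named list pos -> codon).
toyCds <- function(l, fill = "GCT", at = list()) {
  cod <- c("ATG", rep(fill, l - 2L), "TAA")
  for (p in names(at)) cod[as.integer(p) + 1L] <- at[[p]]
  cod
}

# Frame-0 28-nt monosome footprints putting `counts[k+1]` reads on A-site
# codon k (0-based) of the single transcript in `ts`.
toyFootprints <- function(ts, counts, genotype = "wt", replicate = "rep1") {
  l <- unname(cdsLengthCodons(ts))
  stopifnot(length(counts) == l)
  data.frame(transcript_id = transcriptIds(ts),
             five_prime_pos = unname(cdsStart(ts)) + 3L * (seq_len(l) - 1L) - 15L,
             length = 28L, count = as.integer(counts),
             fraction = "monosome", genotype = genotype,
             replicate = replicate, stringsAsFactors = FALSE)
}

toyOccupancy <- function(ts, counts, ...) {
  buildOccupancy(toyFootprints(ts, counts, ...), ts)
}

# Split a simulated footprint table into per-replicate lists by genotype.
splitReps <- function(fp, genotype) {
  sub <- fp[fp$genotype == genotype, , drop = FALSE]
  split(sub, sub$replicate)
}

occList <- function(fp, ts, genotype) {
  lapply(splitReps(fp, genotype),
         function(x) buildOccupancy(selectFootprints(x, ts), ts))
}
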