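#' Locate codon or codon-pair sites
#'
#' Finds every occurrence of a codon (e.g. "AAA") or an ordered P/A-site
#' codon pair (e.g. "CGA-CAA") in the trimmed CDS regions.  The reported
#' position is the A-site codon (the second codon of a pair), i.e. the
#' alignment origin for site-aligned profiles.
#'
#' @param ts a \code{\linkS4class{TranscriptSet}}.
#' @param query a codon or "P-A" pair string (DNA or RNA spelling).
#' @param excludeEnds codons excluded at both CDS ends.
#' @return data.frame(gene, pos).
#' @export
locateSites <- function(ts, query, excludeEnds = 15L) {
  parts <- normalizeCodon(strsplit(query, "-", fixed = TRUE)[[1]])
  codonL <- cdsCodonList(ts)
  out <- lapply(transcriptIds(ts), function(id) {
    cc <- codonL[[id]]
    l <- length(cc)
    lo <- excludeEnds
    hi <- l - excludeEnds - 1L
    if (length(parts) == 1L) {
      pos <- which(cc == parts) - 1L
    } else {
      pos <- which(cc[-l] == parts[1] & cc[-1] == parts[2])  # A-site index
    }
    pos <- pos[pos >= lo & pos <= hi]
    if (length(pos)) data.frame(gene = id, pos = pos) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    warning("no instances of ", query, " found")
    out <- data.frame(gene = character(), pos = integer())
  }
  out
}

## Long-format (gene, pos, value) table of raw A-site counts.
occupancyValues <- function(occ) {
  data.frame(gene = occ@data$gene, pos = occ@data$pos,
             value = occ@data$count, stringsAsFactors = FALSE)
}

## Mean profile of one replicate's value table over site instances.
siteProfileOne <- function(tab, ts, sites, window) {
  lens <- cdsLengthCodons(ts)
  need <- -window[1]
  keep <- sites$pos + window[1] >= 0L &
    sites$pos + window[2] <= lens[sites$gene] - 1L
  sites <- sites[keep, , drop = FALSE]
  if (!nrow(sites)) return(NULL)
  offs <- seq(window[1], window[2])
  key <- paste(tab$gene, tab$pos)
  m <- matrix(NA_real_, nrow(sites), length(offs))
  for (j in seq_along(offs)) {
    m[, j] <- tab$value[match(paste(sites$gene, sites$pos + offs[j]), key)]
  }
  list(mean = colMeans(m, na.rm = TRUE), offs = offs, n = nrow(sites))
}

#' Site-aligned occupancy profile
#'
#' Aligns all instances of a codon/codon-pair query (or an explicit site
#' table) at position 0 and averages the supplied per-position values
#' (pause scores or A-site counts) per relative codon position; the band
#' is the across-replicate dispersion of the per-replicate means (min/max
#' by default, or sd).  Instances whose window leaves the CDS are skipped.
#'
#' @param valueTables list (replicates) of data.frames (gene, pos, value),
#'   e.g. from \code{\link{pauseScores}} (rename \code{score} to
#'   \code{value}) or raw occupancy counts.
#' @param ts a \code{\linkS4class{TranscriptSet}}.
#' @param sites query string (see \code{\link{locateSites}}) or an explicit
#'   data.frame(gene, pos).
#' @param window relative codon range c(lo, hi), default -35..10.
#' @param band \code{"range"} (min/max) or \code{"sd"}.
#' @return a \code{\linkS4class{SiteProfile}}.
#' @export
alignAtSites <- function(valueTables, ts, sites, window = c(-35L, 10L),
                         band = c("range", "sd")) {
  band <- match.arg(band)
  if (is.character(sites)) sites <- locateSites(ts, sites)
  if (!nrow(sites)) {
    warning("query matched no usable site instances; empty profile")
    return(new("SiteProfile",
               profile = data.frame(position = integer(), mean = numeric(),
                                    lo = numeric(), hi = numeric()),
               nSites = 0L))
  }
  per <- lapply(valueTables, siteProfileOne, ts = ts, sites = sites,
                window = window)
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) {
    warning("all site instances fall too close to CDS ends")
    return(new("SiteProfile",
               profile = data.frame(position = integer(), mean = numeric(),
                                    lo = numeric(), hi = numeric()),
               nSites = 0L))
  }
  m <- vapply(per, function(x) x$mean, numeric(length(per[[1]]$offs)))
  m <- matrix(m, ncol = length(per))
  avg <- rowMeans(m, na.rm = TRUE)
  if (band == "range") {
    lo <- apply(m, 1L, min, na.rm = TRUE)
    hi <- apply(m, 1L, max, na.rm = TRUE)
  } else {
    s <- apply(m, 1L, sd, na.rm = TRUE)
    lo <- avg - s; hi <- avg + s
  }
  new("SiteProfile",
      profile = data.frame(position = per[[1]]$offs, mean = avg,
                           lo = lo, hi = hi),
      nSites = per[[1]]$n)
}

#' Disome occupancy aligned at sites of interest
#'
#' Each length-selected (56-64 nt) disome footprint is assigned to the A
#' site of its stalled lead ribosome, 45 nt downstream of the disome 5'
#' end, and contributes its count at the relative codon position
#' (assigned codon - site codon).  The profile is the mean count per site
#' instance.
#'
#' @param fp footprint data.frame (disome fraction rows are used).
#' @param ts a \code{\linkS4class{TranscriptSet}}.
#' @param sites query string or data.frame(gene, pos).
#' @param offsets an \code{\linkS4class{OffsetTable}}.
#' @param window relative codon range, default -40..10.
#' @return a \code{\linkS4class{SiteProfile}}.
#' @export
disomeSiteProfile <- function(fp, ts, sites, offsets = defaultOffsets(),
                              window = c(-40L, 10L)) {
  if (is.character(sites)) sites <- locateSites(ts, sites)
  fp <- fp[fp$fraction == "disome", , drop = FALSE]
  fp <- selectFootprints(fp, ts, offsets)
  k <- assignASite(fp, ts, offsets)
  ok <- !is.na(k)
  fp <- fp[ok, , drop = FALSE]; k <- k[ok]
  offs <- seq(window[1], window[2])
  vals <- setNames(rep(0, length(offs)), offs)
  for (i in seq_len(nrow(sites))) {
    sel <- fp$transcript_id == sites$gene[i]
    rel <- k[sel] - sites$pos[i]
    use <- rel >= window[1] & rel <= window[2]
    if (any(use)) {
      agg <- rowsum(fp$count[sel][use], rel[use])
      vals[rownames(agg)] <- vals[rownames(agg)] + agg[, 1]
    }
  }
  n <- max(nrow(sites), 1L)
  new("SiteProfile",
      profile = data.frame(position = offs, mean = as.numeric(vals) / n,
                           lo = NA_real_, hi = NA_real_),
      nSites = nrow(sites))
}

#' Detect queueing peaks at fixed ribosome spacing
#'
#' Scans a site-aligned profile for local maxima at negative multiples of
#' the collided-ribosome spacing (10 codons; +-1 codon tolerance absorbs
#' offset rounding) that exceed \code{minFold} times the profile median.
#' Returns the peak positions ordered from the site outward
#' (-10, -20, ...).
#'
#' @param profile a \code{SiteProfile}, \code{MetaProfile} or
#'   data.frame(position, mean/value).
#' @param spacing expected inter-peak spacing in codons (default 10).
#' @param minFold required fold over the profile median (default 2).
#' @param tol position tolerance in codons.
#' @return integer vector of queueing-peak positions (possibly empty).
#' @export
detectQueuePeaks <- function(profile, spacing = 10L, minFold = 2,
                             tol = 1L) {
  p <- if (is.data.frame(profile)) profile else profileTable(profile)
  valcol <- if ("mean" %in% names(p)) "mean" else "value"
  pos <- p$position
  val <- p[[valcol]]
  med <- median(val, na.rm = TRUE)
  thresh <- if (med > 0) minFold * med else 0
  peaks <- integer()
  m <- 1L
  repeat {
    target <- -m * spacing
    if (target < min(pos)) break
    win <- which(pos >= target - tol & pos <= target + tol)
    if (length(win)) {
      j <- win[which.max(val[win])]
      neighbours <- val[pos %in% c(pos[j] - 1L, pos[j] + 1L)]
      isMax <- all(val[j] >= neighbours, na.rm = TRUE)
      if (isMax && !is.na(val[j]) && val[j] > thresh)
        peaks <- c(peaks, pos[j])
    }
    m <- m + 1L
  }
  peaks
}
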