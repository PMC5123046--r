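## ---------------------------------------------------------------------------
## Assembly statistics: Nxx/Lxx, gap fraction, genome recovery rate,
## novel-region detection from unmapped-read coverage.
## ---------------------------------------------------------------------------

#' Nxx length and Lxx count of a fragment length set
#'
#' \code{Nxx} is the largest length L such that fragments of length >= L sum
#' to at least x\% of the total included length; \code{Lxx} is the number of
#' fragments at least that long. Fragments shorter than \code{minLen} are
#' excluded from both the candidates and the denominator (the ">= 200 bp"
#' convention of assembly reports).
#'
#' @param lengths positive integer vector of fragment lengths.
#' @param x percentage in (0, 100); may be a vector.
#' @param minLen minimum fragment length included (default 200).
#' @return data.frame with columns \code{x}, \code{Nxx}, \code{Lxx}.
#' @examples
#' nxxLxx(c(5, 4, 3, 2, 1), 50, minLen = 0)   # N50 = 4, L50 = 2
#' @export
nxxLxx <- function(lengths, x, minLen = 200L) {
  lengths <- as.numeric(lengths)
  if (any(lengths <= 0)) stop("fragment lengths must be positive")
  inc <- sort(lengths[lengths >= minLen], decreasing = TRUE)
  if (!length(inc)) stop("no fragments pass the length cutoff")
  if (any(x <= 0 | x >= 100)) stop("x must be in (0, 100)")
  cs <- cumsum(inc)
  total <- cs[length(cs)]
  res <- vapply(x, function(xi) {
    i <- which(cs >= xi / 100 * total)[1L]
    N <- inc[i]
    c(N, sum(inc >= N))
  }, numeric(2))
  data.frame(x = x, Nxx = res[1L, ], Lxx = as.integer(res[2L, ]))
}

#' Standard assembly statistics table
#'
#' N50..N90/L50..L90, longest fragment, totals at two length cutoffs, and
#' gap percentage, computed from an assembly's sequences.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or numeric lengths, in which
#'   case gap statistics are omitted).
#' @param xs percentages to report.
#' @param minLen inclusion cutoff for the Nxx denominator.
#' @return list with \code{nxx} (data.frame), \code{longest},
#'   \code{total200} (total length of fragments >= 200 bp),
#'   \code{total10k}, and \code{gapPercent} (of total assembly length; NA
#'   for bare lengths).
#' @export
assemblyStats <- function(seqs, xs = c(50, 60, 70, 80, 90), minLen = 200L) {
  if (is.numeric(seqs)) {
    lens <- seqs
    gapPercent <- NA_real_
  } else {
    lens <- Biostrings::width(seqs)
    gapPercent <- gapFraction(seqs, mode = "assembly")
  }
  list(nxx = nxxLxx(lens, xs, minLen = minLen),
       longest = max(lens),
       total200 = sum(lens[lens >= 200L]),
       total10k = sum(lens[lens >= 10000L]),
       gapPercent = gapPercent)
}

#' Gap (N-base) percentage of an assembly
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param mode \code{"assembly"} divides the N count by the total assembly
#'   length; \code{"genome"} divides by a supplied expected genome size (the
#'   two conventions both appear in assembly reports).
#' @param expectedSize expected genome size in bp (required for
#'   \code{mode = "genome"}).
#' @return percentage of gap bases.
#' @export
gapFraction <- function(seqs, mode = c("assembly", "genome"),
                        expectedSize = NULL) {
  mode <- match.arg(mode)
  nN <- sum(Biostrings::letterFrequency(seqs, "N")[, 1L])
  denom <- if (mode == "assembly") sum(Biostrings::width(seqs)) else {
    if (is.null(expectedSize))
      stop("expectedSize required for mode = 'genome'")
    expectedSize
  }
  100 * nN / denom
}

#' Genome recovery rate of an assembly alignment
#'
#' The fraction of the reference's non-gap bases covered by the union of
#' alignment intervals, as a percentage.
#'
#' @param intervals data.frame of alignment intervals on reference
#'   coordinates: \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open).
#' @param mask data.frame of non-gap intervals of the reference, same
#'   layout.
#' @param lengths optional named integer vector of reference sequence
#'   lengths; when supplied, intervals beyond a sequence end are an error.
#' @return percentage in [0, 100].
#' @export
recoveryRate <- function(intervals, mask, lengths = NULL) {
  if (!nrow(mask)) stop("empty non-gap mask")
  if (!is.null(lengths)) {
    for (df in list(intervals, mask)) {
      if (!nrow(df)) next
      lim <- lengths[df$chrom]
      if (anyNA(lim) || any(df$end > lim))
        stop("interval beyond sequence end")
    }
  }
  covered <- 0
  maskLen <- 0
  for (chrom in unique(mask$chrom)) {
    m <- mask[mask$chrom == chrom, , drop = FALSE]
    mr <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
    maskLen <- maskLen + sum(IRanges::width(mr))
    iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
    if (!nrow(iv)) next
    ir <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
    covered <- covered + sum(IRanges::width(IRanges::intersect(ir, mr)))
  }
  100 * covered / maskLen
}

#' Detect novel regions from an unmapped-read coverage track
#'
#' Reports the maximal runs of positions whose unmapped-read depth reaches
#' \code{minDepth} and whose length reaches \code{minLen} (both inclusive;
#' runs are never merged across sub-threshold bases).
#'
#' @param track named list of per-chromosome integer [S4Vectors::Rle] depth
#'   vectors (see [coverageTrack()]).
#' @param minDepth minimum read depth (default 3).
#' @param minLen minimum region length in bp (default 100).
#' @return data.frame of regions: \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{length}.
#' @export
novelRegions <- function(track, minDepth = 3L, minLen = 100L) {
  out <- list()
  for (chrom in names(track)) {
    r <- IRanges::slice(track[[chrom]], lower = minDepth, rangesOnly = TRUE)
    r <- r[IRanges::width(r) >= minLen]
    if (length(r))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = IRanges::start(r) - 1L,
        end = IRanges::end(r), length = IRanges::width(r),
        stringsAsFactors = FALSE)
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               length = integer(), stringsAsFactors = FALSE)
  }
}
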