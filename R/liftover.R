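## ---------------------------------------------------------------------------
## Chain-based coordinate and variant mapping between the baseline reference
## and the consensus (both directions).
## ---------------------------------------------------------------------------

chainBlocksFor <- function(chain, chrom, direction) {
  b <- chainBlocks(chain, chrom)
  if (direction == "reverse")
    b <- data.frame(srcStart = b$tgtStart, srcEnd = b$tgtEnd,
                    tgtStart = b$srcStart, tgtEnd = b$srcEnd)
  b
}

#' Map positions through a chain
#'
#' Positions inside an aligned block map affinely; positions inside
#' source-only gaps (bases deleted in the target) are unmappable and return
#' \code{NA}.
#'
#' @param chain a [Chain-class].
#' @param chrom chromosome name (must exist in the chain).
#' @param pos integer vector of 0-based positions in the source system
#'   (\code{direction = "forward"}) or target system (\code{"reverse"}).
#' @param direction \code{"forward"} (source to target) or \code{"reverse"}.
#' @return integer vector of mapped 0-based positions, \code{NA} where
#'   unmapped.
#' @examples
#' ch <- identityChain(c(chr1 = 100L))
#' mapPosition(ch, "chr1", 42L)
#' @export
mapPosition <- function(chain, chrom, pos,
                        direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  b <- chainBlocksFor(chain, chrom, direction)
  lim <- if (direction == "forward") chain@srcLengths[[chrom]] else
    chain@tgtLengths[[chrom]]
  pos <- as.integer(pos)
  if (any(!is.na(pos) & (pos < 0L | pos >= lim)))
    stop("position outside sequence ", chrom)
  if (nrow(b) == 0L) return(rep(NA_integer_, length(pos)))
  i <- findInterval(pos, b$srcStart)
  hit <- i >= 1L & !is.na(pos)
  hit[hit] <- pos[hit] < b$srcEnd[i[hit]]
  out <- rep(NA_integer_, length(pos))
  out[hit] <- b$tgtStart[i[hit]] + (pos[hit] - b$srcStart[i[hit]])
  out
}

#' Map an interval through a chain
#'
#' Returns the images of all block-covered pieces of \code{[start, end)}, in
#' order; pieces falling in source-only gaps are omitted, so the total mapped
#' length never exceeds the input length.
#'
#' @inheritParams mapPosition
#' @param start,end 0-based half-open interval bounds, \code{start < end}.
#' @return data.frame with columns \code{start}, \code{end} (target
#'   coordinates) and \code{srcStart}, \code{srcEnd} (the mapped source
#'   piece); zero rows when the interval is wholly deleted.
#' @export
mapInterval <- function(chain, chrom, start, end,
                        direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(length(start) == 1L, length(end) == 1L, start < end)
  b <- chainBlocksFor(chain, chrom, direction)
  ov <- which(b$srcStart < end & b$srcEnd > start)
  if (!length(ov))
    return(data.frame(start = integer(), end = integer(),
                      srcStart = integer(), srcEnd = integer()))
  s <- pmax(start, b$srcStart[ov])
  e <- pmin(end, b$srcEnd[ov])
  off <- b$tgtStart[ov] - b$srcStart[ov]
  data.frame(start = s + off, end = e + off, srcStart = s, srcEnd = e)
}

## is the span [pos, pos+len) contained in a single aligned block?
## returns the mapped start or NA (len >= 1)
mapSpan <- function(chain, chrom, pos, len, direction = "forward") {
  b <- chainBlocksFor(chain, chrom, direction)
  if (nrow(b) == 0L) return(rep(NA_integer_, length(pos)))
  i <- findInterval(pos, b$srcStart)
  hit <- i >= 1L
  hit[hit] <- (pos[hit] + len[hit]) <= b$srcEnd[i[hit]]
  out <- rep(NA_integer_, length(pos))
  out[hit] <- b$tgtStart[i[hit]] + (pos[hit] - b$srcStart[i[hit]])
  out
}

## parse one GT string into integer allele indices (NA for missing slots)
parseGT <- function(g) {
  parts <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1L]]
  suppressWarnings(as.integer(parts))
}

#' Lift variant calls through a chain onto a target reference
#'
#' Each call's full reference span must fall inside one aligned block;
#' variants partially overlapping a block edge, or inside deleted spans, are
#' returned \code{UNMAPPED} rather than truncated. The lifted reference
#' allele is re-read from the target sequence: when it differs from the
#' call's reference allele (the target absorbed a substitution), the status
#' is \code{REF_CHANGED} and the alleles and genotype are re-expressed
#' against the target base -- a call homozygous for the absorbed allele
#' re-expresses as homozygous-reference, i.e. the variant vanishes on the
#' target.
#'
#' @param calls data.frame of calls with columns \code{chrom}, \code{pos}
#'   (0-based), \code{ref}, \code{alt} (comma-separated) and optionally
#'   \code{gt} (a single sample's GT string); other columns are preserved.
#' @param chain a [Chain-class] from the calls' reference to the target.
#' @param target [Biostrings::DNAStringSet] of the target reference.
#' @param direction \code{"forward"} or \code{"reverse"} chain orientation.
#' @param source optional [Biostrings::DNAStringSet] of the calls'
#'   reference; when supplied, a call whose \code{ref} allele disagrees with
#'   it is an error (corrupt input).
#' @return the input data.frame with added columns \code{status}
#'   (\code{OK}, \code{REF_CHANGED}, \code{UNMAPPED}), \code{newPos},
#'   \code{newRef}, \code{newAlt}, \code{newGt}.
#' @export
liftCalls <- function(calls, chain, target,
                      direction = c("forward", "reverse"), source = NULL) {
  direction <- match.arg(direction)
  calls <- as.data.frame(calls)
  if (!is.null(source)) {
    srcChr <- as.character(source)
    for (i in seq_len(nrow(calls))) {
      sp <- substr(srcChr[[calls$chrom[i]]], calls$pos[i] + 1L,
                   calls$pos[i] + nchar(calls$ref[i]))
      if (sp != calls$ref[i])
        stop(sprintf("call reference allele mismatch at %s:%d", calls$chrom[i],
                     calls$pos[i]))
    }
  }
  n <- nrow(calls)
  status <- character(n)
  newPos <- rep(NA_integer_, n)
  newRef <- rep(NA_character_, n)
  newAlt <- rep(NA_character_, n)
  newGt <- rep(NA_character_, n)
  tgtChr <- as.character(target)
  hasGT <- "gt" %in% names(calls)
  for (chrom in unique(calls$chrom)) {
    idx <- which(calls$chrom == chrom)
    srcLim <- if (direction == "forward") chain@srcLengths[[chrom]] else
      chain@tgtLengths[[chrom]]
    lens <- nchar(calls$ref[idx])
    if (any(calls$pos[idx] + lens > srcLim))
      stop("variant span beyond end of ", chrom)
    mp <- mapSpan(chain, chrom, calls$pos[idx], lens, direction)
    for (j in seq_along(idx)) {
      r <- idx[j]
      if (is.na(mp[j])) { status[r] <- "UNMAPPED"; next }
      np <- mp[j]
      L <- lens[j]
      tseq <- tgtChr[[chrom]]
      tRef <- substr(tseq, np + 1L, np + L)
      newPos[r] <- np
      alts <- setdiff(strsplit(calls$alt[r], ",", fixed = TRUE)[[1L]],
                      c(".", ""))
      if (tRef == calls$ref[r]) {
        status[r] <- "OK"
        newRef[r] <- tRef
        newAlt[r] <- if (length(alts)) paste(alts, collapse = ",") else "."
        if (hasGT) newGt[r] <- calls$gt[r]
      } else {
        status[r] <- "REF_CHANGED"
        alleles <- c(calls$ref[r], alts)
        keep <- alleles[alleles != tRef]
        newRef[r] <- tRef
        newAlt[r] <- if (length(keep)) paste(keep, collapse = ",") else "."
        if (hasGT) {
          gi <- parseGT(calls$gt[r])
          gAll <- ifelse(is.na(gi), NA_character_, alleles[gi + 1L])
          ni <- ifelse(is.na(gAll), NA_integer_,
                       match(gAll, c(tRef, keep)) - 1L)
          newGt[r] <- paste(ifelse(is.na(ni), ".", ni), collapse = "/")
        }
      }
    }
  }
  calls$status <- status
  calls$newPos <- newPos
  calls$newRef <- newRef
  calls$newAlt <- newAlt
  calls$newGt <- newGt
  calls
}
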