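## Independent brute-force oracles used to derive expected values; kept
## deliberately naive and separate from the package's implementations.

## naive splice of an edit table onto one chromosome string, plus the
## per-position source -> target map (NA where a base is not carried over:
## inside a length-changing edit's reference span)
oracleApply <- function(refStr, ed) {
  n <- nchar(refStr)
  ed <- ed[order(ed$pos), , drop = FALSE]
  pieces <- character(0)
  map <- rep(NA_integer_, n)
  cur <- 0L
  tlen <- 0L
  for (i in seq_len(nrow(ed))) {
    pos <- ed$pos[i]
    L <- nchar(ed$ref[i])
    alt <- ed$alt[i]
    if (pos > cur) {
      map[(cur + 1L):pos] <- tlen + seq_len(pos - cur) - 1L
      pieces <- c(pieces, substr(refStr, cur + 1L, pos))
      tlen <- tlen + (pos - cur)
    }
    if (nchar(alt) == L) {
      if (L > 0L) map[(pos + 1L):(pos + L)] <- tlen + seq_len(L) - 1L
      pieces <- c(pieces, alt)
      tlen <- tlen + L
    } else {
      pieces <- c(pieces, alt)
      tlen <- tlen + nchar(alt)
    }
    cur <- pos + L
  }
  if (cur < n) {
    map[(cur + 1L):n] <- tlen + seq_len(n - cur) - 1L
    pieces <- c(pieces, substr(refStr, cur + 1L, n))
  }
  list(seq = paste(pieces, collapse = ""), map = map)
}

## random valid edit table over a random (or supplied) reference string
randomEditCase <- function(len = 2000L, meanGap = 25L, refStr = NULL) {
  if (is.null(refStr))
    refStr <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  len <- nchar(refStr)
  pos <- 0L
  rows <- list()
  repeat {
    pos <- pos + sample.int(meanGap * 2L, 1L)
    if (pos >= len - 12L) break
    kind <- sample(c("SNV", "DEL", "INS", "REPL"), 1L)
    if (kind == "SNV") {
      ref <- substr(refStr, pos + 1L, pos + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      rows[[length(rows) + 1L]] <- data.frame(pos = pos, ref = ref,
                                              alt = alt, kind = "SNV")
      pos <- pos + 1L
    } else if (kind == "DEL") {
      L <- sample.int(5L, 1L)
      ref <- substr(refStr, pos + 1L, pos + L)
      rows[[length(rows) + 1L]] <- data.frame(pos = pos, ref = ref,
                                              alt = "", kind = "INDEL")
      pos <- pos + L
    } else if (kind == "INS") {
      alt <- paste(sample(c("A", "C", "G", "T"), sample.int(5L, 1L), TRUE),
                   collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(pos = pos, ref = "",
                                              alt = alt, kind = "INDEL")
      pos <- pos + 1L
    } else {
      L <- sample.int(4L, 1L)
      a <- sample.int(6L, 1L)
      if (a == L) a <- a + 1L
      ref <- substr(refStr, pos + 1L, pos + L)
      alt <- paste(sample(c("A", "C", "G", "T"), a, TRUE), collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(pos = pos, ref = ref,
                                              alt = alt, kind = "INDEL")
      pos <- pos + L
    }
  }
  ed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               kind = character())
  ed$chrom <- "chr1"
  list(refStr = refStr, edits = ed[, c("chrom", "pos", "ref", "alt", "kind")])
}

## exhaustive fixed-margin enumeration of the two-sided Fisher p-value
oracleFisher <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  n1 <- a + c
  if (m1 + m2 == 0) return(1)
  ks <- max(0, n1 - m2):min(n1, m1)
  probs <- dhyper(ks, m1, m2, n1)
  pObs <- dhyper(a, m1, m2, n1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## brute-force cumulative-sum Nxx/Lxx
oracleNxx <- function(lens, x, minLen = 0) {
  inc <- sort(lens[lens >= minLen], decreasing = TRUE)
  total <- sum(inc)
  cum <- 0
  for (i in seq_along(inc)) {
    cum <- cum + inc[i]
    if (cum >= x / 100 * total)
      return(c(N = inc[i], L = sum(inc >= inc[i])))
  }
}

## per-base boolean scan for thresholded-depth regions
oracleNovel <- function(depths, minDepth, minLen) {
  ok <- depths >= minDepth
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLen
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

## all-pairs single-linkage clustering over an svSame-style predicate
oracleCluster <- function(pooled, same) {
  n <- nrow(pooled)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] != lab[j] &&
          same(pooled[i, , drop = FALSE], pooled[j, , drop = FALSE])) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

## tiny VCF writer for fixtures
writeTinyVcf <- function(path, rows, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
}
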