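#' Write a Chain in UCSC chain format
#'
#' One chain stanza is written per chromosome, with the source genome in the
#' target (t) columns and the lifted-to genome in the query (q) columns, the
#' dialect used by genome-browser lift-over files. All chains are
#' forward-strand and same-named by construction.
#'
#' @param chain a [Chain-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @seealso [readChain()]
#' @export
writeChain <- function(chain, path) {
  stopifnot(is(chain, "Chain"))
  lines <- character()
  id <- 0L
  for (chrom in names(chain@blocks)) {
    b <- chain@blocks[[chrom]]
    if (nrow(b) == 0L) {
      warning("chromosome ", chrom, " has no blocks; stanza skipped")
      next
    }
    id <- id + 1L
    score <- sum(b$srcEnd - b$srcStart)
    lines <- c(lines, sprintf(
      "chain %d %s %d + %d %d %s %d + %d %d %d",
      score, chrom, chain@srcLengths[[chrom]], b$srcStart[1L],
      b$srcEnd[nrow(b)], chrom, chain@tgtLengths[[chrom]], b$tgtStart[1L],
      b$tgtEnd[nrow(b)], id))
    size <- b$srcEnd - b$srcStart
    if (nrow(b) > 1L) {
      dt <- b$srcStart[-1L] - b$srcEnd[-nrow(b)]
      dq <- b$tgtStart[-1L] - b$tgtEnd[-nrow(b)]
      lines <- c(lines,
                 sprintf("%d %d %d", size[-nrow(b)], dt, dq))
    }
    lines <- c(lines, sprintf("%d", size[nrow(b)]), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a UCSC chain file
#'
#' Only the substitution-induced dialect written by [writeChain()] is
#' supported: forward strand on both sides and identical source/target
#' chromosome names. \code{readChain(writeChain(x)) } reproduces \code{x}
#' exactly.
#'
#' @param path path to a chain file.
#' @return A [Chain-class].
#' @export
readChain <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^chain\\b", lines)
  if (!length(heads)) stop("no chain stanza found")
  bounds <- c(heads, length(lines) + 1L)
  blocks <- list()
  srcLengths <- integer()
  tgtLengths <- integer()
  for (i in seq_along(heads)) {
    hdr <- strsplit(trimws(lines[heads[i]]), "\\s+")[[1L]]
    if (length(hdr) != 13L) stop("malformed chain header: ", lines[heads[i]])
    tName <- hdr[3L]; tSize <- as.integer(hdr[4L]); tStrand <- hdr[5L]
    tStart <- as.integer(hdr[6L]); tEnd <- as.integer(hdr[7L])
    qName <- hdr[8L]; qSize <- as.integer(hdr[9L]); qStrand <- hdr[10L]
    qStart <- as.integer(hdr[11L]); qEnd <- as.integer(hdr[12L])
    if (anyNA(c(tSize, tStart, tEnd, qSize, qStart, qEnd)))
      stop("malformed chain header: ", lines[heads[i]])
    if (tStrand != "+" || qStrand != "+")
      stop("only forward-strand chains are supported")
    if (tName != qName)
      stop("source/target chromosome names differ: ", tName, " vs ", qName)
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    parts <- strsplit(trimws(body), "\\s+")
    n <- length(parts)
    if (any(vapply(parts[-n], length, integer(1)) != 3L) ||
        length(parts[[n]]) != 1L)
      stop("malformed chain body for ", tName)
    size <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
    dt <- c(vapply(parts[-n], function(p) as.integer(p[2L]), integer(1)), 0L)
    dq <- c(vapply(parts[-n], function(p) as.integer(p[3L]), integer(1)), 0L)
    if (anyNA(c(size, dt, dq))) stop("malformed chain body for ", tName)
    if (any(dt < 0L) || any(dq < 0L)) stop("negative gap in chain for ", tName)
    srcStart <- tStart + cumsum(c(0L, (size + dt)[-n]))
    tgtStart <- qStart + cumsum(c(0L, (size + dq)[-n]))
    b <- data.frame(srcStart = srcStart, srcEnd = srcStart + size,
                    tgtStart = tgtStart, tgtEnd = tgtStart + size)
    if (b$srcEnd[n] != tEnd || b$tgtEnd[n] != qEnd)
      stop("chain stanza for ", tName, " is inconsistent with its header")
    if (tName %in% names(blocks)) stop("duplicate chain stanza for ", tName)
    blocks[[tName]] <- b
    srcLengths[[tName]] <- tSize
    tgtLengths[[tName]] <- qSize
  }
  Chain(blocks, srcLengths, tgtLengths)
}
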