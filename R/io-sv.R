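#' Validate a structural-variant table
#'
#' SVs are typed intervals on the baseline reference, 0-based half-open:
#' deletions and inversions span \code{[start, end)} with
#' \code{length == end - start >= 1}; insertions are breakpoints with
#' \code{end == start} and \code{length >= 1} (the inserted length).
#'
#' @param svs data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{type} (INS/DEL/INV), \code{length}, and optionally \code{label}
#'   (source assembly/genome).
#' @return the table, with integer coordinates, invisibly checked.
#' @export
validateSVTable <- function(svs) {
  need <- c("chrom", "start", "end", "type", "length")
  if (!all(need %in% names(svs)))
    stop("SV table must have columns ", paste(need, collapse = ", "))
  svs <- as.data.frame(svs)
  svs$start <- as.integer(svs$start)
  svs$end <- as.integer(svs$end)
  svs$length <- as.integer(svs$length)
  if (!all(svs$type %in% c("INS", "DEL", "INV")))
    stop("SV type must be INS, DEL or INV")
  if (any(svs$start > svs$end)) stop("SV with start > end")
  ins <- svs$type == "INS"
  if (any(ins & svs$end != svs$start))
    stop("INS records must have end == start")
  if (any(svs$length < 1L)) stop("SV length must be >= 1")
  if (any(!ins & svs$length != svs$end - svs$start))
    stop("DEL/INV length must equal end - start")
  rownames(svs) <- NULL
  svs
}

#' Read / write a tab-separated SV table
#'
#' The interchange format is a headered TSV with columns \code{chrom},
#' \code{start}, \code{end} (0-based half-open), \code{type}, \code{length},
#' \code{label}.
#'
#' @param path file path.
#' @return \code{readSVTable}: a validated data.frame.
#' @export
readSVTable <- function(path) {
  svs <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  validateSVTable(svs)
}

#' @rdname readSVTable
#' @param svs SV data.frame (see [validateSVTable()]).
#' @export
writeSVTable <- function(svs, path) {
  svs <- validateSVTable(svs)
  write.table(svs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-region single-end/paired read-support counts
#'
#' A headered TSV with one row per SV region: \code{chrom}, \code{start},
#' \code{end}, \code{single} (single-end-mapped reads) and \code{paired}
#' (properly-paired reads).
#'
#' @param path file path.
#' @return data.frame of counts.
#' @seealso [spFilter()]
#' @export
readSPCounts <- function(path) {
  sp <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("single", "paired")
  if (!all(need %in% names(sp)))
    stop("S/P counts need columns ", paste(need, collapse = ", "))
  if (any(sp$single < 0) || any(sp$paired < 0)) stop("negative read count")
  sp
}

#' Read scaffold-on-reference alignment anchors
#'
#' Accepts either the package TSV layout (headered: \code{scaffold},
#' \code{chrom}, \code{sStart}, \code{sEnd}, \code{tStart}, \code{tEnd},
#' \code{strand}, \code{quality}) or minimap2-style PAF (12+ unheadered
#' columns), both with 0-based half-open coordinates.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"tsv"} or \code{"paf"}.
#' @return data.frame of anchors in the TSV layout.
#' @seealso [placeScaffolds()]
#' @export
readAnchors <- function(path, format = c("auto", "tsv", "paf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.paf(\\.gz)?$", path)) "paf" else "tsv"
  if (format == "paf") {
    raw <- read.table(path, header = FALSE, sep = "\t", fill = TRUE,
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 12L) stop("PAF needs at least 12 columns")
    anchors <- data.frame(
      scaffold = as.character(raw[[1L]]),
      chrom    = as.character(raw[[6L]]),
      sStart   = as.integer(raw[[3L]]), sEnd = as.integer(raw[[4L]]),
      tStart   = as.integer(raw[[8L]]), tEnd = as.integer(raw[[9L]]),
      strand   = as.character(raw[[5L]]),
      quality  = as.integer(raw[[12L]]),
      stringsAsFactors = FALSE
    )
  } else {
    anchors <- read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  }
  need <- c("scaffold", "chrom", "sStart", "sEnd", "tStart", "tEnd",
            "strand", "quality")
  if (!all(need %in% names(anchors)))
    stop("anchor table must have columns ", paste(need, collapse = ", "))
  if (!all(anchors$strand %in% c("+", "-"))) stop("strand must be + or -")
  anchors
}

#' Build a coverage track from bedGraph-style intervals
#'
#' @param depths data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{depth}; uncovered positions get depth 0.
#' @param lengths named integer vector of sequence lengths.
#' @return named list of [S4Vectors::Rle] integer depth vectors, one per
#'   sequence in \code{lengths}.
#' @seealso [novelRegions()]
#' @export
coverageTrack <- function(depths, lengths) {
  if (any(depths$depth < 0)) stop("negative depth")
  out <- lapply(names(lengths), function(chrom) {
    n <- as.integer(lengths[[chrom]])
    d <- depths[depths$chrom == chrom, , drop = FALSE]
    if (nrow(d) && any(d$end > n)) stop("interval beyond end of ", chrom)
    cov <- integer(n)
    for (i in seq_len(nrow(d)))
      cov[(d$start[i] + 1L):d$end[i]] <- as.integer(d$depth[i])
    S4Vectors::Rle(cov)
  })
  setNames(out, names(lengths))
}
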