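#' Read / write AGP 2.0 files
#'
#' AGP rows are kept as a 9-column data.frame: \code{object},
#' \code{object_beg}, \code{object_end}, \code{part_number},
#' \code{component_type} (\code{W} component or \code{N} gap), and the four
#' type-dependent fields as character columns \code{field6}..\code{field9}
#' (component id / begin / end / orientation for \code{W}; gap length / gap
#' type / linkage / linkage evidence for \code{N}). Object coordinates are
#' 1-based inclusive, as the format prescribes.
#'
#' @param path file path.
#' @return \code{readAGP}: the AGP data.frame.
#' @seealso [buildChromosomes()], [agpToSequences()]
#' @export
readAGP <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  if (any(vapply(parts, length, integer(1)) != 9L))
    stop("AGP rows must have 9 tab-separated columns")
  m <- do.call(rbind, parts)
  agp <- data.frame(object = m[, 1L],
                    object_beg = as.integer(m[, 2L]),
                    object_end = as.integer(m[, 3L]),
                    part_number = as.integer(m[, 4L]),
                    component_type = m[, 5L],
                    field6 = m[, 6L], field7 = m[, 7L], field8 = m[, 8L],
                    field9 = m[, 9L], stringsAsFactors = FALSE)
  validateAGP(agp)
}

#' @rdname readAGP
#' @param agp AGP data.frame as returned by [readAGP()] or
#'   [buildChromosomes()].
#' @export
writeAGP <- function(agp, path) {
  agp <- validateAGP(agp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

validateAGP <- function(agp) {
  need <- c("object", "object_beg", "object_end", "part_number",
            "component_type", "field6", "field7", "field8", "field9")
  if (!all(need %in% names(agp)))
    stop("AGP table must have columns ", paste(need, collapse = ", "))
  if (!all(agp$component_type %in% c("W", "N", "U")))
    stop("component_type must be W, N or U")
  if (any(agp$object_beg < 1L) || any(agp$object_end < agp$object_beg))
    stop("invalid object coordinates")
  spans <- agp$object_end - agp$object_beg + 1L
  isgap <- agp$component_type %in% c("N", "U")
  if (any(spans[isgap] != as.integer(agp$field6[isgap])))
    stop("gap row span disagrees with gap length")
  if (any(spans[!isgap] != as.integer(agp$field8[!isgap]) -
          as.integer(agp$field7[!isgap]) + 1L))
    stop("component row span disagrees with component coordinates")
  rownames(agp) <- NULL
  agp[, need]
}

#' Rebuild object sequences from an AGP and its component sequences
#'
#' The reconstruction is the format's defining contract: concatenating each
#' object's components (reverse-complemented where orientation is \code{-})
#' and N-gaps in part order reproduces the object sequence exactly.
#'
#' @param agp AGP data.frame (see [readAGP()]).
#' @param components [Biostrings::DNAStringSet] of component (scaffold)
#'   sequences.
#' @return [Biostrings::DNAStringSet] of rebuilt object sequences.
#' @export
agpToSequences <- function(agp, components) {
  agp <- validateAGP(agp)
  comp <- as.character(components)
  objs <- unique(agp$object)
  out <- vapply(objs, function(obj) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    pieces <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$component_type %in% c("N", "U")) {
        strrep("N", as.integer(r$field6))
      } else {
        if (!r$field6 %in% names(comp))
          stop("missing component sequence: ", r$field6)
        s <- substr(comp[[r$field6]], as.integer(r$field7),
                    as.integer(r$field8))
        if (r$field9 == "-") revComp(s) else s
      }
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(out, objs))
}

## reverse complement of a plain character sequence (ACGTN)
revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
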