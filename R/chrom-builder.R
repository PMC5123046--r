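## ---------------------------------------------------------------------------
## Rule-based chromosome building from scaffold alignment anchors: placement
## passes, gap estimation, sequence assembly with telomere pads, chrUn
## binning, AGP emission.
## ---------------------------------------------------------------------------

## best single-chromosome placement for one scaffold's anchors; NULL when
## tied between chromosomes
bestAnchorPlacement <- function(anchors, scaffold) {
  counts <- table(anchors$chrom)
  top <- names(counts)[counts == max(counts)]
  if (length(top) != 1L) {
    warning("scaffold ", scaffold, " ties between chromosomes ",
            paste(top, collapse = ", "), "; left unplaced")
    return(NULL)
  }
  a <- anchors[anchors$chrom == top, , drop = FALSE]
  nMinus <- sum(a$strand == "-")
  orientation <- if (nMinus * 2L > nrow(a)) "-" else {
    if (nMinus * 2L == nrow(a))
      warning("scaffold ", scaffold,
              " has tied anchor orientations; using +")
    "+"
  }
  data.frame(scaffold = scaffold, chrom = top,
             tStart = min(a$tStart), tEnd = max(a$tEnd),
             orientation = orientation, anchors = nrow(a),
             stringsAsFactors = FALSE)
}

#' Place scaffolds on chromosomes from alignment anchors
#'
#' Three passes mirror the chromosome-building rules: a primary pass admits
#' large scaffolds (>= \code{smallMax} bp) with at least
#' \code{primaryMin} anchors on one chromosome; a rescue pass re-examines
#' the remaining large scaffolds (against \code{rescueAnchors} when a second
#' alignment is supplied) with the lower threshold \code{rescueMin}; small
#' scaffolds are placed only through anchors of mapping quality exactly
#' \code{smallQuality}. A scaffold tied between chromosomes (equal best
#' anchor counts) is left unplaced with a warning; otherwise the chromosome
#' with the most anchors wins. Orientation is the majority vote over anchor
#' strands (ties: plus, with a warning).
#'
#' @param anchors anchor data.frame (see [readAnchors()]).
#' @param scaffoldLengths named integer vector of scaffold lengths.
#' @param primaryMin,rescueMin anchor-count thresholds of the primary
#'   (default 7) and rescue (default 4) passes.
#' @param smallMax scaffolds shorter than this are "small" (default 10 kb).
#' @param smallQuality exact mapping quality required for small-scaffold
#'   anchors (default 254).
#' @param rescueAnchors optional anchor table from a second alignment used
#'   by the rescue pass; defaults to \code{anchors}.
#' @return list with \code{placements} (data.frame: \code{scaffold},
#'   \code{chrom}, \code{tStart}, \code{tEnd}, \code{orientation},
#'   \code{anchors}, \code{pass}) and \code{unplaced} (character vector).
#' @export
placeScaffolds <- function(anchors, scaffoldLengths, primaryMin = 7L,
                           rescueMin = 4L, smallMax = 10000L,
                           smallQuality = 254L, rescueAnchors = NULL) {
  if (is.null(rescueAnchors)) rescueAnchors <- anchors
  scaffolds <- names(scaffoldLengths)
  placements <- list()
  placed <- character(0)
  tryPass <- function(scafs, anchorTab, minCount, pass) {
    for (sc in scafs) {
      a <- anchorTab[anchorTab$scaffold == sc, , drop = FALSE]
      if (!nrow(a)) next
      best <- bestAnchorPlacement(a, sc)
      if (is.null(best) || best$anchors < minCount) next
      best$pass <- pass
      placements[[length(placements) + 1L]] <<- best
      placed <<- c(placed, sc)
    }
  }
  large <- scaffolds[scaffoldLengths >= smallMax]
  small <- setdiff(scaffolds, large)
  tryPass(large, anchors, primaryMin, "primary")
  tryPass(setdiff(large, placed), rescueAnchors, rescueMin, "rescue")
  smallAnchors <- anchors[anchors$quality == smallQuality, , drop = FALSE]
  tryPass(small, smallAnchors, 1L, "small")
  placements <- if (length(placements)) do.call(rbind, placements) else
    data.frame(scaffold = character(), chrom = character(),
               tStart = integer(), tEnd = integer(),
               orientation = character(), anchors = integer(),
               pass = character(), stringsAsFactors = FALSE)
  rownames(placements) <- NULL
  list(placements = placements, unplaced = setdiff(scaffolds, placed))
}

#' Estimate inter-scaffold gap sizes on a chromosome
#'
#' The gap between consecutive placed scaffolds is their distance on the
#' guiding reference when positive; when placements overlap or abut, a fixed
#' \code{overlapGap} (default 10 kb) is used instead, since a physical gap
#' size cannot be estimated there (and gap rows must have positive length).
#'
#' @param placements placement data.frame for a single chromosome (see
#'   [placeScaffolds()]).
#' @param overlapGap gap size substituted for overlapping/abutting
#'   placements.
#' @return data.frame of the \code{nrow(placements) - 1} gaps in placement
#'   order: \code{after} (scaffold name), \code{gap}.
#' @export
estimateGaps <- function(placements, overlapGap = 10000L) {
  p <- placements[order(placements$tStart, placements$tEnd), , drop = FALSE]
  n <- nrow(p)
  if (n < 2L)
    return(data.frame(after = character(), gap = integer(),
                      stringsAsFactors = FALSE))
  d <- p$tStart[-1L] - p$tEnd[-n]
  data.frame(after = p$scaffold[-n],
             gap = ifelse(d > 0L, d, as.integer(overlapGap)))
}

#' Build chromosome sequences and AGP from placed scaffolds
#'
#' Each chromosome is assembled as an N-pad of \code{pad} bp (telomeric
#' convention), the placed scaffolds in reference order (reverse-complemented
#' when oriented minus) joined by estimated N-gaps, and a closing N-pad.
#' Unplaced scaffolds are concatenated into an artificial unplaced
#' chromosome (\code{chrUnName}) separated by fixed \code{chrUnSpacer} N
#' runs. The emitted AGP 2.0 rows reproduce the construction exactly.
#'
#' @param placements placement data.frame (see [placeScaffolds()]).
#' @param scaffoldSeqs [Biostrings::DNAStringSet] with every placed and
#'   unplaced scaffold sequence.
#' @param unplaced character vector of scaffolds destined for the unplaced
#'   chromosome (may be empty).
#' @param pad telomeric N-pad length added to both chromosome ends
#'   (default 10 kb).
#' @param overlapGap see [estimateGaps()].
#' @param chrUnSpacer N-spacer between unplaced scaffolds (default 10 kb).
#' @param chrUnName name of the unplaced chromosome.
#' @return list with \code{sequences} (DNAStringSet) and \code{agp}
#'   (data.frame, see [readAGP()]).
#' @export
buildChromosomes <- function(placements, scaffoldSeqs, unplaced = character(),
                             pad = 10000L, overlapGap = 10000L,
                             chrUnSpacer = 10000L, chrUnName = "chrUn") {
  seqChr <- as.character(scaffoldSeqs)
  missing <- setdiff(c(placements$scaffold, unplaced), names(seqChr))
  if (length(missing))
    stop("missing scaffold sequence(s): ", paste(missing, collapse = ", "))
  agpRows <- list()
  outSeqs <- character(0)
  emit <- function(object, pieces) {
    ## pieces: list of list(kind = "W"/"N", ...)
    at <- 1L
    partn <- 0L
    seqParts <- character(length(pieces))
    for (i in seq_along(pieces)) {
      pc <- pieces[[i]]
      partn <- partn + 1L
      if (pc$kind == "N") {
        agpRows[[length(agpRows) + 1L]] <<- data.frame(
          object = object, object_beg = at, object_end = at + pc$len - 1L,
          part_number = partn, component_type = "N",
          field6 = as.character(pc$len), field7 = pc$gapType,
          field8 = pc$linkage, field9 = pc$evidence,
          stringsAsFactors = FALSE)
        seqParts[i] <- strrep("N", pc$len)
        at <- at + pc$len
      } else {
        s <- seqChr[[pc$id]]
        len <- nchar(s)
        agpRows[[length(agpRows) + 1L]] <<- data.frame(
          object = object, object_beg = at, object_end = at + len - 1L,
          part_number = partn, component_type = "W",
          field6 = pc$id, field7 = "1", field8 = as.character(len),
          field9 = pc$orientation, stringsAsFactors = FALSE)
        seqParts[i] <- if (pc$orientation == "-") revComp(s) else s
        at <- at + len
      }
    }
    outSeqs[[object]] <<- paste(seqParts, collapse = "")
  }
  telomere <- function(len) list(kind = "N", len = len, gapType = "telomere",
                                 linkage = "no", evidence = "na")
  scafGap <- function(len) list(kind = "N", len = len, gapType = "scaffold",
                                linkage = "yes", evidence = "align_genus")
  for (chrom in unique(placements$chrom)) {
    p <- placements[placements$chrom == chrom, , drop = FALSE]
    p <- p[order(p$tStart, p$tEnd), , drop = FALSE]
    gaps <- estimateGaps(p, overlapGap)
    pieces <- list(telomere(pad))
    for (i in seq_len(nrow(p))) {
      pieces[[length(pieces) + 1L]] <- list(kind = "W", id = p$scaffold[i],
                                            orientation = p$orientation[i])
      if (i < nrow(p))
        pieces[[length(pieces) + 1L]] <- scafGap(gaps$gap[i])
    }
    pieces[[length(pieces) + 1L]] <- telomere(pad)
    emit(chrom, pieces)
  }
  if (length(unplaced)) {
    pieces <- list()
    for (i in seq_along(unplaced)) {
      pieces[[length(pieces) + 1L]] <- list(kind = "W", id = unplaced[i],
                                            orientation = "+")
      if (i < length(unplaced))
        pieces[[length(pieces) + 1L]] <- list(kind = "N", len = chrUnSpacer,
                                              gapType = "contig",
                                              linkage = "no",
                                              evidence = "na")
    }
    emit(chrUnName, pieces)
  }
  agp <- validateAGP(do.call(rbind, agpRows))
  list(sequences = Biostrings::DNAStringSet(outSeqs), agp = agp)
}
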