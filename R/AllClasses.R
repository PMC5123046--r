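#' @import methods
#' @importFrom S4Vectors Rle runValue runLength
#' @importFrom stats fisher.test rbinom runif rpois setNames
#' @importFrom utils read.table write.table head tail
NULL

## ---------------------------------------------------------------------------
## Chain: forward-strand, same-chromosome alignment between a source and a
## target coordinate system, as ordered gap-free blocks. This is the in-memory
## form of a UCSC lift-over chain restricted to substitution-induced edits
## (no rearrangement, no strand flips).
## ---------------------------------------------------------------------------

#' Chain of aligned coordinate blocks
#'
#' A \code{Chain} describes a forward-strand alignment between two versions of
#' the same chromosome set (for example a baseline reference and a consensus
#' built from it) as, per chromosome, an ordered list of gap-free blocks
#' \code{[srcStart, srcEnd) -> [tgtStart, tgtEnd)}. Blocks are 0-based
#' half-open, strictly increasing in both coordinate systems, and each block
#' has equal source and target width. Gaps between consecutive blocks are
#' source-only (deleted), target-only (inserted), or both.
#'
#' @slot blocks named list, one \code{data.frame} per chromosome with integer
#'   columns \code{srcStart}, \code{srcEnd}, \code{tgtStart}, \code{tgtEnd}.
#' @slot srcLengths named integer vector of source sequence lengths.
#' @slot tgtLengths named integer vector of target sequence lengths.
#'
#' @seealso [mapPosition()], [readChain()], [writeChain()], [applyEdits()]
#' @export
setClass("Chain", representation(
  blocks     = "list",
  srcLengths = "integer",
  tgtLengths = "integer"
))

setValidity("Chain", function(object) {
  msgs <- character()
  chroms <- names(object@blocks)
  if (is.null(chroms) || anyDuplicated(chroms))
    return("blocks must be a uniquely named list")
  if (!all(chroms %in% names(object@srcLengths)) ||
      !all(chroms %in% names(object@tgtLengths)))
    return("every chromosome with blocks needs srcLengths and tgtLengths")
  for (chrom in chroms) {
    b <- object@blocks[[chrom]]
    need <- c("srcStart", "srcEnd", "tgtStart", "tgtEnd")
    if (!is.data.frame(b) || !all(need %in% names(b))) {
      msgs <- c(msgs, sprintf("%s: blocks must have columns %s",
                              chrom, paste(need, collapse = ", ")))
      next
    }
    if (nrow(b) == 0L) next
    if (any((b$srcEnd - b$srcStart) != (b$tgtEnd - b$tgtStart)))
      msgs <- c(msgs, sprintf("%s: block source/target widths differ", chrom))
    if (any(b$srcEnd <= b$srcStart))
      msgs <- c(msgs, sprintf("%s: empty or negative block", chrom))
    if (nrow(b) > 1L) {
      if (any(diff(b$srcStart) <= 0) || any(b$srcStart[-1L] < b$srcEnd[-nrow(b)]))
        msgs <- c(msgs, sprintf("%s: source blocks not strictly increasing", chrom))
      if (any(diff(b$tgtStart) <= 0) || any(b$tgtStart[-1L] < b$tgtEnd[-nrow(b)]))
        msgs <- c(msgs, sprintf("%s: target blocks not strictly increasing", chrom))
    }
    if (b$srcStart[1L] < 0L || b$srcEnd[nrow(b)] > object@srcLengths[[chrom]])
      msgs <- c(msgs, sprintf("%s: blocks exceed source length", chrom))
    if (b$tgtStart[1L] < 0L || b$tgtEnd[nrow(b)] > object@tgtLengths[[chrom]])
      msgs <- c(msgs, sprintf("%s: blocks exceed target length", chrom))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Chain
#'
#' @param blocks named list of per-chromosome block data.frames
#'   (\code{srcStart}, \code{srcEnd}, \code{tgtStart}, \code{tgtEnd};
#'   0-based half-open).
#' @param srcLengths,tgtLengths named integer vectors of sequence lengths in
#'   the source and target coordinate systems.
#' @return A validated [Chain-class] object.
#' @examples
#' identityChain(c(chr1 = 100L))
#' @export
Chain <- function(blocks, srcLengths, tgtLengths) {
  blocks <- lapply(blocks, function(b) {
    b <- as.data.frame(b)[, c("srcStart", "srcEnd", "tgtStart", "tgtEnd")]
    b[] <- lapply(b, as.integer)
    rownames(b) <- NULL
    b
  })
  new("Chain", blocks = blocks,
      srcLengths = setNames(as.integer(srcLengths), names(srcLengths)),
      tgtLengths = setNames(as.integer(tgtLengths), names(tgtLengths)))
}

#' Identity chain over a set of sequences
#'
#' @param lengths named integer vector of sequence lengths.
#' @return A [Chain-class] mapping every position to itself.
#' @export
identityChain <- function(lengths) {
  blocks <- lapply(lengths, function(n)
    data.frame(srcStart = 0L, srcEnd = as.integer(n),
               tgtStart = 0L, tgtEnd = as.integer(n)))
  names(blocks) <- names(lengths)
  Chain(blocks, lengths, lengths)
}

#' @describeIn Chain-class per-chromosome block table
#' @param x,object a \code{Chain}
#' @param chrom chromosome name
#' @export
chainBlocks <- function(x, chrom) {
  stopifnot(is(x, "Chain"))
  if (!chrom %in% names(x@blocks)) stop("unknown chromosome: ", chrom)
  x@blocks[[chrom]]
}

#' Reverse a chain (swap source and target roles)
#'
#' Substitution-induced chains are forward-strand and order-preserving in both
#' coordinate systems, so reversing is an exact swap of the block columns.
#'
#' @param x a [Chain-class]
#' @return the reversed \code{Chain}
#' @export
reverseChain <- function(x) {
  stopifnot(is(x, "Chain"))
  blocks <- lapply(x@blocks, function(b)
    data.frame(srcStart = b$tgtStart, srcEnd = b$tgtEnd,
               tgtStart = b$srcStart, tgtEnd = b$srcEnd))
  Chain(blocks, x@tgtLengths, x@srcLengths)
}

setMethod("show", "Chain", function(object) {
  nb <- vapply(object@blocks, nrow, integer(1))
  cat("Chain with", length(object@blocks), "chromosome(s),",
      sum(nb), "block(s)\n")
  for (chrom in utils::head(names(object@blocks), 5L))
    cat(sprintf("  %s: %d block(s), source %d bp -> target %d bp\n", chrom,
                nb[[chrom]], object@srcLengths[[chrom]],
                object@tgtLengths[[chrom]]))
  if (length(object@blocks) > 5L) cat("  ...\n")
})

## ---------------------------------------------------------------------------
## EditScript: the ordered set of reference edits that induces a consensus.
## ---------------------------------------------------------------------------

#' Ordered reference edit script
#'
#' An \code{EditScript} is the ordered, non-overlapping set of edits that turn
#' a baseline reference into a consensus: length-preserving substitutions
#' (\code{kind = "SNV"}) and length-changing replacements
#' (\code{kind = "INDEL"}, including pure insertions with an empty \code{ref}
#' and pure deletions with an empty \code{alt}). Positions are 0-based; an
#' edit replaces the reference span \code{[pos, pos + nchar(ref))} by
#' \code{alt}.
#'
#' @slot edits data.frame with columns \code{chrom}, \code{pos} (integer),
#'   \code{ref}, \code{alt} (character), \code{kind} ("SNV" or "INDEL").
#'
#' @seealso [applyEdits()], [buildConsensus()]
#' @export
setClass("EditScript", representation(edits = "data.frame"))

setValidity("EditScript", function(object) {
  e <- object@edits
  need <- c("chrom", "pos", "ref", "alt", "kind")
  if (!all(need %in% names(e)))
    return(paste("edits must have columns", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) return(TRUE)
  if (!all(e$kind %in% c("SNV", "INDEL")))
    return("kind must be SNV or INDEL")
  if (any(e$kind == "SNV" & nchar(e$ref) != nchar(e$alt)))
    return("SNV edits must be length-preserving")
  if (any(e$kind == "INDEL" & nchar(e$ref) == nchar(e$alt)))
    return("INDEL edits must change length")
  if (any(e$ref == e$alt)) return("edit replacement equals its reference span")
  msgs <- character()
  for (chrom in unique(e$chrom)) {
    ec <- e[e$chrom == chrom, , drop = FALSE]
    if (is.unsorted(ec$pos, strictly = FALSE))
      msgs <- c(msgs, sprintf("%s: edits not sorted by pos", chrom))
    if (nrow(ec) > 1L) {
      ends <- ec$pos + nchar(ec$ref)
      if (any(ec$pos[-1L] < ends[-nrow(ec)]) || any(diff(ec$pos) == 0L))
        msgs <- c(msgs, sprintf("%s: overlapping edit spans", chrom))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EditScript
#'
#' @param edits data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}, \code{kind}; rows are sorted per chromosome.
#' @return A validated [EditScript-class].
#' @export
EditScript <- function(edits = data.frame(chrom = character(), pos = integer(),
                                          ref = character(), alt = character(),
                                          kind = character())) {
  edits <- as.data.frame(edits)[, c("chrom", "pos", "ref", "alt", "kind")]
  edits$pos <- as.integer(edits$pos)
  edits <- edits[order(edits$chrom, edits$pos), , drop = FALSE]
  rownames(edits) <- NULL
  new("EditScript", edits = edits)
}

#' @describeIn EditScript-class the edit table
#' @param x an \code{EditScript}
#' @export
edits <- function(x) {
  stopifnot(is(x, "EditScript"))
  x@edits
}

setMethod("show", "EditScript", function(object) {
  e <- object@edits
  cat("EditScript with", nrow(e), "edit(s) (",
      sum(e$kind == "SNV"), "SNV,", sum(e$kind == "INDEL"), "indel )\n")
  if (nrow(e)) print(utils::head(e, 5L))
  if (nrow(e) > 5L) cat("  ...\n")
})

## ---------------------------------------------------------------------------
## PloidyScheme: per-chromosome haploid capacity of the cohort, plus the
## per-sample ploidy used for genotype arity checks.
## ---------------------------------------------------------------------------

#' Cohort ploidy scheme
#'
#' Records, per chromosome, the total haploid capacity of a cohort and each
#' sample's ploidy there. For a cohort of diploid samples the autosomal
#' capacity is two haploids per sample; the X capacity counts two haploids per
#' female (males are excluded from X, matching a scheme where only female
#' genomes inform X); the Y capacity counts one haploid per male.
#'
#' @slot capacities named integer vector: per-chromosome haploid capacity.
#' @slot samplePloidy integer matrix (chromosome x sample) of per-sample
#'   ploidies; 0 means the sample is excluded on that chromosome.
#'
#' @seealso [ploidyScheme()], [tallyAlleles()]
#' @export
setClass("PloidyScheme", representation(
  capacities   = "integer",
  samplePloidy = "matrix"
))

setValidity("PloidyScheme", function(object) {
  if (is.null(names(object@capacities))) return("capacities must be named")
  if (any(object@capacities < 1L)) return("capacities must be >= 1")
  if (!identical(sort(names(object@capacities)),
                 sort(rownames(object@samplePloidy))))
    return("capacities and samplePloidy chromosomes disagree")
  bad <- rowSums(object@samplePloidy)[names(object@capacities)] !=
    object@capacities
  if (any(bad))
    return("capacity must equal the sum of per-sample ploidies")
  TRUE
})

#' Build a ploidy scheme from a cohort sex map
#'
#' Autosomes get ploidy 2 for every sample; \code{xChrom} gets ploidy 2 for
#' females and 0 for males; \code{yChrom} gets ploidy 1 for males and 0 for
#' females. For a 40-sample cohort of 25 males and 15 females this yields
#' capacities of 80 (autosomes), 30 (X) and 25 (Y).
#'
#' @param chroms character vector of chromosome names.
#' @param sexes named character vector, one of \code{"M"}/\code{"F"} per
#'   sample.
#' @param xChrom,yChrom names of the sex chromosomes among \code{chroms}
#'   (ignored when absent).
#' @param overrides optional named list \code{chrom -> integer vector} of
#'   per-sample ploidies overriding the default rule (e.g. for
#'   pseudo-autosomal handling).
#' @return A [PloidyScheme-class].
#' @examples
#' sexes <- setNames(rep(c("M", "F"), c(25, 15)), paste0("S", 1:40))
#' ps <- ploidyScheme(c("chr1", "chrX", "chrY"), sexes)
#' capacities(ps)
#' @export
ploidyScheme <- function(chroms, sexes, xChrom = "chrX", yChrom = "chrY",
                         overrides = NULL) {
  if (is.null(names(sexes))) stop("sexes must be a named vector")
  if (!all(sexes %in% c("M", "F"))) stop("sexes must be 'M' or 'F'")
  pl <- matrix(2L, nrow = length(chroms), ncol = length(sexes),
               dimnames = list(chroms, names(sexes)))
  if (xChrom %in% chroms) pl[xChrom, ] <- ifelse(sexes == "F", 2L, 0L)
  if (yChrom %in% chroms) pl[yChrom, ] <- ifelse(sexes == "M", 1L, 0L)
  for (chrom in names(overrides)) pl[chrom, ] <- as.integer(overrides[[chrom]])
  caps <- rowSums(pl)
  if (any(caps < 1L))
    stop("chromosome(s) with zero haploid capacity: ",
         paste(chroms[caps < 1L], collapse = ", "))
  new("PloidyScheme", capacities = setNames(as.integer(caps), chroms),
      samplePloidy = pl)
}

#' @describeIn PloidyScheme-class per-chromosome haploid capacities
#' @param x a \code{PloidyScheme}
#' @export
capacities <- function(x) {
  stopifnot(is(x, "PloidyScheme"))
  x@capacities
}

#' @describeIn PloidyScheme-class per-sample ploidy on one chromosome
#' @param chrom chromosome name
#' @export
samplePloidy <- function(x, chrom) {
  stopifnot(is(x, "PloidyScheme"))
  if (!chrom %in% rownames(x@samplePloidy))
    stop("unknown chromosome: ", chrom)
  x@samplePloidy[chrom, ]
}

setMethod("show", "PloidyScheme", function(object) {
  cat("PloidyScheme over", ncol(object@samplePloidy), "sample(s)\n")
  print(object@capacities)
})

## ---------------------------------------------------------------------------
## CohortCalls: a multi-sample small-variant call set (VCF GT semantics) with
## 0-based positions.
## ---------------------------------------------------------------------------

#' Multi-sample variant calls
#'
#' Holds the small-variant records of a cohort VCF: one row per record with a
#' 0-based reference position, the reference allele, the comma-separated
#' alternate alleles, and a character genotype matrix (records x samples) with
#' VCF GT strings ("0/1", "1", "./.", ...). Missing genotypes are kept as
#' missing, never imputed.
#'
#' @slot variants data.frame with columns \code{chrom}, \code{pos} (0-based
#'   integer), \code{ref}, \code{alt}.
#' @slot gt character matrix of GT strings, \code{nrow(variants)} x
#'   \code{length(samples)}.
#' @slot samples character vector of sample names (matrix columns).
#'
#' @seealso [readVcfCohort()], [tallyAlleles()], [individualCalls()]
#' @export
setClass("CohortCalls", representation(
  variants = "data.frame",
  gt       = "matrix",
  samples  = "character"
))

setValidity("CohortCalls", function(object) {
  v <- object@variants
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns", paste(need, collapse = ", ")))
  if (nrow(v) != nrow(object@gt) || length(object@samples) != ncol(object@gt))
    return("gt matrix dimensions disagree with variants/samples")
  if (anyDuplicated(object@samples)) return("duplicate sample names")
  if (nrow(v) && any(!nzchar(v$ref))) return("empty reference allele")
  if (nrow(v) && any(v$pos < 0L)) return("negative position")
  TRUE
})

#' Construct a CohortCalls object
#'
#' @param variants data.frame with \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt} (comma-separated alternates).
#' @param gt character matrix of VCF GT strings (records x samples).
#' @param samples sample names.
#' @return A validated [CohortCalls-class].
#' @export
CohortCalls <- function(variants, gt, samples = colnames(gt)) {
  variants <- as.data.frame(variants)
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  gt <- as.matrix(gt)
  if (is.null(samples)) stop("sample names required")
  colnames(gt) <- samples
  new("CohortCalls", variants = variants, gt = gt,
      samples = as.character(samples))
}

#' @describeIn CohortCalls-class the variant table (0-based positions)
#' @param x a \code{CohortCalls}
#' @export
variantTable <- function(x) {
  stopifnot(is(x, "CohortCalls"))
  x@variants
}

#' @describeIn CohortCalls-class the genotype matrix
#' @export
genotypes <- function(x) {
  stopifnot(is(x, "CohortCalls"))
  x@gt
}

#' @describeIn CohortCalls-class sample names
#' @export
sampleNames <- function(x) {
  stopifnot(is(x, "CohortCalls"))
  x@samples
}

setMethod("show", "CohortCalls", function(object) {
  cat("CohortCalls:", nrow(object@variants), "record(s) x",
      length(object@samples), "sample(s)\n")
  if (nrow(object@variants)) print(utils::head(object@variants, 5L))
  if (nrow(object@variants) > 5L) cat("  ...\n")
})
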