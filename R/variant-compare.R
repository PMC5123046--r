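## ---------------------------------------------------------------------------
## Per-individual variant comparison across references: shared-region
## restriction, zygosity/class tables, reference-specific variants,
## sharedness spectra.
## ---------------------------------------------------------------------------

#' Extract one individual's variant calls from a cohort
#'
#' Keeps records where the sample carries at least one alternate allele,
#' annotating zygosity (from GT only: identical called alleles are
#' \code{HOM}, differing alleles \code{HET}; haploid non-reference calls are
#' \code{HOM}) and class (\code{SNV} when the reference and every carried
#' alternate are single bases, otherwise \code{INDEL}). Records with a
#' half-missing genotype are excluded and reported in the
#' \code{"excluded"} attribute.
#'
#' @param calls a [CohortCalls-class].
#' @param sample sample name.
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{gt}, \code{zygosity}, \code{class}.
#' @export
individualCalls <- function(calls, sample) {
  stopifnot(is(calls, "CohortCalls"))
  if (!sample %in% sampleNames(calls)) stop("sample not found: ", sample)
  v <- variantTable(calls)
  g <- genotypes(calls)[, sample]
  keep <- logical(nrow(v))
  zyg <- character(nrow(v))
  cls <- character(nrow(v))
  excluded <- integer(0)
  for (i in seq_len(nrow(v))) {
    gi <- parseGT(g[i])
    if (all(is.na(gi))) next
    if (any(is.na(gi))) { excluded <- c(excluded, i); next }
    if (!any(gi > 0L)) next
    keep[i] <- TRUE
    zyg[i] <- if (length(gi) == 1L || gi[1L] == gi[2L]) "HOM" else "HET"
    alts <- strsplit(v$alt[i], ",", fixed = TRUE)[[1L]]
    carried <- alts[setdiff(unique(gi), 0L)]
    cls[i] <- if (nchar(v$ref[i]) == 1L && all(nchar(carried) == 1L))
      "SNV" else "INDEL"
  }
  out <- data.frame(v[keep, , drop = FALSE], gt = g[keep],
                    zygosity = zyg[keep], class = cls[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- v[excluded, , drop = FALSE]
  out
}

#' Restrict calls to regions mappable across all references
#'
#' Keeps only calls whose reference span is mappable under every supplied
#' chain, so comparisons are made within the regions shared by all
#' references. In \code{mode = "span"} (default) the whole span must sit in
#' one aligned block; in \code{mode = "base"} each spanned base must be
#' individually mappable (the span may straddle an insertion).
#'
#' @param calls data.frame of calls (see [individualCalls()]).
#' @param chains list of [Chain-class] objects rooted at the calls'
#'   reference.
#' @param mode \code{"span"} or \code{"base"}.
#' @return the filtered calls.
#' @export
restrictToSharedRegions <- function(calls, chains, mode = c("span", "base")) {
  mode <- match.arg(mode)
  if (!length(chains)) stop("at least one chain is required")
  keep <- rep(TRUE, nrow(calls))
  for (chain in chains) {
    stopifnot(is(chain, "Chain"))
    for (chrom in unique(calls$chrom)) {
      idx <- which(calls$chrom == chrom)
      if (!chrom %in% names(chain@blocks)) { keep[idx] <- FALSE; next }
      lens <- nchar(calls$ref[idx])
      if (mode == "span") {
        keep[idx] <- keep[idx] &
          !is.na(mapSpan(chain, chrom, calls$pos[idx], lens))
      } else {
        for (j in seq_along(idx)) {
          bases <- calls$pos[idx[j]] + seq_len(lens[j]) - 1L
          keep[idx[j]] <- keep[idx[j]] &&
            !anyNA(mapPosition(chain, chrom, bases))
        }
      }
    }
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count calls by zygosity and variant class
#'
#' @param calls data.frame with \code{zygosity} and \code{class} columns.
#' @return 2x2 integer matrix (rows HOM/HET, columns SNV/INDEL); the four
#'   cells partition the input.
#' @export
countByZygosityClass <- function(calls) {
  tab <- table(factor(calls$zygosity, levels = c("HOM", "HET")),
               factor(calls$class, levels = c("SNV", "INDEL")))
  m <- matrix(as.integer(tab), 2L, 2L,
              dimnames = list(c("HOM", "HET"), c("SNV", "INDEL")))
  m
}

## normalized identity key for one call: chrom + per-carried-allele
## normalized events with multiplicities (so genotype must carry the same
## alleles to match)
callKeys <- function(calls, seqs = NULL, lifted = FALSE) {
  n <- nrow(calls)
  out <- character(n)
  for (i in seq_len(n)) {
    chrom <- calls$chrom[i]
    if (lifted) {
      pos <- calls$newPos[i]; ref <- calls$newRef[i]
      alts <- strsplit(calls$newAlt[i], ",", fixed = TRUE)[[1L]]
      gt <- calls$newGt[i]
      if (is.na(gt)) gt <- calls$gt[i]
    } else {
      pos <- calls$pos[i]; ref <- calls$ref[i]
      alts <- strsplit(calls$alt[i], ",", fixed = TRUE)[[1L]]
      gt <- calls$gt[i]
    }
    alts <- setdiff(alts, c(".", ""))
    gi <- parseGT(gt)
    gi <- gi[!is.na(gi)]
    carried <- sort(gi[gi > 0L])
    seqStr <- if (!is.null(seqs) && chrom %in% names(seqs))
      as.character(seqs[[chrom]]) else NULL
    evs <- vapply(carried, function(k) {
      nm <- normalizeAllele(pos, ref, alts[k], seqStr)
      paste(nm$pos, nm$ref, nm$alt, sep = ":")
    }, character(1))
    out[i] <- paste(chrom, paste(evs, collapse = "|"), sep = "@")
  }
  out
}

#' Decompose two references' call sets into shared and reference-specific
#'
#' Lifts the first call set onto the second reference and matches variants
#' by position, normalized alleles and genotype-carried alleles. Calls whose
#' lift fails are reference-A-specific; \code{REF_CHANGED} lifts whose
#' re-expressed genotype is homozygous-reference vanish on B and are also
#' A-specific. Unmatched B calls are B-specific.
#'
#' @param callsA,callsB per-individual call data.frames (same individual)
#'   against references A and B.
#' @param chain [Chain-class] from A to B coordinates.
#' @param targetB [Biostrings::DNAStringSet] of reference B.
#' @return list with \code{shared} (matched A calls), \code{aOnly},
#'   \code{bOnly}, and the lifted A table as \code{liftedA}.
#' @export
referenceSpecificVariants <- function(callsA, callsB, chain, targetB) {
  liftedA <- liftCalls(callsA, chain, targetB)
  aKeys <- rep(NA_character_, nrow(liftedA))
  vanish <- rep(FALSE, nrow(liftedA))
  ok <- liftedA$status != "UNMAPPED"
  if (any(ok)) {
    sub <- liftedA[ok, , drop = FALSE]
    gi <- lapply(ifelse(is.na(sub$newGt), sub$gt, sub$newGt), parseGT)
    vanish[ok] <- vapply(gi, function(x) all(x[!is.na(x)] == 0L), logical(1))
    aKeys[ok] <- callKeys(sub, seqs = targetB, lifted = TRUE)
  }
  bKeys <- callKeys(callsB, seqs = targetB)
  matched <- !is.na(aKeys) & !vanish & aKeys %in% bKeys
  shared <- liftedA[matched, , drop = FALSE]
  aOnly <- liftedA[!matched, , drop = FALSE]
  bOnly <- callsB[!(bKeys %in% aKeys[matched]), , drop = FALSE]
  rownames(shared) <- rownames(aOnly) <- rownames(bOnly) <- NULL
  list(shared = shared, aOnly = aOnly, bOnly = bOnly, liftedA = liftedA)
}

#' Sharedness spectrum of variants across individuals
#'
#' Tabulates, over the distinct variants observed in any individual, how
#' many individuals carry each variant (identity by normalized position and
#' alleles, zygosity ignored), returning the histogram over 1..n
#' individuals.
#'
#' @param callsList list (length >= 2) of per-individual call data.frames on
#'   a common reference.
#' @param seqs optional [Biostrings::DNAStringSet] for indel left-alignment
#'   during normalization.
#' @return named integer vector; element \code{k} counts variants present in
#'   exactly \code{k} individuals.
#' @export
sharednessSpectrum <- function(callsList, seqs = NULL) {
  if (length(callsList) < 2L) stop("need at least two individuals")
  keysets <- lapply(callsList, function(calls) {
    if (!nrow(calls)) return(character(0))
    keys <- character(0)
    for (i in seq_len(nrow(calls))) {
      chrom <- calls$chrom[i]
      seqStr <- if (!is.null(seqs) && chrom %in% names(seqs))
        as.character(seqs[[chrom]]) else NULL
      alts <- setdiff(strsplit(calls$alt[i], ",", fixed = TRUE)[[1L]],
                      c(".", ""))
      gi <- parseGT(calls$gt[i])
      carried <- unique(gi[!is.na(gi) & gi > 0L])
      for (k in carried) {
        nm <- normalizeAllele(calls$pos[i], calls$ref[i], alts[k], seqStr)
        keys <- c(keys, paste(chrom, nm$pos, nm$ref, nm$alt, sep = ":"))
      }
    }
    unique(keys)
  })
  inc <- table(unlist(keysets))
  n <- length(callsList)
  hist <- integer(n)
  if (length(inc)) {
    tb <- table(factor(as.integer(inc), levels = seq_len(n)))
    hist <- as.integer(tb)
  }
  names(hist) <- seq_len(n)
  hist
}
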