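## ---------------------------------------------------------------------------
## Consensus construction: tally cohort alleles per site, select substitutions
## under ploidy-aware thresholds, apply them to the baseline reference, and
## derive the induced lift-over chain.
## ---------------------------------------------------------------------------

#' Normalize one variant allele pair
#'
#' Parsimony-trims the shared suffix then prefix of a ref/alt pair (adjusting
#' the 0-based position) and, when the chromosome sequence is supplied,
#' left-aligns pure insertions and deletions through repeat context, so that
#' identical events in different VCF representations aggregate to the same
#' normalized key.
#'
#' @param pos 0-based position of \code{ref} on the chromosome.
#' @param ref,alt allele strings (\code{ref} non-empty on input).
#' @param seq optional chromosome sequence as a single character string,
#'   enabling left-alignment.
#' @return list with normalized \code{pos}, \code{ref}, \code{alt}.
#' @export
normalizeAllele <- function(pos, ref, alt, seq = NULL) {
  if (ref == alt) stop("ref and alt alleles are identical")
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt)) &&
         !(nchar(ref) == 1L && nchar(alt) == 1L)) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         !(nchar(ref) == 1L && nchar(alt) == 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (!is.null(seq)) {
    if (nchar(alt) == 0L && nchar(ref) > 0L) {
      L <- nchar(ref)
      while (pos > 0L && substr(seq, pos, pos) == substr(seq, pos + L, pos + L))
        pos <- pos - 1L
      ref <- substr(seq, pos + 1L, pos + L)
    } else if (nchar(ref) == 0L && nchar(alt) > 0L) {
      while (pos > 0L &&
             substr(seq, pos, pos) == substr(alt, nchar(alt), nchar(alt))) {
        alt <- paste0(substr(seq, pos, pos), substr(alt, 1L, nchar(alt) - 1L))
        pos <- pos - 1L
      }
    }
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

alleleKind <- function(ref, alt) {
  if (nchar(ref) != nchar(alt)) "INDEL"
  else if (nchar(ref) == 1L) "SNV"
  else "MNV"
}

#' Tally cohort alleles per site over called haploids
#'
#' Decomposes every record per alternate allele (normalized with
#' [normalizeAllele()]), then counts haploid support per allele at each site
#' key \code{(chrom, pos, ref)}. Samples whose ploidy on a chromosome is 0
#' under \code{scheme} are excluded there (e.g. males on X when only female
#' genomes inform X); missing genotype slots are excluded from counts but
#' retained in the chromosome's haploid capacity (\code{total}). The
#' reference-allele count at a site is the number of called haploids not
#' carrying any of the site's alternate alleles.
#'
#' @param calls a [CohortCalls-class].
#' @param scheme a [PloidyScheme-class] covering every chromosome in
#'   \code{calls}.
#' @param reference optional [Biostrings::DNAStringSet] enabling indel
#'   left-alignment.
#' @return data.frame with one row per (site, allele): \code{chrom},
#'   \code{pos}, \code{ref} (site key, 0-based), \code{allele}, \code{kind}
#'   (\code{REF}, \code{SNV}, \code{MNV} or \code{INDEL}), \code{count}
#'   (supporting haploids), \code{called} (called haploids at the record),
#'   \code{total} (chromosome haploid capacity).
#' @examples
#' # 2 diploid samples, both heterozygous at one SNV
#' cc <- CohortCalls(data.frame(chrom = "chr1", pos = 9L, ref = "A", alt = "G"),
#'                   matrix(c("0/1", "0/1"), 1, dimnames = list(NULL, c("s1", "s2"))))
#' ps <- ploidyScheme("chr1", c(s1 = "M", s2 = "F"))
#' tallyAlleles(cc, ps)
#' @export
tallyAlleles <- function(calls, scheme, reference = NULL) {
  stopifnot(is(calls, "CohortCalls"), is(scheme, "PloidyScheme"))
  v <- variantTable(calls)
  gtm <- genotypes(calls)
  pieces <- list()
  for (chrom in unique(v$chrom)) {
    idx <- which(v$chrom == chrom)
    pl <- samplePloidy(scheme, chrom)
    inc <- pl > 0L
    g <- gtm[idx, inc, drop = FALSE]
    pli <- pl[inc]
    g[] <- gsub("|", "/", g, fixed = TRUE)
    nal <- matrix(1L + nchar(g) - nchar(gsub("/", "", g, fixed = TRUE)),
                  nrow = nrow(g))
    if (any(nal > 2L))
      stop("genotypes with more than two alleles are not supported")
    fullMissing <- g == "." | g == "./."
    bad <- !fullMissing & nal != matrix(pli, nrow(g), ncol(g), byrow = TRUE)
    if (any(bad))
      stop("genotype arity conflicts with ploidy scheme on ", chrom)
    a1 <- sub("/.*$", "", g)
    a2 <- ifelse(nal == 2L, sub("^.*/", "", g), NA_character_)
    a1[a1 == "."] <- NA_character_
    a2[!is.na(a2) & a2 == "."] <- NA_character_
    dim(a1) <- dim(g); dim(a2) <- dim(g)
    called <- as.integer(rowSums(!is.na(a1)) + rowSums(!is.na(a2)))
    altLists <- strsplit(v$alt[idx], ",", fixed = TRUE)
    maxK <- max(c(1L, lengths(altLists)))
    cnt <- matrix(0L, length(idx), maxK + 1L)
    for (k in 0:maxK) {
      ks <- as.character(k)
      cnt[, k + 1L] <- as.integer(rowSums(a1 == ks, na.rm = TRUE) +
                                    rowSums(a2 == ks, na.rm = TRUE))
    }
    nAlt <- lengths(altLists)
    for (k in seq_len(maxK))
      if (any(cnt[, k + 1L] > 0L & nAlt < k))
        stop("genotype allele index exceeds the record's allele count")
    cap <- capacities(scheme)[[chrom]]
    seqStr <- if (!is.null(reference) && chrom %in% names(reference))
      as.character(reference[[chrom]]) else NULL

    ## fast path: biallelic SNV records need no normalization
    simple <- !grepl(",", v$alt[idx], fixed = TRUE) &
      nchar(v$ref[idx]) == 1L & nchar(v$alt[idx]) == 1L &
      v$alt[idx] != "."
    if (any(simple)) {
      j <- which(simple)
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = chrom,
        pos = rep(v$pos[idx][j], 2L),
        ref = rep(v$ref[idx][j], 2L),
        allele = c(v$ref[idx][j], v$alt[idx][j]),
        kind = rep(c("REF", "SNV"), each = length(j)),
        count = c(called[j] - cnt[j, 2L], cnt[j, 2L]),
        called = rep(called[j], 2L),
        total = cap, stringsAsFactors = FALSE)
    }
    for (j in which(!simple)) {
      alts <- setdiff(altLists[[j]], c(".", ""))
      rpos <- v$pos[idx][j]; rref <- v$ref[idx][j]
      if (!length(alts)) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = chrom, pos = rpos, ref = rref, allele = rref,
          kind = "REF", count = called[j], called = called[j], total = cap,
          stringsAsFactors = FALSE)
        next
      }
      nm <- lapply(seq_along(alts), function(k)
        normalizeAllele(rpos, rref, alts[k], seqStr))
      ev <- data.frame(
        pos = vapply(nm, `[[`, integer(1), "pos"),
        ref = vapply(nm, `[[`, character(1), "ref"),
        allele = vapply(nm, `[[`, character(1), "alt"),
        count = cnt[j, seq_along(alts) + 1L],
        stringsAsFactors = FALSE)
      ev$kind <- mapply(alleleKind, ev$ref, ev$allele, USE.NAMES = FALSE)
      siteKey <- paste(ev$pos, ev$ref, sep = "\r")
      refRows <- do.call(rbind, lapply(unique(siteKey), function(sk) {
        at <- siteKey == sk
        data.frame(pos = ev$pos[at][1L], ref = ev$ref[at][1L],
                   allele = ev$ref[at][1L], count = called[j] -
                     sum(ev$count[at]), kind = "REF", stringsAsFactors = FALSE)
      }))
      both <- rbind(ev[, c("pos", "ref", "allele", "count", "kind")], refRows)
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = chrom, both[, c("pos", "ref", "allele", "kind", "count")],
        called = called[j], total = cap, stringsAsFactors = FALSE)
    }
  }
  tally <- do.call(rbind, pieces)
  ## aggregate identical normalized events across records
  key <- paste(tally$chrom, tally$pos, tally$ref, tally$allele, tally$kind,
               sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(tally[, c("count", "called")], key, reorder = FALSE)
    first <- !duplicated(key)
    tally <- tally[first, , drop = FALSE]
    tally$count <- agg[match(key[first], rownames(agg)), "count"]
    tally$called <- agg[match(key[first], rownames(agg)), "called"]
  }
  tally <- tally[order(tally$chrom, tally$pos, tally$kind != "REF",
                       -tally$count), , drop = FALSE]
  rownames(tally) <- NULL
  tally
}

#' Select single-nucleotide substitutions from a site tally
#'
#' A substitution is emitted at a site if and only if the most frequent
#' single-base allele over called haploids differs from the reference base;
#' ties (no unique most frequent allele) keep the reference.
#'
#' @param tally output of [tallyAlleles()].
#' @return data.frame of candidate edits: \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{kind = "SNV"}, \code{support},
#'   \code{called}, \code{total}.
#' @export
selectSnvSubstitutions <- function(tally) {
  t1 <- tally[tally$kind %in% c("REF", "SNV") & nchar(tally$ref) == 1L &
                nchar(tally$allele) == 1L, , drop = FALSE]
  if (!nrow(t1)) return(emptyEdits())
  key <- paste(t1$chrom, t1$pos, t1$ref, sep = "\r")
  ## per site: the edit is the unique top-count allele when it is an
  ## alternate; ties (no unique most frequent allele) keep the reference
  o <- order(key, -t1$count, t1$kind == "REF")
  t1 <- t1[o, , drop = FALSE]
  key <- key[o]
  firstAt <- which(!duplicated(key))
  n <- nrow(t1)
  nextAt <- pmin(firstAt + 1L, n)
  tie <- key[nextAt] == key[firstAt] & nextAt > firstAt &
    t1$count[nextAt] == t1$count[firstAt]
  sel <- firstAt[!tie & t1$kind[firstAt] == "SNV" & t1$count[firstAt] > 0L]
  if (!length(sel)) return(emptyEdits())
  picks <- t1[sel, , drop = FALSE]
  ed <- data.frame(chrom = picks$chrom, pos = picks$pos, ref = picks$ref,
                   alt = picks$allele, kind = "SNV", support = picks$count,
                   called = picks$called, total = picks$total,
                   stringsAsFactors = FALSE)
  ed[order(ed$chrom, ed$pos), , drop = FALSE]
}

#' Select indel substitutions from a site tally
#'
#' An indel substitution is emitted when its supporting haploid count
#' strictly exceeds \code{fraction} of the chromosome's haploid capacity: at
#' the default \code{fraction = 0.5} an autosomal indel in a 40-diploid
#' cohort needs more than 40 of 80 haploids, an X indel (15 females) more
#' than 15 of 30.
#'
#' @param tally output of [tallyAlleles()].
#' @param fraction capacity fraction that support must strictly exceed.
#' @return data.frame of candidate edits (same layout as
#'   [selectSnvSubstitutions()], \code{kind = "INDEL"}).
#' @export
selectIndelSubstitutions <- function(tally, fraction = 0.5) {
  t1 <- tally[tally$kind == "INDEL", , drop = FALSE]
  t1 <- t1[t1$count > fraction * t1$total, , drop = FALSE]
  if (!nrow(t1)) return(emptyEdits())
  ## at most one allele can pass per site within a record; across records a
  ## site could collide -- keep the unique best, drop ties
  key <- paste(t1$chrom, t1$pos, t1$ref, sep = "\r")
  picks <- lapply(split(seq_len(nrow(t1)), key), function(i) {
    rows <- t1[i, , drop = FALSE]
    top <- which(rows$count == max(rows$count))
    if (length(top) != 1L) return(NULL)
    rows[top, , drop = FALSE]
  })
  picks <- do.call(rbind, picks)
  if (is.null(picks)) return(emptyEdits())
  ed <- data.frame(chrom = picks$chrom, pos = picks$pos, ref = picks$ref,
                   alt = picks$allele, kind = "INDEL", support = picks$count,
                   called = picks$called, total = picks$total,
                   stringsAsFactors = FALSE)
  ed[order(ed$chrom, ed$pos), , drop = FALSE]
}

emptyEdits <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), kind = character(), support = integer(),
             called = integer(), total = integer(), stringsAsFactors = FALSE)
}

## do spans [s,e) and [os,oe) conflict as edit spans (zero-width = insertion)?
spanConflict <- function(s, e, os, oe) {
  (s < oe & os < e) | s == os
}

#' Combine SNV and indel candidates into a conflict-free edit script
#'
#' Substitution precedence is SNVs first, then indels in decreasing support
#' order; any indel whose reference span overlaps a previously accepted edit
#' is dropped and reported.
#'
#' @param snvEdits,indelEdits candidate tables from
#'   [selectSnvSubstitutions()] / [selectIndelSubstitutions()].
#' @return list with \code{script} (an [EditScript-class]) and \code{report}
#'   (every candidate with \code{status} accepted/dropped and a \code{reason}
#'   for drops).
#' @export
combineEditCandidates <- function(snvEdits, indelEdits) {
  sn <- as.data.frame(snvEdits)
  ind <- as.data.frame(indelEdits)
  ## SNVs first; a duplicate position (multiple records) keeps the best
  ## supported candidate
  sn <- sn[order(sn$chrom, sn$pos, -sn$support), , drop = FALSE]
  dup <- duplicated(paste(sn$chrom, sn$pos, sep = "\r"))
  sn$status <- ifelse(dup, "dropped", "accepted")
  sn$reason <- ifelse(dup, "duplicate SNV candidate at site", "")
  snvPos <- split(sn$pos[!dup], sn$chrom[!dup])
  ## indels in decreasing support order; drop on overlap with any accepted
  ## edit
  ind <- ind[order(-ind$support, ind$chrom, ind$pos), , drop = FALSE]
  ind$status <- rep("accepted", nrow(ind))
  ind$reason <- rep("", nrow(ind))
  occS <- list(); occE <- list()
  for (i in seq_len(nrow(ind))) {
    chrom <- ind$chrom[i]
    s <- ind$pos[i]; e <- s + nchar(ind$ref[i])
    ps <- snvPos[[chrom]]
    hit <- (!is.null(ps) && any(ps >= s & ps < max(e, s + 1L))) ||
      (!is.null(occS[[chrom]]) &&
         any(spanConflict(s, e, occS[[chrom]], occE[[chrom]])))
    if (hit) {
      ind$status[i] <- "dropped"
      ind$reason[i] <- "overlaps accepted edit"
    } else {
      occS[[chrom]] <- c(occS[[chrom]], s)
      occE[[chrom]] <- c(occE[[chrom]], e)
    }
  }
  rep <- rbind(sn, ind)
  rep <- rep[order(rep$chrom, rep$pos), , drop = FALSE]
  rownames(rep) <- NULL
  acc <- rep[rep$status == "accepted", , drop = FALSE]
  list(script = EditScript(acc[, c("chrom", "pos", "ref", "alt", "kind")]),
       report = rep)
}

#' Apply an edit script to a reference
#'
#' Replaces each edit's reference span by its replacement, left to right, and
#' derives the induced lift-over [Chain-class]: length-preserving (SNV) edits
#' do not break chain blocks; indels close the current block and introduce a
#' source gap (deleted bases) and/or target gap (inserted bases).
#'
#' @param reference a [Biostrings::DNAStringSet].
#' @param script an [EditScript-class]; every edit's \code{ref} must match
#'   the reference at its position (checked, mismatch aborts).
#' @return list with \code{consensus} (a \code{DNAStringSet}) and
#'   \code{chain} (a [Chain-class] from reference to consensus coordinates).
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' es <- EditScript(data.frame(chrom = "chr1", pos = c(2L, 4L),
#'                             ref = c("G", "AC"), alt = c("T", ""),
#'                             kind = c("SNV", "INDEL")))
#' applyEdits(ref, es)$consensus
#' @export
applyEdits <- function(reference, script) {
  stopifnot(is(script, "EditScript"))
  refChr <- as.character(reference)
  e <- edits(script)
  cons <- character(length(refChr))
  names(cons) <- names(refChr)
  blocks <- list()
  tgtLengths <- integer()
  for (chrom in names(refChr)) {
    s <- refChr[[chrom]]
    n <- nchar(s)
    ec <- e[e$chrom == chrom, , drop = FALSE]
    pieces <- character(0)
    blk <- list()
    blockStart <- 0L; delta <- 0L; cur <- 0L
    for (i in seq_len(nrow(ec))) {
      pos <- ec$pos[i]; ref <- ec$ref[i]; alt <- ec$alt[i]
      L <- nchar(ref)
      if (pos + L > n)
        stop(sprintf("edit beyond end of %s at position %d", chrom, pos))
      span <- if (L > 0L) substr(s, pos + 1L, pos + L) else ""
      if (span != ref)
        stop(sprintf("edit reference mismatch at %s:%d (expected '%s', found '%s')",
                     chrom, pos, ref, span))
      if (pos > cur) pieces <- c(pieces, substr(s, cur + 1L, pos))
      if (nchar(alt) == L) {              # length-preserving: block continues
        pieces <- c(pieces, alt)
        cur <- pos + L
      } else {
        if (pos > blockStart)
          blk[[length(blk) + 1L]] <- c(blockStart, pos, blockStart + delta,
                                       pos + delta)
        pieces <- c(pieces, alt)
        delta <- delta + nchar(alt) - L
        cur <- pos + L
        blockStart <- cur
      }
    }
    if (cur < n) pieces <- c(pieces, substr(s, cur + 1L, n))
    if (n > blockStart)
      blk[[length(blk) + 1L]] <- c(blockStart, n, blockStart + delta,
                                   n + delta)
    cons[[chrom]] <- paste(pieces, collapse = "")
    bm <- if (length(blk)) do.call(rbind, blk) else
      matrix(integer(), 0L, 4L)
    blocks[[chrom]] <- data.frame(srcStart = bm[, 1L], srcEnd = bm[, 2L],
                                  tgtStart = bm[, 3L], tgtEnd = bm[, 4L])
    tgtLengths[[chrom]] <- nchar(cons[[chrom]])
  }
  list(consensus = Biostrings::DNAStringSet(cons),
       chain = Chain(blocks, seqLengths(reference), tgtLengths))
}

#' Build a consensus reference from a cohort call set
#'
#' End-to-end composition: tally alleles under the ploidy scheme, select
#' single-nucleotide substitutions (cohort-major allele) and indel
#' substitutions (haploid support strictly above \code{indelFraction} of
#' chromosome capacity), resolve conflicts, and apply the resulting edit
#' script to the baseline reference.
#'
#' @param reference baseline reference, a [Biostrings::DNAStringSet].
#' @param calls cohort [CohortCalls-class].
#' @param scheme [PloidyScheme-class] for the cohort.
#' @param indelFraction capacity fraction an indel's haploid support must
#'   strictly exceed (default 0.5, i.e. more than 40 of 80 autosomal
#'   haploids in a 40-diploid cohort).
#' @return list with \code{consensus} (DNAStringSet), \code{chain}
#'   ([Chain-class] reference -> consensus), \code{script}
#'   ([EditScript-class]) and \code{report} (every candidate substitution
#'   with haploid support and accepted/dropped status).
#' @export
buildConsensus <- function(reference, calls, scheme, indelFraction = 0.5) {
  tally <- tallyAlleles(calls, scheme, reference = reference)
  snv <- selectSnvSubstitutions(tally)
  ind <- selectIndelSubstitutions(tally, fraction = indelFraction)
  comb <- combineEditCandidates(snv, ind)
  applied <- applyEdits(reference, comb$script)
  list(consensus = applied$consensus, chain = applied$chain,
       script = comb$script, report = comb$report)
}
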