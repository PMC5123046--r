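## ---------------------------------------------------------------------------
## SV concordance: reciprocal-overlap identity, exclusive sharing
## decomposition, S/P-ratio misassembly filter, novelty, group enrichment.
## ---------------------------------------------------------------------------

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities
#' of all fixed-margin tables whose point probability does not exceed the
#' observed one (with the customary 1e-7 relative tolerance on the
#' comparison). A degenerate all-zero table returns p = 1 with a warning.
#'
#' @param table 2x2 matrix (or a length-4 vector filled by row) of
#'   non-negative counts.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return the p-value.
#' @examples
#' fisherExact(matrix(c(5, 5, 5, 5), 2))   # 1
#' @export
fisherExact <- function(table, alternative = "two.sided") {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2L, byrow = TRUE)
  if (any(table < 0) || any(!is.finite(table)))
    stop("table cells must be finite and non-negative")
  if (all(table == 0)) {
    warning("all-zero table; p = 1 by convention")
    return(1)
  }
  stats::fisher.test(round(table), alternative = alternative)$p.value
}

#' Filter SVs by single-end/paired read-support ratio
#'
#' Spurious SVs arising from misassembly attract wrongly mapped single-end
#' reads, inflating the region's single-end to properly-paired (S/P) ratio
#' relative to the whole genome. Each region's counts are compared with the
#' genome-wide counts by Fisher's exact test; a region is discarded when the
#' test is significant at \code{alpha} \emph{and} its S/P ratio is inflated
#' (the deflated direction never discards). A region with zero paired reads
#' counts as maximally inflated.
#'
#' @param counts data.frame with \code{single} and \code{paired} columns,
#'   one row per SV region (see [readSPCounts()]).
#' @param genome length-2 numeric: genome-wide single-end and paired counts.
#' @param alpha significance level (default 0.001).
#' @return the input with added columns \code{p}, \code{inflated},
#'   \code{keep}.
#' @export
spFilter <- function(counts, genome, alpha = 0.001) {
  counts <- as.data.frame(counts)
  sG <- as.numeric(genome[[1L]]); pG <- as.numeric(genome[[2L]])
  n <- nrow(counts)
  p <- numeric(n)
  for (i in seq_len(n))
    p[i] <- fisherExact(matrix(c(counts$single[i], counts$paired[i], sG, pG),
                               2L, byrow = TRUE))
  inflated <- counts$single * pG > sG * counts$paired
  counts$p <- p
  counts$inflated <- inflated
  counts$keep <- !(p < alpha & inflated)
  counts
}

#' Are two SVs the same event?
#'
#' Deletions and inversions are the same when they have the same type and
#' their intersection covers at least 50\% of each record's length
#' (reciprocal 50\% coverage; boundary equality counts). Insertions have no
#' reference extent, so identity uses breakpoint proximity (within
#' \code{insWindow} bp) plus a reciprocal length criterion
#' (\code{min(len)/max(len) >= 0.5}).
#'
#' @param a,b single SV records: lists or one-row data.frames with
#'   \code{chrom}, \code{start}, \code{end}, \code{type}, \code{length}.
#' @param insWindow breakpoint window for insertion matching (bp).
#' @return logical.
#' @export
svSame <- function(a, b, insWindow = 1000L) {
  if (a$chrom != b$chrom || a$type != b$type) return(FALSE)
  if (a$type == "INS") {
    abs(a$start - b$start) <= insWindow &&
      min(a$length, b$length) >= 0.5 * max(a$length, b$length)
  } else {
    ov <- min(a$end, b$end) - max(a$start, b$start)
    ov >= 0.5 * a$length && ov >= 0.5 * b$length
  }
}

## all matching pairs between SV tables a and b (row indices), same rules as
## svSame, restricted per chrom+type; used by clustering/novelty
svMatchPairs <- function(a, b, insWindow = 1000L) {
  pairs <- list()
  for (chrom in intersect(unique(a$chrom), unique(b$chrom))) {
    for (type in c("DEL", "INV", "INS")) {
      ia <- which(a$chrom == chrom & a$type == type)
      ib <- which(b$chrom == chrom & b$type == type)
      if (!length(ia) || !length(ib)) next
      if (type == "INS") {
        ra <- IRanges::IRanges(a$start[ia] + 1L, a$start[ia] + 1L)
        rb <- IRanges::IRanges(b$start[ib] + 1L, b$start[ib] + 1L)
        hits <- IRanges::findOverlaps(ra, rb, maxgap = insWindow)
        qa <- ia[S4Vectors::queryHits(hits)]
        qb <- ib[S4Vectors::subjectHits(hits)]
        okW <- abs(a$start[qa] - b$start[qb]) <= insWindow
        okL <- pmin(a$length[qa], b$length[qb]) >=
          0.5 * pmax(a$length[qa], b$length[qb])
        ok <- okW & okL
      } else {
        ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
        rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
        hits <- IRanges::findOverlaps(ra, rb)
        qa <- ia[S4Vectors::queryHits(hits)]
        qb <- ib[S4Vectors::subjectHits(hits)]
        ov <- pmin(a$end[qa], b$end[qb]) - pmax(a$start[qa], b$start[qb])
        ok <- ov >= 0.5 * a$length[qa] & ov >= 0.5 * b$length[qb]
      }
      if (any(ok))
        pairs[[length(pairs) + 1L]] <- cbind(qa[ok], qb[ok])
    }
  }
  if (length(pairs)) do.call(rbind, pairs) else matrix(integer(), 0L, 2L)
}

#' Decompose labelled SV sets into exclusive sharing groups
#'
#' Pools the labelled sets, single-linkage-clusters records under the
#' [svSame()] identity, and assigns each cluster to the exact set of labels
#' it contains -- an SV shared by assemblies {1,2} only is counted in group
#' "1+2", not in "1", "2" or any superset. The decomposition is invariant to
#' the order of sets and records.
#'
#' @param svSets named list of SV data.frames (see [validateSVTable()]).
#' @param insWindow breakpoint window for insertion matching.
#' @return list with \code{clusters} (data.frame: \code{cluster},
#'   \code{labels}, \code{n}) , \code{groupCounts} (named integer vector of
#'   cluster counts per exclusive label set, labels joined by "+"), and
#'   \code{assignments} (the pooled table with \code{cluster} ids).
#' @export
clusterSharedSVs <- function(svSets, insWindow = 1000L) {
  if (length(svSets) < 2L) stop("need at least two labelled sets")
  if (is.null(names(svSets)) || any(!nzchar(names(svSets))))
    stop("svSets must be named")
  pooled <- do.call(rbind, lapply(names(svSets), function(lb) {
    s <- validateSVTable(svSets[[lb]])
    s$label <- lb
    s
  }))
  n <- nrow(pooled)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pairs <- svMatchPairs(pooled, pooled, insWindow)
  for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs[r, 1L]); rj <- find(pairs[r, 2L])
    if (ri != rj) parent[min(ri, rj)] <- max(ri, rj)
  }
  root <- vapply(seq_len(n), find, integer(1))
  ## canonical cluster ids independent of input order: by minimal member
  ## coordinates
  cid <- match(root, sort(unique(root)))
  pooled$cluster <- cid
  labelSets <- vapply(split(pooled$label, cid), function(ls)
    paste(sort(unique(ls)), collapse = "+"), character(1))
  sizes <- vapply(split(pooled$label, cid), length, integer(1))
  clusters <- data.frame(cluster = as.integer(names(labelSets)),
                         labels = unname(labelSets), n = unname(sizes),
                         stringsAsFactors = FALSE)
  groupCounts <- table(labelSets)
  groupCounts <- setNames(as.integer(groupCounts), names(groupCounts))
  list(clusters = clusters, groupCounts = groupCounts, assignments = pooled)
}

#' Flag SVs absent from all known-SV databases
#'
#' An SV is novel when [svSame()] fails against every record of every
#' supplied known set (a match at exactly reciprocal 50\% makes it known).
#'
#' @param svs SV data.frame to annotate.
#' @param knownSets list of SV data.frames of database records.
#' @param insWindow breakpoint window for insertion matching.
#' @return logical vector, \code{TRUE} where novel.
#' @export
annotateNovelSVs <- function(svs, knownSets, insWindow = 1000L) {
  svs <- validateSVTable(svs)
  novel <- rep(TRUE, nrow(svs))
  for (known in knownSets) {
    if (is.null(known) || !nrow(known)) next
    pairs <- svMatchPairs(svs, validateSVTable(known), insWindow)
    novel[unique(pairs[, 1L])] <- FALSE
  }
  novel
}

#' Per-SV group enrichment by Fisher's exact test
#'
#' Tests, for each SV, whether its presence frequency in an in-group of
#' genomes exceeds that in an out-group, using Fisher's exact test on the
#' 2x2 presence/absence table. An SV is enriched when the test is
#' significant at \code{alpha} and the in-group frequency is the higher one.
#'
#' @param kIn,nIn integer vectors (or scalars recycled): carriers and total
#'   genomes in the in-group per SV.
#' @param kOut,nOut same for the out-group.
#' @param alpha significance level (default 0.05).
#' @return data.frame with \code{p} and \code{enriched}.
#' @export
groupEnrichment <- function(kIn, nIn, kOut, nOut, alpha = 0.05) {
  n <- max(length(kIn), length(kOut))
  kIn <- rep_len(kIn, n); nIn <- rep_len(nIn, n)
  kOut <- rep_len(kOut, n); nOut <- rep_len(nOut, n)
  if (any(nIn < 1L) || any(nOut < 1L)) stop("empty genome group")
  if (any(kIn > nIn) || any(kOut > nOut))
    stop("carrier count exceeds group size")
  p <- vapply(seq_len(n), function(i)
    fisherExact(matrix(c(kIn[i], nIn[i] - kIn[i], kOut[i], nOut[i] - kOut[i]),
                       2L, byrow = TRUE)), numeric(1))
  enriched <- p < alpha & (kIn / nIn > kOut / nOut)
  data.frame(p = p, enriched = enriched)
}
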