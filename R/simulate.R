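## ---------------------------------------------------------------------------
## Seeded synthetic-data generators with planted ground truth: a diploid
## cohort over a toy reference, SV universes with planted sharing structure,
## S/P read-count profiles, and scaffold fragmentations.
## ---------------------------------------------------------------------------

## run code under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Toy population model for cohort simulation
#'
#' Defaults mirror the study conditions the package is exercised under: a
#' 50 kb autosome carrying 2,000 single-nucleotide and 200 indel sites, a
#' cohort of 40 diploid samples (25 male, 15 female), and small X/Y
#' chromosomes so the sex-specific haploid arithmetic (30 X haploids from
#' females, 25 Y haploids from males) is exercised. Per-site alternate
#' allele frequencies are uniform on (0, 1); genotypes are drawn under
#' Hardy-Weinberg; indel carrier counts are planted directly, including
#' explicit threshold-boundary sites (e.g. 40 and 41 of 80 autosomal
#' haploids).
#'
#' @param refLength autosome length (bp).
#' @param nSnv,nIndel autosomal site counts.
#' @param nMale,nFemale cohort sex composition.
#' @param missingness per-sample, per-SNV-site missing genotype probability
#'   (indel sites are never missing, keeping planted carrier counts exact).
#' @param maxIndelLen maximum indel length (bp).
#' @param xLength,nSnvX,nIndelX X-chromosome length and site counts (females
#'   only carry X here; 0 disables).
#' @param yLength,nSnvY,nIndelY Y-chromosome analogues (males, haploid).
#' @return a list of class \code{"PopulationModel"}.
#' @export
populationModel <- function(refLength = 50000L, nSnv = 2000L, nIndel = 200L,
                            nMale = 25L, nFemale = 15L, missingness = 0.02,
                            maxIndelLen = 10L,
                            xLength = 6000L, nSnvX = 60L, nIndelX = 20L,
                            yLength = 4000L, nSnvY = 40L, nIndelY = 10L) {
  model <- list(refLength = as.integer(refLength), nSnv = as.integer(nSnv),
                nIndel = as.integer(nIndel), nMale = as.integer(nMale),
                nFemale = as.integer(nFemale), missingness = missingness,
                maxIndelLen = as.integer(maxIndelLen),
                xLength = as.integer(xLength), nSnvX = as.integer(nSnvX),
                nIndelX = as.integer(nIndelX), yLength = as.integer(yLength),
                nSnvY = as.integer(nSnvY), nIndelY = as.integer(nIndelY))
  class(model) <- "PopulationModel"
  model
}

BASES <- c("A", "C", "G", "T")

## plant carriers for one indel site among the included samples
## returns GT strings over the included samples (ploidy pli each)
plantCarriers <- function(count, pli, order) {
  gt <- character(length(pli))
  remaining <- count
  for (s in order) {
    take <- min(pli[s], remaining)
    gt[s] <- if (pli[s] == 1L) as.character(take)
    else paste(c(rep("1", take), rep("0", pli[s] - take)), collapse = "/")
    remaining <- remaining - take
  }
  if (remaining > 0L) stop("carrier count exceeds haploid capacity")
  gt
}

#' Simulate a diploid cohort over a toy reference
#'
#' Generates a random reference, plants SNV and indel sites per the model,
#' draws cohort genotypes (Hardy-Weinberg at SNV sites; exact planted
#' carrier counts at indel sites), and records the ground truth every
#' downstream recovery test needs: each site's realized cohort-major allele
#' over called haploids (ties resolved to the reference) and its haploid
#' support. Byte-reproducible for a fixed seed.
#'
#' @param model a [populationModel()].
#' @param seed integer seed.
#' @param dir optional directory; when given, \code{ref.fa},
#'   \code{cohort.vcf}, \code{truth.tsv} and \code{sexes.tsv} are written
#'   there.
#' @return list with \code{reference} (DNAStringSet), \code{cohort}
#'   ([CohortCalls-class]), \code{scheme} ([PloidyScheme-class]),
#'   \code{truth} (data.frame: record coordinates, normalized event,
#'   population frequency, realized haploid support \code{altCount} /
#'   \code{called} / \code{total}, realized major allele, and
#'   \code{isEdit}), and \code{sexes}.
#' @export
simulateCohort <- function(model = populationModel(), seed = 1L, dir = NULL) {
  stopifnot(inherits(model, "PopulationModel"))
  withSeed(seed, {
    nSamples <- model$nMale + model$nFemale
    sexes <- setNames(rep(c("M", "F"), c(model$nMale, model$nFemale)),
                      sprintf("S%02d", seq_len(nSamples)))
    chromCfg <- list(chr1 = c(model$refLength, model$nSnv, model$nIndel))
    if (model$xLength > 0L && (model$nSnvX + model$nIndelX) > 0L)
      chromCfg$chrX <- c(model$xLength, model$nSnvX, model$nIndelX)
    if (model$yLength > 0L && (model$nSnvY + model$nIndelY) > 0L)
      chromCfg$chrY <- c(model$yLength, model$nSnvY, model$nIndelY)
    scheme <- ploidyScheme(names(chromCfg), sexes)
    refSeqs <- character(0)
    recs <- list()
    gts <- list()
    truth <- list()
    for (chrom in names(chromCfg)) {
      len <- chromCfg[[chrom]][1L]
      nS <- chromCfg[[chrom]][2L]
      nI <- chromCfg[[chrom]][3L]
      m <- nS + nI
      chars <- sample(BASES, len, replace = TRUE)
      margin <- 50L
      spacing <- (len - 2L * margin) %/% m
      if (spacing < model$maxIndelLen + 4L)
        stop("site density too high for ", chrom)
      jitter <- sample.int(spacing - model$maxIndelLen - 3L, m,
                           replace = TRUE) - 1L
      pos <- margin + (seq_len(m) - 1L) * spacing + jitter
      indelAt <- sort(sample.int(m, nI))
      isIndel <- seq_len(m) %in% indelAt
      pl <- samplePloidy(scheme, chrom)
      inc <- which(pl > 0L)
      pli <- pl[inc]
      cap <- capacities(scheme)[[chrom]]
      ## --- indel shape decisions + reference fixups (before reading ref
      ## bases) so every planted event is already left-aligned and trim-stable
      indelType <- rep(c("DEL", "INS"), length.out = nI)
      indelLen <- sample.int(model$maxIndelLen, nI, replace = TRUE)
      insSeq <- character(nI)
      for (k in seq_len(nI)) {
        p <- pos[indelAt[k]]
        L <- indelLen[k]
        if (indelType[k] == "DEL") {
          if (chars[p + 1L] == chars[p + L + 1L])
            chars[p + 1L] <- sample(setdiff(BASES, chars[p + L + 1L]), 1L)
        } else {
          body <- sample(BASES, L, replace = TRUE)
          if (body[L] == chars[p + 1L])
            body[L] <- sample(setdiff(BASES, chars[p + 1L]), 1L)
          insSeq[k] <- paste(body, collapse = "")
        }
      }
      seqStr <- paste(chars, collapse = "")
      ## --- SNV sites: Hardy-Weinberg draws over included samples
      snvAt <- which(!isIndel)
      nSnvHere <- length(snvAt)
      popFreq <- runif(nSnvHere)
      refBase <- chars[pos[snvAt] + 1L]
      altBase <- vapply(refBase, function(b) sample(setdiff(BASES, b), 1L),
                        character(1), USE.NAMES = FALSE)
      gtChrom <- matrix(".", m, nSamples,
                        dimnames = list(NULL, names(sexes)))
      altCount <- integer(m)
      calledHap <- integer(m)
      dip <- inc[pli == 2L]
      hap <- inc[pli == 1L]
      if (length(dip)) {
        a1 <- matrix(rbinom(nSnvHere * length(dip), 1L, popFreq),
                     nSnvHere, length(dip))
        a2 <- matrix(rbinom(nSnvHere * length(dip), 1L, popFreq),
                     nSnvHere, length(dip))
        mis <- matrix(runif(nSnvHere * length(dip)) < model$missingness,
                      nSnvHere, length(dip))
        gtS <- matrix(paste(a1, a2, sep = "/"), nSnvHere, length(dip))
        gtS[mis] <- "./."
        gtChrom[snvAt, dip] <- gtS
        altCount[snvAt] <- altCount[snvAt] +
          rowSums((a1 + a2) * !mis)
        calledHap[snvAt] <- calledHap[snvAt] + 2L * rowSums(!mis)
      }
      if (length(hap)) {
        a1 <- matrix(rbinom(nSnvHere * length(hap), 1L, popFreq),
                     nSnvHere, length(hap))
        mis <- matrix(runif(nSnvHere * length(hap)) < model$missingness,
                      nSnvHere, length(hap))
        gtS <- matrix(as.character(a1), nSnvHere, length(hap))
        gtS[mis] <- "."
        gtChrom[snvAt, hap] <- gtS
        altCount[snvAt] <- altCount[snvAt] + rowSums(a1 * !mis)
        calledHap[snvAt] <- calledHap[snvAt] + rowSums(!mis)
      }
      ## --- indel sites: plant exact carrier counts, thresholds exercised
      ## at the boundary (floor(cap/2) and floor(cap/2) + 1 first)
      half <- cap %/% 2L
      counts <- c(half, half + 1L,
                  if (nI > 2L) rbinom(nI - 2L, cap, 0.5))[seq_len(nI)]
      for (k in seq_len(nI)) {
        i <- indelAt[k]
        p <- pos[i]
        order <- sample(length(inc))
        gtChrom[i, inc] <- plantCarriers(counts[k], pli, order)
        altCount[i] <- counts[k]
        calledHap[i] <- cap
      }
      ## --- assemble records + truth
      anchor <- chars[pos + 1L]
      recRef <- character(m)
      recAlt <- character(m)
      normPos <- integer(m)
      normRef <- character(m)
      normAlt <- character(m)
      siteType <- ifelse(isIndel, "INDEL", "SNV")
      recRef[snvAt] <- refBase
      recAlt[snvAt] <- altBase
      normPos[snvAt] <- pos[snvAt]
      normRef[snvAt] <- refBase
      normAlt[snvAt] <- altBase
      for (k in seq_len(nI)) {
        i <- indelAt[k]
        p <- pos[i]
        L <- indelLen[k]
        if (indelType[k] == "DEL") {
          span <- paste(chars[(p + 2L):(p + L + 1L)], collapse = "")
          recRef[i] <- paste0(anchor[i], span)
          recAlt[i] <- anchor[i]
          normPos[i] <- p + 1L
          normRef[i] <- span
          normAlt[i] <- ""
        } else {
          recRef[i] <- anchor[i]
          recAlt[i] <- paste0(anchor[i], insSeq[k])
          normPos[i] <- p + 1L
          normRef[i] <- ""
          normAlt[i] <- insSeq[k]
        }
      }
      pf <- rep(NA_real_, m)
      pf[snvAt] <- popFreq
      refCount <- calledHap - altCount
      major <- ifelse(altCount > refCount,
                      ifelse(isIndel, recAlt, normAlt),
                      ifelse(isIndel, recRef, normRef))
      isEdit <- ifelse(isIndel, altCount > 0.5 * cap, altCount > refCount)
      refSeqs[[chrom]] <- seqStr
      recs[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = recRef,
                                  alt = recAlt, stringsAsFactors = FALSE)
      gts[[chrom]] <- gtChrom
      truth[[chrom]] <- data.frame(
        chrom = chrom, pos = pos, type = siteType, ref = recRef,
        alt = recAlt, normPos = normPos, normRef = normRef,
        normAlt = normAlt, popFreq = pf, altCount = altCount,
        called = calledHap, total = cap, major = major, isEdit = isEdit,
        stringsAsFactors = FALSE)
    }
    reference <- Biostrings::DNAStringSet(refSeqs)
    cohort <- CohortCalls(do.call(rbind, recs), do.call(rbind, gts),
                          samples = names(sexes))
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    sim <- list(reference = reference, cohort = cohort, scheme = scheme,
                truth = truth, sexes = sexes, model = model, seed = seed)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeFasta(reference, file.path(dir, "ref.fa"))
      writeCohortVcf(cohort, file.path(dir, "cohort.vcf"),
                     lengths = seqLengths(reference))
      write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(sample = names(sexes), sex = sexes),
                  file.path(dir, "sexes.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    sim
  })
}

#' Draw a held-out individual from a simulated population
#'
#' Draws a fresh diploid genotype at every SNV site of a [simulateCohort()]
#' output, from the same per-site population frequencies (X sites only for
#' females, Y sites haploid for males).
#'
#' @param sim output of [simulateCohort()].
#' @param seed integer seed (independent of the cohort's).
#' @param sex \code{"F"} or \code{"M"}.
#' @return data.frame of SNV truth rows with allele draws \code{a1},
#'   \code{a2} (\code{a2} is NA on haploid chromosomes); 1 = alternate.
#' @export
simulateIndividual <- function(sim, seed, sex = c("F", "M")) {
  sex <- match.arg(sex)
  withSeed(seed, {
    tr <- sim$truth[sim$truth$type == "SNV", , drop = FALSE]
    ploidy <- ifelse(tr$chrom == "chrY", ifelse(sex == "M", 1L, 0L),
                     ifelse(tr$chrom == "chrX" & sex == "M", 0L, 2L))
    tr <- tr[ploidy > 0L, , drop = FALSE]
    ploidy <- ploidy[ploidy > 0L]
    tr$a1 <- rbinom(nrow(tr), 1L, tr$popFreq)
    tr$a2 <- ifelse(ploidy == 2L, rbinom(nrow(tr), 1L, tr$popFreq),
                    NA_integer_)
    rownames(tr) <- NULL
    tr
  })
}

#' Count an individual's homozygous SNV variants against a reference
#'
#' For each SNV site the individual's base (reference or alternate per the
#' draws) is compared with the base the target reference carries there. With
#' no \code{target} the baseline reference allele is used; with a consensus
#' \code{target} and its \code{chain}, the site is mapped and the consensus
#' base read out (sites deleted in the consensus are skipped). A site counts
#' when both alleles agree and differ from the target's base.
#'
#' @param indiv output of [simulateIndividual()].
#' @param target optional consensus [Biostrings::DNAStringSet].
#' @param chain [Chain-class] from baseline to \code{target} (required with
#'   \code{target}).
#' @return integer count of homozygous variant sites.
#' @export
countHomozygousVariants <- function(indiv, target = NULL, chain = NULL) {
  hom <- !is.na(indiv$a1) &
    (is.na(indiv$a2) | indiv$a1 == indiv$a2)
  base <- ifelse(indiv$a1 == 1L, indiv$normAlt, indiv$normRef)
  if (is.null(target)) {
    return(sum(hom & base != indiv$normRef))
  }
  stopifnot(!is.null(chain))
  tgtChr <- as.character(target)
  count <- 0L
  for (chrom in unique(indiv$chrom)) {
    idx <- which(indiv$chrom == chrom & hom)
    if (!length(idx)) next
    mp <- mapPosition(chain, chrom, indiv$pos[idx])
    ok <- !is.na(mp)
    tbase <- substring(tgtChr[[chrom]], mp[ok] + 1L, mp[ok] + 1L)
    count <- count + sum(base[idx][ok] != tbase)
  }
  count
}

#' Simulate labelled SV sets with planted sharing structure
#'
#' Each design entry plants one SV cluster present in exactly the given
#' label subset: member copies are jittered well within the reciprocal-50\%
#' identity (same type, shifted/rescaled within tolerance), and clusters are
#' placed in disjoint 100 kb windows so distinct clusters never match.
#'
#' @param nSets number of labelled sets ("assemblies").
#' @param design list of integer vectors, each a subset of \code{1:nSets};
#'   one planted SV cluster per entry.
#' @param seed integer seed.
#' @param labels set labels (default \code{asm1..asmN}).
#' @return list with \code{sets} (named list of SV data.frames) and
#'   \code{truth} (data.frame: \code{cluster}, \code{labels}, \code{type}).
#' @export
simulateSVUniverse <- function(nSets, design, seed = 1L,
                               labels = paste0("asm", seq_len(nSets))) {
  stopifnot(length(labels) == nSets)
  if (!length(design)) stop("empty sharing design")
  if (any(vapply(design, function(d)
    any(d < 1L | d > nSets) || !length(d), logical(1))))
    stop("design entries must be non-empty subsets of 1:nSets")
  withSeed(seed, {
    sets <- setNames(rep(list(NULL), nSets), labels)
    truth <- list()
    for (i in seq_along(design)) {
      w0 <- (i - 1L) * 100000L + 10000L
      type <- sample(c("DEL", "INV", "INS"), 1L)
      len <- sample(300:3000, 1L)
      start <- w0 + sample(0:1000, 1L)
      for (s in design[[i]]) {
        if (type == "INS") {
          p <- start + sample(-200:200, 1L)
          lenJ <- as.integer(round(len * runif(1L, 0.8, 1.2)))
          rec <- data.frame(chrom = "chr1", start = p, end = p,
                            type = type, length = lenJ,
                            label = labels[s], stringsAsFactors = FALSE)
        } else {
          shiftMax <- max(1L, as.integer(0.15 * len))
          sh <- sample(seq(-shiftMax, shiftMax), 1L)
          lenJ <- as.integer(round(len * runif(1L, 0.9, 1.1)))
          rec <- data.frame(chrom = "chr1", start = start + sh,
                            end = start + sh + lenJ, type = type,
                            length = lenJ, label = labels[s],
                            stringsAsFactors = FALSE)
        }
        sets[[labels[s]]] <- rbind(sets[[labels[s]]], rec)
      }
      truth[[i]] <- data.frame(
        cluster = i,
        labels = paste(sort(labels[design[[i]]]), collapse = "+"),
        type = type, stringsAsFactors = FALSE)
    }
    sets <- sets[!vapply(sets, is.null, logical(1))]
    list(sets = sets, truth = do.call(rbind, truth))
  })
}

#' Simulate single-end/paired read-support profiles
#'
#' Authentic SV regions draw their single-end read fraction at the
#' genome-wide rate; spurious regions at an \code{inflation}-fold higher
#' rate, emulating the pile-up of wrongly mapped single-end reads over
#' misassembly-derived SVs.
#'
#' @param nAuthentic,nSpurious region counts.
#' @param genome genome-wide \code{c(single, paired)} counts.
#' @param inflation single-end rate multiplier for spurious regions.
#' @param meanReads,minReads region read-depth model: total reads per region
#'   are \code{minReads + Poisson(meanReads - minReads)}.
#' @param seed integer seed.
#' @return list with \code{counts} (data.frame \code{single}, \code{paired},
#'   \code{truth} in \{authentic, spurious\}) and \code{genome}.
#' @export
simulateSPCounts <- function(nAuthentic, nSpurious,
                             genome = c(single = 1000, paired = 99000),
                             inflation = 10, meanReads = 200,
                             minReads = 100, seed = 1L) {
  withSeed(seed, {
    rate <- genome[[1L]] / (genome[[1L]] + genome[[2L]])
    n <- nAuthentic + nSpurious
    rateVec <- rep(c(rate, min(1, inflation * rate)),
                   c(nAuthentic, nSpurious))
    total <- minReads + rpois(n, meanReads - minReads)
    s <- rbinom(n, total, rateVec)
    list(counts = data.frame(
      single = s, paired = total - s,
      truth = rep(c("authentic", "spurious"), c(nAuthentic, nSpurious)),
      stringsAsFactors = FALSE),
      genome = genome)
  })
}

#' Fragment a reference into oriented scaffolds with perfect anchors
#'
#' Cuts each chromosome into contiguous non-overlapping fragments, assigns
#' random orientations and shuffled names, and emits evenly spaced exact
#' anchors (mapping quality 254) per fragment, plus the ground-truth order
#' and orientation -- the round-trip input for chromosome building.
#'
#' @param reference [Biostrings::DNAStringSet].
#' @param nScaffolds fragments per chromosome.
#' @param seed integer seed.
#' @param anchorsPerScaffold exact anchors emitted per fragment.
#' @return list with \code{scaffolds} (DNAStringSet, oriented as assembled),
#'   \code{anchors} (data.frame, see [readAnchors()]) and \code{truth}
#'   (data.frame: \code{scaffold}, \code{chrom}, \code{tStart}, \code{tEnd},
#'   \code{orientation}, \code{rank}).
#' @export
fragmentAssembly <- function(reference, nScaffolds, seed = 1L,
                             anchorsPerScaffold = 10L) {
  withSeed(seed, {
    refChr <- as.character(reference)
    nTotal <- nScaffolds * length(refChr)
    scafNames <- sample(sprintf("scaf_%03d", seq_len(nTotal)))
    scafIdx <- 0L
    scaffolds <- character(0)
    anchors <- list()
    truth <- list()
    for (chrom in names(refChr)) {
      s <- refChr[[chrom]]
      len <- nchar(s)
      minw <- max(4L * anchorsPerScaffold, 50L)
      if (len < nScaffolds * minw)
        stop("chromosome ", chrom, " too short for ", nScaffolds,
             " scaffolds")
      for (try in 1:100) {
        cuts <- sort(sample(seq_len(len - 1L), nScaffolds - 1L))
        bounds <- c(0L, cuts, len)
        if (all(diff(bounds) >= minw)) break
        if (try == 100L) stop("could not fragment ", chrom)
      }
      for (i in seq_len(nScaffolds)) {
        scafIdx <- scafIdx + 1L
        nm <- scafNames[scafIdx]
        t0 <- bounds[i]; t1 <- bounds[i + 1L]
        w <- t1 - t0
        orientation <- sample(c("+", "-"), 1L)
        frag <- substr(s, t0 + 1L, t1)
        scaffolds[[nm]] <- if (orientation == "-") revComp(frag) else frag
        k <- anchorsPerScaffold
        ab <- unique(as.integer(round(seq(0L, w, length.out = k + 1L))))
        a0 <- ab[-length(ab)]; a1 <- ab[-1L]
        sS <- if (orientation == "+") a0 else w - a1
        sE <- if (orientation == "+") a1 else w - a0
        anchors[[length(anchors) + 1L]] <- data.frame(
          scaffold = nm, chrom = chrom, sStart = sS, sEnd = sE,
          tStart = t0 + a0, tEnd = t0 + a1, strand = orientation,
          quality = 254L, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          scaffold = nm, chrom = chrom, tStart = t0, tEnd = t1,
          orientation = orientation, rank = i, stringsAsFactors = FALSE)
      }
    }
    list(scaffolds = Biostrings::DNAStringSet(scaffolds),
         anchors = do.call(rbind, anchors),
         truth = do.call(rbind, truth))
  })
}
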