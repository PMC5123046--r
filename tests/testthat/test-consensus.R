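diploidScheme <- function(n, chroms = "chr1") {
  ploidyScheme(chroms, setNames(rep(c("M", "F"), length.out = n),
                                sprintf("S%02d", seq_len(n))))
}

cohortOf <- function(variants, gtRows) {
  CohortCalls(variants, do.call(rbind, gtRows),
              samples = sprintf("S%02d", seq_len(length(gtRows[[1]]))))
}

test_that("tallyAlleles counts haploids, missingness and sex chromosomes", {
  ## 40 diploids all 0/1 at one SNV: ref 40 / alt 40, called 80
  cc <- cohortOf(data.frame(chrom = "chr1", pos = 99L, ref = "A", alt = "G"),
                 list(rep("0/1", 40)))
  t1 <- tallyAlleles(cc, diploidScheme(40))
  expect_equal(t1$count[t1$kind == "REF"], 40L)
  expect_equal(t1$count[t1$kind == "SNV"], 40L)
  expect_equal(unique(t1$called), 80L)
  expect_equal(unique(t1$total), 80L)

  ## 2 of 40 samples missing: called 76, capacity still 80
  gts <- rep("0/1", 40); gts[c(3, 17)] <- "./."
  cc <- cohortOf(data.frame(chrom = "chr1", pos = 99L, ref = "A", alt = "G"),
                 list(gts))
  t2 <- tallyAlleles(cc, diploidScheme(40))
  expect_equal(unique(t2$called), 76L)
  expect_equal(unique(t2$total), 80L)

  ## Y-chromosome site: 25 male haploid calls, capacity 25
  sexes <- setNames(rep(c("M", "F"), c(25, 15)), sprintf("S%02d", 1:40))
  ps <- ploidyScheme(c("chr1", "chrX", "chrY"), sexes)
  expect_equal(unname(capacities(ps)[c("chr1", "chrX", "chrY")]),
               c(80L, 30L, 25L))
  g <- ifelse(sexes == "M", "1", ".")
  cc <- cohortOf(data.frame(chrom = "chrY", pos = 10L, ref = "C", alt = "T"),
                 list(unname(g)))
  t3 <- tallyAlleles(cc, ps)
  expect_equal(unique(t3$total), 25L)
  expect_equal(t3$count[t3$kind == "SNV"], 25L)
})

test_that("genotype arity must match the ploidy scheme", {
  sexes <- setNames(rep("M", 4), sprintf("S%02d", 1:4))
  ps <- ploidyScheme("chrY", sexes)
  cc <- cohortOf(data.frame(chrom = "chrY", pos = 5L, ref = "A", alt = "G"),
                 list(c("0/1", "1", "0", "1")))
  expect_error(tallyAlleles(cc, ps), "arity")
})

test_that("multiallelic records decompose per normalized allele", {
  cc <- cohortOf(data.frame(chrom = "chr1", pos = 50L, ref = "A",
                            alt = "G,T"),
                 list(c("1/2", "0/1", "2/2")))
  t1 <- tallyAlleles(cc, diploidScheme(3))
  expect_equal(t1$count[t1$allele == "G"], 2L)
  expect_equal(t1$count[t1$allele == "T"], 3L)
  expect_equal(t1$count[t1$kind == "REF"], 1L)

  ## mixed SNV + indel alternates split into distinct normalized sites
  cc <- cohortOf(data.frame(chrom = "chr1", pos = 10L, ref = "AC",
                            alt = "A,GC"),
                 list(c("0/1", "1/2", "2/2")))
  t2 <- tallyAlleles(cc, diploidScheme(3))
  del <- t2[t2$kind == "INDEL", ]
  expect_equal(del$pos, 11L)        # deletion of the C, left-trimmed
  expect_equal(del$ref, "C")
  expect_equal(del$allele, "")
  expect_equal(del$count, 2L)
  snv <- t2[t2$kind == "SNV", ]
  expect_equal(snv$pos, 10L)        # A>G after suffix-trimming GC
  expect_equal(snv$allele, "G")
  expect_equal(snv$count, 3L)
})

test_that("indel normalization left-aligns through repeat context", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "GGAAAAC"))
  ## deleting the last A of the run, expressed at the right edge
  nm <- normalizeAllele(4L, "AA", "A", as.character(ref[[1]]))
  expect_equal(nm$pos, 2L)   # shifts to the leftmost A of the run
  expect_equal(nm$ref, "A")
  expect_equal(nm$alt, "")
})

test_that("SNV substitution selection follows the most-frequent-allele rule", {
  mk <- function(refCount, altCount) data.frame(
    chrom = "chr1", pos = 10L, ref = "A",
    allele = c("A", "G"), kind = c("REF", "SNV"),
    count = c(refCount, altCount), called = refCount + altCount, total = 80L,
    stringsAsFactors = FALSE)
  expect_equal(selectSnvSubstitutions(mk(30L, 50L))$alt, "G")
  expect_equal(nrow(selectSnvSubstitutions(mk(40L, 40L))), 0L)  # tie: keep ref
  expect_equal(nrow(selectSnvSubstitutions(mk(50L, 30L))), 0L)  # ref major
})

test_that("indel substitution threshold is strict majority of capacity", {
  mk <- function(count, total) data.frame(
    chrom = "chr1", pos = 10L, ref = "CT", allele = "C", kind = "INDEL",
    count = count, called = total, total = total, stringsAsFactors = FALSE)
  expect_equal(nrow(selectIndelSubstitutions(mk(41L, 80L))), 1L)
  expect_equal(nrow(selectIndelSubstitutions(mk(40L, 80L))), 0L)
  ## X-chromosome capacity 30: 16 passes, 15 does not
  expect_equal(nrow(selectIndelSubstitutions(mk(16L, 30L))), 1L)
  expect_equal(nrow(selectIndelSubstitutions(mk(15L, 30L))), 0L)
})

test_that("raising the indel threshold never increases the edit count", {
  set.seed(5)
  tall <- data.frame(chrom = "chr1", pos = seq(10L, 2000L, by = 20L),
                     ref = "CT", allele = "C", kind = "INDEL",
                     count = sample(0:80, 100, TRUE), called = 80L,
                     total = 80L, stringsAsFactors = FALSE)
  fr <- seq(0.1, 0.9, by = 0.1)
  counts <- vapply(fr, function(f)
    nrow(selectIndelSubstitutions(tall, fraction = f)), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("applyEdits replays edits and derives the correct chain", {
  ## no edits: identity
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  out <- applyEdits(ref, EditScript())
  expect_equal(as.character(out$consensus), c(chr1 = "ACGTACGT"))
  expect_equal(chainBlocks(out$chain, "chr1"),
               data.frame(srcStart = 0L, srcEnd = 8L, tgtStart = 0L,
                          tgtEnd = 8L))

  ## SNV pos2 G>T plus deletion of [4,6): "ACGTACGT" -> "ACTTGT"
  es <- EditScript(data.frame(chrom = "chr1", pos = c(2L, 4L),
                              ref = c("G", "AC"), alt = c("T", ""),
                              kind = c("SNV", "INDEL")))
  out <- applyEdits(ref, es)
  expect_equal(as.character(out$consensus), c(chr1 = "ACTTGT"))
  expect_equal(chainBlocks(out$chain, "chr1"),
               data.frame(srcStart = c(0L, 6L), srcEnd = c(4L, 8L),
                          tgtStart = c(0L, 4L), tgtEnd = c(4L, 6L)))

  ## pure insertion, against the naive splice oracle
  ref2 <- Biostrings::DNAStringSet(c(chr1 = "AAAA"))
  es2 <- EditScript(data.frame(chrom = "chr1", pos = 3L, ref = "",
                               alt = "GG", kind = "INDEL"))
  out2 <- applyEdits(ref2, es2)
  expect_equal(as.character(out2$consensus)[["chr1"]],
               oracleApply("AAAA", edits(es2))$seq)
  expect_equal(as.character(out2$consensus)[["chr1"]], "AAAGGA")

  ## mismatching edit reference aborts with the position
  esBad <- EditScript(data.frame(chrom = "chr1", pos = 2L, ref = "T",
                                 alt = "A", kind = "SNV"))
  expect_error(applyEdits(ref, esBad), "mismatch at chr1:2")
})

test_that("applyEdits equals the naive splice oracle on random edit scripts", {
  set.seed(42)
  for (i in 1:20) {
    cs <- randomEditCase(2000L)
    ref <- Biostrings::DNAStringSet(c(chr1 = cs$refStr))
    out <- applyEdits(ref, EditScript(cs$edits))
    orc <- oracleApply(cs$refStr, cs$edits)
    expect_identical(as.character(out$consensus)[["chr1"]], orc$seq)
    ## chain-mapped unedited positions carry identical bases
    b <- chainBlocks(out$chain, "chr1")
    snvPos <- cs$edits$pos[cs$edits$kind == "SNV"]
    for (j in seq_len(nrow(b))) {
      pos <- setdiff(b$srcStart[j]:(b$srcEnd[j] - 1L), snvPos)
      if (!length(pos)) next
      src <- substring(cs$refStr, pos + 1L, pos + 1L)
      tgt <- substring(orc$seq, b$tgtStart[j] + (pos - b$srcStart[j]) + 1L,
                       b$tgtStart[j] + (pos - b$srcStart[j]) + 1L)
      expect_identical(src, tgt)
    }
  }
})

test_that("EditScript validity rejects unsorted and overlapping edits", {
  expect_error(new("EditScript", edits = data.frame(
    chrom = "chr1", pos = c(5L, 3L), ref = c("A", "C"), alt = c("G", "T"),
    kind = "SNV")), "sorted")
  expect_error(EditScript(data.frame(
    chrom = "chr1", pos = c(3L, 4L), ref = c("ACG", "C"), alt = c("", "T"),
    kind = c("INDEL", "SNV"))), "overlap")
})

test_that("conflicting indel candidates are dropped and reported", {
  snv <- data.frame(chrom = "chr1", pos = 5L, ref = "A", alt = "G",
                    kind = "SNV", support = 50L, called = 80L, total = 80L,
                    stringsAsFactors = FALSE)
  ind <- data.frame(chrom = "chr1", pos = c(4L, 20L), ref = c("CAT", "GG"),
                    alt = c("C", ""), kind = "INDEL",
                    support = c(60L, 45L), called = 80L, total = 80L,
                    stringsAsFactors = FALSE)
  comb <- combineEditCandidates(snv, ind)
  rep <- comb$report
  expect_equal(rep$status[rep$pos == 4L], "dropped")
  expect_match(rep$reason[rep$pos == 4L], "overlap")
  expect_equal(sort(edits(comb$script)$pos), c(5L, 20L))
})

test_that("planted-truth recovery: substituted sets equal the simulated truth", {
  sim <- simulateCohort(populationModel(refLength = 20000L, nSnv = 600L,
                                        nIndel = 60L), seed = 31)
  res <- buildConsensus(sim$reference, sim$cohort, sim$scheme)
  acc <- res$report[res$report$status == "accepted", ]
  keyGot <- with(acc, paste(chrom, pos, ref, alt))
  tru <- sim$truth[sim$truth$isEdit, ]
  keyExp <- with(tru, paste(chrom, normPos, normRef, normAlt))
  expect_setequal(keyGot, keyExp)
  expect_equal(nrow(acc), nrow(tru))
  ## haploid support is reported for every substitution
  expect_true(all(acc$support >= 1L))

  ## idempotence: a cohort homozygous for the consensus alleles yields no
  ## edits against the consensus
  v <- variantTable(sim$cohort)
  gt2 <- genotypes(sim$cohort)
  consAllele <- ifelse(sim$truth$isEdit, 1L, 0L)
  ## re-express each record against the consensus: keep only records whose
  ## consensus allele is the reference one, all samples hom-ref
  keep <- consAllele == 0L
  gt2[] <- "0/0"
  gt2[v$chrom == "chrY", samplePloidy(sim$scheme, "chrY") > 0] <- "0"
  cc2 <- CohortCalls(v[keep, ], gt2[keep, , drop = FALSE],
                     sampleNames(sim$cohort))
  res2 <- buildConsensus(sim$reference, cc2, sim$scheme)
  expect_equal(nrow(edits(res2$script)), 0L)
  expect_equal(as.character(res2$consensus), as.character(sim$reference))
})
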