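mkCalls <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("individualCalls derives zygosity and class from GT alone", {
  cc <- CohortCalls(
    data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
               ref = c("A", "C", "G", "AT", "T"),
               alt = c("G", "T", "A", "A", "C")),
    cbind(c("0/1", "1/1", "0/0", "1/1", "./1")),
    samples = "s1")
  ic <- individualCalls(cc, "s1")
  expect_equal(ic$pos, c(10L, 20L, 40L))   # hom-ref and half-missing dropped
  expect_equal(ic$zygosity, c("HET", "HOM", "HOM"))
  expect_equal(ic$class, c("SNV", "SNV", "INDEL"))
  expect_equal(attr(ic, "excluded")$pos, 50L)
  expect_error(individualCalls(cc, "nope"), "not found")
})

test_that("countByZygosityClass partitions calls exhaustively", {
  calls <- mkCalls(zygosity = c(rep("HOM", 3), rep("HET", 2)),
                   class = c(rep("SNV", 3), rep("INDEL", 2)))
  tab <- countByZygosityClass(calls)
  expect_equal(tab["HOM", "SNV"], 3L)
  expect_equal(tab["HET", "INDEL"], 2L)
  expect_equal(sum(tab), nrow(calls))

  empty <- countByZygosityClass(mkCalls(zygosity = character(),
                                        class = character()))
  expect_equal(sum(empty), 0L)

  ## recount oracle on a random 1,000-call set
  set.seed(3)
  calls <- mkCalls(zygosity = sample(c("HOM", "HET"), 1000, TRUE),
                   class = sample(c("SNV", "INDEL"), 1000, TRUE))
  tab <- countByZygosityClass(calls)
  for (z in c("HOM", "HET")) for (k in c("SNV", "INDEL"))
    expect_equal(tab[z, k], sum(calls$zygosity == z & calls$class == k))
})

test_that("shared-region restriction matches the per-base mask oracle", {
  set.seed(17)
  cs1 <- randomEditCase(1500L)
  cs2 <- randomEditCase(refStr = cs1$refStr)
  ref <- Biostrings::DNAStringSet(c(chr1 = cs1$refStr))
  ch1 <- applyEdits(ref, EditScript(cs1$edits))$chain
  ch2 <- applyEdits(Biostrings::DNAStringSet(c(chr1 = cs1$refStr)),
                    EditScript(cs2$edits))$chain
  pos <- sample(0:1400, 150)
  calls <- mkCalls(chrom = "chr1", pos = pos,
                   ref = substring(cs1$refStr, pos + 1L, pos + 1L),
                   alt = "N", gt = "0/1")
  ## identity chains remove nothing
  idc <- identityChain(c(chr1 = 1500L))
  expect_equal(nrow(restrictToSharedRegions(calls, list(idc, idc))),
               nrow(calls))
  ## per-base mask oracle (single-base calls: span mode == base mode)
  m1 <- oracleApply(cs1$refStr, cs1$edits)$map
  m2 <- oracleApply(cs1$refStr, cs2$edits)$map
  expMask <- !is.na(m1[pos + 1L]) & !is.na(m2[pos + 1L])
  got <- restrictToSharedRegions(calls, list(ch1, ch2))
  expect_equal(got$pos, pos[expMask])
  gotBase <- restrictToSharedRegions(calls, list(ch1, ch2), mode = "base")
  expect_equal(gotBase$pos, pos[expMask])
})

test_that("reference-specific decomposition obeys conservation and symmetry", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGTACGTACGT"))
  es <- EditScript(data.frame(chrom = "chr1", pos = 2L, ref = "G", alt = "T",
                              kind = "SNV"))
  ap <- applyEdits(ref, es)
  cons <- ap$consensus

  ## individual: hom-ALT at the substituted site (vanishes on consensus),
  ## one shared het, one consensus-only call
  callsA <- mkCalls(chrom = "chr1", pos = c(2L, 5L), ref = c("G", "C"),
                    alt = c("T", "A"), gt = c("1/1", "0/1"),
                    zygosity = c("HOM", "HET"), class = "SNV")
  callsB <- mkCalls(chrom = "chr1", pos = c(5L, 9L), ref = c("C", "C"),
                    alt = c("A", "G"), gt = c("0/1", "1/1"),
                    zygosity = c("HET", "HOM"), class = "SNV")
  res <- referenceSpecificVariants(callsA, callsB, ap$chain, cons)
  expect_equal(res$shared$pos, 5L)
  expect_equal(res$aOnly$pos, 2L)       # absorbed by the consensus
  expect_equal(res$bOnly$pos, 9L)
  ## conservation
  expect_equal(nrow(res$shared) + nrow(res$aOnly), nrow(callsA))
  expect_equal(nrow(res$shared) + nrow(res$bOnly), nrow(callsB))

  ## symmetry: swapping A and B (with the reversed chain) swaps the sets
  rev <- referenceSpecificVariants(callsB, callsA, reverseChain(ap$chain),
                                   ref)
  expect_equal(rev$aOnly$pos, res$bOnly$pos)
  expect_equal(sort(rev$bOnly$pos), sort(res$aOnly$pos))
  expect_equal(nrow(rev$shared), nrow(res$shared))

  ## identical sets under an identity chain are all shared
  idc <- identityChain(c(chr1 = 20L))
  same <- referenceSpecificVariants(callsA, callsA, idc, ref)
  expect_equal(nrow(same$aOnly), 0L)
  expect_equal(nrow(same$bOnly), 0L)
})

test_that("sharedness spectrum equals brute-force incidence tabulation", {
  ## variant present in 2 of 3 individuals lands in bin 2
  v1 <- mkCalls(chrom = "chr1", pos = c(5L, 9L), ref = "A", alt = "G",
                gt = "0/1")
  v2 <- mkCalls(chrom = "chr1", pos = 5L, ref = "A", alt = "G", gt = "1/1")
  v3 <- mkCalls(chrom = "chr1", pos = 14L, ref = "C", alt = "T", gt = "0/1")
  sp <- sharednessSpectrum(list(v1, v2, v3))
  expect_equal(unname(sp), c(2L, 1L, 0L))

  ## all individuals share one variant
  spAll <- sharednessSpectrum(list(v2, v2, v2))
  expect_equal(unname(spAll), c(0L, 0L, 1L))

  ## random incidence matrix oracle
  set.seed(23)
  nInd <- 6L; nVar <- 80L
  inc <- matrix(runif(nInd * nVar) < 0.4, nVar, nInd)
  callsList <- lapply(seq_len(nInd), function(j) {
    rows <- which(inc[, j])
    mkCalls(chrom = "chr1", pos = rows * 10L, ref = "A", alt = "G",
            gt = "0/1")
  })
  sp <- sharednessSpectrum(callsList)
  colSums <- rowSums(inc)
  expected <- vapply(seq_len(nInd), function(k)
    sum(colSums == k), integer(1))
  expect_equal(unname(sp), expected)
  ## incidence conservation
  expect_equal(sum(sp * seq_len(nInd)), sum(inc))
})

test_that("a consensus-trained population yields fewer homozygous variants", {
  ## one replicate of the reference-bias phenomenon (bulk runs in the
  ## acceptance suite): a held-out individual from the cohort population has
  ## fewer homozygous variants against the consensus than the baseline
  sim <- simulateCohort(populationModel(refLength = 30000L, nSnv = 1200L,
                                        nIndel = 100L, xLength = 0L,
                                        yLength = 0L), seed = 8)
  res <- buildConsensus(sim$reference, sim$cohort, sim$scheme)
  indiv <- simulateIndividual(sim, seed = 1008)
  nBase <- countHomozygousVariants(indiv)
  nCons <- countHomozygousVariants(indiv, res$consensus, res$chain)
  expect_lt(nCons, nBase)
})
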