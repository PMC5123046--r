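test_that("cohort simulation is byte-reproducible under a fixed seed", {
  m <- populationModel(refLength = 8000L, nSnv = 80L, nIndel = 10L,
                       nMale = 4L, nFemale = 4L, xLength = 2000L,
                       nSnvX = 10L, nIndelX = 4L, yLength = 1500L,
                       nSnvY = 8L, nIndelY = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateCohort(m, seed = 5, dir = d1)
  simulateCohort(m, seed = 5, dir = d2)
  for (f in c("ref.fa", "cohort.vcf", "truth.tsv", "sexes.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ## a different seed changes the output
  d3 <- withr::local_tempdir()
  simulateCohort(m, seed = 6, dir = d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("the simulated truth matches its own VCF on re-tally", {
  sim <- simulateCohort(populationModel(refLength = 10000L, nSnv = 150L,
                                        nIndel = 20L, nMale = 5L,
                                        nFemale = 5L, xLength = 0L,
                                        yLength = 0L), seed = 9)
  tally <- tallyAlleles(sim$cohort, sim$scheme, sim$reference)
  alt <- tally[tally$kind != "REF", ]
  key <- paste(alt$chrom, alt$pos, alt$ref, alt$allele)
  tkey <- paste(sim$truth$chrom, sim$truth$normPos, sim$truth$normRef,
                sim$truth$normAlt)
  expect_setequal(key, tkey)
  expect_equal(alt$count[match(tkey, key)], sim$truth$altCount)
  expect_equal(alt$called[match(tkey, key)], sim$truth$called)
})

test_that("planted indel boundary sites straddle the substitution threshold", {
  sim <- simulateCohort(populationModel(refLength = 20000L, nSnv = 100L,
                                        nIndel = 20L, xLength = 0L,
                                        yLength = 0L), seed = 2)
  ind <- sim$truth[sim$truth$type == "INDEL", ]
  expect_true(any(ind$altCount == 40L & !ind$isEdit))
  expect_true(any(ind$altCount == 41L & ind$isEdit))
  expect_equal(unique(ind$total), 80L)
})

test_that("haploid support at a planted frequency matches its expectation", {
  ## many sites at frequency 0.5125 in an 80-haploid cohort: mean support
  ## approx 41 of 80
  m <- populationModel(refLength = 50000L, nSnv = 1000L, nIndel = 0L,
                       missingness = 0, xLength = 0L, yLength = 0L)
  sim <- simulateCohort(m, seed = 12)
  ## rebuild genotypes at a fixed frequency by drawing directly: use the
  ## generator's own HW machinery via popFreq replacement is not possible
  ## post hoc, so check the generator's realized counts against binomial
  ## theory where popFreq happens to be near 0.5125
  near <- abs(sim$truth$popFreq - 0.5125) < 0.15
  expect_gte(sum(near), 50)
  expect_equal(mean(sim$truth$altCount[near]),
               mean(sim$truth$popFreq[near]) * 80, tolerance = 0.05)
})

test_that("sex-chromosome sites follow the cohort composition", {
  sim <- simulateCohort(populationModel(refLength = 6000L, nSnv = 40L,
                                        nIndel = 6L), seed = 3)
  tx <- sim$truth[sim$truth$chrom == "chrX", ]
  ty <- sim$truth[sim$truth$chrom == "chrY", ]
  expect_true(all(tx$total == 30L))
  expect_true(all(ty$total == 25L))
  g <- genotypes(sim$cohort)
  v <- variantTable(sim$cohort)
  males <- names(sim$sexes)[sim$sexes == "M"]
  females <- names(sim$sexes)[sim$sexes == "F"]
  ## males carry no X genotypes, females no Y genotypes; Y calls are haploid
  expect_true(all(g[v$chrom == "chrX", males] == "."))
  expect_true(all(g[v$chrom == "chrY", females] == "."))
  expect_false(any(grepl("/", g[v$chrom == "chrY", males])))
})

test_that("SV universe generators plant what they claim", {
  design <- list(1L, c(1L, 2L), c(2L, 3L), c(1L, 2L, 3L))
  sim <- simulateSVUniverse(3, design, seed = 7)
  ## membership counts per set
  sizes <- vapply(sim$sets, nrow, integer(1))
  expect_equal(unname(sizes), c(3L, 3L, 2L))
  ## recovered sharing equals the design
  cl <- clusterSharedSVs(sim$sets)
  expect_equal(sum(cl$groupCounts), length(design))
  expect_error(simulateSVUniverse(3, list(c(0L, 1L))), "subsets")
  ## determinism
  sim2 <- simulateSVUniverse(3, design, seed = 7)
  expect_identical(sim$sets, sim2$sets)
})

test_that("S/P count simulation separates authentic from spurious rates", {
  sp <- simulateSPCounts(200, 200, seed = 5)
  cnt <- sp$counts
  expect_true(all(cnt$single + cnt$paired >= 100))
  rA <- with(cnt[cnt$truth == "authentic", ], sum(single) / sum(paired))
  rS <- with(cnt[cnt$truth == "spurious", ], sum(single) / sum(paired))
  expect_gt(rS, 5 * rA)
  expect_identical(simulateSPCounts(200, 200, seed = 5)$counts, cnt)
})

test_that("fragmentAssembly emits consistent scaffolds, anchors and truth", {
  set.seed(2)
  ref <- Biostrings::DNAStringSet(c(c1 = paste(
    sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")))
  fr <- fragmentAssembly(ref, 4L, seed = 3)
  ## single fragment is the identity case
  fr1 <- fragmentAssembly(ref, 1L, seed = 3)
  expect_equal(nrow(fr1$truth), 1L)
  expect_equal(fr1$truth$tStart, 0L)
  expect_equal(fr1$truth$tEnd, 20000L)
  ## fragments tile the chromosome
  tr <- fr$truth[order(fr$truth$tStart), ]
  expect_equal(tr$tStart, c(0L, tr$tEnd[-4]))
  expect_equal(tr$tEnd[4], 20000L)
  ## scaffold sequences match the reference modulo orientation
  for (i in seq_len(4)) {
    frag <- substr(as.character(ref[["c1"]]), tr$tStart[i] + 1L, tr$tEnd[i])
    got <- as.character(fr$scaffolds[[tr$scaffold[i]]])
    if (tr$orientation[i] == "-")
      got <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(got)))
    expect_equal(got, frag)
  }
  ## determinism
  expect_identical(fragmentAssembly(ref, 4L, seed = 3)$anchors, fr$anchors)
})
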