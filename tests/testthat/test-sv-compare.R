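test_that("fisherExact matches the exhaustive enumeration oracle", {
  expect_equal(fisherExact(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1.0)
  expect_equal(fisherExact(matrix(c(0, 10, 10, 0), 2, byrow = TRUE)),
               oracleFisher(0, 10, 10, 0), tolerance = 1e-12)
  p <- fisherExact(matrix(c(9, 2, 1, 9), 2, byrow = TRUE))
  expect_equal(p, oracleFisher(9, 2, 1, 9), tolerance = 1e-12)
  expect_lt(p, 0.05)

  expect_warning(p0 <- fisherExact(matrix(0, 2, 2)), "all-zero")
  expect_equal(p0, 1)

  ## property: random tables with margins <= 60
  set.seed(13)
  for (i in 1:100) {
    tb <- matrix(sample(0:30, 4, TRUE), 2)
    expect_equal(fisherExact(tb),
                 oracleFisher(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("S/P filter discards only significantly inflated regions", {
  genome <- c(1000, 99000)
  out <- spFilter(data.frame(single = c(50, 1, 0),
                             paired = c(50, 99, 80)), genome)
  expect_equal(out$keep, c(FALSE, TRUE, TRUE))
  ## (50,50) is both significant and inflated
  expect_lt(out$p[1], 0.001)
  expect_true(out$inflated[1])
  ## (0,80): deflated direction never discards
  expect_false(out$inflated[3])

  ## zero paired reads with single-end support: maximal inflation
  z <- spFilter(data.frame(single = 40, paired = 0), genome)
  expect_false(z$keep)
})

test_that("svSame implements reciprocal 50% coverage with inclusive boundary", {
  del <- function(s, e) list(chrom = "chr1", start = s, end = e,
                             type = "DEL", length = e - s)
  expect_true(svSame(del(100, 200), del(150, 250)))    # exactly 50% of each
  expect_false(svSame(del(100, 200), del(151, 250)))   # 49 bp overlap
  inv <- del(100, 200); inv$type <- "INV"
  expect_false(svSame(del(100, 200), inv))             # type mismatch
  ## symmetry and reflexivity
  expect_true(svSame(del(100, 200), del(100, 200)))
  expect_equal(svSame(del(100, 200), del(150, 250)),
               svSame(del(150, 250), del(100, 200)))

  ins <- function(p, len) list(chrom = "chr1", start = p, end = p,
                               type = "INS", length = len)
  expect_true(svSame(ins(1000, 400), ins(1900, 300)))   # within window
  expect_false(svSame(ins(1000, 400), ins(2100, 300)))  # beyond window
  expect_false(svSame(ins(1000, 400), ins(1100, 150)))  # length ratio < 0.5
})

test_that("exclusive sharing groups recover a planted design", {
  sim <- simulateSVUniverse(5, design = list(
    c(1, 2), c(1, 2), 3L, c(1, 2, 3, 4, 5), c(2, 4), 1L, c(3, 5), c(1, 2)),
    seed = 11)
  cl <- clusterSharedSVs(sim$sets)
  expected <- table(sim$truth$labels)
  expect_equal(cl$groupCounts[names(expected)],
               setNames(as.integer(expected), names(expected)))
  expect_equal(sum(cl$groupCounts), nrow(sim$truth))

  ## order invariance: shuffling sets and records changes nothing
  sets2 <- rev(lapply(sim$sets, function(s) s[sample(nrow(s)), ]))
  cl2 <- clusterSharedSVs(sets2)
  expect_equal(cl2$groupCounts[names(cl$groupCounts)], cl$groupCounts)

  ## brute-force all-pairs single-linkage oracle agrees
  pooled <- cl$assignments
  lab <- oracleCluster(pooled, function(a, b) svSame(a, b))
  expect_equal(length(unique(lab)), nrow(cl$clusters))
  expect_true(all(tapply(pooled$cluster, lab, function(x)
    length(unique(x)) == 1L)))
})

test_that("an SV shared by exactly two of three sets lands in that group only", {
  a <- data.frame(chrom = "chr1", start = 100L, end = 300L, type = "DEL",
                  length = 200L)
  b <- data.frame(chrom = "chr1", start = 120L, end = 320L, type = "DEL",
                  length = 200L)
  c3 <- data.frame(chrom = "chr1", start = 5000L, end = 5100L, type = "INV",
                   length = 100L)
  cl <- clusterSharedSVs(list(s1 = a, s2 = b, s3 = c3))
  expect_equal(unname(cl$groupCounts[c("s1+s2", "s3")]), c(1L, 1L))
})

test_that("novelty annotation is a complete all-pairs check", {
  svs <- data.frame(chrom = "chr1", start = c(100L, 1000L),
                    end = c(200L, 1400L), type = "DEL",
                    length = c(100L, 400L), stringsAsFactors = FALSE)
  ## known record at exactly reciprocal 50%: known, not novel
  known <- data.frame(chrom = "chr1", start = 150L, end = 250L,
                      type = "DEL", length = 100L, stringsAsFactors = FALSE)
  expect_equal(annotateNovelSVs(svs, list(known)), c(FALSE, TRUE))
  ## empty known sets: everything novel
  expect_equal(annotateNovelSVs(svs, list()), c(TRUE, TRUE))

  ## random planted design equals the brute-force check
  set.seed(29)
  sim <- simulateSVUniverse(2, design = rep(list(1L, 2L, c(1L, 2L)), 6),
                            seed = 3)
  q <- sim$sets[[1]]
  kn <- sim$sets[[2]]
  brute <- vapply(seq_len(nrow(q)), function(i)
    !any(vapply(seq_len(nrow(kn)), function(j)
      svSame(q[i, ], kn[j, ]), logical(1))), logical(1))
  expect_equal(annotateNovelSVs(q, list(kn)), brute)
})

test_that("group enrichment requires significance and the right direction", {
  res <- groupEnrichment(kIn = c(11L, 5L, 0L), nIn = 11L,
                         kOut = c(0L, 5L, 10L), nOut = 10L)
  expect_equal(res$enriched, c(TRUE, FALSE, FALSE))
  expect_equal(res$p[1], oracleFisher(11, 0, 0, 10), tolerance = 1e-12)
  ## equal frequencies are never enriched; wrong direction never enriched
  expect_gt(res$p[2], 0.05)
  expect_lt(res$p[3], 0.05)  # significant, but deflated: not enriched
  expect_error(groupEnrichment(1L, 0L, 1L, 10L), "empty")
})
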