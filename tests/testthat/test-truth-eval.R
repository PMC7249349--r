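# Brute-force scoring oracle: pairwise matching over small record sets.
bruteScore <- function(called, truth) {
  cKey <- unique(paste(called$pos, called$alt))
  tKey <- unique(paste(truth$pos, truth$alt))
  tp <- 0L
  for (k in cKey) if (any(k == tKey)) tp <- tp + 1L
  list(tp = tp, fp = length(cKey) - tp, fn = length(tKey) - tp)
}

randomCallSet <- function(n, maxPos = 30) {
  data.frame(pos = sample.int(maxPos, n, replace = TRUE),
             alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("scoring reproduces the printed worked-example metrics", {
  # 90 truth sites; 156 calls with 88 true: recall 97.77%, precision 56.4%
  truth <- data.frame(pos = 1:90, alt = "A")
  monovar <- data.frame(pos = c(1:88, 1001:1068), alt = "A")
  rep1 <- scoreCalls(monovar, truth)
  expect_identical(rep1@tp, 88L)
  expect_equal(round(100 * rep1@recall, 2), 97.78)  # 88/90
  expect_equal(round(100 * rep1@precision, 1), 56.4)
  expect_equal(round(rep1@f1, 3), 0.715)
  # 154 calls with the same 88 true: precision 57.1%
  bcftools <- data.frame(pos = c(1:88, 1001:1066), alt = "A")
  rep2 <- scoreCalls(bcftools, truth)
  expect_equal(round(100 * rep2@precision, 1), 57.1)
  expect_equal(round(100 * rep2@recall, 2), 97.78)
})

test_that("a perfect caller scores recall = precision = F1 = 1", {
  truth <- data.frame(pos = c(5, 9, 20), alt = c("A", "T", "G"))
  rep <- scoreCalls(truth, truth)
  expect_identical(c(rep@recall, rep@precision, rep@f1), c(1, 1, 1))
  expect_identical(rep@fp + rep@fn, 0L)
})

test_that("scoring matches the brute-force oracle on random small sets", {
  withr::with_seed(80, {
    for (i in 1:30) {
      called <- randomCallSet(sample.int(20, 1))
      truth <- randomCallSet(sample.int(20, 1))
      oracle <- bruteScore(called, truth)
      got <- suppressWarnings(scoreCalls(called, truth))
      expect_identical(got@tp, oracle$tp)
      expect_identical(got@fp, oracle$fp)
      expect_identical(got@fn, oracle$fn)
      # F1 consistency identity
      expected <- if (got@precision + got@recall == 0) 0 else
        2 * got@precision * got@recall / (got@precision + got@recall)
      expect_equal(got@f1, expected, tolerance = 1e-9)
    }
  })
})

test_that("matching requires the alt allele, not just the position", {
  truth <- data.frame(pos = c(10, 20), alt = c("A", "C"))
  called <- data.frame(pos = c(10, 20), alt = c("G", "C"))
  rep <- scoreCalls(called, truth)
  expect_identical(rep@tp, 1L)
})

test_that("edge cases: empty calls warn, off-by-one shifts warn", {
  truth <- data.frame(pos = 1:10, alt = "A")
  expect_warning(rep <- scoreCalls(truth[0, ], truth), "empty call set")
  expect_identical(rep@precision, 0)
  expect_identical(rep@f1, 0)
  sparse <- data.frame(pos = seq(10L, 100L, by = 10L), alt = "A")
  shifted <- data.frame(pos = sparse$pos - 1L, alt = "A")
  expect_warning(scoreCalls(shifted, sparse), "coordinate system")
})

test_that("post-filters enforce strict thresholds and the strand-bias rule", {
  calls <- data.frame(
    pos = 1:6, ref = "A", alt = "G",
    mq = c(1, 60, 60, 60, 60, 60),      # call 1: MQ == 1 removed (strict >)
    bq = c(35, 30, 35, 35, 35, 35),     # call 2: BQ == 30 removed
    altReads = c(10, 10, 5, 6, 10, 10), # call 3: 5 alt reads removed
    altFwd = c(5, 5, 3, 3, 10, 1),      # call 5: all-forward, removed
    altRev = c(5, 5, 2, 3, 0, 0)        # call 6: one-strand but < strandMin, kept
  )
  kept <- applyPostFilters(calls)
  expect_identical(kept$pos, c(4L, 6L))
  # filters are individually disabling
  keptNoStrand <- applyPostFilters(calls, list(strandMin = NA))
  expect_identical(keptNoStrand$pos, c(4L, 5L, 6L))
  # missing annotation: filter passes with a warning
  expect_warning(keptMiss <- applyPostFilters(calls[, c("pos", "ref", "alt", "mq")]),
                 "missing annotations")
  expect_identical(keptMiss$pos, 2:6)
})

test_that("filtering can only lower recall and, when it removes FPs, raise precision", {
  withr::with_seed(81, {
    truth <- randomCallSet(15, maxPos = 50)
    calls <- randomCallSet(40, maxPos = 50)
    calls$mq <- sample(c(0, 60), 40, replace = TRUE)
    calls$bq <- sample(c(20, 40), 40, replace = TRUE)
    calls$altReads <- sample(1:20, 40, replace = TRUE)
    calls$altFwd <- calls$altReads
    calls$altRev <- 0
    pre <- suppressWarnings(scoreCalls(calls, truth))
    post <- suppressWarnings(scoreCalls(applyPostFilters(calls), truth))
    expect_lte(post@recall, pre@recall)
    expect_true(post@precision >= pre@precision || post@fp < pre@fp)
  })
})

test_that("Ti/Tv arithmetic, boundaries and errors", {
  expect_equal(titvRatio(c("A", "C", "A"), c("G", "T", "C")), 2.0)
  expect_identical(titvRatio(c("A", "G"), c("G", "A")), Inf)
  expect_equal(titvRatio(c("A", "A"), c("C", "T")), 0)
  expect_error(titvRatio(character(0), character(0)), "empty")
  expect_error(titvRatio("A", "A"), "not SNVs")
})

test_that("caller VCFs round through readCallsVcf with filter annotations", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr20,length=1000000>",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="MQ">',
    '##INFO=<ID=DP4,Number=4,Type=Integer,Description="strand depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr20\t101\t.\tA\tG\t50\tPASS\tMQ=58;DP4=10,12,4,3",
    "chr20\t205\t.\tC\tT,A\t50\tPASS\tMQ=12;DP4=8,9,6,0"
  ), f)
  calls <- readCallsVcf(f)
  expect_identical(calls$pos, c(101L, 205L))
  expect_identical(calls$alt, c("G", "T"))  # first ALT allele
  expect_equal(calls$mq, c(58, 12))
  expect_equal(calls$altFwd, c(4, 6))
  expect_equal(calls$altReads, c(7, 6))
  # and the simulator's own truth VCF feeds scoreCalls
  ref <- tinyReference(600)
  sites <- placeSnvSites(600, 6, 2, seed = 82)
  sites <- assignSubstitutions(sites, ref, seed = 83)
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeTruthVcf(sites, tf, regionLength = 600L)
  truth <- readTruthVcf(tf)
  rep <- scoreCalls(data.frame(pos = truth$position + 1L, alt = truth$alt,
                               ref = truth$ref),
                    data.frame(pos = truth$position + 1L, alt = truth$alt))
  expect_identical(rep@recall, 1)
  expect_false(is.na(rep@titv))
})
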