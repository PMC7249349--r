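test_that("a full run produces all outputs with manifest-consistent counts", {
  refPath <- withr::local_tempfile(fileext = ".fa")
  makeFixtureReference(20000, seed = 90, path = refPath, name = "fix")
  d <- exampleDesign(regionLength = 20000, coverage = 2, nBulkReads = 2000,
                     nSnv = 20, seed = 91)
  out <- withr::local_tempdir()
  manifest <- runSimulation(d, refPath, out, quiet = TRUE)

  st <- sampleTable(d)
  # 8 FASTQ pairs, 4 cell truth VCFs, prototype truth VCF + TSV, manifest
  for (sid in st$sample) {
    expect_true(all(file.exists(file.path(out, paste0(sid, c("_R1.fastq.gz", "_R2.fastq.gz"))))))
  }
  expect_identical(sum(vapply(manifest$samples, `[[`, "", "type") == "single_cell"), 4L)
  expect_true(file.exists(file.path(out, "prototypes.truth.vcf")))
  expect_true(file.exists(file.path(out, "prototypes.truth.tsv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  for (sid in st$sample[st$type == "single_cell"]) {
    expect_true(file.exists(file.path(out, paste0(sid, ".truth.vcf"))))
  }

  # manifest record counts match the FASTQ files
  for (sid in st$sample) {
    fq <- readFastqPair(file.path(out, sid))
    expect_identical(2L * nrow(fq), as.integer(manifest$samples[[sid]]$records))
  }
  # bulk composition TSV agrees with decoded read provenance
  for (sid in st$sample[st$type == "bulk"]) {
    comp <- utils::read.table(file.path(out, paste0(sid, ".composition.tsv")),
                              header = TRUE, sep = "\t")
    expect_identical(comp$allocatedPairs, comp$drawnPairs)
    fq <- readFastqPair(file.path(out, sid))
    decoded <- table(factor(parseReadNames(fq$name)$src, levels = paste0("p", 1:3)))
    expect_identical(as.integer(decoded), comp$allocatedPairs)
  }
  # truth TSV matches the truth VCF site set
  sites <- readTruthTsv(file.path(out, "prototypes.truth.tsv"))
  vcf <- readTruthVcf(file.path(out, "prototypes.truth.vcf"))
  present <- rowSums(sites$zygosity > 0) > 0
  expect_identical(vcf$position, sites$position[present])
})

test_that("reruns with the same seed are byte-identical; different seeds differ", {
  refPath <- withr::local_tempfile(fileext = ".fa")
  makeFixtureReference(8000, seed = 92, path = refPath)
  d <- tinyDesign(regionLength = 8000, nSnv = 10, coverage = 1, nBulkReads = 100,
                  seed = 93)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  out3 <- withr::local_tempdir()
  runSimulation(d, refPath, out1, quiet = TRUE)
  runSimulation(d, refPath, out2, quiet = TRUE)
  runSimulation(d, refPath, out3, seed = 94, quiet = TRUE)
  files <- list.files(out1)
  expect_identical(files, list.files(out2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     info = f)
  }
  fq1 <- readFastqPair(file.path(out1, "u1_sc"))
  fq3 <- readFastqPair(file.path(out3, "u1_sc"))
  expect_false(identical(fq1, fq3))
})

test_that("degenerate designs abort with stage-named errors", {
  d <- tinyDesign(regionLength = 4000, nSnv = 5)
  ref <- tinyReference(2000)  # shorter than the region
  expect_error(runSimulation(d, ref, withr::local_tempdir(), quiet = TRUE),
               "shorter than the region|reference length")
  dBad <- d
  dBad@units <- list()
  expect_error(runSimulation(dBad, tinyReference(4000), withr::local_tempdir(),
                             quiet = TRUE),
               "no biological units")
})

test_that("fixture references hit the requested GC fraction deterministically", {
  ref <- makeFixtureReference(1e5, gcFraction = 0.41, seed = 95)
  gc <- mean(strsplit(unname(ref), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.41), 3 * sqrt(0.41 * 0.59 / 1e5))
  expect_identical(makeFixtureReference(500, seed = 96),
                   makeFixtureReference(500, seed = 96))
  expect_identical(nchar(unname(makeFixtureReference(1, seed = 97))), 1L)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  makeFixtureReference(1000, seed = 98, path = f1)
  makeFixtureReference(1000, seed = 98, path = f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
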