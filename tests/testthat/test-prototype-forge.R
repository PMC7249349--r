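test_that("SNV placement reproduces the documented equal-spacing rule", {
  sites <- placeSnvSites(1e6, 100, 3, marginFraction = 0.1, seed = 1)
  pos <- sites$position
  expect_identical(length(pos), 100L)
  expect_identical(unique(diff(pos)), 8080L)     # floor(0.8e6 / 99)
  expect_identical(pos[1], 100000L)              # floor(0.1 * L)
  expect_false(is.unsorted(pos, strictly = TRUE))
})

test_that("tier counts follow the deterministic split and presence rules", {
  # 99 = 3 * 33: exactly one third per tier, 'all' sites in all K prototypes
  sites <- placeSnvSites(1e5, 99, 4, seed = 2)
  counts <- table(sites$tier)
  expect_identical(as.integer(counts[c("all", "half", "uniform")]), c(33L, 33L, 33L))
  allRows <- sites$tier == "all"
  expect_true(all(sites$presence[allRows, ]))
  # 'half' sites present in exactly ceiling(K/2) prototypes
  halfRows <- sites$tier == "half"
  expect_true(all(rowSums(sites$presence[halfRows, , drop = FALSE]) == 2L))
  # uniform sites present in >= 1 prototype (no orphans)
  unifRows <- sites$tier == "uniform"
  expect_true(all(rowSums(sites$presence[unifRows, , drop = FALSE]) >= 1L))

  # counts for n not divisible by 3: (ceil(n/3), ceil((n - nAll)/2), rest)
  for (n in c(10, 11, 100, 101)) {
    s <- placeSnvSites(10000, n, 3, seed = n)
    nAll <- ceiling(n / 3); nHalf <- ceiling((n - nAll) / 2)
    got <- table(factor(s$tier, levels = c("all", "half", "uniform")))
    expect_identical(as.integer(got), as.integer(c(nAll, nHalf, n - nAll - nHalf)))
  }
  # odd K: half means ceiling(K/2)
  s5 <- placeSnvSites(10000, 30, 5, seed = 9)
  expect_true(all(rowSums(s5$presence[s5$tier == "half", , drop = FALSE]) == 3L))
})

test_that("a single SNV lands at the region midpoint, tier all", {
  s <- placeSnvSites(1001, 1, 3, seed = 1)
  expect_identical(s$position, 500L)
  expect_identical(s$tier, "all")
  expect_true(all(s$presence))
})

test_that("placement rejects regions too small for the spacing rule", {
  expect_error(placeSnvSites(40, 20, 2, marginFraction = 0.4), "spacing")
})

test_that("substitution assignment respects pHet and the matrix", {
  ref <- tinyReference(5000)
  sites <- placeSnvSites(5000, 50, 3, seed = 4)
  allHet <- assignSubstitutions(sites, ref, subst = list(pHet = 1), seed = 5)
  expect_true(all(allHet$zygosity[allHet$presence] == 1L))
  allHom <- assignSubstitutions(sites, ref, subst = list(pHet = 0), seed = 5)
  expect_true(all(allHom$zygosity[allHom$presence] == 2L))
  expect_true(all(allHet$zygosity[!allHet$presence] == 0L))
  expect_true(all(allHet$alt != allHet$ref))

  # deterministic matrix: every A-site gets alt G
  m <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  m["A", "G"] <- 1; m["C", "T"] <- 1; m["G", "A"] <- 1; m["T", "C"] <- 1
  det <- assignSubstitutions(sites, ref, subst = list(matrix = m), seed = 6)
  expect_true(all(det$alt[det$ref == "A"] == "G"))
  expect_true(all(det$alt[det$ref == "T"] == "C"))

  # malformed matrix rejected
  bad <- m; bad[1, 2] <- 0.5
  expect_error(assignSubstitutions(sites, ref, subst = list(matrix = bad)), "sum to 1")
})

test_that("sites on N reference bases are relocated rightward to real bases", {
  ref <- paste0(strrep("N", 120), strrep("A", 880))
  sites <- placeSnvSites(1000, 5, 2, seed = 7)
  expect_true(any(sites$position < 120))
  out <- assignSubstitutions(sites, ref, seed = 8)
  expect_true(all(out$ref %in% c("A", "C", "G", "T")))
  expect_true(all(out$position >= 120))
  expect_false(is.unsorted(out$position, strictly = TRUE))
})

test_that("prototype genomes honor zygosity and match the brute-force diff oracle", {
  ref <- tinyReference(1000)
  sites <- placeSnvSites(1000, 10, 3, seed = 10)
  sites <- assignSubstitutions(sites, ref, seed = 11)
  protos <- buildPrototypeGenomes(sites, seed = 12)
  editedUnion <- integer(0)
  for (k in 1:3) {
    p <- protos[[k]]
    hapA <- materializeHaplotype(ref, p@hapA)
    hapB <- materializeHaplotype(ref, p@hapB)
    # conservation: SNVs only, length preserved
    expect_identical(nchar(hapA), 1000L)
    # brute-force per-base diff recovers exactly the edit lists
    expect_identical(bruteForceDiff(ref, hapA), p@hapA)
    expect_identical(bruteForceDiff(ref, hapB), p@hapB)
    # hom sites on both haplotypes, het on exactly one
    z <- sites$zygosity[, k]
    homPos <- sites$position[z == 2L]
    hetPos <- sites$position[z == 1L]
    expect_true(all(homPos %in% p@hapA$pos) && all(homPos %in% p@hapB$pos))
    expect_identical(sort(c(setdiff(p@hapA$pos, p@hapB$pos),
                            setdiff(p@hapB$pos, p@hapA$pos))), sort(hetPos))
    editedUnion <- union(editedUnion, c(p@hapA$pos, p@hapB$pos))
  }
  # union of edited positions == sites present in >= 1 prototype
  expect_setequal(editedUnion, sites$position[rowSums(sites$presence) > 0])
})

test_that("a prototype with empty presence equals the reference", {
  ref <- tinyReference(400)
  sites <- placeSnvSites(400, 4, 2, seed = 13)
  sites$presence[] <- FALSE
  sites$presence[, 1] <- TRUE   # everything on prototype 1 only
  sites <- assignSubstitutions(sites, ref, seed = 14)
  # the uniform/half machinery is bypassed: zygosity follows presence
  protos <- buildPrototypeGenomes(sites, seed = 15)
  expect_identical(nrow(protos[[2]]@hapA), 0L)
  expect_identical(materializeHaplotype(ref, protos[[2]]@hapA), unname(ref))
})

test_that("Ti/Tv of sites from the default matrix lands in the expected band", {
  ref <- makeFixtureReference(1e5, seed = 20)
  sites <- placeSnvSites(1e5, 3000, 3, seed = 21)
  sites <- assignSubstitutions(sites, ref, seed = 22)
  tt <- titvRatio(sites$ref, sites$alt)
  expect_gte(tt, 1.2)
  expect_lte(tt, 1.6)
})
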