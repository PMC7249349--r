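# Internal paired-end read engine: uniform fragment placement on a randomly
# chosen haplotype, Gaussian fragment lengths, uniform per-base substitution
# errors, constant Phred qualities. A self-contained, fully seeded
# replacement for an external short-read simulator, so the whole pipeline is
# reproducible and testable without shelling out.

#' Number of read pairs needed for a target mean coverage
#'
#' `round(coverage * regionLength / (2 * readLength))`: each pair
#' contributes `2 * readLength` sequenced bases.
#'
#' @param regionLength region length in bp.
#' @param coverage target mean fold-coverage.
#' @param readLength read length in bp.
#' @return integer pair count
#' @examples
#' pairCountForCoverage(1e5, 24, 100)  # 12000
#' @export
pairCountForCoverage <- function(regionLength, coverage, readLength) {
  stopifnot(regionLength > 0, coverage >= 0, readLength > 0)
  as.integer(round(coverage * regionLength / (2 * readLength)))
}

reverseComplement <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute each base of `reads` independently with probability errorRate
# to a uniformly random different base. Draws the total error count once
# (binomial over all emitted bases), then places errors; O(errors), not
# O(bases).
injectReadErrors <- function(reads, readLength, errorRate) {
  if (errorRate <= 0 || !length(reads)) return(reads)
  totalBases <- length(reads) * readLength
  nErr <- stats::rbinom(1L, totalBases, errorRate)
  if (nErr == 0L) return(reads)
  gidx <- sample.int(totalBases, nErr)
  ridx <- (gidx - 1L) %/% readLength + 1L
  off <- (gidx - 1L) %% readLength + 1L
  pick <- sample.int(3L, nErr, replace = TRUE)
  for (i in seq_len(nErr)) {
    orig <- substr(reads[ridx[i]], off[i], off[i])
    alts <- DNA_BASES[DNA_BASES != orig]
    if (length(alts) == 4L) alts <- alts[1:3]  # orig was N: substitute to A/C/G
    substr(reads[ridx[i]], off[i], off[i]) <- alts[pick[i]]
  }
  reads
}

#' Simulate paired-end reads from a diploid genome
#'
#' Per pair: a haplotype is chosen by fair coin; the fragment length is
#' Normal(`fragmentMean`, `fragmentSd`) truncated (by resampling) to
#' `[2*readLength, L]` and rounded; the fragment start is uniform over valid
#' starts; read 1 is the fragment prefix and read 2 the reverse complement
#' of the fragment suffix. Each emitted base is substituted independently
#' with probability `errorRate` to a uniformly random different base.
#' Provenance (origin, source genome, haplotype, fragment coordinates,
#' serial) is encoded in the read name (see [makeReadNames()]).
#'
#' @param hapA,hapB the two haplotype sequences (character scalars of equal
#'   length), e.g. from [materializeHaplotype()].
#' @param nPairs number of read pairs to emit.
#' @param params read parameters (`readLength`, `fragmentMean`,
#'   `fragmentSd`, `errorRate`, `baseQuality`); defaults are Illumina-like
#'   (100 bp reads, 500 +- 50 bp fragments, 0.1% error, Q30).
#' @param origin origin label for read names (sample or pool id).
#' @param src source-genome label for read names.
#' @param seed integer seed.
#' @return data.frame with columns `name`, `seq1`, `seq2`
#' @export
simulateReads <- function(hapA, hapB, nPairs, params = list(),
                          origin = "sample", src = "g1", seed = NULL) {
  params <- utils::modifyList(defaultReadParams(), params)
  rl <- params$readLength
  L <- nchar(hapA)
  if (nPairs < 0) stop("n_pairs must be >= 0", call. = FALSE)
  stopifnot(nchar(hapB) == L, params$fragmentMean <= L, 2 * rl <= L)
  if (nPairs == 0L) {
    return(data.frame(name = character(0), seq1 = character(0),
                      seq2 = character(0), stringsAsFactors = FALSE))
  }
  withSeed(seed, {
    hapIdx <- sample.int(2L, nPairs, replace = TRUE)
    flen <- round(stats::rnorm(nPairs, params$fragmentMean, params$fragmentSd))
    bad <- which(flen < 2 * rl | flen > L)
    while (length(bad)) {
      flen[bad] <- round(stats::rnorm(length(bad), params$fragmentMean, params$fragmentSd))
      bad <- bad[flen[bad] < 2 * rl | flen[bad] > L]
    }
    start <- floor(stats::runif(nPairs) * (L - flen + 1))
    haps <- c(hapA, hapB)
    seq1 <- character(nPairs); seq2 <- character(nPairs)
    for (h in 1:2) {
      idx <- which(hapIdx == h)
      if (!length(idx)) next
      seq1[idx] <- substring(haps[h], start[idx] + 1L, start[idx] + rl)
      seq2[idx] <- reverseComplement(
        substring(haps[h], start[idx] + flen[idx] - rl + 1L, start[idx] + flen[idx]))
    }
    all <- injectReadErrors(c(seq1, seq2), rl, params$errorRate)
    data.frame(
      name = makeReadNames(origin, src, c("A", "B")[hapIdx],
                           as.integer(start), as.integer(start + flen),
                           seq_len(nPairs)),
      seq1 = all[seq_len(nPairs)],
      seq2 = all[nPairs + seq_len(nPairs)],
      stringsAsFactors = FALSE
    )
  })
}
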