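# Forging the K mutated diploid prototype genomes: equally spaced SNV
# locations, three sharing tiers (all / half / uniform), zygosity and
# substitution alleles from a row-stochastic transition matrix.

tierCounts <- function(n) {
  nAll <- ceiling(n / 3)
  nHalf <- ceiling((n - nAll) / 2)
  c(all = nAll, half = nHalf, uniform = n - nAll - nHalf)
}

#' Place potential SNV locations and assign sharing tiers
#'
#' Positions are equally spaced across the central `(1 - 2*marginFraction)`
#' of the region: the first site at `floor(marginFraction * L)`, spacing
#' `floor((1 - 2*marginFraction) * L / (n - 1))`. Sharing tiers split the
#' sites three ways — shared by all prototypes, by half of them
#' (`ceiling(K/2)`), or by a uniformly-drawn proportion — with counts
#' `ceiling(n/3)`, `ceiling((n - ceiling(n/3))/2)` and the remainder, tier
#' labels shuffled across sites per seed. Uniform-tier sites are present in
#' `max(1, round(p*K))` prototypes with `p ~ Uniform(0,1)`, so no site is
#' orphaned.
#'
#' @param regionLength region length L in bp.
#' @param nSnv number of potential SNV locations n.
#' @param K number of prototype genomes.
#' @param marginFraction SNV-free margin at each end. Default 0.1 (with
#'   L = 1e6 and n = 100 this gives the 8080 bp spacing used in the worked
#'   examples).
#' @param seed integer seed (NULL = current RNG stream).
#' @return an SNV site table: data.frame with columns `position` (0-based,
#'   strictly increasing), `tier`, and a logical `presence` matrix column
#'   (n x K)
#' @export
placeSnvSites <- function(regionLength, nSnv, K, marginFraction = 0.1, seed = NULL) {
  stopifnot(nSnv >= 1, K >= 1, regionLength >= 2 * nSnv,
            marginFraction >= 0, marginFraction < 0.5)
  if (nSnv == 1L) {
    positions <- as.integer(floor(regionLength / 2))
    tiers <- "all"
  } else {
    spacing <- floor((1 - 2 * marginFraction) * regionLength / (nSnv - 1))
    if (spacing < 1) {
      stop(sprintf("region too small: spacing %d < 1 bp for %d sites in %d bp (margin %.3g)",
                   spacing, nSnv, regionLength, marginFraction), call. = FALSE)
    }
    first <- floor(marginFraction * regionLength)
    positions <- as.integer(first + spacing * (seq_len(nSnv) - 1L))
    counts <- tierCounts(nSnv)
    labels <- rep(names(counts), counts)
    tiers <- withSeed(seed, sample(labels))
  }
  presence <- withSeed(if (is.null(seed)) NULL else seed + 1L, {
    t(vapply(tiers, function(tier) {
      pres <- rep(FALSE, K)
      idx <- switch(tier,
        all = seq_len(K),
        half = sample.int(K, ceiling(K / 2)),
        uniform = sample.int(K, max(1L, round(stats::runif(1) * K)))
      )
      pres[idx] <- TRUE
      pres
    }, logical(K)))
  })
  dimnames(presence) <- NULL
  if (K == 1L) presence <- matrix(presence, ncol = 1L)
  sites <- data.frame(position = positions, tier = tiers,
                      stringsAsFactors = FALSE, row.names = NULL)
  sites$presence <- presence
  sites
}

#' Assign zygosity and substitution alleles to placed SNV sites
#'
#' For each site, the alternate allele is drawn once from the substitution
#' matrix row of its reference base and shared by every prototype carrying
#' the site; per present (site, prototype) pair the mutation is heterozygous
#' with probability `pHet`, else homozygous. Sites landing on an `N`
#' reference base are moved deterministically rightward to the nearest
#' usable base.
#'
#' @param sites site table from [placeSnvSites()].
#' @param reference region sequence (character scalar).
#' @param subst substitution-model list with `pHet` and the 4x4 `matrix`
#'   (see [defaultSubstitutionMatrix()]). Defaults used for missing entries.
#' @param seed integer seed.
#' @return the site table with `ref`, `alt` columns and an integer
#'   `zygosity` matrix column (0 = absent, 1 = het, 2 = hom) added
#' @export
assignSubstitutions <- function(sites, reference, subst = list(), seed = NULL) {
  subst <- utils::modifyList(defaultSubstParams(), subst)
  msgs <- validateSubstParams(subst)
  if (length(msgs)) stop(paste(msgs, collapse = "; "), call. = FALSE)
  m <- subst$matrix
  reference <- unname(reference)
  L <- nchar(reference)
  n <- nrow(sites)
  K <- ncol(sites$presence)
  stopifnot(all(sites$position < L))

  refBase <- substring(reference, sites$position + 1L, sites$position + 1L)
  if (any(refBase == "N")) {
    taken <- sites$position
    for (i in which(refBase == "N")) {
      p <- sites$position[i]
      repeat {
        p <- p + 1L
        if (p >= L) stop("ran off the region while relocating a site away from N bases")
        b <- substring(reference, p + 1L, p + 1L)
        if (b != "N" && !(p %in% taken)) break
      }
      sites$position[i] <- p
      taken[i] <- p
      refBase[i] <- substring(reference, p + 1L, p + 1L)
    }
    ord <- order(sites$position)
    sites <- sites[ord, , drop = FALSE]
    refBase <- refBase[ord]
    rownames(sites) <- NULL
  }
  stopifnot(all(refBase %in% DNA_BASES))

  withSeed(seed, {
    alt <- vapply(refBase, function(b) sample(DNA_BASES, 1L, prob = m[b, ]), "")
    zyg <- matrix(0L, n, K)
    pres <- sites$presence
    nPresent <- sum(pres)
    isHet <- stats::runif(nPresent) < subst$pHet
    zyg[pres] <- ifelse(isHet, 1L, 2L)
    sites$ref <- refBase
    sites$alt <- unname(alt)
    sites$zygosity <- zyg
    sites
  })
}

#' Materialize the K prototype genomes as haplotype edit lists
#'
#' Homozygous sites edit both haplotypes; heterozygous sites edit exactly
#' one, chosen by a fair coin per site per prototype.
#'
#' @param sites fully assigned site table from [assignSubstitutions()].
#' @param seed integer seed for the haplotype coin flips.
#' @return list of K [PrototypeGenome-class] objects
#' @export
buildPrototypeGenomes <- function(sites, seed = NULL) {
  stopifnot(!is.null(sites$zygosity), !is.null(sites$alt))
  K <- ncol(sites$zygosity)
  withSeed(seed, {
    lapply(seq_len(K), function(k) {
      z <- sites$zygosity[, k]
      hetIdx <- which(z == 1L)
      homIdx <- which(z == 2L)
      hetOnA <- stats::runif(length(hetIdx)) < 0.5
      aIdx <- sort(c(homIdx, hetIdx[hetOnA]))
      bIdx <- sort(c(homIdx, hetIdx[!hetOnA]))
      methods::new("PrototypeGenome", k = k,
        hapA = data.frame(pos = sites$position[aIdx], alt = sites$alt[aIdx],
                          stringsAsFactors = FALSE),
        hapB = data.frame(pos = sites$position[bIdx], alt = sites$alt[bIdx],
                          stringsAsFactors = FALSE))
    })
  })
}

#' Heterozygous positions of a diploid edit-list genome
#' @param genome a [PrototypeGenome-class] or [CellGenome-class]
#' @return integer vector of 0-based positions edited on exactly one haplotype
#' @export
heterozygousPositions <- function(genome) {
  a <- genome@hapA$pos
  b <- genome@hapB$pos
  sort(c(setdiff(a, b), setdiff(b, a)))
}
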