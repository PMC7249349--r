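# Whole-genome-amplification error model for single cells: the cell's
# genotype is one categorical draw from its sample distribution G_ij, then
# allelic dropout (per heterozygous site) and false-positive mutations
# (per-base over the whole region) are applied to the chosen prototype.

#' Pick the genotype of a single cell
#'
#' One categorical draw `k ~ Categorical(gSample)`. A single cell has one
#' genotype; the hierarchical model keeps `gSample` concentrated near a
#' vertex for small gamma, so in practice cells from the same unit tend to
#' share a prototype.
#'
#' @param gSample simplex vector over the K prototypes.
#' @param seed integer seed.
#' @return integer prototype index in 1..K
#' @export
selectCellGenotype <- function(gSample, seed = NULL) {
  stopifnot(length(gSample) >= 1L, all(gSample >= 0), abs(sum(gSample) - 1) < 1e-6)
  withSeed(seed, sample.int(length(gSample), 1L, prob = gSample))
}

#' Apply the WGA error model to a prototype genome
#'
#' Allelic dropout: independently for each heterozygous site, with
#' probability `adoRate` one allele is lost — the surviving allele is chosen
#' uniformly, and the site becomes homozygous for it (homozygous sites are
#' never altered). False positives: the number of FP sites is
#' `Binomial(regionLength, fpRate)`; positions are uniform without
#' replacement over non-variant positions, and each FP is a heterozygous
#' substitution with the alternate base drawn from the substitution-matrix
#' row of the reference base (placed on a random haplotype).
#'
#' @param prototype a [PrototypeGenome-class].
#' @param reference the region sequence (character scalar); defines
#'   `regionLength` and the FP reference bases.
#' @param adoRate per-heterozygous-site dropout probability in \[0, 1\].
#' @param fpRate per-base false-positive probability in \[0, 1\].
#' @param substMatrix 4x4 substitution matrix for FP alternate alleles.
#' @param seed integer seed.
#' @return a [CellGenome-class]
#' @export
applyWga <- function(prototype, reference, adoRate = 0.2, fpRate = 3.2e-5,
                     substMatrix = defaultSubstitutionMatrix(), seed = NULL) {
  stopifnot(methods::is(prototype, "PrototypeGenome"))
  if (!is.numeric(adoRate) || adoRate < 0 || adoRate > 1) {
    stop("ado_rate must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(fpRate) || fpRate < 0 || fpRate > 1) {
    stop("fp_rate must be in [0, 1]", call. = FALSE)
  }
  reference <- unname(reference)
  L <- nchar(reference)
  hapA <- prototype@hapA
  hapB <- prototype@hapB
  variantPos <- sort(unique(c(hapA$pos, hapB$pos)))
  hetPos <- heterozygousPositions(prototype)

  withSeed(seed, {
    # --- allelic dropout ---
    dropped <- hetPos[stats::runif(length(hetPos)) < adoRate]
    adoEvents <- data.frame(pos = integer(0), droppedAllele = character(0),
                            stringsAsFactors = FALSE)
    for (p in dropped) {
      onA <- p %in% hapA$pos
      altBase <- if (onA) hapA$alt[hapA$pos == p] else hapB$alt[hapB$pos == p]
      refBase <- substring(reference, p + 1L, p + 1L)
      altSurvives <- stats::runif(1) < 0.5
      if (altSurvives) {
        # site becomes hom-alt: copy the edit onto the other haplotype
        if (onA) hapB <- rbind(hapB, data.frame(pos = p, alt = altBase, stringsAsFactors = FALSE))
        else hapA <- rbind(hapA, data.frame(pos = p, alt = altBase, stringsAsFactors = FALSE))
        droppedAllele <- refBase
      } else {
        # ref allele survives: the variant disappears from the cell
        if (onA) hapA <- hapA[hapA$pos != p, , drop = FALSE]
        else hapB <- hapB[hapB$pos != p, , drop = FALSE]
        droppedAllele <- altBase
      }
      adoEvents <- rbind(adoEvents,
                         data.frame(pos = p, droppedAllele = droppedAllele,
                                    stringsAsFactors = FALSE))
    }

    # --- WGA false positives ---
    nFp <- stats::rbinom(1L, L, fpRate)
    fpPos <- integer(0)
    while (length(fpPos) < nFp) {
      cand <- sample.int(L, nFp - length(fpPos)) - 1L
      cand <- setdiff(cand, c(variantPos, fpPos))
      fpPos <- c(fpPos, cand)
    }
    fpPos <- sort(fpPos)
    fpEvents <- data.frame(pos = integer(0), ref = character(0),
                           alt = character(0), stringsAsFactors = FALSE)
    if (length(fpPos)) {
      fpRef <- substring(reference, fpPos + 1L, fpPos + 1L)
      usable <- fpRef %in% DNA_BASES
      fpPos <- fpPos[usable]; fpRef <- fpRef[usable]
      fpAlt <- vapply(fpRef, function(b) sample(DNA_BASES, 1L, prob = substMatrix[b, ]), "")
      fpEvents <- data.frame(pos = fpPos, ref = fpRef, alt = unname(fpAlt),
                             stringsAsFactors = FALSE)
    }
    if (nrow(fpEvents)) {
      onA <- stats::runif(nrow(fpEvents)) < 0.5
      addA <- fpEvents[onA, c("pos", "alt"), drop = FALSE]
      addB <- fpEvents[!onA, c("pos", "alt"), drop = FALSE]
      hapA <- rbind(hapA, addA)
      hapB <- rbind(hapB, addB)
    }

    hapA <- hapA[order(hapA$pos), , drop = FALSE]
    hapB <- hapB[order(hapB$pos), , drop = FALSE]
    rownames(hapA) <- rownames(hapB) <- NULL
    methods::new("CellGenome",
      sourcePrototype = prototype@k,
      hapA = hapA, hapB = hapB,
      adoEvents = adoEvents, fpEvents = fpEvents)
  })
}
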