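#' @import methods
NULL

VALID_SAMPLE_TYPES <- c("bulk", "single_cell")
DNA_BASES <- c("A", "C", "G", "T")

#' ExperimentDesign: the parsed experiment design
#'
#' Container for everything a simulation run needs besides the reference
#' sequence: the region of interest, the number of prototype genomes `K` and
#' potential SNV locations, the Dirichlet concentration parameters of the
#' three-level hierarchy (population alpha, per-unit beta, per-sample gamma),
#' per-sample type and coverage, the WGA error rates, the read-engine
#' parameters, the SNV substitution model and the master seed.
#'
#' Construct with [loadDesign()] (from YAML) or [newExperimentDesign()].
#'
#' @slot regionStart integer, 0-based offset of the simulated region into the
#'   reference sequence.
#' @slot regionLength integer, length of the simulated region in bp.
#' @slot K integer, number of mutated prototype genomes.
#' @slot nSnv integer, number of potential SNV locations.
#' @slot marginFraction numeric, fraction of the region kept free of SNVs at
#'   each end before equal spacing.
#' @slot alpha numeric vector of length `K`, population Dirichlet parameter.
#' @slot units list of biological units; each unit is a list with elements
#'   `id`, `beta` and `samples` (each sample a list with `id`, `type`,
#'   `gamma`, `coverage` and, for bulk samples, `nBulkReads`).
#' @slot wga list with `adoRate` and `fpRate`.
#' @slot reads list with `readLength`, `fragmentMean`, `fragmentSd`,
#'   `errorRate`, `baseQuality`.
#' @slot subst list with `tierFractions`, `pHet` and the 4x4 row-stochastic
#'   substitution `matrix`.
#' @slot seed integer master seed.
#' @slot reference character, path to the reference FASTA as given in the
#'   design file ("" when supplied separately).
#'
#' @export
setClass("ExperimentDesign",
  representation(
    regionStart = "integer",
    regionLength = "integer",
    K = "integer",
    nSnv = "integer",
    marginFraction = "numeric",
    alpha = "numeric",
    units = "list",
    wga = "list",
    reads = "list",
    subst = "list",
    seed = "integer",
    reference = "character"
  )
)

validSampleSpec <- function(s, unitId) {
  msgs <- character(0)
  where <- sprintf("unit '%s' sample '%s'", unitId, s$id %||% "?")
  if (is.null(s$id) || !nzchar(s$id)) {
    msgs <- c(msgs, sprintf("missing required field 'id' in a sample of unit '%s'", unitId))
  }
  if (is.null(s$type) || !(s$type %in% VALID_SAMPLE_TYPES)) {
    msgs <- c(msgs, sprintf("%s: 'type' must be one of %s",
                            where, paste(VALID_SAMPLE_TYPES, collapse = ", ")))
  }
  if (is.null(s$gamma)) {
    msgs <- c(msgs, sprintf("%s: missing required field 'gamma'", where))
  } else if (!is.numeric(s$gamma) || s$gamma <= 0) {
    msgs <- c(msgs, sprintf("%s: 'gamma' must be > 0", where))
  }
  if (is.null(s$coverage) || !is.numeric(s$coverage) || s$coverage <= 0) {
    msgs <- c(msgs, sprintf("%s: 'coverage' must be > 0", where))
  }
  isBulk <- identical(s$type, "bulk")
  if (isBulk && is.null(s$nBulkReads)) {
    msgs <- c(msgs, sprintf("%s: missing required field 'n_bulk_reads' (required for bulk samples)", where))
  }
  if (!isBulk && !is.null(s$nBulkReads)) {
    msgs <- c(msgs, sprintf("%s: 'n_bulk_reads' is only valid for bulk samples", where))
  }
  if (isBulk && !is.null(s$nBulkReads) &&
      (!is.numeric(s$nBulkReads) || s$nBulkReads < 0 || s$nBulkReads %% 2 != 0)) {
    msgs <- c(msgs, sprintf("%s: 'n_bulk_reads' must be a non-negative even integer (reads are drawn as pairs)", where))
  }
  msgs
}

setValidity("ExperimentDesign", function(object) {
  msgs <- character(0)
  K <- object@K
  if (K < 1L) msgs <- c(msgs, "K must be >= 1")
  if (object@nSnv < 1L) msgs <- c(msgs, "n_snv must be >= 1")
  if (length(object@alpha) != K) {
    msgs <- c(msgs, sprintf("alpha has length %d but K = %d", length(object@alpha), K))
  }
  if (any(!is.finite(object@alpha)) || any(object@alpha <= 0)) {
    msgs <- c(msgs, "every entry of alpha must be > 0")
  }
  if (object@regionLength < 2L * object@nSnv) {
    msgs <- c(msgs, sprintf("region length %d too small for %d distinct SNV positions (need >= 2*n_snv)",
                            object@regionLength, object@nSnv))
  }
  if (object@marginFraction < 0 || object@marginFraction >= 0.5) {
    msgs <- c(msgs, "margin_fraction must be in [0, 0.5)")
  }
  if (length(object@units) < 1L) msgs <- c(msgs, "no biological units")
  for (u in object@units) {
    if (is.null(u$id) || !nzchar(u$id)) {
      msgs <- c(msgs, "missing required field 'id' in a biological unit")
      next
    }
    if (is.null(u$beta) || !is.numeric(u$beta) || u$beta <= 0) {
      msgs <- c(msgs, sprintf("unit '%s': 'beta' must be > 0", u$id))
    }
    if (length(u$samples) < 1L) {
      msgs <- c(msgs, sprintf("unit '%s': at least one sample required", u$id))
    }
    for (s in u$samples) msgs <- c(msgs, validSampleSpec(s, u$id))
  }
  ids <- unlist(lapply(object@units, function(u) vapply(u$samples, `[[`, "", "id")))
  if (anyDuplicated(ids)) msgs <- c(msgs, "sample ids must be unique across the design")
  if (any(grepl(":", c(ids, vapply(object@units, `[[`, "", "id"))))) {
    msgs <- c(msgs, "unit and sample ids must not contain ':' (reserved in read names)")
  }
  w <- object@wga
  if (!is.numeric(w$adoRate) || w$adoRate < 0 || w$adoRate > 1) {
    msgs <- c(msgs, "wga ado_rate must be in [0, 1]")
  }
  if (!is.numeric(w$fpRate) || w$fpRate < 0 || w$fpRate > 1) {
    msgs <- c(msgs, "wga fp_rate must be in [0, 1]")
  }
  r <- object@reads
  if (r$readLength < 1L) msgs <- c(msgs, "read length must be >= 1")
  if (r$fragmentMean < 2 * r$readLength) {
    msgs <- c(msgs, "fragment_mean must be >= 2 * read_length")
  }
  if (r$errorRate < 0 || r$errorRate >= 1) msgs <- c(msgs, "error_rate must be in [0, 1)")
  msgs <- c(msgs, validateSubstParams(object@subst))
  if (length(msgs)) msgs else TRUE
})

validateSubstParams <- function(subst) {
  msgs <- character(0)
  tf <- subst$tierFractions
  if (length(tf) != 3L || abs(sum(tf) - 1) > 1e-9 || any(tf < 0)) {
    msgs <- c(msgs, "tier_fractions must be three non-negative proportions summing to 1")
  }
  if (!is.numeric(subst$pHet) || subst$pHet < 0 || subst$pHet > 1) {
    msgs <- c(msgs, "p_het must be in [0, 1]")
  }
  m <- subst$matrix
  if (!is.matrix(m) || !all(dim(m) == c(4L, 4L))) {
    msgs <- c(msgs, "substitution matrix must be 4x4")
  } else {
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      msgs <- c(msgs, "every substitution matrix row must sum to 1 (within 1e-9)")
    }
    if (any(diag(m) != 0)) msgs <- c(msgs, "substitution matrix diagonal must be 0")
    if (any(m < 0)) msgs <- c(msgs, "substitution matrix entries must be non-negative")
  }
  msgs
}

#' HierarchyDraw: one realization of the three-level Dirichlet hierarchy
#'
#' Holds the population distribution over prototype genomes, the per-unit
#' distributions, and the per-sample distributions, all K-dimensional simplex
#' vectors drawn as G'' ~ Dir(alpha), G'_i ~ Dir(beta_i G''),
#' G_ij ~ Dir(gamma_ij G'_i).
#'
#' @slot gPop numeric simplex vector of length K (population level).
#' @slot gUnit numeric matrix, one row per biological unit.
#' @slot gSample numeric matrix, one row per sample (across all units).
#' @slot unitIds character, ids of the units (rows of `gUnit`).
#' @slot sampleUnit character, the unit id each row of `gSample` belongs to.
#' @slot sampleIds character, ids of the samples (rows of `gSample`).
#'
#' @export
setClass("HierarchyDraw",
  representation(
    gPop = "numeric",
    gUnit = "matrix",
    gSample = "matrix",
    unitIds = "character",
    sampleUnit = "character",
    sampleIds = "character"
  )
)

setValidity("HierarchyDraw", function(object) {
  msgs <- character(0)
  K <- length(object@gPop)
  checkSimplex <- function(v, what) {
    if (any(v < 0)) return(sprintf("%s has negative entries", what))
    if (abs(sum(v) - 1) > 1e-9) return(sprintf("%s does not sum to 1 (within 1e-9)", what))
    NULL
  }
  msgs <- c(msgs, checkSimplex(object@gPop, "gPop"))
  if (ncol(object@gUnit) != K || ncol(object@gSample) != K) {
    msgs <- c(msgs, "all levels must have dimension K")
  }
  for (i in seq_len(nrow(object@gUnit))) {
    msgs <- c(msgs, checkSimplex(object@gUnit[i, ], sprintf("gUnit[%d]", i)))
  }
  for (i in seq_len(nrow(object@gSample))) {
    msgs <- c(msgs, checkSimplex(object@gSample[i, ], sprintf("gSample[%d]", i)))
  }
  if (nrow(object@gUnit) != length(object@unitIds)) msgs <- c(msgs, "unitIds length mismatch")
  if (nrow(object@gSample) != length(object@sampleIds)) msgs <- c(msgs, "sampleIds length mismatch")
  if (length(msgs)) msgs else TRUE
})

#' PrototypeGenome: one mutated diploid synthetic genome
#'
#' A diploid genome stored as two haplotype edit lists over the reference
#' region: data frames with 0-based `pos` and single-character `alt` columns.
#' Heterozygous sites edit exactly one haplotype, homozygous sites both.
#'
#' @slot k integer prototype index (1-based).
#' @slot hapA data.frame with columns `pos`, `alt`.
#' @slot hapB data.frame with columns `pos`, `alt`.
#'
#' @export
setClass("PrototypeGenome",
  representation(k = "integer", hapA = "data.frame", hapB = "data.frame")
)

validEditList <- function(df, what) {
  msgs <- character(0)
  if (!all(c("pos", "alt") %in% names(df))) {
    return(sprintf("%s must have columns pos, alt", what))
  }
  if (nrow(df)) {
    if (any(df$pos < 0)) msgs <- c(msgs, sprintf("%s has negative positions", what))
    if (anyDuplicated(df$pos)) msgs <- c(msgs, sprintf("%s has duplicated positions", what))
    if (!all(df$alt %in% DNA_BASES)) msgs <- c(msgs, sprintf("%s alt bases must be A/C/G/T", what))
  }
  msgs
}

setValidity("PrototypeGenome", function(object) {
  msgs <- c(validEditList(object@hapA, "hapA"), validEditList(object@hapB, "hapB"))
  if (length(msgs)) msgs else TRUE
})

#' CellGenome: a single cell's genome after whole-genome amplification
#'
#' The prototype genome chosen for the cell, with the WGA error model
#' applied: allelic-dropout events convert heterozygous sites to homozygous
#' for the surviving allele, and false-positive events add spurious
#' heterozygous variants at previously non-variant positions.
#'
#' @slot sourcePrototype integer index of the prototype the cell derives from.
#' @slot hapA,hapB data.frame edit lists (as in [PrototypeGenome-class]).
#' @slot adoEvents data.frame with columns `pos` and `droppedAllele`
#'   (the base lost at that site).
#' @slot fpEvents data.frame with columns `pos` and `alt`.
#'
#' @export
setClass("CellGenome",
  representation(
    sourcePrototype = "integer",
    hapA = "data.frame",
    hapB = "data.frame",
    adoEvents = "data.frame",
    fpEvents = "data.frame"
  )
)

setValidity("CellGenome", function(object) {
  msgs <- c(validEditList(object@hapA, "hapA"), validEditList(object@hapB, "hapB"))
  if (nrow(object@fpEvents) && nrow(object@adoEvents) &&
      length(intersect(object@fpEvents$pos, object@adoEvents$pos))) {
    msgs <- c(msgs, "FP positions must be disjoint from ADO positions")
  }
  if (length(msgs)) msgs else TRUE
})

#' ScoreReport: truth-aware evaluation of a variant call set
#'
#' Site-level comparison of a call set against the simulator's truth:
#' counts, recall = TP / n_truth, precision = TP / n_called,
#' F1 = 2PR/(P+R), and the Ti/Tv ratio of the call set.
#'
#' @slot nTruth,nCalled,tp,fp,fn integer counts.
#' @slot recall,precision,f1 numeric in [0, 1].
#' @slot titv numeric Ti/Tv ratio of the calls (may be `Inf`; `NA` when the
#'   call set is empty or lacks ref alleles).
#'
#' @export
setClass("ScoreReport",
  representation(
    nTruth = "integer", nCalled = "integer",
    tp = "integer", fp = "integer", fn = "integer",
    recall = "numeric", precision = "numeric", f1 = "numeric",
    titv = "numeric"
  )
)

setValidity("ScoreReport", function(object) {
  msgs <- character(0)
  if (object@tp + object@fn != object@nTruth) msgs <- c(msgs, "tp + fn must equal n_truth")
  if (object@tp + object@fp != object@nCalled) msgs <- c(msgs, "tp + fp must equal n_called")
  p <- object@precision; r <- object@recall
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  if (!isTRUE(all.equal(f1, object@f1, tolerance = 1e-9))) {
    msgs <- c(msgs, "f1 inconsistent with recall/precision")
  }
  if (length(msgs)) msgs else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
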