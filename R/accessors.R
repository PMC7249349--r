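#' @describeIn ExperimentDesign-class number of prototype genomes K
#' @param object an object of the documented class
#' @export
setGeneric("nPrototypes", function(object) standardGeneric("nPrototypes"))

#' @export
setMethod("nPrototypes", "ExperimentDesign", function(object) object@K)

#' @describeIn ExperimentDesign-class number of potential SNV locations
#' @export
setGeneric("nSnvSites", function(object) standardGeneric("nSnvSites"))

#' @export
setMethod("nSnvSites", "ExperimentDesign", function(object) object@nSnv)

#' Population-level Dirichlet concentration parameter
#'
#' @param object an [ExperimentDesign-class]
#' @return numeric vector of length `K`
#' @export
setGeneric("dirichletAlpha", function(object) standardGeneric("dirichletAlpha"))

#' @export
setMethod("dirichletAlpha", "ExperimentDesign", function(object) object@alpha)

#' Master seed of a design
#' @param object an [ExperimentDesign-class]
#' @export
setGeneric("designSeed", function(object) standardGeneric("designSeed"))

#' @export
setMethod("designSeed", "ExperimentDesign", function(object) object@seed)

#' Flat per-sample table of a design
#'
#' One row per sample with its unit id, unit concentration beta, sample id,
#' type, gamma, coverage and (bulk only) total read count.
#'
#' @param object an [ExperimentDesign-class]
#' @return a data.frame with columns `unit`, `beta`, `sample`, `type`,
#'   `gamma`, `coverage`, `nBulkReads`
#' @export
setGeneric("sampleTable", function(object) standardGeneric("sampleTable"))

#' @export
setMethod("sampleTable", "ExperimentDesign", function(object) {
  rows <- lapply(object@units, function(u) {
    do.call(rbind, lapply(u$samples, function(s) {
      data.frame(
        unit = u$id, beta = u$beta, sample = s$id, type = s$type,
        gamma = s$gamma, coverage = s$coverage,
        nBulkReads = if (is.null(s$nBulkReads)) NA_integer_ else as.integer(s$nBulkReads),
        stringsAsFactors = FALSE
      )
    }))
  })
  do.call(rbind, rows)
})

#' WGA error-model parameters of a design
#' @param object an [ExperimentDesign-class]
#' @return list with `adoRate`, `fpRate`
#' @export
setGeneric("wgaParams", function(object) standardGeneric("wgaParams"))

#' @export
setMethod("wgaParams", "ExperimentDesign", function(object) object@wga)

#' Read-engine parameters of a design
#' @param object an [ExperimentDesign-class]
#' @export
setGeneric("readParams", function(object) standardGeneric("readParams"))

#' @export
setMethod("readParams", "ExperimentDesign", function(object) object@reads)

#' SNV substitution-model parameters of a design
#' @param object an [ExperimentDesign-class]
#' @export
setGeneric("substParams", function(object) standardGeneric("substParams"))

#' @export
setMethod("substParams", "ExperimentDesign", function(object) object@subst)

setMethod("show", "ExperimentDesign", function(object) {
  st <- sampleTable(object)
  cat("ExperimentDesign\n")
  cat(sprintf("  region: start %d, length %d bp (margin %.3g)\n",
              object@regionStart, object@regionLength, object@marginFraction))
  cat(sprintf("  prototypes: K = %d, potential SNVs = %d\n", object@K, object@nSnv))
  cat(sprintf("  alpha: (%s)\n", paste(format(object@alpha), collapse = ", ")))
  cat(sprintf("  units: %d; samples: %d (%d single-cell, %d bulk)\n",
              length(object@units), nrow(st),
              sum(st$type == "single_cell"), sum(st$type == "bulk")))
  cat(sprintf("  wga: ADO %.3g, FP %.3g; reads: %dbp, coverage per sample\n",
              object@wga$adoRate, object@wga$fpRate, object@reads$readLength))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "HierarchyDraw", function(object) {
  cat(sprintf("HierarchyDraw (K = %d)\n", length(object@gPop)))
  cat("  gPop:", paste(sprintf("%.4f", object@gPop), collapse = " "), "\n")
  cat(sprintf("  %d unit vectors, %d sample vectors\n",
              nrow(object@gUnit), nrow(object@gSample)))
})

setMethod("show", "PrototypeGenome", function(object) {
  cat(sprintf("PrototypeGenome k = %d: %d edits on haplotype A, %d on haplotype B\n",
              object@k, nrow(object@hapA), nrow(object@hapB)))
})

setMethod("show", "CellGenome", function(object) {
  cat(sprintf("CellGenome from prototype %d: %d ADO events, %d FP events\n",
              object@sourcePrototype, nrow(object@adoEvents), nrow(object@fpEvents)))
})

setMethod("show", "ScoreReport", function(object) {
  cat("ScoreReport\n")
  cat(sprintf("  truth: %d  called: %d  TP: %d  FP: %d  FN: %d\n",
              object@nTruth, object@nCalled, object@tp, object@fp, object@fn))
  cat(sprintf("  recall: %.4f  precision: %.4f  F1: %.4f  Ti/Tv: %s\n",
              object@recall, object@precision, object@f1, format(object@titv)))
})

#' Turn a ScoreReport into a one-row data.frame
#' @param x a [ScoreReport-class]
#' @param row.names,optional,... ignored, present for the generic
#' @export
as.data.frame.ScoreReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    nTruth = x@nTruth, nCalled = x@nCalled, tp = x@tp, fp = x@fp, fn = x@fn,
    recall = x@recall, precision = x@precision, f1 = x@f1, titv = x@titv
  )
}
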