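# The truncated hierarchical Dirichlet mixture: a population distribution
# over the K prototype genomes, a per-unit distribution concentrated around
# it by beta_i, and a per-sample distribution concentrated around the unit
# by gamma_ij. Small concentrations put draws near a simplex vertex, which
# is what makes single-cell samples land on (almost) one genotype.

DIRICHLET_FLOOR <- 1e-12

#' Draw one vector from a Dirichlet distribution
#'
#' Standard gamma-normalization draw. Concentration entries are clamped at
#' a floor of 1e-12 before drawing (child concentrations `beta * G''_k` can
#' underflow when a parent component is tiny), and output entries below the
#' floor are clamped and the vector renormalized, so downstream categorical
#' draws never see an exact zero where mass should be merely minute.
#'
#' @param concentration numeric vector of non-negative concentrations, at
#'   least one positive.
#' @param seed integer seed (NULL = current RNG stream).
#' @return a simplex vector of the same length
#' @examples
#' sampleDirichlet(c(0.1, 0.3, 0.6), seed = 1)
#' @export
sampleDirichlet <- function(concentration, seed = NULL) {
  if (length(concentration) < 1L || any(!is.finite(concentration)) ||
      any(concentration < 0) || all(concentration == 0)) {
    stop("degenerate Dirichlet parameter: concentrations must be non-negative with at least one positive entry",
         call. = FALSE)
  }
  conc <- pmax(concentration, DIRICHLET_FLOOR)
  withSeed(seed, {
    g <- stats::rgamma(length(conc), shape = conc, rate = 1)
    if (sum(g) == 0) g <- conc  # all-underflow fallback: fall back to the mean
    x <- g / sum(g)
    x <- pmax(x, DIRICHLET_FLOOR)
    x / sum(x)
  })
}

#' Draw the full three-level hierarchy for a design
#'
#' One population vector `G'' ~ Dir(alpha)`; per biological unit `i` a
#' vector `G'_i ~ Dir(beta_i G'')`; per sample `j` of unit `i` a vector
#' `G_ij ~ Dir(gamma_ij G'_i)`. Each draw runs under its own child seed
#' derived from the master seed and the unit/sample ids, so adding a sample
#' to a design never perturbs the draws of existing samples.
#'
#' @param design an [ExperimentDesign-class].
#' @param seed master seed (default: the design's seed).
#' @return a [HierarchyDraw-class]
#' @export
sampleHierarchy <- function(design, seed = designSeed(design)) {
  stopifnot(methods::is(design, "ExperimentDesign"))
  K <- design@K
  gPop <- sampleDirichlet(design@alpha, seed = childSeed(seed, "hierarchy", "population"))
  unitIds <- vapply(design@units, `[[`, "", "id")
  gUnit <- matrix(NA_real_, length(unitIds), K)
  gs <- list(); sUnit <- character(0); sIds <- character(0)
  for (i in seq_along(design@units)) {
    u <- design@units[[i]]
    gUnit[i, ] <- sampleDirichlet(u$beta * gPop,
                                  seed = childSeed(seed, "hierarchy", "unit", u$id))
    for (s in u$samples) {
      gs[[length(gs) + 1L]] <- sampleDirichlet(
        s$gamma * gUnit[i, ],
        seed = childSeed(seed, "hierarchy", "sample", u$id, s$id))
      sUnit <- c(sUnit, u$id)
      sIds <- c(sIds, s$id)
    }
  }
  methods::new("HierarchyDraw",
    gPop = gPop, gUnit = gUnit,
    gSample = do.call(rbind, gs),
    unitIds = unitIds, sampleUnit = sUnit, sampleIds = sIds)
}

#' The per-sample simplex vector of a hierarchy draw
#' @param draw a [HierarchyDraw-class]
#' @param sampleId a sample id from the design
#' @return numeric simplex vector of length K
#' @export
gSampleOf <- function(draw, sampleId) {
  i <- match(sampleId, draw@sampleIds)
  if (is.na(i)) stop(sprintf("no sample '%s' in this hierarchy draw", sampleId))
  draw@gSample[i, ]
}
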