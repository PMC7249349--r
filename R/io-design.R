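#' Default SNV substitution matrix
#'
#' Row-stochastic 4x4 matrix of substitution probabilities (rows = reference
#' base, columns = alternate base, zero diagonal). The default puts
#' probability `transitionProb` on the transition partner of each base
#' (A<->G, C<->T) and splits the remainder equally between the two
#' transversions, which yields an expected Ti/Tv ratio of
#' `transitionProb / (1 - transitionProb)` (about 1.38 at the default,
#' inside the 1.2-1.6 band typical of germline SNV sets).
#'
#' @param transitionProb probability mass on the transition substitution,
#'   per row. Default 0.58.
#' @return a 4x4 numeric matrix with dimnames A/C/G/T
#' @examples
#' defaultSubstitutionMatrix()
#' @export
defaultSubstitutionMatrix <- function(transitionProb = 0.58) {
  stopifnot(transitionProb > 0, transitionProb < 1)
  tv <- (1 - transitionProb) / 2
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  partner <- c(A = "G", C = "T", G = "A", T = "C")
  for (b in DNA_BASES) {
    m[b, partner[[b]]] <- transitionProb
    m[b, setdiff(DNA_BASES, c(b, partner[[b]]))] <- tv
  }
  m
}

defaultReadParams <- function() {
  list(readLength = 100L, fragmentMean = 500, fragmentSd = 50,
       errorRate = 0.001, baseQuality = 30L)
}

defaultSubstParams <- function() {
  list(tierFractions = c(1, 1, 1) / 3, pHet = 0.5,
       matrix = defaultSubstitutionMatrix())
}

need <- function(x, field, where = "design") {
  if (is.null(x)) stop(sprintf("missing required field '%s' in %s", field, where), call. = FALSE)
  x
}

#' Construct an ExperimentDesign directly from R values
#'
#' Programmatic alternative to [loadDesign()]; applies the same defaults and
#' validation. `units` uses the same nested-list shape as the YAML schema
#' (see [loadDesign()]), with camelCase `nBulkReads`.
#'
#' @param regionLength region length in bp.
#' @param K number of prototype genomes.
#' @param nSnv number of potential SNV locations.
#' @param alpha numeric vector of length `K`.
#' @param units list of units: `list(id=, beta=, samples=list(list(id=,
#'   type=, gamma=, coverage=, nBulkReads=), ...))`.
#' @param regionStart 0-based region offset into the reference.
#' @param marginFraction SNV-free margin fraction at each end of the region.
#' @param adoRate,fpRate WGA error rates.
#' @param reads read-engine parameter list (see [readParams()]); missing
#'   entries take the defaults.
#' @param subst substitution-model list (`tierFractions`, `pHet`, `matrix`);
#'   missing entries take the defaults.
#' @param seed master seed.
#' @param reference path to the reference FASTA (optional here; can be given
#'   to [runSimulation()] directly).
#' @return a validated [ExperimentDesign-class]
#' @export
newExperimentDesign <- function(regionLength, K, nSnv, alpha, units,
                                regionStart = 0L, marginFraction = 0.1,
                                adoRate = 0.2, fpRate = 3.2e-5,
                                reads = list(), subst = list(),
                                seed = 1L, reference = "") {
  rd <- utils::modifyList(defaultReadParams(), reads)
  sb <- utils::modifyList(defaultSubstParams(), subst)
  methods::new("ExperimentDesign",
    regionStart = as.integer(regionStart),
    regionLength = as.integer(regionLength),
    K = as.integer(K), nSnv = as.integer(nSnv),
    marginFraction = as.numeric(marginFraction),
    alpha = as.numeric(alpha),
    units = units,
    wga = list(adoRate = as.numeric(adoRate), fpRate = as.numeric(fpRate)),
    reads = rd, subst = sb,
    seed = as.integer(seed), reference = as.character(reference)
  )
}

parseSampleSpec <- function(s, unitId, globalCoverage) {
  if (!is.null(s$gamma) && is.numeric(s$gamma) && s$gamma <= 0) {
    stop(sprintf("unit '%s' sample '%s': 'gamma' must be > 0 (got %s)",
                 unitId, s$id %||% "?", s$gamma), call. = FALSE)
  }
  list(
    id = need(s$id, "id", sprintf("a sample of unit '%s'", unitId)),
    type = need(s$type, "type", sprintf("sample '%s'", s$id %||% "?")),
    gamma = need(s$gamma, "gamma", sprintf("sample '%s'", s$id %||% "?")),
    coverage = s$coverage %||% globalCoverage,
    nBulkReads = if (is.null(s$n_bulk_reads)) NULL else as.integer(s$n_bulk_reads)
  )
}

#' Parse and validate a YAML experiment design
#'
#' Reads the experiment-design YAML (a file path or the YAML text itself),
#' fills defaults for omitted optional fields (WGA rates 0.2 / 3.2e-5,
#' margin fraction 0.1, Illumina-like read parameters, the default
#' substitution model) and validates every invariant: `alpha` must have
#' length `K` with positive entries, every concentration parameter must be
#' positive, every sample type must be `bulk` or `single_cell`, bulk samples
#' must state `n_bulk_reads`.
#'
#' The schema keys are: `reference`, `region: {start, length}`,
#' `prototypes: {K, n_snv, margin_fraction, substitution: {p_het,
#' transition_prob | matrix, tier_fractions}}`, `alpha`,
#' `units: [{id, beta, samples: [{id, type, gamma, coverage,
#' n_bulk_reads}]}]`, `coverage` (global default), `wga: {ado_rate,
#' fp_rate}`, `reads: {length, fragment_mean, fragment_sd, error_rate,
#' base_quality}`, `seed`.
#'
#' @param yaml a file path to a YAML design, or a character scalar holding
#'   YAML text.
#' @return a validated [ExperimentDesign-class]
#' @seealso [designToYaml()] for the inverse, [exampleDesign()] for a ready
#'   design
#' @export
loadDesign <- function(yaml) {
  stopifnot(is.character(yaml), length(yaml) == 1L)
  cfg <- if (file.exists(yaml) && !grepl("\n", yaml)) {
    yaml::read_yaml(yaml)
  } else {
    yaml::yaml.load(yaml)
  }
  if (!is.list(cfg)) stop("design YAML must be a mapping", call. = FALSE)

  region <- need(cfg$region, "region")
  proto <- need(cfg$prototypes, "prototypes")
  K <- as.integer(need(proto$K, "prototypes.K"))
  alpha <- as.numeric(need(cfg$alpha, "alpha"))
  if (length(alpha) != K) {
    stop(sprintf("alpha has length %d but prototypes.K is %d", length(alpha), K),
         call. = FALSE)
  }

  subst <- list()
  ps <- proto$substitution
  if (!is.null(ps)) {
    if (!is.null(ps$p_het)) subst$pHet <- as.numeric(ps$p_het)
    if (!is.null(ps$tier_fractions)) subst$tierFractions <- as.numeric(ps$tier_fractions)
    if (!is.null(ps$matrix)) {
      m <- do.call(rbind, lapply(ps$matrix, as.numeric))
      dimnames(m) <- list(DNA_BASES, DNA_BASES)
      subst$matrix <- m
    } else if (!is.null(ps$transition_prob)) {
      subst$matrix <- defaultSubstitutionMatrix(as.numeric(ps$transition_prob))
    }
  }

  reads <- list()
  rr <- cfg$reads
  if (!is.null(rr)) {
    ren <- c(length = "readLength", fragment_mean = "fragmentMean",
             fragment_sd = "fragmentSd", error_rate = "errorRate",
             base_quality = "baseQuality")
    for (k in names(ren)) if (!is.null(rr[[k]])) reads[[ren[[k]]]] <- rr[[k]]
    if (!is.null(reads$readLength)) reads$readLength <- as.integer(reads$readLength)
    if (!is.null(reads$baseQuality)) reads$baseQuality <- as.integer(reads$baseQuality)
  }

  globalCoverage <- cfg$coverage
  units <- lapply(need(cfg$units, "units"), function(u) {
    uid <- need(u$id, "id", "a biological unit")
    if (!is.null(u$beta) && is.numeric(u$beta) && u$beta <= 0) {
      stop(sprintf("unit '%s': 'beta' must be > 0 (got %s)", uid, u$beta), call. = FALSE)
    }
    list(
      id = uid,
      beta = need(u$beta, "beta", sprintf("unit '%s'", uid)),
      samples = lapply(need(u$samples, "samples", sprintf("unit '%s'", uid)),
                       parseSampleSpec, unitId = uid, globalCoverage = globalCoverage)
    )
  })

  newExperimentDesign(
    regionLength = need(region$length, "region.length"),
    regionStart = region$start %||% 0L,
    K = K,
    nSnv = need(proto$n_snv, "prototypes.n_snv"),
    marginFraction = proto$margin_fraction %||% 0.1,
    alpha = alpha,
    units = units,
    adoRate = cfg$wga$ado_rate %||% 0.2,
    fpRate = cfg$wga$fp_rate %||% 3.2e-5,
    reads = reads, subst = subst,
    seed = cfg$seed %||% 1L,
    reference = cfg$reference %||% ""
  )
}

#' Serialize an ExperimentDesign back to YAML
#'
#' Inverse of [loadDesign()]: `loadDesign(designToYaml(d))` reconstructs an
#' identical design.
#'
#' @param design an [ExperimentDesign-class]
#' @param path optional file to write; when `NULL` the YAML text is returned.
#' @return YAML text (invisibly when `path` is given)
#' @export
designToYaml <- function(design, path = NULL) {
  stopifnot(methods::is(design, "ExperimentDesign"))
  r <- design@reads
  cfg <- list(
    reference = design@reference,
    region = list(start = design@regionStart, length = design@regionLength),
    prototypes = list(
      K = design@K, n_snv = design@nSnv,
      margin_fraction = design@marginFraction,
      substitution = list(
        p_het = design@subst$pHet,
        tier_fractions = as.numeric(design@subst$tierFractions),
        matrix = lapply(seq_len(4), function(i) as.numeric(design@subst$matrix[i, ]))
      )
    ),
    alpha = as.numeric(design@alpha),
    units = lapply(design@units, function(u) list(
      id = u$id, beta = u$beta,
      samples = lapply(u$samples, function(s) {
        out <- list(id = s$id, type = s$type, gamma = s$gamma, coverage = s$coverage)
        if (!is.null(s$nBulkReads)) out$n_bulk_reads <- s$nBulkReads
        out
      })
    )),
    wga = list(ado_rate = design@wga$adoRate, fp_rate = design@wga$fpRate),
    reads = list(length = r$readLength, fragment_mean = r$fragmentMean,
                 fragment_sd = r$fragmentSd, error_rate = r$errorRate,
                 base_quality = r$baseQuality),
    seed = design@seed
  )
  txt <- yaml::as.yaml(cfg, precision = 15L)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
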