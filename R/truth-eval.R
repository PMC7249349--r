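# Truth-aware evaluation of variant call sets: site-level matching on
# (position, alt allele), standard post-filters, recall / precision / F1
# and the Ti/Tv sanity statistic.

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Transition/transversion ratio of an SNV set
#'
#' Transitions are A<->G and C<->T; everything else with `ref != alt` is a
#' transversion. With no transversions the ratio is reported as `Inf`.
#'
#' @param ref,alt character vectors of reference and alternate alleles.
#' @return the Ti/Tv ratio
#' @examples
#' titvRatio(c("A", "C", "A"), c("G", "T", "C"))  # 2 transitions, 1 transversion
#' @export
titvRatio <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (!length(ref)) stop("Ti/Tv is undefined for an empty SNV set", call. = FALSE)
  if (any(ref == alt)) stop("ref == alt in input: not SNVs", call. = FALSE)
  ti <- sum(paste(ref, alt, sep = ">") %in% TRANSITIONS)
  tv <- length(ref) - ti
  if (tv == 0L) Inf else ti / tv
}

#' Score a call set against the simulator's truth
#'
#' Site-level matching: a call is a true positive iff some truth site has
#' the same (1-based) position and the same alternate allele. Truth and
#' calls may be pooled over samples beforehand; duplicated (position, alt)
#' records are collapsed. An empty call set yields precision 0 with a
#' warning; if nothing matches but shifting every call by one base would
#' match most of the truth, a coordinate-system warning is raised (never a
#' silent correction).
#'
#' @param called data.frame with columns `pos` (1-based), `alt`, and
#'   optionally `ref` (used for the Ti/Tv of the call set).
#' @param truth data.frame with columns `pos` (1-based) and `alt`.
#' @return a [ScoreReport-class]
#' @export
scoreCalls <- function(called, truth) {
  keyC <- unique(paste(called$pos, called$alt, sep = "@"))
  keyT <- unique(paste(truth$pos, truth$alt, sep = "@"))
  nCalled <- length(keyC)
  nTruth <- length(keyT)
  tp <- sum(keyC %in% keyT)
  if (nCalled && nTruth && tp == 0L) {
    up <- sum(paste(called$pos + 1L, called$alt, sep = "@") %in% keyT)
    down <- sum(paste(called$pos - 1L, called$alt, sep = "@") %in% keyT)
    if (max(up, down) >= 0.5 * min(nCalled, nTruth)) {
      warning("no calls match the truth, but most match after an off-by-one shift: check the coordinate system (1-based POS expected)")
    }
  }
  fp <- nCalled - tp
  fn <- nTruth - tp
  recall <- if (nTruth == 0L) 0 else tp / nTruth
  precision <- if (nCalled == 0L) {
    warning("empty call set: precision reported as 0")
    0
  } else tp / nCalled
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  titv <- NA_real_
  if (!is.null(called$ref) && nCalled > 0L) {
    dedup <- !duplicated(paste(called$pos, called$alt, sep = "@"))
    ok <- dedup & called$ref != called$alt
    if (any(ok)) titv <- titvRatio(called$ref[ok], called$alt[ok])
  }
  methods::new("ScoreReport",
    nTruth = as.integer(nTruth), nCalled = as.integer(nCalled),
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    recall = recall, precision = precision, f1 = f1, titv = titv)
}

#' Apply standard post-filters to a call set
#'
#' The default thresholds are the usual hard filters for single-cell SNV
#' calls: minimum mapping quality strictly above 1, minimum base quality
#' strictly above 30, strictly more than 5 variant-supporting reads, and
#' removal of strand-biased calls. Strand bias is, by default, the
#' deterministic one-strand-only rule: a call fails iff it has at least
#' `strandMin` (default 4) alt-supporting reads and all of them sit on one
#' strand; alternatively `strandMethod = "fisher"` removes calls whose
#' ref/alt-by-strand Fisher exact test has p < `fisherP` (needs `refFwd`,
#' `refRev` columns).
#'
#' A record missing an annotation needed by an enabled filter passes that
#' filter; one warning reports how many records were affected.
#'
#' @param calls data.frame with (as available) columns `mq`, `bq`,
#'   `altReads`, `altFwd`, `altRev`, `refFwd`, `refRev`.
#' @param thresholds named list overriding any of `minMq` (1), `minBq`
#'   (30), `minAltReads` (5), `strandMin` (4), `strandMethod`
#'   ("one_strand" or "fisher"), `fisherP` (0.001). Set a threshold to `NA`
#'   to disable that filter.
#' @return the surviving rows of `calls`
#' @export
applyPostFilters <- function(calls, thresholds = list()) {
  th <- utils::modifyList(
    list(minMq = 1, minBq = 30, minAltReads = 5,
         strandMin = 4, strandMethod = "one_strand", fisherP = 0.001),
    thresholds)
  n <- nrow(calls)
  keep <- rep(TRUE, n)
  nMissing <- 0L

  passNumeric <- function(col, minVal) {
    if (is.na(minVal)) return(rep(TRUE, n))
    v <- calls[[col]]
    if (is.null(v)) v <- rep(NA_real_, n)
    miss <- is.na(v)
    nMissing <<- nMissing + sum(miss & keep)
    miss | v > minVal  # strict >
  }
  keep <- keep & passNumeric("mq", th$minMq)
  keep <- keep & passNumeric("bq", th$minBq)
  keep <- keep & passNumeric("altReads", th$minAltReads)

  if (!is.na(th$strandMin)) {
    fwd <- calls$altFwd %||% rep(NA_real_, n)
    rev <- calls$altRev %||% rep(NA_real_, n)
    miss <- is.na(fwd) | is.na(rev)
    nMissing <- nMissing + sum(miss & keep)
    if (identical(th$strandMethod, "fisher")) {
      rf <- calls$refFwd %||% rep(NA_real_, n)
      rr <- calls$refRev %||% rep(NA_real_, n)
      miss <- miss | is.na(rf) | is.na(rr)
      biased <- vapply(seq_len(n), function(i) {
        if (miss[i]) return(FALSE)
        p <- stats::fisher.test(matrix(c(rf[i], rr[i], fwd[i], rev[i]), 2))$p.value
        p < th$fisherP
      }, logical(1))
    } else {
      biased <- !miss & (fwd + rev >= th$strandMin) & (fwd == 0 | rev == 0)
    }
    keep <- keep & !biased
  }

  if (nMissing > 0L) {
    warning(sprintf("%d record-filter checks skipped for missing annotations (records kept)", nMissing))
  }
  calls[keep, , drop = FALSE]
}

#' Read a variant-caller VCF into a call table
#'
#' Pulls 1-based POS, REF, the first ALT allele, and — when present — the
#' annotations the post-filters consume: `INFO/MQ` as `mq`, `INFO/BQ` as
#' `bq`, and per-strand depths from `INFO/DP4` as
#' `refFwd`/`refRev`/`altFwd`/`altRev` (with `altReads` their alt-side
#' sum). Missing annotations come back as `NA` and the corresponding
#' filters will pass (with a warning) in [applyPostFilters()].
#'
#' @param path a VCF file.
#' @return data.frame with columns `pos`, `ref`, `alt` and any of `mq`,
#'   `bq`, `altReads`, `altFwd`, `altRev`, `refFwd`, `refRev`
#' @export
readCallsVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0)))
  }
  out <- data.frame(
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = sub(",.*$", "", fix$ALT),
    stringsAsFactors = FALSE
  )
  getInfoNum <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_real_, nrow(fix)) else suppressWarnings(as.numeric(x))
  }
  out$mq <- getInfoNum("MQ")
  out$bq <- getInfoNum("BQ")
  dp4 <- vcfR::extract.info(v, element = "DP4")
  if (!is.null(dp4) && any(!is.na(dp4))) {
    parts <- strsplit(dp4, ",", fixed = TRUE)
    getp <- function(i) vapply(parts, function(p) {
      if (length(p) == 4L) suppressWarnings(as.numeric(p[i])) else NA_real_
    }, numeric(1))
    out$refFwd <- getp(1); out$refRev <- getp(2)
    out$altFwd <- getp(3); out$altRev <- getp(4)
    out$altReads <- out$altFwd + out$altRev
  }
  out
}

#' Write a ScoreReport as JSON and TSV
#' @param report a [ScoreReport-class]
#' @param prefix output path prefix (writes `<prefix>.json` and
#'   `<prefix>.tsv`)
#' @return the two paths, invisibly
#' @export
writeScoreReport <- function(report, prefix) {
  df <- as.data.frame(report)
  jsonPath <- paste0(prefix, ".json")
  tsvPath <- paste0(prefix, ".tsv")
  jsonlite::write_json(as.list(df), jsonPath, auto_unbox = TRUE, digits = NA)
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jsonPath, tsvPath))
}
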