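# End-to-end orchestration: reference + design in; prototype genomes,
# hierarchy draw, single-cell WGA reads, bulk pools and mixtures, truth
# VCF/TSV and a machine-readable run manifest out. Every stage runs under a
# child seed derived from the master seed, so reruns are byte-identical.

#' Run the full simulation workflow
#'
#' Stage order: forge prototypes; draw the hierarchy; per single-cell
#' sample select a genotype, apply WGA and simulate reads; generate pure
#' per-prototype read pools sized to the exact bulk demand; per bulk sample
#' allocate, draw without replacement and write; truth files and the
#' manifest last. Any stage error aborts with a stage-named message and
#' removes the partial outputs this run created.
#'
#' @param design an [ExperimentDesign-class] or the path to a design YAML.
#' @param reference path to the reference FASTA, or a (named) character
#'   scalar holding the sequence; defaults to the `reference` path recorded
#'   in the design.
#' @param outdir output directory (created if absent).
#' @param seed optional master-seed override; default is the design's seed.
#' @param quiet suppress per-stage progress messages.
#' @return the run manifest, invisibly (also written to
#'   `<outdir>/manifest.json`)
#' @export
runSimulation <- function(design, reference = NULL, outdir, seed = NULL,
                          quiet = FALSE) {
  if (is.character(design)) design <- loadDesign(design)
  stopifnot(methods::is(design, "ExperimentDesign"))
  methods::validObject(design)
  if (is.null(reference)) {
    if (!nzchar(design@reference)) stop("no reference given and none recorded in the design")
    reference <- design@reference
  }
  stopifnot(is.character(reference), length(reference) == 1L)
  refSeq <- if (file.exists(reference)) readReference(reference) else reference
  contig <- names(refSeq) %||% "region"
  if (is.null(names(refSeq)) || !nzchar(contig)) contig <- "region"
  L <- design@regionLength
  if (nchar(refSeq) < design@regionStart + L) {
    stop(sprintf("reference length %d shorter than region start %d + length %d",
                 nchar(refSeq), design@regionStart, L))
  }
  region <- substr(unname(refSeq), design@regionStart + 1L, design@regionStart + L)
  master <- as.integer(seed %||% designSeed(design))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  created <- character(0)
  note <- function(...) if (!quiet) message(sprintf(...))
  stage <- "setup"

  result <- tryCatch({
    stage <- "prototype forging"
    note("[%s] placing %d SNV sites over %d bp, K = %d", stage, design@nSnv, L, design@K)
    sites <- placeSnvSites(L, design@nSnv, design@K, design@marginFraction,
                           seed = childSeed(master, "sites"))
    sites <- assignSubstitutions(sites, region, design@subst,
                                 seed = childSeed(master, "substitutions"))
    protos <- buildPrototypeGenomes(sites, seed = childSeed(master, "haplotypes"))

    stage <- "hierarchy draw"
    draw <- sampleHierarchy(design, seed = master)
    st <- sampleTable(design)
    rp <- design@reads
    manifestSamples <- list()

    stage <- "single-cell simulation"
    protoHaps <- vector("list", design@K)  # lazily materialized
    getProtoHaps <- function(k) {
      if (is.null(protoHaps[[k]])) {
        protoHaps[[k]] <<- list(A = materializeHaplotype(region, protos[[k]]@hapA),
                                B = materializeHaplotype(region, protos[[k]]@hapB))
      }
      protoHaps[[k]]
    }
    for (r in which(st$type == "single_cell")) {
      sid <- st$sample[r]; uid <- st$unit[r]
      g <- gSampleOf(draw, sid)
      k <- selectCellGenotype(g, seed = childSeed(master, "genotype", uid, sid))
      cell <- applyWga(protos[[k]], region,
                       adoRate = design@wga$adoRate, fpRate = design@wga$fpRate,
                       substMatrix = design@subst$matrix,
                       seed = childSeed(master, "wga", uid, sid))
      hapA <- materializeHaplotype(region, cell@hapA)
      hapB <- materializeHaplotype(region, cell@hapB)
      nPairs <- pairCountForCoverage(L, st$coverage[r], rp$readLength)
      reads <- simulateReads(hapA, hapB, nPairs, rp, origin = sid,
                             src = sprintf("p%d", k),
                             seed = childSeed(master, "reads", uid, sid))
      prefix <- file.path(outdir, sid)
      created <- c(created, writeFastqPair(reads, prefix, rp$baseQuality))
      vcfPath <- file.path(outdir, paste0(sid, ".truth.vcf"))
      writeTruthVcf(sites, vcfPath, cell = cell, contig = contig,
                    regionStart = design@regionStart, regionLength = L)
      created <- c(created, vcfPath)
      note("[%s] %s: prototype %d, %d ADO, %d FP, %d pairs", stage, sid, k,
           nrow(cell@adoEvents), nrow(cell@fpEvents), nPairs)
      manifestSamples[[sid]] <- list(
        type = "single_cell", unit = uid, prototype = k,
        adoEvents = nrow(cell@adoEvents), fpEvents = nrow(cell@fpEvents),
        readPairs = nPairs, records = 2L * nPairs,
        fastq = basename(writeFastqPairPaths(prefix)), truthVcf = basename(vcfPath))
    }

    stage <- "bulk pool generation"
    demand <- bulkPoolDemand(design, draw)
    pools <- vector("list", design@K)
    for (k in seq_len(design@K)) {
      if (demand[k] > 0L) {
        h <- getProtoHaps(k)
        poolReads <- simulateReads(h$A, h$B, demand[k], rp,
                                   origin = sprintf("pool%d", k),
                                   src = sprintf("p%d", k),
                                   seed = childSeed(master, "pool", k))
      } else {
        poolReads <- data.frame(name = character(0), seq1 = character(0),
                                seq2 = character(0), stringsAsFactors = FALSE)
      }
      pools[[k]] <- newReadPool(k, poolReads)
      note("[%s] pool %d: %d pairs", stage, k, demand[k])
    }

    stage <- "bulk mixing"
    for (r in which(st$type == "bulk")) {
      sid <- st$sample[r]; uid <- st$unit[r]
      g <- gSampleOf(draw, sid)
      res <- composeBulkSample(pools, g, st$nBulkReads[r],
                               seed = childSeed(master, "bulk", uid, sid))
      pools <- res$pools
      prefix <- file.path(outdir, sid)
      created <- c(created, writeFastqPair(res$reads, prefix, rp$baseQuality))
      compPath <- file.path(outdir, paste0(sid, ".composition.tsv"))
      drawnComp <- table(factor(parseReadNames(res$reads$name)$src,
                                levels = sprintf("p%d", seq_len(design@K))))
      utils::write.table(
        data.frame(prototype = seq_len(design@K),
                   allocatedPairs = res$allocation,
                   drawnPairs = as.integer(drawnComp)),
        compPath, sep = "\t", quote = FALSE, row.names = FALSE)
      created <- c(created, compPath)
      note("[%s] %s: %d records, composition %s", stage, sid, st$nBulkReads[r],
           paste(res$allocation, collapse = "/"))
      manifestSamples[[sid]] <- list(
        type = "bulk", unit = uid,
        allocationPairs = res$allocation,
        readPairs = sum(res$allocation), records = st$nBulkReads[r],
        fastq = basename(writeFastqPairPaths(prefix)),
        composition = basename(compPath))
    }

    stage <- "truth output"
    protoVcf <- file.path(outdir, "prototypes.truth.vcf")
    protoTsv <- file.path(outdir, "prototypes.truth.tsv")
    writeTruthVcf(sites, protoVcf, contig = contig,
                  regionStart = design@regionStart, regionLength = L)
    writeTruthTsv(sites, protoTsv)
    created <- c(created, protoVcf, protoTsv)

    stage <- "manifest"
    manifest <- list(
      package = "scbulksim",
      version = as.character(utils::packageVersion("scbulksim")),
      masterSeed = master,
      design = yaml::yaml.load(designToYaml(design)),
      hierarchy = list(gPop = draw@gPop,
                       gUnit = apply(draw@gUnit, 1, identity, simplify = FALSE),
                       gSample = stats::setNames(
                         apply(draw@gSample, 1, identity, simplify = FALSE),
                         draw@sampleIds)),
      poolDemandPairs = as.integer(demand),
      samples = manifestSamples,
      truth = list(vcf = basename(protoVcf), tsv = basename(protoTsv))
    )
    manifestPath <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    created <- c(created, manifestPath)
    manifest
  }, error = function(e) {
    unlink(created)
    stop(sprintf("simulation failed during stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

writeFastqPairPaths <- function(prefix) paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))

#' A ready-made example experiment design
#'
#' Three prototype genomes with 100 potential SNVs on a 1 Mbp region,
#' population Dirichlet parameter (0.1, 0.3, 0.6), four biological units
#' (all beta = 0.1) with two samples each (all gamma = 0.1): units 1 and 4
#' one bulk + one single-cell sample, unit 2 two single cells, unit 3 two
#' bulks. Coverage 24x, bulk samples of 1,000,000 reads, WGA ADO 20% and
#' FP 3.2e-5. Arguments let tests and examples scale the region, coverage
#' and bulk totals down without touching the structure.
#'
#' @param regionLength region length in bp.
#' @param coverage mean fold-coverage for read simulation.
#' @param nBulkReads total FASTQ records per bulk sample (even).
#' @param nSnv number of potential SNV locations.
#' @param seed master seed.
#' @return an [ExperimentDesign-class]
#' @examples
#' exampleDesign()
#' @export
exampleDesign <- function(regionLength = 1e6, coverage = 24,
                          nBulkReads = 1e6, nSnv = 100, seed = 1L) {
  mkSample <- function(id, type) {
    s <- list(id = id, type = type, gamma = 0.1, coverage = coverage)
    if (type == "bulk") s$nBulkReads <- as.integer(nBulkReads)
    s
  }
  mkUnit <- function(i, types) {
    list(id = sprintf("unit%d", i), beta = 0.1,
         samples = lapply(seq_along(types), function(j) {
           mkSample(sprintf("unit%d_s%d_%s", i, j,
                            if (types[j] == "bulk") "bulk" else "sc"),
                    types[j])
         }))
  }
  newExperimentDesign(
    regionLength = regionLength, K = 3L, nSnv = nSnv,
    alpha = c(0.1, 0.3, 0.6),
    units = list(
      mkUnit(1, c("bulk", "single_cell")),
      mkUnit(2, c("single_cell", "single_cell")),
      mkUnit(3, c("bulk", "bulk")),
      mkUnit(4, c("bulk", "single_cell"))
    ),
    seed = seed
  )
}
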