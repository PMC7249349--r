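# Shared fixtures: tiny references and designs, built in code at test time.

tinyReference <- function(length = 2000, seed = 101, gc = 0.41) {
  makeFixtureReference(length, gcFraction = gc, seed = seed)
}

# A minimal two-unit design: one single-cell + one bulk sample.
tinyDesign <- function(regionLength = 2000, nSnv = 10, K = 3,
                       coverage = 2, nBulkReads = 200, seed = 11,
                       reads = list(readLength = 30L, fragmentMean = 80,
                                    fragmentSd = 8, errorRate = 0,
                                    baseQuality = 30L)) {
  newExperimentDesign(
    regionLength = regionLength, K = K, nSnv = nSnv,
    alpha = rep(1, K) / K,
    units = list(
      list(id = "u1", beta = 1, samples = list(
        list(id = "u1_sc", type = "single_cell", gamma = 1, coverage = coverage),
        list(id = "u1_bulk", type = "bulk", gamma = 1, coverage = coverage,
             nBulkReads = as.integer(nBulkReads))
      ))
    ),
    reads = reads, seed = seed
  )
}

# YAML text of the worked-example protocol: K = 3, 100 SNVs, alpha
# (0.1, 0.3, 0.6), four units of two samples (bulk+sc / sc+sc / bulk+bulk /
# bulk+sc), all beta = gamma = 0.1, coverage 24.
protocolYaml <- function(regionLength = 1000000L, nBulkReads = 1000000L) {
  sprintf('
reference: ref.fa
region: {start: 0, length: %d}
prototypes: {K: 3, n_snv: 100, margin_fraction: 0.1}
alpha: [0.1, 0.3, 0.6]
coverage: 24
units:
  - id: unit1
    beta: 0.1
    samples:
      - {id: u1_bulk, type: bulk, gamma: 0.1, n_bulk_reads: %d}
      - {id: u1_sc, type: single_cell, gamma: 0.1}
  - id: unit2
    beta: 0.1
    samples:
      - {id: u2_sc1, type: single_cell, gamma: 0.1}
      - {id: u2_sc2, type: single_cell, gamma: 0.1}
  - id: unit3
    beta: 0.1
    samples:
      - {id: u3_bulk1, type: bulk, gamma: 0.1, n_bulk_reads: %d}
      - {id: u3_bulk2, type: bulk, gamma: 0.1, n_bulk_reads: %d}
  - id: unit4
    beta: 0.1
    samples:
      - {id: u4_bulk, type: bulk, gamma: 0.1, n_bulk_reads: %d}
      - {id: u4_sc, type: single_cell, gamma: 0.1}
wga: {ado_rate: 0.2, fp_rate: 3.2e-5}
seed: 42
', regionLength, nBulkReads, nBulkReads, nBulkReads, nBulkReads)
}

# Brute-force diff of a materialized haplotype against the reference:
# the independent oracle for edit-list correctness.
bruteForceDiff <- function(reference, haplotype) {
  a <- strsplit(unname(reference), "")[[1]]
  b <- strsplit(haplotype, "")[[1]]
  stopifnot(length(a) == length(b))
  idx <- which(a != b)
  data.frame(pos = idx - 1L, alt = b[idx], stringsAsFactors = FALSE)
}
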