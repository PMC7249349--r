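# Bulk samples are composed from pure per-prototype read pools: the
# realized sample distribution G_ij is turned into exact integer counts by
# largest-remainder apportionment, and reads are drawn without replacement
# from each pool. Pools are shared across all bulk samples of a run and
# depleted monotonically, so no read is ever duplicated between samples.

#' Largest-remainder apportionment of a total over a simplex vector
#'
#' Hamilton's method: floor the quotas `total * g`, then hand the leftover
#' units to the largest fractional remainders, ties broken by lowest index.
#' Counts are non-negative, sum exactly to `total`, and each deviates from
#' its quota by less than 1.
#'
#' @param gSample simplex vector of length K.
#' @param total non-negative integer.
#' @return integer vector of K counts summing to `total`
#' @examples
#' allocateCounts(c(0.1, 0.3, 0.6), 10)   # 1 3 6
#' allocateCounts(rep(1/3, 3), 10)        # 4 3 3
#' @export
allocateCounts <- function(gSample, total) {
  stopifnot(total >= 0, all(gSample >= 0), abs(sum(gSample) - 1) < 1e-6)
  quota <- total * gSample / sum(gSample)
  base <- floor(quota)
  leftover <- as.integer(round(total - sum(base)))
  counts <- as.integer(base)
  if (leftover > 0L) {
    gets <- order(quota - base, seq_along(quota), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(leftover)]
    counts[gets] <- counts[gets] + 1L
  }
  counts
}

#' Create a read pool for one prototype
#' @param prototype prototype index k.
#' @param reads read data.frame from [simulateReads()].
#' @return a ReadPool: list with `prototype`, `reads`, `remaining`
#' @export
newReadPool <- function(prototype, reads) {
  list(prototype = as.integer(prototype), reads = reads,
       remaining = nrow(reads))
}

#' Draw reads from a pool without replacement
#'
#' A uniformly random subset of `count` read pairs is removed from the
#' pool; a read pair is drawn at most once over the pool's lifetime.
#'
#' @param pool a pool from [newReadPool()].
#' @param count number of pairs to draw.
#' @param seed integer seed.
#' @return list with `reads` (the drawn pairs) and `pool` (the depleted pool)
#' @export
drawWithoutReplacement <- function(pool, count, seed = NULL) {
  stopifnot(count >= 0)
  if (count > pool$remaining) {
    stop(sprintf("read pool for prototype %d exhausted: requested %d pairs, %d remaining (shortfall %d)",
                 pool$prototype, count, pool$remaining, count - pool$remaining),
         call. = FALSE)
  }
  count <- as.integer(count)
  if (count == 0L) return(list(reads = pool$reads[0, , drop = FALSE], pool = pool))
  idx <- withSeed(seed, sample.int(pool$remaining, count))
  drawn <- pool$reads[idx, , drop = FALSE]
  pool$reads <- pool$reads[-idx, , drop = FALSE]
  pool$remaining <- pool$remaining - count
  rownames(drawn) <- NULL
  list(reads = drawn, pool = pool)
}

#' Compose a bulk sample from pure per-prototype pools
#'
#' Allocates `totalReads / 2` pairs over the K pools by largest remainder
#' according to `gSample`, draws each pool's share without replacement,
#' and shuffles the interleaving order. The decoded per-prototype
#' composition of the result equals the allocation exactly.
#'
#' @param pools list of K pools (from [newReadPool()]), in prototype order.
#' @param gSample realized simplex vector G_ij for this sample.
#' @param totalReads total FASTQ records across the R1/R2 pair; must be
#'   even (reads are drawn as whole pairs, mates never separated).
#' @param seed integer seed.
#' @return list with `reads` (data.frame of `totalReads / 2` pairs),
#'   `pools` (depleted), and `allocation` (integer pair counts per
#'   prototype)
#' @export
composeBulkSample <- function(pools, gSample, totalReads, seed = NULL) {
  if (totalReads %% 2L != 0L) {
    stop("totalReads must be even: reads are drawn as whole pairs", call. = FALSE)
  }
  counts <- allocateCounts(gSample, totalReads %/% 2L)
  stopifnot(length(pools) == length(counts))
  withSeed(seed, {
    drawnList <- vector("list", length(pools))
    for (k in seq_along(pools)) {
      res <- drawWithoutReplacement(pools[[k]], counts[k])
      drawnList[[k]] <- res$reads
      pools[[k]] <- res$pool
    }
    reads <- do.call(rbind, drawnList)
    if (nrow(reads)) reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    rownames(reads) <- NULL
    list(reads = reads, pools = pools, allocation = counts)
  })
}

#' Exact per-prototype pair demand across the bulk samples of a design
#'
#' Because largest-remainder allocation is deterministic given the realized
#' G_ij, the total demand each pool must satisfy is known before any read
#' is simulated; pools are generated at exactly this size.
#'
#' @param design an [ExperimentDesign-class].
#' @param draw a [HierarchyDraw-class] for that design.
#' @return integer vector of K pair counts
#' @export
bulkPoolDemand <- function(design, draw) {
  st <- sampleTable(design)
  demand <- integer(design@K)
  for (r in which(st$type == "bulk")) {
    g <- gSampleOf(draw, st$sample[r])
    demand <- demand + allocateCounts(g, st$nBulkReads[r] %/% 2L)
  }
  demand
}
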