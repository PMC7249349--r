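# FASTQ emission. Reads travel through the package as plain data frames
# (name, seq1, seq2); qualities are constant-Phred and attached at write
# time. Read names carry full provenance:
#   <origin>:<src>:<hap>:<fragStart>:<fragEnd>:<serial>
# origin = sample or pool id, src = prototype/cell label, hap = A or B,
# fragment coordinates 0-based half-open over the region.

#' Compose a provenance-encoded read name
#' @param origin sample or pool id.
#' @param src source genome label (e.g. `"p2"` for prototype 2).
#' @param hap `"A"` or `"B"`.
#' @param fragStart,fragEnd 0-based half-open fragment coordinates.
#' @param serial integer pair serial within the origin.
#' @return character vector of read names
#' @export
makeReadNames <- function(origin, src, hap, fragStart, fragEnd, serial) {
  sprintf("%s:%s:%s:%d:%d:%d", origin, src, hap, fragStart, fragEnd, serial)
}

#' Decode provenance-encoded read names
#' @param names character vector of names from [makeReadNames()].
#' @return data.frame with columns `origin`, `src`, `hap`, `fragStart`,
#'   `fragEnd`, `serial`
#' @export
parseReadNames <- function(names) {
  parts <- strsplit(names, ":", fixed = TRUE)
  bad <- lengths(parts) != 6L
  if (any(bad)) {
    stop(sprintf("%d read name(s) do not follow the origin:src:hap:start:end:serial grammar",
                 sum(bad)))
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  data.frame(
    origin = m[, 1], src = m[, 2], hap = m[, 3],
    fragStart = as.integer(m[, 4]), fragEnd = as.integer(m[, 5]),
    serial = as.integer(m[, 6]), stringsAsFactors = FALSE
  )
}

#' Write a paired gzipped FASTQ (`<prefix>_R1.fastq.gz`, `_R2.fastq.gz`)
#'
#' Qualities are constant at `baseQuality` (Phred+33). Mate suffixes `/1`
#' and `/2` are appended to the shared read name. Output bytes are
#' deterministic for fixed input.
#'
#' @param reads data.frame with columns `name`, `seq1`, `seq2`.
#' @param prefix output path prefix.
#' @param baseQuality integer Phred quality for every base.
#' @return character vector of the two paths, invisibly
#' @export
writeFastqPair <- function(reads, prefix, baseQuality = 30L) {
  qchar <- intToUtf8(as.integer(baseQuality) + 33L)
  paths <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  for (mate in 1:2) {
    seqs <- reads[[paste0("seq", mate)]]
    quals <- strrep(qchar, nchar(seqs))
    block <- rbind(paste0("@", reads$name, "/", mate), seqs, "+", quals)
    con <- gzfile(paths[mate], "w")
    writeLines(as.vector(block), con)
    close(con)
  }
  invisible(paths)
}

#' Read a paired gzipped FASTQ written by [writeFastqPair()]
#' @param prefix the path prefix used at write time.
#' @return data.frame with columns `name`, `seq1`, `qual1`, `seq2`, `qual2`
#' @export
readFastqPair <- function(prefix) {
  readOne <- function(path) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) %% 4L != 0L) stop(sprintf("truncated FASTQ: %s", path))
    idx <- seq(1L, length(lines), by = 4L)
    data.frame(name = sub("^@", "", sub("/[12]$", "", lines[idx])),
               seq = lines[idx + 1L], qual = lines[idx + 3L],
               stringsAsFactors = FALSE)
  }
  r1 <- readOne(paste0(prefix, "_R1.fastq.gz"))
  r2 <- readOne(paste0(prefix, "_R2.fastq.gz"))
  stopifnot(identical(r1$name, r2$name))
  data.frame(name = r1$name, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}
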