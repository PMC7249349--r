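#' Read the haploid reference sequence from a FASTA file
#'
#' Returns the first record of the FASTA, uppercased, as a named character
#' scalar (the name is the contig id). The simulator uses a single haploid
#' reference; if the file holds more than one record the extra records are
#' ignored with a warning.
#'
#' @param fastaPath path to a FASTA file (plain or gzipped).
#' @return a character scalar over A/C/G/T/N, named by the contig
#' @export
readReference <- function(fastaPath) {
  if (!file.exists(fastaPath)) {
    stop(sprintf("reference FASTA not found: %s", fastaPath), call. = FALSE)
  }
  set <- tryCatch(Biostrings::readDNAStringSet(fastaPath),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   fastaPath, conditionMessage(e)),
                                           call. = FALSE))
  if (length(set) == 0L) stop(sprintf("FASTA '%s' contains no records", fastaPath), call. = FALSE)
  if (length(set) > 1L) {
    warning(sprintf("FASTA '%s' has %d records; using the first ('%s')",
                    fastaPath, length(set), names(set)[1]))
  }
  seqstr <- toupper(as.character(set[[1]]))
  if (grepl("[^ACGTN]", seqstr)) {
    # collapse IUPAC ambiguity codes to N: the SNV model needs concrete bases
    seqstr <- gsub("[^ACGTN]", "N", seqstr)
  }
  contig <- sub("\\s.*$", "", names(set)[1])
  stats::setNames(seqstr, contig)
}

#' Generate a random fixture reference FASTA
#'
#' Writes (or returns) an i.i.d. random DNA sequence with the requested GC
#' fraction — a stand-in reference so tests and examples need no genome
#' download. Deterministic per seed.
#'
#' @param length sequence length in bp.
#' @param gcFraction expected fraction of G/C bases. Default 0.41
#'   (human-like).
#' @param seed integer seed.
#' @param path optional FASTA path to write; when `NULL` the sequence is
#'   returned as a named character scalar.
#' @param name contig name. Default `"fixture"`.
#' @return the sequence (invisibly when written to `path`)
#' @examples
#' ref <- makeFixtureReference(1000, seed = 7)
#' nchar(ref)
#' @export
makeFixtureReference <- function(length, gcFraction = 0.41, seed = 1L,
                                 path = NULL, name = "fixture") {
  stopifnot(length >= 1, gcFraction >= 0, gcFraction <= 1)
  p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
         G = gcFraction / 2, T = (1 - gcFraction) / 2)
  seqstr <- withSeed(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  out <- stats::setNames(seqstr, name)
  if (!is.null(path)) {
    set <- Biostrings::DNAStringSet(seqstr)
    names(set) <- name
    Biostrings::writeXStringSet(set, path, width = 70L)
    return(invisible(out))
  }
  out
}

#' Apply an edit list to a reference string
#'
#' Materializes one haplotype: substitutes `alt` at each 0-based `pos` of the
#' edit list. SNVs only, so the output length equals the input length.
#'
#' @param reference character scalar.
#' @param edits data.frame with columns `pos` (0-based) and `alt`.
#' @return character scalar of the same length
#' @export
materializeHaplotype <- function(reference, edits) {
  if (!nrow(edits)) return(unname(reference))
  chars <- strsplit(unname(reference), "", fixed = TRUE)[[1]]
  stopifnot(max(edits$pos) < length(chars))
  chars[edits$pos + 1L] <- edits$alt
  paste(chars, collapse = "")
}
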