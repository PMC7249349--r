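# Truth output. The VCF writer is deliberately minimal: it only ever emits
# biallelic SNV rows the simulator itself produced (never parses), with
# 1-based POS at the VCF boundary and 0-based positions everywhere else.

vcfHeader <- function(contig, contigLength, sampleNames, cell = FALSE) {
  h <- c(
    "##fileformat=VCFv4.2",
    "##source=scbulksim",
    sprintf("##contig=<ID=%s,length=%d>", contig, as.integer(contigLength)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (cell) {
    h <- c(h,
      '##INFO=<ID=WGAFP,Number=0,Type=Flag,Description="False-positive variant introduced by whole-genome amplification">',
      '##FORMAT=<ID=ADO,Number=1,Type=Integer,Description="1 if the genotype was altered by allelic dropout">'
    )
  }
  c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
               "FORMAT", sampleNames), collapse = "\t"))
}

gtString <- function(zyg) c("0/0", "0/1", "1/1")[zyg + 1L]

#' Write the simulator's truth as a VCF 4.2 file
#'
#' Two flavors share one writer. Without `cell`, the prototype truth is
#' written: one row per SNV position present in at least one prototype, one
#' genotype column per prototype. With a [CellGenome-class], the per-cell
#' truth is written: the cell's post-WGA genotypes, allelic-dropout-altered
#' sites flagged `FORMAT/ADO=1` and WGA false-positive rows flagged
#' `INFO/WGAFP`.
#'
#' Internal positions are 0-based; POS is emitted 1-based, offset by
#' `regionStart`. Rows must be in increasing position order (they are, by
#' construction, for all simulator output).
#'
#' @param sites SNV site table from [assignSubstitutions()].
#' @param path output path.
#' @param cell optional [CellGenome-class]; switches to per-cell truth.
#' @param contig contig name for CHROM. Default `"region"`.
#' @param regionStart 0-based offset added to positions before the 1-based
#'   conversion.
#' @param regionLength contig length recorded in the header.
#' @return `path`, invisibly
#' @export
writeTruthVcf <- function(sites, path, cell = NULL, contig = "region",
                          regionStart = 0L, regionLength = max(sites$position, 0L) + 1L) {
  if (is.null(cell)) {
    K <- ncol(sites$zygosity)
    keep <- which(rowSums(sites$zygosity) > 0L)
    pos0 <- sites$position[keep]
    if (is.unsorted(pos0, strictly = TRUE)) {
      stop("internal error: truth VCF rows must be emitted in strictly increasing position order")
    }
    lines <- vcfHeader(contig, regionLength, paste0("proto", seq_len(K)))
    if (length(keep)) {
      gt <- apply(sites$zygosity[keep, , drop = FALSE], 1, function(z) {
        paste(gtString(z), collapse = "\t")
      })
      lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                                contig, regionStart + pos0 + 1L,
                                sites$ref[keep], sites$alt[keep], gt))
    }
  } else {
    stopifnot(methods::is(cell, "CellGenome"))
    k <- cell@sourcePrototype
    inProto <- which(sites$zygosity[, k] > 0L)
    pos0 <- sites$position[inProto]
    adoPos <- cell@adoEvents$pos
    edited <- sort(unique(c(cell@hapA$pos, cell@hapB$pos)))
    rows <- data.frame(
      pos = pos0, ref = sites$ref[inProto], alt = sites$alt[inProto],
      wgafp = FALSE, ado = sites$position[inProto] %in% adoPos,
      stringsAsFactors = FALSE
    )
    # post-ADO genotype: count haplotypes carrying the alt
    zyg <- (rows$pos %in% cell@hapA$pos) + (rows$pos %in% cell@hapB$pos)
    rows$gt <- gtString(zyg)
    if (nrow(cell@fpEvents)) {
      fp <- data.frame(
        pos = cell@fpEvents$pos, ref = cell@fpEvents$ref, alt = cell@fpEvents$alt,
        wgafp = TRUE, ado = FALSE, gt = "0/1", stringsAsFactors = FALSE
      )
      rows <- rbind(rows, fp)
    }
    rows <- rows[order(rows$pos), , drop = FALSE]
    if (is.unsorted(rows$pos, strictly = TRUE)) {
      stop("internal error: truth VCF rows must be emitted in strictly increasing position order")
    }
    lines <- vcfHeader(contig, regionLength, sprintf("cell_proto%d", k), cell = TRUE)
    if (nrow(rows)) {
      lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:ADO\t%s:%d",
                                contig, regionStart + rows$pos + 1L,
                                rows$ref, rows$alt,
                                ifelse(rows$wgafp, "WGAFP", "."),
                                rows$gt, as.integer(rows$ado)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a truth VCF back into position/allele/genotype form
#'
#' Companion to [writeTruthVcf()], used to verify round trips and to feed
#' [scoreCalls()] with truth sets. Positions are returned 0-based after
#' removing `regionStart`.
#'
#' @param path a VCF written by [writeTruthVcf()] (any VCF with GT works).
#' @param regionStart offset subtracted from POS-1.
#' @return data.frame with columns `position` (0-based), `ref`, `alt`,
#'   `wgafp` (logical) plus a `zygosity` matrix column (0/1/2 per sample
#'   column) and an `ado` logical matrix column when present
#' @export
readTruthVcf <- function(path, regionStart = 0L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0L) {
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), wgafp = logical(0)))
  }
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  zyg <- matrix(match(gtRaw, c("0/0", "0/1", "1/1")) - 1L, nrow = n,
                dimnames = dimnames(gtRaw))
  info <- if ("INFO" %in% names(fix)) fix$INFO else rep(".", n)
  out <- data.frame(
    position = as.integer(fix$POS) - 1L - as.integer(regionStart),
    ref = fix$REF, alt = fix$ALT,
    wgafp = grepl("WGAFP", info),
    stringsAsFactors = FALSE
  )
  out$zygosity <- zyg
  fmt <- v@gt
  if (!is.null(fmt) && any(grepl("ADO", fmt[, 1]))) {
    adoRaw <- vcfR::extract.gt(v, element = "ADO")
    out$ado <- matrix(adoRaw == "1", nrow = n)
  }
  out
}

#' Write the flat TSV truth table
#'
#' A column-per-prototype table (position, tier, ref, alt, zygosity as
#' absent/het/hom) that is trivially machine-readable; the exact complement
#' of the truth VCF.
#'
#' @param sites SNV site table from [assignSubstitutions()].
#' @param path output path.
#' @return `path`, invisibly
#' @export
writeTruthTsv <- function(sites, path) {
  K <- ncol(sites$zygosity)
  zygChr <- matrix(c("absent", "het", "hom")[sites$zygosity + 1L],
                   ncol = K, dimnames = list(NULL, paste0("proto", seq_len(K))))
  flat <- cbind(
    data.frame(position = sites$position, tier = sites$tier,
               ref = sites$ref, alt = sites$alt, stringsAsFactors = FALSE),
    as.data.frame(zygChr, stringsAsFactors = FALSE)
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the flat TSV truth table back into site-table form
#' @param path a TSV written by [writeTruthTsv()]
#' @return an SNV site table (see [assignSubstitutions()])
#' @export
readTruthTsv <- function(path) {
  flat <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  protoCols <- grep("^proto", names(flat), value = TRUE)
  zyg <- matrix(match(as.matrix(flat[protoCols]), c("absent", "het", "hom")) - 1L,
                ncol = length(protoCols))
  sites <- data.frame(position = flat$position, tier = flat$tier,
                      ref = flat$ref, alt = flat$alt, stringsAsFactors = FALSE)
  sites$zygosity <- zyg
  sites$presence <- zyg > 0L
  sites
}
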