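#' Write and re-read simulation truth tables
#'
#' Writes the insertion, event, derivative-cassette and per-cell truth
#' tables of a simulation as TSV files with documented headers, plus the
#' insertion table as a BED6 file (0-based half-open, name `bc1|bc2`,
#' strand `+` for top-CS2 and `-` for bottom-CS1). `readTruth()` restores
#' the tables with their column types, so the pair round-trips losslessly.
#'
#' @param sim a [ShuffleSim-class].
#' @param outDir output directory (created if missing).
#' @return `writeTruth()` the directory invisibly; `readTruth()` a named
#'   list of data.frames.
#' @export
writeTruth <- function(sim, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  writeTsv(sim@insertions, file.path(outDir, "insertions.tsv"))
  writeTsv(sim@events, file.path(outDir, "events.tsv"))
  writeTsv(sim@derivatives, file.path(outDir, "derivatives.tsv"))
  writeTsv(sim@cells, file.path(outDir, "cells.tsv"))
  if (nrow(sim@insertions))
    writeInsertionsBed(sim@insertions, file.path(outDir, "insertions.bed"))
  invisible(outDir)
}

#' @rdname writeTruth
#' @param dir directory written by `writeTruth()`.
#' @export
readTruth <- function(dir) {
  der <- readTsv(file.path(dir, "derivatives.tsv"))
  ## all-NA barcode columns (no detectable product) must stay character
  for (cn in c("bc1", "bc2"))
    if (cn %in% names(der) && is.logical(der[[cn]]))
      der[[cn]] <- as.character(der[[cn]])
  list(insertions = readTsv(file.path(dir, "insertions.tsv")),
       events = readTsv(file.path(dir, "events.tsv")),
       derivatives = der,
       cells = readTsv(file.path(dir, "cells.tsv")))
}

#' TSV readers and writers with stable types
#'
#' Plain tab-separated writers used for all tabular outputs: header
#' always present (also for empty tables), no quoting, no row names.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `writeTsv()` the path invisibly; `readTsv()` a data.frame.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = NA, na.strings = "NA",
                      check.names = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        data.frame()
      else stop(e)
    })
}

#' Export insertions as BED6
#'
#' Converts the 1-based insertion positions to 0-based half-open
#' intervals covering the TTAA target site, names each feature by its
#' barcode pair and encodes the cassette orientation in the strand column
#' (`+` = top-CS2, `-` = bottom-CS1).
#'
#' @param insertionTable insertion table.
#' @param path output `.bed` path.
#' @export
writeInsertionsBed <- function(insertionTable, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = insertionTable$chrom,
    ranges = IRanges::IRanges(start = insertionTable$pos,
                              width = 4L),
    strand = ifelse(insertionTable$orientation == "top-CS2", "+", "-"),
    name = pairKey(insertionTable$bc1, insertionTable$bc2),
    score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export rearrangement calls as BEDPE
#'
#' One anchor interval per parental insertion (0-based half-open TTAA
#' footprints). BEDPE has no writer among the genomic-range packages used
#' here, so the ten canonical columns are written directly.
#'
#' @param calls Rearrangement table.
#' @param path output `.bedpe` path.
#' @export
writeCallsBedpe <- function(calls, path) {
  df <- data.frame(
    chrom1 = calls$chrom_a, start1 = calls$pos_a - 1L,
    end1 = calls$pos_a + 3L,
    chrom2 = calls$chrom_b, start2 = calls$pos_b - 1L,
    end2 = calls$pos_b + 3L,
    name = paste(pairKey(calls$bc1, calls$bc2), calls$class, sep = ";"),
    score = if ("umi_count" %in% names(calls)) calls$umi_count else 0L,
    strand1 = ifelse(calls$orientation_a == "top-CS2", "+", "-"),
    strand2 = ifelse(calls$orientation_b == "top-CS2", "+", "-"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a sparse barcode-by-cell matrix as MTX plus dimension files
#'
#' @param mat dgCMatrix from [buildBcCellMatrix()].
#' @param outDir output directory; writes `matrix.mtx`, `pairs.tsv`,
#'   `cells.tsv`.
#' @return the directory, invisibly.
#' @export
writeBcCellMatrix <- function(mat, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  Matrix::writeMM(mat, file.path(outDir, "matrix.mtx"))
  writeTsv(data.frame(pair = rownames(mat)), file.path(outDir, "pairs.tsv"))
  writeTsv(data.frame(cell_bc = colnames(mat)),
           file.path(outDir, "cells.tsv"))
  invisible(outDir)
}

#' @rdname writeBcCellMatrix
#' @param dir directory written by `writeBcCellMatrix()`.
#' @export
readBcCellMatrix <- function(dir) {
  mat <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                     "CsparseMatrix")
  dimnames(mat) <- list(readTsv(file.path(dir, "pairs.tsv"))$pair,
                        readTsv(file.path(dir, "cells.tsv"))$cell_bc)
  mat
}

#' FASTQ writers and readers for simulated reads
#'
#' Read pairs are written as two gzipped FASTQ files with matching
#' identifiers and constant quality; `readFastqReads()` restores a
#' read table from them.
#'
#' @param reads data.frame with read_id (optional), read1 and read2.
#' @param prefix output prefix; writes `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz`.
#' @return `writeFastqReads()` the two paths; `readFastqReads()` a
#'   data.frame with read_id/read1/read2.
#' @export
writeFastqReads <- function(reads, prefix) {
  ids <- if ("read_id" %in% names(reads)) reads$read_id
  else sprintf("read%07d", seq_len(nrow(reads)))
  paths <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  for (k in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("read", k)]])
    names(seqs) <- ids
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads[[paste0("read", k)]])))
    x <- Biostrings::QualityScaledDNAStringSet(
      seqs, Biostrings::PhredQuality(qual))
    Biostrings::writeQualityScaledXStringSet(x, paths[k], compress = TRUE)
  }
  invisible(paths)
}

#' @rdname writeFastqReads
#' @export
readFastqReads <- function(prefix) {
  paths <- paste0(prefix, c("_R1.fastq.gz", "_R2.fastq.gz"))
  r1 <- Biostrings::readDNAStringSet(paths[1L], format = "fastq")
  r2 <- Biostrings::readDNAStringSet(paths[2L], format = "fastq")
  if (length(r1) != length(r2) || !identical(names(r1), names(r2)))
    stop("paired FASTQ files disagree on read identifiers")
  data.frame(read_id = names(r1), read1 = as.character(r1),
             read2 = as.character(r2), stringsAsFactors = FALSE)
}
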