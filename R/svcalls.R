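#' Count amplicon reads per barcode pair
#'
#' Tallies reads and distinct UMIs per (bc1, bc2) pair — and per amplicon
#' type for the 4-primer dialect. Malformed records (missing barcode or
#' UMI) are skipped and tallied.
#'
#' @param reads read table from [emitAmpliconReads()] or an equivalently
#'   formatted extraction (columns bc1, bc2, umi, optionally
#'   amplicon_type, sample_id, replicate_id).
#' @param dialect `"two_primer"` or `"four_primer"`.
#' @return PairCount data.frame with read_count and umi_count; attribute
#'   `skipped` counts malformed records.
#' @export
countAmpliconPairs <- function(reads, dialect = c("two_primer",
                                                  "four_primer")) {
  dialect <- match.arg(dialect)
  need <- c("bc1", "bc2", "umi")
  if (nrow(reads) == 0L) {
    out <- emptyPairCounts(dialect)
    attr(out, "skipped") <- 0L
    return(out)
  }
  bad <- !stats::complete.cases(reads[, need]) |
    reads$bc1 == "" | reads$bc2 == "" | reads$umi == ""
  reads <- reads[!bad, , drop = FALSE]
  dt <- data.table::as.data.table(reads)
  if (!"sample_id" %in% names(dt)) dt$sample_id <- "sample1"
  if (!"replicate_id" %in% names(dt)) dt$replicate_id <- "rep1"
  by <- c("sample_id", "replicate_id", "bc1", "bc2")
  if (dialect == "four_primer") by <- c(by, "amplicon_type")
  out <- dt[, .(read_count = .N, umi_count = data.table::uniqueN(umi)),
            by = by]
  out <- as.data.frame(out)
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(bad)
  out
}

emptyPairCounts <- function(dialect = "two_primer") {
  out <- data.frame(sample_id = character(0), replicate_id = character(0),
                    bc1 = character(0), bc2 = character(0),
                    stringsAsFactors = FALSE)
  if (dialect == "four_primer") out$amplicon_type <- character(0)
  out$read_count <- integer(0)
  out$umi_count <- integer(0)
  out
}

#' Collapse 4-primer amplicon counts to one row per cassette
#'
#' The 4-primer dialect yields two amplicon types per cassette; reads from
#' the same cassette are collapsed on the shared barcode pair, summing
#' read and UMI counts. Pairs detected under only one amplicon type are
#' discarded. Input without an amplicon_type column passes through
#' unchanged.
#'
#' @param counts PairCount table from [countAmpliconPairs()].
#' @return collapsed PairCount table.
#' @export
collapseFourPrimer <- function(counts) {
  if (!"amplicon_type" %in% names(counts)) return(counts)
  dt <- data.table::as.data.table(counts)
  out <- dt[, .(read_count = sum(read_count), umi_count = sum(umi_count),
                n_types = data.table::uniqueN(amplicon_type)),
            by = .(sample_id, replicate_id, bc1, bc2)]
  out <- out[out$n_types >= 2L, ]
  out$n_types <- NULL
  out <- as.data.frame(out)
  out <- out[order(out$sample_id, out$replicate_id, out$bc1, out$bc2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Depth-normalise pair counts
#'
#' Adds `normalized_read_count` and `normalized_umi_count`: counts scaled
#' to `scale` total per (sample, replicate) library (counts per million by
#' default).
#'
#' @param counts PairCount table.
#' @param scale library-size target (default 1e6).
#' @return counts with normalised columns.
#' @export
normalizeCounts <- function(counts, scale = 1e6) {
  if (nrow(counts) == 0L) {
    counts$normalized_read_count <- numeric(0)
    counts$normalized_umi_count <- numeric(0)
    return(counts)
  }
  lib <- paste(counts$sample_id, counts$replicate_id)
  totR <- tapply(counts$read_count, lib, sum)[lib]
  totU <- tapply(counts$umi_count, lib, sum)[lib]
  counts$normalized_read_count <- counts$read_count / totR * scale
  counts$normalized_umi_count <- counts$umi_count / totU * scale
  counts
}

#' Average parental replicates on a depth-comparable scale
#'
#' Normalised read and UMI counts are averaged over replicates per pair
#' and scaled back to the mean library depth, yielding the support values
#' the bonafide insertion filter compares against its read/UMI thresholds.
#'
#' @param counts normalised PairCount table across parental replicates.
#' @param scale the scale used in [normalizeCounts()].
#' @return data.frame with bc1, bc2, reads, umis.
#' @export
averageParentalCounts <- function(counts, scale = 1e6) {
  counts <- normalizeCountsIfNeeded(counts, scale)
  lib <- paste(counts$sample_id, counts$replicate_id)
  nrep <- length(unique(lib))
  meanDepthR <- mean(tapply(counts$read_count, lib, sum))
  meanDepthU <- mean(tapply(counts$umi_count, lib, sum))
  dt <- data.table::as.data.table(counts)
  out <- dt[, .(reads = sum(normalized_read_count) / nrep / scale,
                umis = sum(normalized_umi_count) / nrep / scale),
            by = .(bc1, bc2)]
  out$reads <- out$reads * meanDepthR
  out$umis <- out$umis * meanDepthU
  out <- as.data.frame(out)
  out[order(out$bc1, out$bc2), , drop = FALSE]
}

normalizeCountsIfNeeded <- function(counts, scale) {
  if (!"normalized_read_count" %in% names(counts))
    counts <- normalizeCounts(counts, scale)
  counts
}

#' Barcode-pair set of a single sorted clone well
#'
#' Wells with fewer than `minWellReads` total reads are rejected. Within a
#' well, the clone's own pairs are taken as those whose read counts exceed
#' one population standard deviation above the mean read count of pairs
#' detected in that well (z-score > 1 with ddof = 0).
#'
#' @param wellCounts PairCount table for one well.
#' @param minWellReads minimum total reads per well (default 1e5).
#' @return data.frame of retained bc1/bc2 pairs (zero rows if the well is
#'   rejected or nothing exceeds the cutoff); attribute `wellRejected`
#'   says whether the well failed the depth check.
#' @export
deriveWellBarcodeSet <- function(wellCounts, minWellReads = 1e5) {
  out <- wellCounts[0L, c("bc1", "bc2"), drop = FALSE]
  if (sum(wellCounts$read_count) < minWellReads) {
    attr(out, "wellRejected") <- TRUE
    return(out)
  }
  x <- wellCounts$read_count
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  keep <- x > mu + sdev
  out <- wellCounts[keep, c("bc1", "bc2"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "wellRejected") <- FALSE
  out
}

#' Call rearrangements from novel barcode pairs
#'
#' A pair is called a rearrangement iff both barcodes are found in the
#' bonafide insertion list (bc1 among insertion first barcodes, bc2 among
#' second barcodes), the pair itself is not a parental combination, and it
#' is supported by at least `minUmi` UMIs. Calls are linked to their two
#' parental insertions and classified; barcodes matching more than one
#' insertion are reported as ambiguous, not called.
#'
#' @param counts PairCount table for the sample.
#' @param bonafide bonafide insertion table (chrom, pos, orientation,
#'   allele, bc1, bc2).
#' @param minUmi minimum UMI support (default 2, i.e. "more than 1 UMI").
#' @param parentalPairs optional character vector of parental pair keys
#'   (`bc1|bc2`); defaults to the bonafide pairs.
#' @return Rearrangement data.frame; ambiguous pairs are attached as
#'   attribute `ambiguous`.
#' @export
callRearrangements <- function(counts, bonafide, minUmi = 2L,
                               parentalPairs = NULL) {
  if (is.null(parentalPairs))
    parentalPairs <- pairKey(bonafide$bc1, bonafide$bc2)
  key <- pairKey(counts$bc1, counts$bc2)
  novel <- counts[!(key %in% parentalPairs) & counts$umi_count >= minUmi, ,
                  drop = FALSE]
  i <- match(novel$bc1, bonafide$bc1)
  j <- match(novel$bc2, bonafide$bc2)
  amb1 <- novel$bc1 %in% bonafide$bc1[duplicated(bonafide$bc1)]
  amb2 <- novel$bc2 %in% bonafide$bc2[duplicated(bonafide$bc2)]
  ambiguous <- novel[amb1 | amb2, , drop = FALSE]
  ok <- !is.na(i) & !is.na(j) & !amb1 & !amb2
  novel <- novel[ok, , drop = FALSE]
  i <- i[ok]; j <- j[ok]
  calls <- classifySv(novel, bonafide[i, , drop = FALSE],
                      bonafide[j, , drop = FALSE])
  attr(calls, "ambiguous") <- ambiguous
  calls
}

#' Classify rearrangements from parental insertion geometry
#'
#' Same chromosome and same cassette orientation is a deletion; same
#' chromosome and opposite orientation an inversion; different chromosomes
#' a translocation. Rearrangement size is the distance between the two
#' parental insertion positions (cis classes only). Deletion calls are
#' further assigned a genomic-scar or ecDNA topology with
#' [classifyDeletionTopology()], and cis calls joining insertions assigned
#' to different haplotypes are flagged as possible inter-homolog events.
#'
#' @param novel PairCount rows of the novel pairs (may be zero rows).
#' @param insA,insB parental insertion rows matched to bc1 and bc2.
#' @return Rearrangement data.frame.
#' @export
classifySv <- function(novel, insA, insB) {
  n <- nrow(novel)
  sameChrom <- insA$chrom == insB$chrom
  sameOrient <- insA$orientation == insB$orientation
  class <- ifelse(!sameChrom, "translocation",
                  ifelse(sameOrient, "deletion", "inversion"))
  size <- ifelse(sameChrom, abs(insA$pos - insB$pos), NA_integer_)
  topology <- rep("n/a", n)
  isDel <- which(class == "deletion")
  if (length(isDel))
    topology[isDel] <- classifyDeletionTopology(
      insA[isDel, , drop = FALSE], insB[isDel, , drop = FALSE])
  out <- data.frame(
    bc1 = novel$bc1, bc2 = novel$bc2,
    class = class, size = size, topology = topology,
    chrom_a = insA$chrom, pos_a = insA$pos,
    orientation_a = insA$orientation, allele_a = insA$allele,
    insertion_a = insA$insertion_id,
    chrom_b = insB$chrom, pos_b = insB$pos,
    orientation_b = insB$orientation, allele_b = insB$allele,
    insertion_b = insB$insertion_id,
    allele_mismatch = sameChrom & insA$allele != insB$allele &
      insA$allele %in% c("BL6", "CAST") & insB$allele %in% c("BL6", "CAST"),
    stringsAsFactors = FALSE)
  if ("read_count" %in% names(novel)) out$read_count <- novel$read_count
  if ("umi_count" %in% names(novel)) out$umi_count <- novel$umi_count
  if ("sample_id" %in% names(novel)) out$sample_id <- novel$sample_id
  if ("replicate_id" %in% names(novel)) out$replicate_id <- novel$replicate_id
  rownames(out) <- NULL
  out
}

#' Assign deletion topology (genomic scar vs ecDNA)
#'
#' For a deletion between insertions X (left) and Y (right) in top-CS2
#' orientation, the genomic scar carries X's CS2 barcode with Y's CS1
#' barcode, and the excised circle carries Y's CS2 barcode with X's CS1
#' barcode; for bottom-CS1 pairs the assignment is mirrored. The inputs
#' are the insertions contributing bc1 (CS2 side) and bc2 (CS1 side) of
#' the novel pair.
#'
#' @param insA insertion rows contributing the CS2-side barcode.
#' @param insB insertion rows contributing the CS1-side barcode.
#' @return character vector, `"genomic_scar"` or `"ecDNA"`.
#' @export
classifyDeletionTopology <- function(insA, insB) {
  aIsLeft <- insA$pos < insB$pos
  top <- insA$orientation == "top-CS2"
  ifelse(top,
         ifelse(aIsLeft, "genomic_scar", "ecDNA"),
         ifelse(aIsLeft, "ecDNA", "genomic_scar"))
}

#' Intersect rearrangement calls between technical replicates
#'
#' Marks every call with whether its pair was observed in both replicates
#' of the sample and merges support columns.
#'
#' @param callsRep1,callsRep2 Rearrangement tables for the two replicates.
#' @return union table with a `replicated` flag.
#' @export
intersectReplicates <- function(callsRep1, callsRep2) {
  k1 <- pairKey(callsRep1$bc1, callsRep1$bc2)
  k2 <- pairKey(callsRep2$bc1, callsRep2$bc2)
  callsRep1$.rep <- rep("rep1", nrow(callsRep1))
  callsRep2$.rep <- rep("rep2", nrow(callsRep2))
  both <- rbind(callsRep1, callsRep2)
  key <- pairKey(both$bc1, both$bc2)
  out <- both[!duplicated(key), , drop = FALSE]
  out$replicated <- pairKey(out$bc1, out$bc2) %in% intersect(k1, k2)
  out$.rep <- NULL
  rownames(out) <- NULL
  out
}

#' Cross-condition sharing of replicated calls
#'
#' Fraction of pairs replicated within a condition that are also observed
#' in at least one other condition.
#'
#' @param callsByCondition named list of call tables carrying a
#'   `replicated` column.
#' @return named numeric vector of sharing fractions.
#' @export
crossConditionSharing <- function(callsByCondition) {
  keys <- lapply(callsByCondition, function(x)
    unique(pairKey(x$bc1, x$bc2)))
  repKeys <- lapply(callsByCondition, function(x)
    unique(pairKey(x$bc1[x$replicated], x$bc2[x$replicated])))
  vapply(seq_along(callsByCondition), function(i) {
    others <- unique(unlist(keys[-i]))
    if (length(repKeys[[i]]) == 0L) return(NA_real_)
    mean(repKeys[[i]] %in% others)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(names(callsByCondition))
}

#' Validate rearrangement calls against post-Cre IVT data
#'
#' A call is supported iff at least one alignment cluster in the post-Cre
#' IVT data carries the novel barcode pair while the parental IVT data
#' does not. Cluster barcode pairs are canonicalised through the cassette
#' strand (bottom-strand clusters are reverse complemented and swapped).
#' In `mode = "flank"` the supporting cluster must additionally sit at a
#' junction coordinate of one of the two parental insertions.
#'
#' @param calls Rearrangement table.
#' @param postClusters clusters from post-Cre IVT observations.
#' @param parentalClusters clusters from parental IVT observations.
#' @param mode `"barcode"` (default) or `"flank"`.
#' @return calls with an `ivt_supported` column; per-class supported
#'   fractions attached as attribute `supportSummary`.
#' @export
validateWithIvt <- function(calls, postClusters, parentalClusters = NULL,
                            mode = c("barcode", "flank")) {
  mode <- match.arg(mode)
  canonical <- function(cl) {
    if (nrow(cl) == 0L) return(character(0))
    top <- cl$cassette_strand == "top-CS2"
    pairKey(ifelse(top, cl$barcode1, revComp(cl$barcode2)),
            ifelse(top, cl$barcode2, revComp(cl$barcode1)))
  }
  postKeys <- canonical(postClusters)
  parentalKeys <- if (is.null(parentalClusters)) character(0)
  else canonical(parentalClusters)
  key <- pairKey(calls$bc1, calls$bc2)
  supported <- key %in% setdiff(postKeys, parentalKeys)
  if (mode == "flank" && any(supported)) {
    for (i in which(supported)) {
      hits <- which(postKeys == key[i])
      anchors <- c(calls$pos_a[i] - 1L, calls$pos_a[i] + 3L,
                   calls$pos_b[i] - 1L, calls$pos_b[i] + 3L)
      chroms <- c(calls$chrom_a[i], calls$chrom_a[i],
                  calls$chrom_b[i], calls$chrom_b[i])
      okFlank <- any(postClusters$position[hits] %in% anchors &
                       postClusters$chrom[hits] %in% chroms)
      supported[i] <- okFlank
    }
  }
  calls$ivt_supported <- supported
  summary <- if (nrow(calls))
    tapply(calls$ivt_supported, calls$class, mean) else numeric(0)
  attr(calls, "supportSummary") <- summary
  calls
}
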