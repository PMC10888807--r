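#' Filter IVT alignments before clustering
#'
#' Drops observations that do not align to a TTAA transposon target site,
#' that map to more than one genomic location, or whose allele call is
#' inconclusive (mixed variant evidence).
#'
#' @param obs observation table from [placeIvtReads()] or an equivalent
#'   TSV.
#' @return the kept observations, with a `dropReasons` attribute tallying
#'   removals.
#' @export
filterAlignments <- function(obs) {
  reason <- rep(NA_character_, nrow(obs))
  reason[!obs$junction_is_ttaa] <- "junction_not_ttaa"
  reason[is.na(reason) & obs$multimapped] <- "multimapped"
  reason[is.na(reason) & obs$allele_call == "inconclusive"] <-
    "inconclusive_allele"
  kept <- obs[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "dropReasons") <- table(reason[!is.na(reason)])
  kept
}

#' Position rule for IVT alignments
#'
#' Collapses an alignment to the junction-pinned coordinate: the 0-based
#' exclusive end for plus-strand alignments (numerically the 1-based
#' inclusive end) and the 0-based start for minus-strand alignments. Under
#' this rule the two clusters flanking one integration sit exactly 4 bp
#' apart, the minus-strand cluster first.
#'
#' @param alignStart,alignEnd 1-based inclusive alignment span.
#' @param genomeStrand `"+"` or `"-"`.
#' @return integer vector of cluster positions.
#' @export
alignmentPosition <- function(alignStart, alignEnd, genomeStrand) {
  ifelse(genomeStrand == "+", alignEnd, alignStart - 1L)
}

#' Cluster IVT observations by position and barcode similarity
#'
#' Observations are grouped by chromosome and position-rule coordinate;
#' within a group, observations whose joint barcode Levenshtein distance
#' (sum over the two barcodes) is at most `levBudget` are merged by single
#' linkage. Each cluster reports the modal barcode pair, genome strand and
#' cassette strand (ties broken lexicographically), the majority allele
#' ignoring `noVariant` members, and support counts including the number
#' of distinct aligned lengths.
#'
#' @param obs filtered observation table.
#' @param levBudget joint Levenshtein budget (default 6).
#' @return data.frame of clusters, canonically ordered.
#' @export
clusterObservations <- function(obs, levBudget = 6L) {
  if (nrow(obs) == 0L) return(emptyClusters())
  pos <- alignmentPosition(obs$align_start, obs$align_end, obs$genome_strand)
  key <- paste(obs$chrom, pos, sep = ":")
  groups <- split(seq_len(nrow(obs)), key)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    d <- jointLevenshtein(obs$barcode1[idx], obs$barcode2[idx])
    comp <- componentsUnderThreshold(d, levBudget)
    rows <- lapply(split(idx, comp), function(members) {
      lens <- obs$align_end[members] - obs$align_start[members] + 1L
      allele <- obs$allele_call[members]
      allele <- allele[allele != "noVariant"]
      data.frame(
        chrom = obs$chrom[members[1L]],
        position = pos[members[1L]],
        barcode1 = modalValue(obs$barcode1[members]),
        barcode2 = modalValue(obs$barcode2[members]),
        genome_strand = modalValue(obs$genome_strand[members]),
        cassette_strand = modalValue(obs$cassette_strand[members]),
        allele = if (length(allele)) modalValue(allele) else "noVariant",
        read_count = length(members),
        umi1_count = length(unique(obs$umi1[members])),
        umi2_count = length(unique(obs$umi2[members])),
        n_unique_lengths = length(unique(lens)),
        stringsAsFactors = FALSE)
    })
    out[[g]] <- do.call(rbind, rows)
  }
  cl <- do.call(rbind, out)
  cl <- cl[order(cl$chrom, cl$position, cl$barcode1, cl$barcode2), ,
           drop = FALSE]
  rownames(cl) <- NULL
  cl
}

emptyClusters <- function() {
  data.frame(chrom = character(0), position = integer(0),
             barcode1 = character(0), barcode2 = character(0),
             genome_strand = character(0), cassette_strand = character(0),
             allele = character(0), read_count = integer(0),
             umi1_count = integer(0), umi2_count = integer(0),
             n_unique_lengths = integer(0), stringsAsFactors = FALSE)
}

#' Merge alignment clusters across replicates
#'
#' Inner join on chromosome, position, barcodes, genome strand and
#' cassette strand; a cluster present in only one replicate is excluded.
#' Support counts are retained per replicate (suffixes `_rep1`, `_rep2`,
#' ...) and the allele is reconciled: `noVariant` defers to the other
#' replicate and disagreements become `inconclusive`.
#'
#' @param clusterList list of per-replicate cluster tables (length >= 1).
#' @return merged cluster table.
#' @export
mergeReplicates <- function(clusterList) {
  stopifnot(length(clusterList) >= 1L)
  keys <- c("chrom", "position", "barcode1", "barcode2", "genome_strand",
            "cassette_strand")
  countCols <- c("read_count", "umi1_count", "umi2_count",
                 "n_unique_lengths")
  merged <- clusterList[[1L]]
  names(merged)[match(countCols, names(merged))] <-
    paste0(countCols, "_rep1")
  names(merged)[match("allele", names(merged))] <- "allele_rep1"
  if (length(clusterList) > 1L) {
    for (r in 2L:length(clusterList)) {
      nxt <- clusterList[[r]]
      names(nxt)[match(countCols, names(nxt))] <-
        paste0(countCols, "_rep", r)
      names(nxt)[match("allele", names(nxt))] <- paste0("allele_rep", r)
      merged <- merge(merged, nxt, by = keys)
    }
  }
  alleleCols <- grep("^allele_rep", names(merged), value = TRUE)
  merged$allele <- Reduce(function(a, b) reconcileAllele(a, b),
                          lapply(alleleCols, function(cn) merged[[cn]]))
  merged <- merged[order(merged$chrom, merged$position, merged$barcode1), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

reconcileAllele <- function(a, b) {
  ifelse(a == "noVariant", b,
         ifelse(b == "noVariant", a,
                ifelse(a == b, a, "inconclusive")))
}

#' Pair flanking clusters into candidate insertions
#'
#' Two clusters on the same chromosome form a candidate cassette
#' integration iff their positions differ by exactly `pairOffset` (4 bp,
#' the piggyBac TTAA target-site duplication), the first (lower-position)
#' cluster maps to the minus strand and the second to the plus strand,
#' they report different cassette strands, and their barcodes are mutual
#' reverse complements. The insertion position is the minus-strand
#' cluster's position converted to the 1-based first base of the TTAA;
#' orientation is the minus-side cassette strand; canonical barcodes are
#' taken from the top-CS2 member.
#'
#' @param clusters (merged) cluster table.
#' @param pairOffset expected position offset (default 4).
#' @return list with `candidates` (one row per paired insertion) and
#'   `unpaired` (clusters in no pair).
#' @export
pairClusters <- function(clusters, pairOffset = 4L) {
  if (nrow(clusters) == 0L)
    return(list(candidates = emptyCandidates(), unpaired = clusters))
  cl <- clusters[order(clusters$chrom, clusters$position), , drop = FALSE]
  minus <- which(cl$genome_strand == "-")
  plus <- which(cl$genome_strand == "+")
  plusByKey <- split(plus, paste(cl$chrom[plus], cl$position[plus]))
  paired <- logical(nrow(cl))
  rows <- list()
  rcB1 <- revComp(cl$barcode1)
  rcB2 <- revComp(cl$barcode2)
  for (i in minus) {
    cand <- plusByKey[[paste(cl$chrom[i], cl$position[i] + pairOffset)]]
    if (is.null(cand)) next
    j <- cand[cl$cassette_strand[cand] != cl$cassette_strand[i] &
                cl$barcode1[cand] == rcB2[i] &
                cl$barcode2[cand] == rcB1[i]]
    if (length(j) == 0L) next
    for (jj in j) {
      paired[c(i, jj)] <- TRUE
      topSide <- if (cl$cassette_strand[i] == "top-CS2") i else jj
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cl$chrom[i],
        pos = cl$position[i] + 1L,
        orientation = cl$cassette_strand[i],
        bc1 = cl$barcode1[topSide],
        bc2 = cl$barcode2[topSide],
        allele = assignInsertionAllele(clusterAllele(cl, i),
                                       clusterAllele(cl, jj)),
        left_reads = clusterCount(cl, i, "read_count"),
        right_reads = clusterCount(cl, jj, "read_count"),
        left_unique_lengths = clusterCount(cl, i, "n_unique_lengths"),
        right_unique_lengths = clusterCount(cl, jj, "n_unique_lengths"),
        stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else emptyCandidates()
  rownames(candidates) <- NULL
  list(candidates = candidates,
       unpaired = cl[!paired, , drop = FALSE])
}

clusterAllele <- function(cl, i) {
  if ("allele" %in% names(cl)) cl$allele[i] else "noVariant"
}

## support count for a cluster row; prefers the last replicate's column
clusterCount <- function(cl, i, what) {
  cols <- grep(paste0("^", what), names(cl), value = TRUE)
  if (length(cols) == 0L) return(NA_integer_)
  cl[[cols[length(cols)]]][i]
}

emptyCandidates <- function() {
  data.frame(chrom = character(0), pos = integer(0),
             orientation = character(0), bc1 = character(0),
             bc2 = character(0), allele = character(0),
             left_reads = integer(0), right_reads = integer(0),
             left_unique_lengths = integer(0),
             right_unique_lengths = integer(0), stringsAsFactors = FALSE)
}

#' Reconcile the allele of the two clusters of an insertion
#'
#' One-sided evidence (`noVariant` on the other side) carries the call;
#' congruent calls keep it; disagreement between the two flanks is
#' `inconclusive`; two `noVariant` flanks yield `noVariant` (no call).
#'
#' @param alleleLeft,alleleRight allele values of the paired clusters.
#' @return character vector of insertion alleles.
#' @export
assignInsertionAllele <- function(alleleLeft, alleleRight) {
  reconcileAllele(alleleLeft, alleleRight)
}

#' Filter candidate insertions to the bonafide set
#'
#' Applies, in order: the cluster support filter (a candidate is removed
#' iff a flank has fewer than `minClusterReads` reads AND fewer than
#' `minUniqueLengths` distinct aligned lengths), the unique-location filter
#' (barcode pairs recovered at more than one genomic position are
#' removed), the amplicon support filter (the canonical pair must exceed
#' `parentalMinReads` reads and `parentalMinUmis` UMIs in parental
#' amplicon data), and multi-pair site resolution (one insertion per
#' position, keeping the candidate with the most distinct aligned lengths
#' on its left flank).
#'
#' @param candidates candidate table from [pairClusters()].
#' @param ampliconCounts data.frame with columns bc1, bc2, reads, umis
#'   (depth-scaled parental averages); `NULL` skips the amplicon filter.
#' @param minClusterReads,minUniqueLengths cluster support thresholds
#'   (defaults 6 and 3; removal requires failing both).
#' @param parentalMinReads,parentalMinUmis exclusive amplicon support
#'   thresholds (defaults 50 and 30).
#' @return bonafide insertion table with an insertion_id column; a
#'   per-stage removal tally is attached as attribute `filterLog`.
#' @export
filterBonafideInsertions <- function(candidates, ampliconCounts = NULL,
                                     minClusterReads = 6L,
                                     minUniqueLengths = 3L,
                                     parentalMinReads = 50,
                                     parentalMinUmis = 30) {
  log <- c(input = nrow(candidates))
  weak <- function(reads, lens)
    !is.na(reads) & reads < minClusterReads & lens < minUniqueLengths
  drop <- weak(candidates$left_reads, candidates$left_unique_lengths) |
    weak(candidates$right_reads, candidates$right_unique_lengths)
  candidates <- candidates[!drop, , drop = FALSE]
  log <- c(log, low_support = sum(drop))

  key <- pairKey(candidates$bc1, candidates$bc2)
  locus <- paste(candidates$chrom, candidates$pos)
  nLoci <- vapply(split(locus, key), function(x) length(unique(x)),
                  integer(1))
  multi <- key %in% names(nLoci)[nLoci > 1L]
  candidates <- candidates[!multi, , drop = FALSE]
  log <- c(log, multi_locus_barcodes = sum(multi))

  if (!is.null(ampliconCounts)) {
    m <- match(pairKey(candidates$bc1, candidates$bc2),
               pairKey(ampliconCounts$bc1, ampliconCounts$bc2))
    reads <- ampliconCounts$reads[m]
    umis <- ampliconCounts$umis[m]
    ok <- !is.na(reads) & reads > parentalMinReads & umis > parentalMinUmis
    log <- c(log, no_amplicon_support = sum(!ok))
    candidates <- candidates[ok, , drop = FALSE]
  }

  site <- paste(candidates$chrom, candidates$pos)
  keep <- unlist(lapply(split(seq_len(nrow(candidates)), site),
                        function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[order(-candidates$left_unique_lengths[idx],
              candidates$bc1[idx])][1L]
  }), use.names = FALSE)
  log <- c(log, multi_pair_site = nrow(candidates) - length(keep))
  out <- candidates[sort(keep), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  if (nrow(out)) out$insertion_id <- sprintf("mapped%05d", seq_len(nrow(out)))
  else out$insertion_id <- character(0)
  rownames(out) <- NULL
  log <- c(log, output = nrow(out))
  attr(out, "filterLog") <- log
  out
}

#' Map cassette insertions from IVT observations
#'
#' End-to-end mapper: per-replicate alignment filtering and clustering,
#' replicate merging, cluster pairing at the TTAA target-site duplication
#' offset, allele assignment, and the bonafide filters.
#'
#' @param obsList list of per-replicate observation tables (length >= 1).
#' @param ampliconCounts parental amplicon support (see
#'   [filterBonafideInsertions()]); `NULL` to skip.
#' @param config a [shuffleConfig()] list (thresholds used:
#'   levenshtein_budget, cluster_pair_offset, min_cluster_reads,
#'   min_unique_lengths, parental_min_reads, parental_min_umis).
#' @return list with `insertions` (bonafide table), `candidates`,
#'   `unpaired` clusters, `clusters` (merged) and `log`.
#' @export
mapInsertions <- function(obsList, ampliconCounts = NULL,
                          config = shuffleConfig()) {
  if (is.data.frame(obsList)) obsList <- list(obsList)
  clusters <- lapply(obsList, function(o)
    clusterObservations(filterAlignments(o),
                        levBudget = config$levenshtein_budget))
  merged <- mergeReplicates(clusters)
  pairing <- pairClusters(merged, pairOffset = config$cluster_pair_offset)
  bona <- filterBonafideInsertions(
    pairing$candidates, ampliconCounts,
    minClusterReads = config$min_cluster_reads,
    minUniqueLengths = config$min_unique_lengths,
    parentalMinReads = config$parental_min_reads,
    parentalMinUmis = config$parental_min_umis)
  list(insertions = bona, candidates = pairing$candidates,
       unpaired = pairing$unpaired, clusters = merged,
       log = attr(bona, "filterLog"))
}
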