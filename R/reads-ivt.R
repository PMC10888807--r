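## Flank geometry around an integration at 1-based TTAA start `pos`.
##
## piggyBac duplicates the TTAA target site, so both junction-flanking
## reads carry a TTAA copy that aligns to the single reference motif at
## [pos, pos+3]. A transcript reading into the left flank yields plus-strand
## alignments whose 1-based inclusive end is pinned at pos+3; a transcript
## reading into the right flank yields minus-strand alignments whose
## 0-based start is pinned at pos-1. Under the position rule this places
## the paired clusters exactly 4 bp apart.

#' Emit T7 IVT read pairs for mapping
#'
#' For every insertion (and every detectable derivative cassette, if
#' supplied) emits `depthPerSide` read pairs per T7 side. Read 1 covers the
#' barcode region of the transcript in the side-dependent layout; read 2
#' covers up to `readLen` nt of flanking genomic sequence whose first 8 nt double as a degenerate
#' UMI, with a random alignment length per read so that independent
#' molecules produce distinct aligned lengths. Substitution errors are
#' applied to both reads at `errRate` per base.
#'
#' @param sim a [ShuffleSim-class].
#' @param depthPerSide read pairs per cassette end (default 10).
#' @param readLen maximum genomic read-2 length (default 120).
#' @param minFlank minimum genomic read-2 length (default 40).
#' @param errRate per-base substitution error rate.
#' @param includeDerivatives emit reads for detectable derivative
#'   cassettes as well (post-Cre IVT library).
#' @param seed integer seed.
#' @return data.frame of read records with truth columns (prefixed
#'   `truth_`) retained for evaluation; downstream tools use only
#'   read_id/read1/read2.
#' @export
emitIvtReads <- function(sim, depthPerSide = 10L, readLen = 120L,
                         minFlank = 40L, errRate = 0, seed = 1L,
                         includeDerivatives = FALSE) {
  if (readLen < minFlank) stop("readLen must be >= minFlank")
  barcodeRegion <- nchar(cassetteReadTop(sim@design, strrep("A", sim@design@bc1Length),
                                         strrep("A", sim@design@bc2Length)))
  if (readLen < 8L) stop("readLen shorter than the degenerate UMI")
  set.seed(seed)
  ins <- sim@insertions
  units <- data.frame(unit_id = ins$insertion_id, chrom = ins$chrom,
                      pos = ins$pos, orientation = ins$orientation,
                      allele = ins$allele, bc1 = ins$bc1, bc2 = ins$bc2,
                      unit_type = "insertion",
                      left_anchor_pos = ins$pos, right_anchor_pos = ins$pos,
                      left_flipped = FALSE, right_flipped = FALSE,
                      stringsAsFactors = FALSE)
  if (includeDerivatives && nrow(sim@derivatives)) {
    der <- sim@derivatives[sim@derivatives$detectable, , drop = FALSE]
    if (nrow(der)) {
      insAt <- function(id, col) ins[[col]][match(id, ins$insertion_id)]
      dunits <- data.frame(
        unit_id = paste0(der$event_id, ".p", der$product),
        chrom = insAt(der$left_insertion, "chrom"),
        pos = insAt(der$left_insertion, "pos"),
        orientation = ifelse(der$left_side == "CS2", "top-CS2", "bottom-CS1"),
        allele = insAt(der$left_insertion, "allele"),
        bc1 = der$bc1, bc2 = der$bc2,
        unit_type = "derivative",
        left_anchor_pos = insAt(der$left_insertion, "pos"),
        right_anchor_pos = insAt(der$right_insertion, "pos"),
        left_flipped = der$left_flipped,
        right_flipped = der$right_flipped,
        stringsAsFactors = FALSE)
      dunits$right_chrom <- insAt(der$right_insertion, "chrom")
      dunits$right_allele <- insAt(der$right_insertion, "allele")
      units$right_chrom <- units$chrom
      units$right_allele <- units$allele
      units <- rbind(units, dunits)
    }
  }
  if (!"right_chrom" %in% colnames(units)) {
    units$right_chrom <- units$chrom
    units$right_allele <- units$allele
  }
  n <- nrow(units)
  rec <- units[rep(seq_len(n), each = 2L * depthPerSide), , drop = FALSE]
  rec$side <- rep(rep(c("left", "right"), each = depthPerSide), times = n)
  rec$len <- sample(seq.int(minFlank, readLen), nrow(rec), replace = TRUE)

  isLeft <- rec$side == "left"
  ## left flank: span [pos+4-L, pos+3]; right flank: span [pos, pos+L-1]
  anchor <- ifelse(isLeft, rec$left_anchor_pos, rec$right_anchor_pos)
  spanChrom <- ifelse(isLeft, rec$chrom, rec$right_chrom)
  spanAllele <- ifelse(isLeft, rec$allele, rec$right_allele)
  start <- ifelse(isLeft, pmax(1L, anchor + 4L - rec$len), anchor)
  end <- ifelse(isLeft, anchor + 3L, anchor + rec$len - 1L)
  flipped <- ifelse(isLeft, rec$left_flipped, rec$right_flipped)

  slices <- character(nrow(rec))
  for (h in unique(spanAllele)) {
    idx <- which(spanAllele == h)
    slices[idx] <- genomeSlices(sim@genome, h, spanChrom[idx],
                                start[idx], end[idx])
  }
  ## unflipped: left flank reads align +, right flank reads align -
  ## flipped parts sit in inverted orientation at the junction, so their
  ## reads carry the opposite strand of the same slice.
  plusLike <- xor(isLeft, flipped)
  read2 <- ifelse(plusLike, slices, revComp(slices))

  layoutTop <- (rec$orientation == "top-CS2") == (rec$side == "right")
  read1 <- character(nrow(rec))
  read1[layoutTop] <- cassetteReadTop(sim@design, rec$bc1[layoutTop],
                                      rec$bc2[layoutTop])
  read1[!layoutTop] <- cassetteReadBottom(sim@design, rec$bc1[!layoutTop],
                                          rec$bc2[!layoutTop])
  out <- data.frame(
    read_id = sprintf("r%07d", seq_len(nrow(rec))),
    read1 = injectErrors(read1, errRate),
    read2 = injectErrors(read2, errRate),
    umi1 = randomDnaStrings(nrow(rec), 10L),
    truth_unit = rec$unit_id,
    truth_type = rec$unit_type,
    truth_side = rec$side,
    truth_chrom = spanChrom,
    truth_start = start,
    truth_end = end,
    truth_strand = ifelse(plusLike, "+", "-"),
    truth_allele = spanAllele,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract barcode observations from IVT read 1 sequences
#'
#' Recovers the two 20-nt barcodes and the cassette strand from the
#' barcode-region read using exact matches to the constant bases around
#' the barcode slots: the top-strand (CS2) layout
#' `TGAGC(.{20})ATAAC ... GTTAT(.{20})` or the bottom-strand (CS1) layout
#' `AAAGC(.{20})ATAAC ... GTTAT(.{20})`. The loxPsym interior between the
#' two anchor blocks is not required to match. Barcodes are reported as
#' read (no reverse-complementing); reads matching neither layout are
#' rejected.
#'
#' @param read1 character vector of barcode-region reads.
#' @param bcLength barcode slot width.
#' @param loxLength loxPsym length (sets the gap between anchor blocks).
#' @return data.frame with columns barcode1, barcode2, cassette_strand,
#'   extracted (logical).
#' @export
extractIvtObservations <- function(read1, bcLength = 20L, loxLength = 34L) {
  gap <- loxLength - 10L
  patTop <- sprintf("TGAGC([ACGT]{%d})ATAAC[ACGT]{%d}GTTAT([ACGT]{%d})",
                    bcLength, gap, bcLength)
  patBottom <- sprintf("AAAGC([ACGT]{%d})ATAAC[ACGT]{%d}GTTAT([ACGT]{%d})",
                       bcLength, gap, bcLength)
  captureGroups <- function(pattern, txt) {
    m <- regexpr(pattern, txt, perl = TRUE)
    cs <- attr(m, "capture.start")
    cl <- attr(m, "capture.length")
    list(ok = m != -1L,
         g1 = substr(txt, cs[, 1L], cs[, 1L] + cl[, 1L] - 1L),
         g2 = substr(txt, cs[, 2L], cs[, 2L] + cl[, 2L] - 1L))
  }
  mTop <- captureGroups(patTop, read1)
  mBottom <- captureGroups(patBottom, read1)
  okTop <- mTop$ok
  okBottom <- !okTop & mBottom$ok
  barcode1 <- rep(NA_character_, length(read1))
  barcode2 <- rep(NA_character_, length(read1))
  barcode1[okTop] <- mTop$g1[okTop]
  barcode2[okTop] <- mTop$g2[okTop]
  barcode1[okBottom] <- mBottom$g1[okBottom]
  barcode2[okBottom] <- mBottom$g2[okBottom]
  data.frame(barcode1 = barcode1, barcode2 = barcode2,
             cassette_strand = ifelse(okTop, "top-CS2",
                                      ifelse(okBottom, "bottom-CS1",
                                             NA_character_)),
             extracted = okTop | okBottom,
             stringsAsFactors = FALSE)
}

## Collect (pattern, chrom, start, haplotype-agnostic) anchor hits of a
## PDict against every chromosome of both haplotypes.
anchorHits <- function(patterns, genome) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))
  hits <- list()
  k <- 1L
  for (h in seq_along(genome@haplotypes)) {
    hap <- genome@haplotypes[[h]]
    for (ch in names(hap)) {
      m <- Biostrings::matchPDict(pd, hap[[ch]])
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0L) next
      hits[[k]] <- data.frame(
        pattern = rep(seq_along(cnt), cnt),
        chrom = ch,
        start = unlist(Biostrings::startIndex(m), use.names = FALSE),
        stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  if (length(hits) == 0L)
    return(data.frame(pattern = integer(0), chrom = character(0),
                      start = integer(0)))
  out <- do.call(rbind, hits)
  unique(out)  # same locus on both haplotypes counts once
}

#' Place IVT reads on a synthetic genome by exact anchor matching
#'
#' A deliberately simple read placer for simulator output: the first
#' `anchorLen` bases of read 2 (and of its reverse complement) are matched
#' exactly against both haplotypes with [Biostrings::matchPDict()]. A
#' forward hit of the read anchor yields a plus-strand alignment; a forward
#' hit of the reverse-complement anchor yields a minus-strand alignment.
#' Reads whose anchors hit more than one genomic locus are flagged
#' multimapped; reads with no hit are rejected. The junction TTAA check and
#' the per-read allele call against the variant table are performed on the
#' resulting alignment span. Real-genome alignment is out of scope; this
#' placer exists so the mapper can consume self-contained synthetic data.
#'
#' @param reads read table from [emitIvtReads()].
#' @param genome a [ShuffleGenome-class].
#' @param design cassette design used for barcode extraction.
#' @param anchorLen exact anchor length in nt (default 24).
#' @return data.frame of observations: read_id, barcode1, barcode2,
#'   cassette_strand, chrom, align_start, align_end (1-based inclusive),
#'   genome_strand, umi1, umi2, multimapped, junction_is_ttaa, allele_call.
#'   Rejected reads are dropped; a tally of reasons is attached as
#'   attribute `dropReasons`.
#' @export
placeIvtReads <- function(reads, genome, design = shuffleCassetteDesign(),
                          anchorLen = 24L) {
  ext <- extractIvtObservations(reads$read1, design@bc1Length,
                                nchar(design@loxPsym))
  drops <- c(no_barcode_anchor = sum(!ext$extracted))
  keep <- which(ext$extracted)
  reads <- reads[keep, , drop = FALSE]
  ext <- ext[keep, , drop = FALSE]

  len <- nchar(reads$read2)
  fwdAnchor <- substr(reads$read2, 1L, anchorLen)
  rcRead2 <- revComp(reads$read2)
  revAnchor <- substr(rcRead2, 1L, anchorLen)
  ok <- nchar(fwdAnchor) == anchorLen & isDnaString(fwdAnchor) &
    isDnaString(revAnchor)
  drops <- c(drops, short_read2 = sum(!ok))
  reads <- reads[ok, , drop = FALSE]; ext <- ext[ok, , drop = FALSE]
  fwdAnchor <- fwdAnchor[ok]; revAnchor <- revAnchor[ok]
  rcRead2 <- rcRead2[ok]; len <- len[ok]
  if (nrow(reads) == 0L) {
    obs <- emptyObservations()
    attr(obs, "dropReasons") <- drops
    return(obs)
  }

  fHits <- anchorHits(fwdAnchor, genome)
  rHits <- anchorHits(revAnchor, genome)
  fHits$strand <- "+"; rHits$strand <- "-"
  hits <- rbind(fHits, rHits)
  nLoci <- tabulate(hits$pattern, nbins = nrow(reads))
  first <- hits[!duplicated(hits$pattern), , drop = FALSE]
  first <- first[order(first$pattern), , drop = FALSE]

  aligned <- nLoci > 0L
  drops <- c(drops, unaligned = sum(!aligned))
  idx <- first$pattern
  obs <- data.frame(
    read_id = reads$read_id[idx],
    barcode1 = ext$barcode1[idx],
    barcode2 = ext$barcode2[idx],
    cassette_strand = ext$cassette_strand[idx],
    chrom = first$chrom,
    align_start = first$start,
    align_end = first$start + len[idx] - 1L,
    genome_strand = first$strand,
    umi1 = reads$umi1[idx],
    umi2 = substr(reads$read2[idx], 1L, 8L),
    multimapped = nLoci[idx] > 1L,
    stringsAsFactors = FALSE)

  ## junction TTAA check on the reference motif at the pinned end
  jStart <- ifelse(obs$genome_strand == "-", obs$align_start,
                   obs$align_end - 3L)
  motif <- genomeSlices(genome, 1L, obs$chrom, jStart, jStart + 3L)
  obs$junction_is_ttaa <- motif == "TTAA"

  orientedRead <- ifelse(obs$genome_strand == "+",
                         reads$read2[idx], rcRead2[idx])
  obs$allele_call <- callReadAllele(obs$chrom, obs$align_start,
                                    obs$align_end, orientedRead,
                                    variantTable(genome),
                                    haplotypeNames(genome))
  rownames(obs) <- NULL
  attr(obs, "dropReasons") <- drops
  obs
}

emptyObservations <- function() {
  data.frame(read_id = character(0), barcode1 = character(0),
             barcode2 = character(0), cassette_strand = character(0),
             chrom = character(0), align_start = integer(0),
             align_end = integer(0), genome_strand = character(0),
             umi1 = character(0), umi2 = character(0),
             multimapped = logical(0), junction_is_ttaa = logical(0),
             allele_call = character(0), stringsAsFactors = FALSE)
}

#' Call the haplotype of aligned reads from overlapped variants
#'
#' For every alignment, compares the read base at each overlapped
#' heterozygous variant with the two haplotype alleles: consistent
#' reference matches give the first haplotype, consistent alternate
#' matches the second, alignments overlapping no variant are `noVariant`,
#' and mixed evidence is `inconclusive` (discarded downstream).
#'
#' @param chrom,alignStart,alignEnd alignment spans (1-based inclusive).
#' @param orientedRead read sequence in genome (plus-strand) orientation.
#' @param variants variant table (chrom, pos, ref, alt).
#' @param haplotypeNames two labels, reference first.
#' @return character vector of allele calls.
#' @export
callReadAllele <- function(chrom, alignStart, alignEnd, orientedRead,
                           variants, haplotypeNames = c("BL6", "CAST")) {
  n <- length(chrom)
  call <- rep("noVariant", n)
  if (n == 0L || nrow(variants) == 0L) return(call)
  dt <- data.table::data.table(i = seq_len(n), chrom = chrom,
                               s = alignStart, e = alignEnd)
  vt <- data.table::data.table(chrom = variants$chrom, pos = variants$pos,
                               ref = variants$ref, alt = variants$alt)
  ov <- vt[dt, on = .(chrom, pos >= s, pos <= e), nomatch = NULL,
           .(i, vpos = x.pos, ref, alt)]
  if (nrow(ov) == 0L) return(call)
  base <- substr(orientedRead[ov$i], ov$vpos - alignStart[ov$i] + 1L,
                 ov$vpos - alignStart[ov$i] + 1L)
  evidence <- ifelse(base == ov$ref, "ref",
                     ifelse(base == ov$alt, "alt", NA_character_))
  ok <- !is.na(evidence)
  if (!any(ok)) return(call)
  agg <- data.table::data.table(i = ov$i[ok], ev = evidence[ok])
  agg <- agg[, .(nref = sum(ev == "ref"), nalt = sum(ev == "alt")), by = i]
  call[agg$i[agg$nref > 0L & agg$nalt == 0L]] <- haplotypeNames[1L]
  call[agg$i[agg$nalt > 0L & agg$nref == 0L]] <- haplotypeNames[2L]
  call[agg$i[agg$nalt > 0L & agg$nref > 0L]] <- "inconclusive"
  call
}
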