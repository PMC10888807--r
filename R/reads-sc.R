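#' Emit single-cell T7 feature reads and a cell QC table
#'
#' Simulates in-situ T7 transcription of cassette barcode pairs captured
#' in a 3' single-cell experiment. Each cell belongs to one clone (or two,
#' for doublets). Cre events of a clone are assigned to
#' `cellsPerEvent` of its cells; a cell carrying an event loses the two
#' recombined parental cassettes and gains the event's detectable
#' derivative pairs. Every pair present in a cell is captured
#' independently with `captureRate`; a captured pair yields a
#' zero-truncated Poisson(`umiDepth`) number of UMIs on a random capture
#' side, each observed `readsPerUmi` times. Ambient contamination adds
#' reads drawn from the pooled pair abundance across all cells at
#' `ambientRate` of the cell's reads, each with a fresh UMI and flagged in
#' truth. The QC table draws transcriptome UMI totals, mitochondrial
#' fractions and doublet scores from simple parametric distributions.
#'
#' @param sim a [ShuffleSim-class].
#' @param nCells number of cells.
#' @param captureRate per-pair capture probability in `[0, 1]`.
#' @param umiDepth mean UMIs per captured pair.
#' @param readsPerUmi reads per UMI.
#' @param ambientRate expected ambient fraction of reads per cell.
#' @param doubletRate fraction of cells that are doublets.
#' @param cellsPerEvent number of cells of the clone carrying each event.
#' @param seed integer seed.
#' @return list with `reads` (cell_bc, umi, bc1, bc2, capture_side,
#'   truth_ambient), `cells` (per-cell truth: clone(s), event list),
#'   `qc` (cell_bc, transcriptome_umis, mito_fraction, doublet_score) and
#'   `whitelist` (all emitted cell barcodes).
#' @export
emitT7SingleCellReads <- function(sim, nCells = 1000L, captureRate = 0.7,
                                  umiDepth = 4, readsPerUmi = 2L,
                                  ambientRate = 0.02, doubletRate = 0.03,
                                  cellsPerEvent = 1L, seed = 1L) {
  if (captureRate < 0 || captureRate > 1)
    stop("captureRate must be in [0, 1]")
  set.seed(seed)
  ins <- sim@insertions
  clones <- unique(ins$clone_id)
  cellBc <- uniqueBarcodes(nCells, 16L)
  clone1 <- sample(clones, nCells, replace = TRUE)
  isDoublet <- runif(nCells) < doubletRate
  clone2 <- rep(NA_character_, nCells)
  clone2[isDoublet] <- sample(clones, sum(isDoublet), replace = TRUE)

  parentalPairs <- split(pairKey(ins$bc1, ins$bc2), ins$clone_id)
  pairClone <- stats::setNames(ins$clone_id, pairKey(ins$bc1, ins$bc2))

  ## assign events to cells of their clone
  ev <- sim@events
  der <- sim@derivatives
  cellEvents <- rep(list(character(0)), nCells)
  if (nrow(ev)) {
    for (e in seq_len(nrow(ev))) {
      eligible <- which(clone1 == ev$clone_id[e] |
                          (!is.na(clone2) & clone2 == ev$clone_id[e]))
      if (length(eligible) == 0L) next
      hit <- sample(eligible, min(cellsPerEvent, length(eligible)))
      for (h in hit)
        cellEvents[[h]] <- c(cellEvents[[h]], ev$event_id[e])
    }
  }

  ## per-cell pair sets
  cellPairRows <- vector("list", nCells)
  evById <- if (nrow(ev)) split(seq_len(nrow(ev)), ev$event_id) else list()
  for (c in seq_len(nCells)) {
    pairs <- parentalPairs[[clone1[c]]]
    if (isDoublet[c]) pairs <- union(pairs, parentalPairs[[clone2[c]]])
    rearranged <- character(0)
    for (eid in cellEvents[[c]]) {
      e <- evById[[eid]]
      lost <- ins[match(c(ev$insertion_a[e], ev$insertion_b[e]),
                        ins$insertion_id), ]
      pairs <- setdiff(pairs, pairKey(lost$bc1, lost$bc2))
      dd <- der[der$event_id == eid & der$detectable, , drop = FALSE]
      if (nrow(dd)) rearranged <- c(rearranged, pairKey(dd$bc1, dd$bc2))
    }
    cellPairRows[[c]] <- unique(c(pairs, rearranged))
  }

  ## capture and UMI draws
  allPairs <- unlist(cellPairRows, use.names = FALSE)
  cellOfPair <- rep(seq_len(nCells), lengths(cellPairRows))
  captured <- runif(length(allPairs)) < captureRate
  allPairs <- allPairs[captured]
  cellOfPair <- cellOfPair[captured]
  nUmis <- 1L + rpois(length(allPairs), max(umiDepth - 1, 0))
  umiPair <- rep(allPairs, nUmis)
  umiCell <- rep(cellOfPair, nUmis)
  side <- sample(c("CS2", "CS1"), length(umiPair), replace = TRUE)
  umi <- randomDnaStrings(length(umiPair), 12L)
  reads <- data.frame(
    cell_bc = cellBc[rep(umiCell, each = readsPerUmi)],
    umi = rep(umi, each = readsPerUmi),
    pair = rep(umiPair, each = readsPerUmi),
    capture_side = rep(side, each = readsPerUmi),
    truth_ambient = FALSE, stringsAsFactors = FALSE)

  ## ambient contamination from the pooled pair abundance
  if (ambientRate > 0 && nrow(reads)) {
    perCellReads <- tabulate(match(reads$cell_bc, cellBc), nbins = nCells)
    nAmb <- rpois(nCells, perCellReads * ambientRate)
    pool <- reads$pair  # abundance-weighted pool across all cells
    ambPair <- sample(pool, sum(nAmb), replace = TRUE)
    amb <- data.frame(
      cell_bc = rep(cellBc, nAmb),
      umi = randomDnaStrings(sum(nAmb), 12L),
      pair = ambPair,
      capture_side = sample(c("CS2", "CS1"), sum(nAmb), replace = TRUE),
      truth_ambient = TRUE, stringsAsFactors = FALSE)
    reads <- rbind(reads, amb)
  }
  bc <- strsplit(reads$pair, "|", fixed = TRUE)
  reads$bc1 <- vapply(bc, `[`, character(1), 1L)
  reads$bc2 <- vapply(bc, `[`, character(1), 2L)
  reads$pair <- NULL
  rownames(reads) <- NULL

  cells <- data.frame(
    cell_bc = cellBc, clone_id = clone1,
    clone_id2 = clone2, is_doublet = isDoublet,
    events = vapply(cellEvents, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  qc <- data.frame(
    cell_bc = cellBc,
    transcriptome_umis = round(stats::rlnorm(nCells, log(5000), 0.4)),
    mito_fraction = 100 * stats::rbeta(nCells, 4, 60),
    doublet_score = ifelse(isDoublet, stats::rbeta(nCells, 5, 5),
                           stats::rbeta(nCells, 2, 20)),
    stringsAsFactors = FALSE)
  list(reads = reads, cells = cells, qc = qc, whitelist = cellBc)
}

#' Format and extract single-cell T7 reads
#'
#' `formatT7Reads()` renders read records as 10x-style sequences: read 1
#' is the 16-nt cell barcode followed by the 12-nt UMI; read 2 carries the
#' barcode region in the capture-side-dependent layout (CS2 capture:
#' `TGAGC<bc1>ATAAC...GTTAT<bc2>` with the anchor at offset 15; CS1
#' capture: `AAAGC<revcomp(bc2)>ATAAC...GTTAT<revcomp(bc1)>`).
#' `extractT7Records()` inverts this: it pattern-matches both layouts
#' within a configurable window, re-orients CS1-capture barcodes back to
#' the canonical bc1/bc2, and optionally restricts cell barcodes to a
#' whitelist (exact match).
#'
#' @param reads read table from [emitT7SingleCellReads()].
#' @param design cassette design.
#' @return `formatT7Reads()`: data.frame with read1/read2 sequences.
#' @export
formatT7Reads <- function(reads, design = shuffleCassetteDesign()) {
  seq2 <- character(nrow(reads))
  cs2 <- reads$capture_side == "CS2"
  seq2[cs2] <- cassetteReadTop(design, reads$bc1[cs2], reads$bc2[cs2])
  seq2[!cs2] <- cassetteReadBottom(design, reads$bc1[!cs2],
                                   reads$bc2[!cs2])
  data.frame(read1 = paste0(reads$cell_bc, reads$umi), read2 = seq2,
             stringsAsFactors = FALSE)
}

#' @rdname formatT7Reads
#' @param formatted data.frame with read1/read2 (as from
#'   [formatT7Reads()]) or raw sequences read from FASTQ.
#' @param whitelist optional character vector of valid cell barcodes.
#' @param anchorWindow allowed start offsets (1-based) of the first
#'   anchor in read 2.
#' @param bcLength,loxLength barcode and loxPsym lengths.
#' @return `extractT7Records()`: data.frame of T7 records (cell_bc, umi,
#'   bc1, bc2, capture_side); rejected reads are dropped and tallied in
#'   attribute `dropReasons`.
#' @export
extractT7Records <- function(formatted, whitelist = NULL,
                             anchorWindow = c(10L, 25L), bcLength = 20L,
                             loxLength = 34L) {
  cellBc <- substr(formatted$read1, 1L, 16L)
  umi <- substr(formatted$read1, 17L, 28L)
  gap <- loxLength - 10L
  patTop <- sprintf("TGAGC([ACGT]{%d})ATAAC[ACGT]{%d}GTTAT([ACGT]{%d})",
                    bcLength, gap, bcLength)
  patBottom <- sprintf("AAAGC([ACGT]{%d})ATAAC[ACGT]{%d}GTTAT([ACGT]{%d})",
                       bcLength, gap, bcLength)
  grab <- function(pattern, txt) {
    m <- regexpr(pattern, txt, perl = TRUE)
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    list(at = as.integer(m),
         g1 = substr(txt, cs[, 1L], cs[, 1L] + cl[, 1L] - 1L),
         g2 = substr(txt, cs[, 2L], cs[, 2L] + cl[, 2L] - 1L))
  }
  top <- grab(patTop, formatted$read2)
  bottom <- grab(patBottom, formatted$read2)
  inWindow <- function(at) at >= anchorWindow[1L] & at <= anchorWindow[2L]
  okTop <- top$at > 0L & inWindow(top$at)
  okBottom <- !okTop & bottom$at > 0L & inWindow(bottom$at)
  drops <- c(no_anchor = sum(!okTop & !okBottom))
  bc1 <- ifelse(okTop, top$g1, revComp(bottom$g2))
  bc2 <- ifelse(okTop, top$g2, revComp(bottom$g1))
  out <- data.frame(cell_bc = cellBc, umi = umi, bc1 = bc1, bc2 = bc2,
                    capture_side = ifelse(okTop, "CS2", "CS1"),
                    stringsAsFactors = FALSE)
  out <- out[okTop | okBottom, , drop = FALSE]
  if (!is.null(whitelist)) {
    onList <- out$cell_bc %in% whitelist
    drops <- c(drops, not_whitelisted = sum(!onList))
    out <- out[onList, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "dropReasons") <- drops
  out
}
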