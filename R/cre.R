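## Junction-side bookkeeping for Cre crossovers.
##
## On the chromosome, the sequence left of a cassette's loxPsym carries one
## barcode with its capture-sequence label, and the sequence right of the
## loxPsym carries the other:
##   top-CS2 orientation:    left = (bc1, CS2), right = (bc2, CS1)
##   bottom-CS1 orientation: left = (bc2, CS1), right = (bc1, CS2)
cassettePart <- function(ins, part) {
  top <- ins$orientation == "top-CS2"
  if (part == "left") {
    data.frame(insertion_id = ins$insertion_id, part = "left",
               bc = ifelse(top, ins$bc1, ins$bc2),
               side = ifelse(top, "CS2", "CS1"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(insertion_id = ins$insertion_id, part = "right",
               bc = ifelse(top, ins$bc2, ins$bc1),
               side = ifelse(top, "CS1", "CS2"),
               stringsAsFactors = FALSE)
  }
}

#' Draw Cre recombination events within clones
#'
#' Samples recombination events between cassette integrations of the same
#' clone. Cis (same-chromosome) pairs are drawn with probability
#' proportional to `exp(-distance / cisDecayLambda)`, reflecting the
#' exponential decay of Cre efficiency with genomic distance; trans pairs
#' (different chromosomes) are drawn uniformly. Each event resolves in one
#' of the two recombination registers of the palindromic loxPsym site with
#' probability 1/2 each: on the same chromosome the direct register
#' excises a deletion (one genomic scar plus one extrachromosomal circle)
#' and the inverted register inverts the intervening segment; between
#' chromosomes both registers yield reciprocal translocation products.
#'
#' @param insertionTable insertion table from [placeInsertions()].
#' @param cisRate mean number of cis events per clone.
#' @param transRate mean number of trans events per clone.
#' @param cisDecayLambda exponential decay length in bp (must be > 0).
#' @param seed integer seed.
#' @return data.frame of events with columns event_id, clone_id,
#'   insertion_a, insertion_b (a is the leftmost for cis events), register
#'   (`direct`/`inverted`), resolved_class, distance.
#' @export
applyCreEvents <- function(insertionTable, cisRate = 5, transRate = 0.5,
                           cisDecayLambda = 1e5, seed = 1L) {
  if (cisDecayLambda <= 0) stop("cisDecayLambda must be > 0")
  set.seed(seed)
  rows <- list()
  for (cl in unique(insertionTable$clone_id)) {
    ins <- insertionTable[insertionTable$clone_id == cl, , drop = FALSE]
    if (nrow(ins) < 2L) next
    idx <- utils::combn(nrow(ins), 2L)
    sameChrom <- ins$chrom[idx[1, ]] == ins$chrom[idx[2, ]]
    dist <- abs(ins$pos[idx[1, ]] - ins$pos[idx[2, ]])
    nCis <- rpois(1L, cisRate)
    nTrans <- rpois(1L, transRate)
    pickCis <- if (nCis > 0L && any(sameChrom)) {
      w <- exp(-dist[sameChrom] / cisDecayLambda)
      if (sum(w) == 0) integer(0)
      else which(sameChrom)[sample.int(sum(sameChrom), nCis, replace = TRUE,
                                       prob = w)]
    } else integer(0)
    pickTrans <- if (nTrans > 0L && any(!sameChrom)) {
      which(!sameChrom)[sample.int(sum(!sameChrom), nTrans, replace = TRUE)]
    } else integer(0)
    pick <- c(pickCis, pickTrans)
    if (length(pick) == 0L) next
    a <- idx[1, pick]; b <- idx[2, pick]
    ## order cis partners by position so insertion_a is the leftmost
    swap <- sameChrom[pick] & ins$pos[a] > ins$pos[b]
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    register <- sample(c("direct", "inverted"), length(pick), replace = TRUE)
    cls <- ifelse(!sameChrom[pick], "translocation_reciprocal",
                  ifelse(register == "direct", "deletion", "inversion"))
    rows[[cl]] <- data.frame(
      clone_id = cl,
      insertion_a = ins$insertion_id[a],
      insertion_b = ins$insertion_id[b],
      register = register,
      resolved_class = cls,
      distance = ifelse(sameChrom[pick], dist[pick], NA_integer_),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(event_id = character(0), clone_id = character(0),
                      insertion_a = character(0), insertion_b = character(0),
                      register = character(0), resolved_class = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  cbind(event_id = sprintf("ev%05d", seq_len(nrow(ev))), ev,
        stringsAsFactors = FALSE)
}

#' Compute derivative cassettes for Cre events
#'
#' Each crossover at the loxPsym yields two junction products. In the
#' direct register, product 1 joins the left-of-loxPsym part of cassette A
#' to the right-of-loxPsym part of cassette B, and product 2 joins B's left
#' part to A's right part. In the inverted register the partner cassette is
#' engaged in the opposite alignment, so each junction joins two same-name
#' parts with one of them flipped onto the opposite side (its
#' capture-sequence label travels with it): product 1 joins A's left part
#' to B's flipped left part and product 2 joins A's flipped right part to
#' B's right part.
#'
#' A product is PCR-detectable only when its two sides carry different
#' capture sequences; same-CS junctions are suppressed (suppressive PCR).
#' For a cis deletion the product joining the outer parts is the genomic
#' scar and the product joining the two inner parts is the excised circle
#' (ecDNA); every deletion yields exactly one of each.
#'
#' @param eventTable events from [applyCreEvents()].
#' @param insertionTable insertion table from [placeInsertions()].
#' @return data.frame with one row per product: event_id, product (1/2),
#'   resolved_class, left/right insertion, part, flipped flag, barcode and
#'   capture side per junction side, topology (`genomic`/`circle`),
#'   detectable, and for detectable products the canonical amplicon
#'   barcodes bc1 (CS2 side) and bc2 (CS1 side).
#' @export
computeDerivatives <- function(eventTable, insertionTable) {
  if (nrow(eventTable) == 0L) return(emptyDerivatives())
  insA <- insertionTable[match(eventTable$insertion_a,
                               insertionTable$insertion_id), ]
  insB <- insertionTable[match(eventTable$insertion_b,
                               insertionTable$insertion_id), ]
  aL <- cassettePart(insA, "left"); aR <- cassettePart(insA, "right")
  bL <- cassettePart(insB, "left"); bR <- cassettePart(insB, "right")
  direct <- eventTable$register == "direct"

  pickSide <- function(whenDirect, whenInverted, col) {
    ifelse(direct, whenDirect[[col]], whenInverted[[col]])
  }
  p1 <- data.frame(
    event_id = eventTable$event_id, product = 1L,
    resolved_class = eventTable$resolved_class,
    left_insertion = aL$insertion_id, left_part = "left",
    left_flipped = FALSE, left_bc = aL$bc, left_side = aL$side,
    right_insertion = bL$insertion_id,
    right_part = ifelse(direct, "right", "left"),
    right_flipped = !direct,
    right_bc = pickSide(bR, bL, "bc"),
    right_side = pickSide(bR, bL, "side"),
    stringsAsFactors = FALSE)
  p2 <- data.frame(
    event_id = eventTable$event_id, product = 2L,
    resolved_class = eventTable$resolved_class,
    left_insertion = ifelse(direct, bL$insertion_id, aR$insertion_id),
    left_part = ifelse(direct, "left", "right"),
    left_flipped = !direct,
    left_bc = pickSide(bL, aR, "bc"),
    left_side = pickSide(bL, aR, "side"),
    right_insertion = ifelse(direct, aR$insertion_id, bR$insertion_id),
    right_part = "right", right_flipped = FALSE,
    right_bc = pickSide(aR, bR, "bc"),
    right_side = pickSide(aR, bR, "side"),
    stringsAsFactors = FALSE)
  der <- rbind(p1, p2)
  der <- der[order(der$event_id, der$product), ]
  der$topology <- "genomic"
  der$topology[der$resolved_class == "deletion" & der$product == 2L] <- "circle"
  der$detectable <- der$left_side != der$right_side
  der$bc1 <- ifelse(der$detectable,
                    ifelse(der$left_side == "CS2", der$left_bc, der$right_bc),
                    NA_character_)
  der$bc2 <- ifelse(der$detectable,
                    ifelse(der$left_side == "CS1", der$left_bc, der$right_bc),
                    NA_character_)
  rownames(der) <- NULL
  der
}

emptyDerivatives <- function() {
  data.frame(event_id = character(0), product = integer(0),
             resolved_class = character(0),
             left_insertion = character(0), left_part = character(0),
             left_flipped = logical(0), left_bc = character(0),
             left_side = character(0),
             right_insertion = character(0), right_part = character(0),
             right_flipped = logical(0), right_bc = character(0),
             right_side = character(0), topology = character(0),
             detectable = logical(0), bc1 = character(0),
             bc2 = character(0), stringsAsFactors = FALSE)
}

#' Simulate a complete shuffle experiment
#'
#' Convenience wrapper tying together [simulateReference()],
#' [placeInsertions()], [applyCreEvents()] and [computeDerivatives()] into
#' one [ShuffleSim-class] truth object, deriving one sub-seed per stage
#' from the master seed.
#'
#' @param chromLengths named chromosome lengths (bp).
#' @param nClones,insertionsPerClone population structure.
#' @param cisRate,transRate,cisDecayLambda Cre event parameters; set
#'   `cisRate = 0` and `transRate = 0` for a no-Cre control population.
#' @param variantSpacing heterozygous variant spacing in bp.
#' @param design cassette design.
#' @param seed master integer seed.
#' @return a [ShuffleSim-class] object.
#' @export
simulateShuffleExperiment <- function(chromLengths = c(chr1 = 5e5, chr2 = 5e5),
                                      nClones = 20L, insertionsPerClone = 20L,
                                      cisRate = 2, transRate = 0.2,
                                      cisDecayLambda = 1e5,
                                      variantSpacing = 150,
                                      design = shuffleCassetteDesign(),
                                      seed = 1L) {
  genome <- simulateReference(chromLengths, variantSpacing = variantSpacing,
                              seed = deriveSeed(seed, 1L))
  ins <- placeInsertions(genome, nClones, insertionsPerClone,
                         seed = deriveSeed(seed, 2L),
                         bcLength = design@bc1Length)
  ev <- if (cisRate > 0 || transRate > 0)
    applyCreEvents(ins, cisRate, transRate, cisDecayLambda,
                   seed = deriveSeed(seed, 3L))
  else applyCreEvents(ins, 0, 0, cisDecayLambda, seed = deriveSeed(seed, 3L))
  der <- computeDerivatives(ev, ins)
  new("ShuffleSim", genome = genome, design = design, insertions = ins,
      events = ev, derivatives = der, cells = data.frame(),
      seed = as.integer(seed))
}
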