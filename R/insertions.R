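#' Place cassette integrations across founder clones
#'
#' Samples TTAA integration sites for `nClones` clones with
#' `insertionsPerClone` cassettes each. Sites are sampled without
#' replacement within a clone; by default they are also unique across the
#' whole population, which emulates the negligible probability of two
#' clones hitting the same TTAA in a genome four orders of magnitude larger
#' than the desk-scale synthetic one. Orientation and haplotype allele are
#' uniform at random, and every barcode is unique across the population.
#'
#' @param genome a [ShuffleGenome-class].
#' @param nClones number of founder clones (default 100).
#' @param insertionsPerClone cassettes per clone (default 50, emulating a
#'   bottlenecked high-MOI population).
#' @param seed integer seed.
#' @param bcLength barcode length in nt.
#' @param uniqueSitesAcrossClones logical; sample sites without replacement
#'   across the whole population (default TRUE).
#' @return data.frame with columns insertion_id, clone_id, chrom, pos
#'   (1-based first base of the left TTAA duplication), orientation
#'   (`top-CS2`/`bottom-CS1`), allele, bc1, bc2.
#' @export
placeInsertions <- function(genome, nClones = 100L, insertionsPerClone = 50L,
                            seed = 1L, bcLength = 20L,
                            uniqueSitesAcrossClones = TRUE) {
  set.seed(seed)
  siteTab <- data.frame(
    chrom = rep(names(genome@ttaaSites), lengths(genome@ttaaSites)),
    pos = unlist(genome@ttaaSites, use.names = FALSE),
    stringsAsFactors = FALSE)
  total <- nClones * insertionsPerClone
  if (uniqueSitesAcrossClones) {
    if (total > nrow(siteTab))
      stop(sprintf("demand (%d insertions) exceeds available TTAA sites (%d)",
                   total, nrow(siteTab)))
    pick <- sample(nrow(siteTab), total)
  } else {
    if (insertionsPerClone > nrow(siteTab))
      stop("insertionsPerClone exceeds available TTAA sites")
    pick <- unlist(lapply(seq_len(nClones), function(i)
      sample(nrow(siteTab), insertionsPerClone)), use.names = FALSE)
  }
  ins <- siteTab[pick, , drop = FALSE]
  ins$clone_id <- rep(sprintf("clone%03d", seq_len(nClones)),
                      each = insertionsPerClone)
  ins$orientation <- sample(c("top-CS2", "bottom-CS1"), total, replace = TRUE)
  ins$allele <- sample(genome@haplotypeNames, total, replace = TRUE)
  bcs <- uniqueBarcodes(2L * total, bcLength)
  ins$bc1 <- bcs[seq_len(total)]
  ins$bc2 <- bcs[total + seq_len(total)]
  ins$insertion_id <- sprintf("ins%05d", seq_len(total))
  rownames(ins) <- NULL
  ins[, c("insertion_id", "clone_id", "chrom", "pos", "orientation",
          "allele", "bc1", "bc2")]
}
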