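#' Shuffle cassette design
#'
#' Describes the fixed elements of the doubly barcoded loxPsym shuffle
#' cassette: convergent T7 promoters at the outer edges, the two 10x
#' feature-barcoding capture sequences (CS2 toward the left end of the top
#' strand, CS1 toward the right), PCR primer sites flanking the two random
#' barcode slots, and the palindromic loxPsym site between them. The
#' assembled template is 176 bp by default with two 20-nt barcode slots.
#'
#' `captureSeq1` is stored in its capture orientation, i.e. as it appears
#' on the bottom strand read 5' to 3'; the assembled top strand carries its
#' reverse complement.
#'
#' @slot t7PromoterFwd,t7PromoterRev character, the two promoter sequences
#'   (the reverse promoter is stored as it appears on the top strand).
#' @slot captureSeq2,captureSeq1 character capture sequences.
#' @slot primerSiteLeft character, must end in the anchor `TGAGC`.
#' @slot primerSiteRight character, must start with `GCTTT` so the bottom
#'   strand carries the `AAAGC` anchor in front of the barcode-2 slot.
#' @slot bc1Length,bc2Length integer barcode slot widths.
#' @slot loxPsym character, must begin `ATAAC` and end `GTTAT`.
#' @slot cassetteLength integer total assembled length.
#' @export
setClass("ShuffleCassetteDesign", representation(
  t7PromoterFwd = "character",
  captureSeq2 = "character",
  primerSiteLeft = "character",
  bc1Length = "integer",
  loxPsym = "character",
  bc2Length = "integer",
  primerSiteRight = "character",
  captureSeq1 = "character",
  t7PromoterRev = "character",
  cassetteLength = "integer"
))

setValidity("ShuffleCassetteDesign", function(object) {
  msg <- character(0)
  parts <- c(object@t7PromoterFwd, object@captureSeq2, object@primerSiteLeft,
             object@loxPsym, object@primerSiteRight, object@captureSeq1,
             object@t7PromoterRev)
  if (!all(isDnaString(parts)))
    msg <- c(msg, "all fixed elements must be ACGT strings")
  if (!grepl("TGAGC$", object@primerSiteLeft))
    msg <- c(msg, "primerSiteLeft must end in the TGAGC anchor")
  if (!grepl("^GCTTT", object@primerSiteRight))
    msg <- c(msg, "primerSiteRight must start with GCTTT")
  if (!grepl("^ATAAC", object@loxPsym) || !grepl("GTTAT$", object@loxPsym))
    msg <- c(msg, "loxPsym must begin ATAAC and end GTTAT")
  fixedLen <- sum(nchar(parts))
  if (fixedLen + object@bc1Length + object@bc2Length != object@cassetteLength)
    msg <- c(msg, sprintf("element lengths sum to %d, not cassetteLength %d",
                          fixedLen + object@bc1Length + object@bc2Length,
                          object@cassetteLength))
  if (length(msg)) msg else TRUE
})

#' Synthetic diploid reference genome
#'
#' A small two-haplotype genome (e.g. emulating a BL6xCAST F1 hybrid):
#' per-haplotype chromosome sequences sharing coordinates, a table of
#' heterozygous single-nucleotide variants distinguishing the haplotypes,
#' and the sorted 1-based start positions of TTAA transposon target sites
#' per chromosome. Variants are never placed inside a listed TTAA motif, so
#' every listed site is intact on both haplotypes.
#'
#' @slot haplotypes named list of two [Biostrings::DNAStringSet] objects.
#' @slot haplotypeNames character of length 2.
#' @slot variants data.frame with columns chrom, pos (1-based), ref, alt.
#' @slot ttaaSites named list of sorted integer vectors per chromosome.
#' @slot seed integer seed the genome was generated with.
#' @export
setClass("ShuffleGenome", representation(
  haplotypes = "list",
  haplotypeNames = "character",
  variants = "data.frame",
  ttaaSites = "list",
  seed = "integer"
))

setValidity("ShuffleGenome", function(object) {
  msg <- character(0)
  if (length(object@haplotypes) != 2L || length(object@haplotypeNames) != 2L)
    msg <- c(msg, "exactly two haplotypes are required")
  ch1 <- names(object@haplotypes[[1]])
  if (!identical(ch1, names(object@haplotypes[[2]])))
    msg <- c(msg, "haplotypes must share chromosome names")
  if (!all(names(object@ttaaSites) %in% ch1))
    msg <- c(msg, "ttaaSites names must be chromosomes")
  if (nrow(object@variants) &&
      !all(c("chrom", "pos", "ref", "alt") %in% colnames(object@variants)))
    msg <- c(msg, "variants must have chrom, pos, ref, alt columns")
  if (length(msg)) msg else TRUE
})

#' Simulated shuffle experiment with truth tables
#'
#' Container for one synthetic experiment: the genome and cassette design,
#' the table of cassette integrations across founder clones, the table of
#' Cre recombination events, the derivative cassettes (junction products)
#' each event created, and optionally the per-cell identities used for
#' single-cell read emission. All tables round-trip losslessly through
#' [writeTruth()] / [readTruth()].
#'
#' @slot genome a [ShuffleGenome-class].
#' @slot design a [ShuffleCassetteDesign-class].
#' @slot insertions data.frame of cassette integrations.
#' @slot events data.frame of Cre events.
#' @slot derivatives data.frame of derivative cassettes (two per event).
#' @slot cells data.frame of per-cell truth (may be empty).
#' @slot seed integer master seed.
#' @export
setClass("ShuffleSim", representation(
  genome = "ShuffleGenome",
  design = "ShuffleCassetteDesign",
  insertions = "data.frame",
  events = "data.frame",
  derivatives = "data.frame",
  cells = "data.frame",
  seed = "integer"
))

#' Set of reconstructed or supplied clonotypes
#'
#' A clonotype is the full set of barcode pairs carried by one founder
#' clone. The object stores one metadata row per clonotype and a long table
#' of member barcode pairs.
#'
#' @slot info data.frame with columns clonotype_id, provenance, n_pairs,
#'   max_detection_fraction.
#' @slot pairs data.frame with columns clonotype_id, bc1, bc2.
#' @export
setClass("ClonotypeSet", representation(
  info = "data.frame",
  pairs = "data.frame"
))

setValidity("ClonotypeSet", function(object) {
  msg <- character(0)
  if (!all(c("clonotype_id", "provenance", "n_pairs",
             "max_detection_fraction") %in% colnames(object@info)))
    msg <- c(msg, "info must have clonotype_id/provenance/n_pairs/max_detection_fraction")
  if (!all(c("clonotype_id", "bc1", "bc2") %in% colnames(object@pairs)))
    msg <- c(msg, "pairs must have clonotype_id/bc1/bc2")
  if (!all(object@pairs$clonotype_id %in% object@info$clonotype_id))
    msg <- c(msg, "pairs reference unknown clonotypes")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn ShuffleGenome-class chromosome lengths (named integer).
#' @param genome,object a `ShuffleGenome`.
#' @export
chromLengths <- function(genome) {
  stats::setNames(Biostrings::width(genome@haplotypes[[1]]),
                  names(genome@haplotypes[[1]]))
}

#' @describeIn ShuffleGenome-class variant table accessor.
#' @export
variantTable <- function(genome) genome@variants

#' @describeIn ShuffleGenome-class TTAA site list accessor.
#' @export
ttaaSites <- function(genome) genome@ttaaSites

#' @describeIn ShuffleGenome-class haplotype name accessor.
#' @export
haplotypeNames <- function(genome) genome@haplotypeNames

#' Accessors for simulated truth tables
#'
#' @param sim a [ShuffleSim-class] object.
#' @return the requested truth table (data.frame).
#' @export
insertions <- function(sim) sim@insertions

#' @rdname insertions
#' @export
creEvents <- function(sim) sim@events

#' @rdname insertions
#' @export
derivativeCassettes <- function(sim) sim@derivatives

#' @rdname insertions
#' @export
simCells <- function(sim) sim@cells

#' Clonotype accessors
#'
#' @param x a [ClonotypeSet-class].
#' @return `clonotypeInfo()` the metadata table; `clonotypePairs()` the long
#'   member-pair table; `clonotypePairSets()` a named list of pair-key sets.
#' @export
clonotypeInfo <- function(x) x@info

#' @rdname clonotypeInfo
#' @export
clonotypePairs <- function(x) x@pairs

#' @rdname clonotypeInfo
#' @export
clonotypePairSets <- function(x) {
  split(pairKey(x@pairs$bc1, x@pairs$bc2), x@pairs$clonotype_id)
}

## ---- show methods ----

setMethod("show", "ShuffleCassetteDesign", function(object) {
  cat("ShuffleCassetteDesign of", object@cassetteLength, "bp\n")
  cat("  barcode slots:", object@bc1Length, "nt (CS2-proximal) /",
      object@bc2Length, "nt (CS1-proximal)\n")
  cat("  loxPsym:", object@loxPsym, "\n")
})

setMethod("show", "ShuffleGenome", function(object) {
  cl <- chromLengths(object)
  cat("ShuffleGenome:", length(cl), "chromosome(s),",
      paste(object@haplotypeNames, collapse = "/"), "haplotypes\n")
  cat("  total length:", sum(cl), "bp;",
      nrow(object@variants), "heterozygous variants;",
      sum(lengths(object@ttaaSites)), "TTAA sites\n")
})

setMethod("show", "ShuffleSim", function(object) {
  cat("ShuffleSim:", length(unique(object@insertions$clone_id)), "clones,",
      nrow(object@insertions), "insertions,",
      nrow(object@events), "Cre events,",
      nrow(object@derivatives), "derivative cassettes\n")
  if (nrow(object@cells))
    cat("  single-cell truth for", nrow(object@cells), "cells\n")
})

setMethod("show", "ClonotypeSet", function(object) {
  cat("ClonotypeSet:", nrow(object@info), "clonotypes (",
      paste(unique(object@info$provenance), collapse = ", "), ")\n")
  cat("  pairs per clonotype: median",
      if (nrow(object@info)) stats::median(object@info$n_pairs) else 0, "\n")
})
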