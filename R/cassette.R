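## Palindromic loxP variant: 13-bp arms around the symmetric ATGTACAT spacer.
LOXPSYM <- "ATAACTTCGTATAATGTACATTATACGAAGTTAT"
T7_PROMOTER <- "TAATACGACTCACTATAGGG"

#' Default shuffle cassette design
#'
#' Builds the default 176-bp cassette layout. The fixed elements other than
#' the anchors (`TGAGC` before the first barcode, `ATAAC`/`GTTAT` at the
#' loxPsym boundaries and the `AAAGC` bottom-strand anchor) are arbitrary
#' spacer-grade sequence; only the element order, the anchors and the total
#' length are biologically constrained.
#'
#' @param bc1Length,bc2Length barcode slot widths in nt (default 20).
#' @param cassetteLength total template length in bp (default 176).
#' @return a [ShuffleCassetteDesign-class] object.
#' @examples
#' design <- shuffleCassetteDesign()
#' nchar(buildCassette(design, strrep("A", 20), strrep("C", 20)))
#' @export
shuffleCassetteDesign <- function(bc1Length = 20L, bc2Length = 20L,
                                  cassetteLength = 176L) {
  new("ShuffleCassetteDesign",
      t7PromoterFwd = T7_PROMOTER,
      captureSeq2 = "GGAGCCTTAGCCGCTAATAGG",
      primerSiteLeft = "CGTAGTGAGC",
      bc1Length = as.integer(bc1Length),
      loxPsym = LOXPSYM,
      bc2Length = as.integer(bc2Length),
      primerSiteRight = "GCTTTCGAGA",
      captureSeq1 = "GCCGGTCCTAGCAACCTAAGG",
      t7PromoterRev = revComp(T7_PROMOTER),
      cassetteLength = as.integer(cassetteLength))
}

checkBarcode <- function(bc, len, label) {
  bad <- nchar(bc) != len | !isDnaString(bc)
  if (any(bad))
    stop(sprintf("%s must be %d-nt ACGT strings", label, len), call. = FALSE)
  invisible(bc)
}

#' Assemble a shuffle cassette top-strand template
#'
#' Concatenates the fixed design elements with the two supplied barcodes.
#' On the top strand the first barcode sits immediately downstream of the
#' `TGAGC` anchor (CS2-proximal) and immediately upstream of the loxPsym
#' `ATAAC` boundary; the second barcode follows the loxPsym `GTTAT`
#' boundary (CS1-proximal).
#'
#' @param design a [ShuffleCassetteDesign-class].
#' @param bc1,bc2 barcode sequences of the configured lengths.
#' @return single character string of length `cassetteLength`.
#' @export
buildCassette <- function(design = shuffleCassetteDesign(), bc1, bc2) {
  stopifnot(is(design, "ShuffleCassetteDesign"),
            length(bc1) == 1L, length(bc2) == 1L)
  checkBarcode(bc1, design@bc1Length, "bc1")
  checkBarcode(bc2, design@bc2Length, "bc2")
  paste0(design@t7PromoterFwd, design@captureSeq2, design@primerSiteLeft,
         bc1, design@loxPsym, bc2,
         design@primerSiteRight, revComp(design@captureSeq1),
         design@t7PromoterRev)
}

#' Barcode-region read sequences of a cassette
#'
#' Returns the portion of a T7 transcript that covers the barcode region,
#' as sequenced: `cassetteReadTop()` gives the top-strand (CS2-capture)
#' layout `...TGAGC <bc1> ATAAC...GTTAT <bc2>...`; `cassetteReadBottom()`
#' the bottom-strand (CS1-capture) layout
#' `...AAAGC <revcomp(bc2)> ATAAC...GTTAT <revcomp(bc1)>...`.
#' Both include 14 nt of fixed sequence ahead of the anchor so that the
#' anchors sit at the read offsets the extraction windows expect.
#'
#' @param design a [ShuffleCassetteDesign-class].
#' @param bc1,bc2 barcode character vectors (recycled together).
#' @return character vector of read sequences.
#' @export
cassetteReadTop <- function(design, bc1, bc2) {
  pre <- paste0(design@captureSeq2, design@primerSiteLeft)
  prefix <- substr(pre, nchar(pre) - 18L, nchar(pre) - 5L)
  tail <- substr(design@primerSiteRight, 1L, 6L)
  paste0(prefix, "TGAGC", bc1, design@loxPsym, bc2, tail)
}

#' @rdname cassetteReadTop
#' @export
cassetteReadBottom <- function(design, bc1, bc2) {
  pre <- paste0(design@captureSeq1, revComp(design@primerSiteRight))
  prefix <- substr(pre, nchar(pre) - 18L, nchar(pre) - 5L)
  tail <- substr(revComp(design@primerSiteLeft), 1L, 6L)
  paste0(prefix, "AAAGC", revComp(bc2), design@loxPsym, revComp(bc1), tail)
}
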