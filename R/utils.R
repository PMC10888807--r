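#' @importFrom stats rpois rbinom runif setNames aggregate prcomp sd
#' @importFrom utils adist head modifyList
#' @importFrom data.table data.table as.data.table uniqueN :=
#' @import methods
NULL

.datatable.aware <- TRUE

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Random DNA strings
#'
#' Draws `n` independent random DNA strings of a fixed width with uniform
#' base composition. Used for barcodes, UMIs and synthetic chromosomes.
#'
#' @param n number of strings.
#' @param width string length in nucleotides.
#' @return character vector of length `n`.
#' @keywords internal
randomDnaStrings <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_ALPHABET, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## unique random barcodes; redraws collisions (vanishingly rare at 20 nt)
uniqueBarcodes <- function(n, width) {
  bc <- randomDnaStrings(n, width)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- randomDnaStrings(length(dup), width)
  }
  bc
}

#' Reverse complement of character vectors
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

isDnaString <- function(x) {
  grepl("^[ACGT]+$", x)
}

## Uniform substitution errors at `rate` per base; no indels.
injectErrors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  widths <- nchar(seqs)
  total <- sum(widths)
  hits <- which(runif(total) < rate)
  if (length(hits) == 0L) return(seqs)
  ends <- cumsum(widths)
  seqIdx <- findInterval(hits - 1L, ends) + 1L
  posIdx <- hits - c(0L, ends)[seqIdx]
  for (k in seq_along(hits)) {
    i <- seqIdx[k]; p <- posIdx[k]
    old <- substr(seqs[i], p, p)
    substr(seqs[i], p, p) <- sample(setdiff(DNA_ALPHABET, old), 1L)
  }
  seqs
}

#' Joint barcode Levenshtein distance matrix
#'
#' Distance between two barcode-pair observations is the sum of the
#' Levenshtein distances of their first and second barcodes, a single edit
#' budget over the whole barcode region of a cassette read.
#'
#' @param bc1,bc2 character vectors of equal length.
#' @return integer matrix of pairwise joint distances.
#' @export
jointLevenshtein <- function(bc1, bc2) {
  stopifnot(length(bc1) == length(bc2))
  adist(bc1) + adist(bc2)
}

#' Hamming distance matrix for equal-length strings
#'
#' @param x character vector of equal-length strings.
#' @return integer matrix of pairwise Hamming distances.
#' @export
hammingDistance <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(0L, 0L, 0L))
  w <- unique(nchar(x))
  if (length(w) != 1L)
    stop("hammingDistance() requires equal-length strings")
  m <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
              nrow = w)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) d[, i] <- colSums(m != m[, i])
  d
}

## Connected components under d <= threshold, by union-find (single linkage).
componentsUnderThreshold <- function(d, threshold) {
  n <- nrow(d)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (d[i, j] <= threshold) {
          ri <- findRoot(i); rj <- findRoot(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  match(roots, unique(roots))
}

## Modal value with deterministic lexicographic tie-break.
modalValue <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)][1L]
}

pairKey <- function(bc1, bc2) paste(bc1, bc2, sep = "|")

jaccardIndex <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

## Derive a stream-specific 32-bit seed from a master seed.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% .Machine$integer.max
}
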