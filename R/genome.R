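#' Simulate a small diploid hybrid reference genome
#'
#' Generates random chromosome sequences for a first haplotype, then
#' derives the second haplotype by planting heterozygous single-nucleotide
#' substitutions at an average spacing of `variantSpacing` bp (the variant
#' count per chromosome is Poisson with mean `length / variantSpacing`).
#' Variants are never placed inside a TTAA transposon target site, so the
#' listed sites are present on both haplotypes at shared coordinates.
#'
#' @param chromLengths named integer vector of chromosome lengths in bp.
#' @param variantSpacing mean distance in bp between heterozygous variants
#'   (default 150, the density of a BL6xCAST F1 hybrid); `0` or `Inf`
#'   disables variants.
#' @param haplotypeNames two haplotype labels (default `c("BL6", "CAST")`).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a [ShuffleGenome-class] object.
#' @examples
#' g <- simulateReference(c(chr1 = 5e4, chr2 = 5e4), seed = 1)
#' g
#' @export
simulateReference <- function(chromLengths,
                              variantSpacing = 150,
                              haplotypeNames = c("BL6", "CAST"),
                              seed = 1L) {
  stopifnot(length(chromLengths) >= 1L, all(chromLengths >= 100))
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  set.seed(seed)
  hap1 <- character(length(chromLengths))
  hap2 <- character(length(chromLengths))
  sites <- vector("list", length(chromLengths))
  vlist <- vector("list", length(chromLengths))
  for (i in seq_along(chromLengths)) {
    len <- as.integer(chromLengths[i])
    s1 <- paste(sample(DNA_ALPHABET, len, replace = TRUE), collapse = "")
    tt <- Biostrings::start(
      Biostrings::matchPattern("TTAA", Biostrings::DNAString(s1)))
    if (length(tt) == 0L)
      stop("chromosome ", names(chromLengths)[i], " has no TTAA site")
    nvar <- if (variantSpacing <= 0 || !is.finite(variantSpacing)) 0L
            else rpois(1L, len / variantSpacing)
    inMotif <- logical(len)
    inMotif[rep(tt, each = 4L) + rep(0:3, times = length(tt))] <- TRUE
    free <- which(!inMotif)
    nvar <- min(nvar, length(free))
    vpos <- if (nvar > 0L) sort(sample(free, nvar)) else integer(0)
    ref <- if (nvar > 0L) substring(s1, vpos, vpos) else character(0)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_ALPHABET, b), 1L),
                  character(1), USE.NAMES = FALSE)
    d1 <- Biostrings::DNAString(s1)
    d2 <- if (nvar > 0L)
      Biostrings::replaceLetterAt(d1, vpos, paste(alt, collapse = ""))
    else d1
    hap1[i] <- s1
    hap2[i] <- as.character(d2)
    sites[[i]] <- tt
    vlist[[i]] <- data.frame(chrom = rep(names(chromLengths)[i], nvar),
                             pos = vpos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE)
  }
  names(sites) <- names(chromLengths)
  variants <- do.call(rbind, vlist)
  rownames(variants) <- NULL
  haps <- list(Biostrings::DNAStringSet(stats::setNames(hap1, names(chromLengths))),
               Biostrings::DNAStringSet(stats::setNames(hap2, names(chromLengths))))
  names(haps) <- haplotypeNames
  new("ShuffleGenome", haplotypes = haps, haplotypeNames = haplotypeNames,
      variants = variants, ttaaSites = sites, seed = as.integer(seed))
}

## Character sequence of one chromosome of one haplotype.
haplotypeSeq <- function(genome, haplotype, chrom) {
  as.character(genome@haplotypes[[haplotype]][[chrom]])
}

## Vectorised substring extraction from one haplotype across chromosomes.
genomeSlices <- function(genome, haplotype, chrom, start, end) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- as.character(genome@haplotypes[[haplotype]][[ch]])
    out[idx] <- substring(s, start[idx], end[idx])
  }
  out
}
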