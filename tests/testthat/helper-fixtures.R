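## Small fixture builders shared across test files. All fixtures are
## generated in code under fixed seeds; nothing is read from disk.

smallGenome <- function(seed = 7L, nChrom = 2L, len = 2e5) {
  lens <- stats::setNames(rep(len, nChrom), paste0("chr", seq_len(nChrom)))
  simulateReference(lens, seed = seed)
}

smallSim <- function(nClones = 5L, insertionsPerClone = 10L, cisRate = 0,
                     transRate = 0, seed = 5L, lambda = 1e5) {
  simulateShuffleExperiment(chromLengths = c(chr1 = 2e5, chr2 = 2e5),
                            nClones = nClones,
                            insertionsPerClone = insertionsPerClone,
                            cisRate = cisRate, transRate = transRate,
                            cisDecayLambda = lambda, seed = seed)
}

## A minimal hand-built insertion table for geometry tests.
toyInsertions <- function(orientation = c("top-CS2", "top-CS2"),
                          chrom = c("chr1", "chr1"),
                          pos = c(1000L, 1100L),
                          allele = c("BL6", "BL6")) {
  n <- length(pos)
  data.frame(insertion_id = sprintf("ins%d", seq_len(n)),
             clone_id = "clone001", chrom = chrom, pos = pos,
             orientation = orientation, allele = allele,
             bc1 = vapply(seq_len(n), function(i)
               strrep(c("A", "C", "G", "T")[(i - 1L) %% 4L + 1L], 20L),
               character(1)),
             bc2 = vapply(seq_len(n), function(i)
               paste0(strrep("A", 10L),
                      strrep(c("T", "G", "C", "A")[(i - 1L) %% 4L + 1L],
                             10L)),
               character(1)),
             stringsAsFactors = FALSE)
}

## one-event table in a fixed register
toyEvent <- function(register = "direct", class = "deletion") {
  data.frame(event_id = "ev00001", clone_id = "clone001",
             insertion_a = "ins1", insertion_b = "ins2",
             register = register, resolved_class = class,
             distance = 100L, stringsAsFactors = FALSE)
}

## brute-force single-linkage components (independent oracle)
bruteComponents <- function(d, threshold) {
  n <- nrow(d)
  adj <- d <= threshold
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

randomBc <- function(width) {
  paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
        collapse = "")
}

## random barcode-like strings with controlled perturbations
mutateString <- function(x, nSub) {
  for (k in seq_len(nSub)) {
    p <- sample(nchar(x), 1L)
    old <- substr(x, p, p)
    substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  x
}
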