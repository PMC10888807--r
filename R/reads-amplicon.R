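#' Emit barcode-pair amplicon reads
#'
#' Simulates PCR amplicon sequencing of cassette barcode pairs. Only
#' PCR-detectable templates (one CS2 and one CS1 side) are amplified:
#' all parental cassettes and the detectable derivative cassettes of the
#' requested events. Each template yields `moleculesPerCassette` tagged
#' molecules carrying `umisPerMolecule` UMIs each, and every UMI is
#' observed as `readsPerUmi` reads. Chimeric PCR is modelled by swapping
#' the CS1-side barcode of a read with that of another co-amplified
#' molecule at `chimeraRate`; chimeric reads are flagged in the truth
#' column. In the 4-primer dialect every template additionally appears
#' under both amplicon types (`top-CS2` and `bottom-CS1` strands).
#'
#' @param sim a [ShuffleSim-class].
#' @param dialect `"two_primer"` or `"four_primer"`.
#' @param moleculesPerCassette molecules per template per replicate.
#' @param umisPerMolecule UMIs per molecule.
#' @param readsPerUmi reads per UMI.
#' @param chimeraRate per-read probability of a barcode-2 swap.
#' @param includeDerivatives include detectable derivative cassettes
#'   (post-Cre sample) or parental cassettes only.
#' @param sampleId,replicateId labels stamped on every read.
#' @param seed integer seed.
#' @return data.frame of read records: bc1, bc2, umi, amplicon_type,
#'   sample_id, replicate_id, truth_template, truth_chimera.
#' @export
emitAmpliconReads <- function(sim, dialect = c("two_primer", "four_primer"),
                              moleculesPerCassette = 40L,
                              umisPerMolecule = 1L, readsPerUmi = 2L,
                              chimeraRate = 0, includeDerivatives = TRUE,
                              sampleId = "sample1", replicateId = "rep1",
                              seed = 1L) {
  dialect <- match.arg(dialect)
  stopifnot(chimeraRate >= 0, chimeraRate <= 1, moleculesPerCassette >= 1)
  set.seed(seed)
  templates <- data.frame(template = sim@insertions$insertion_id,
                          bc1 = sim@insertions$bc1,
                          bc2 = sim@insertions$bc2,
                          stringsAsFactors = FALSE)
  if (includeDerivatives && nrow(sim@derivatives)) {
    det <- sim@derivatives[sim@derivatives$detectable, , drop = FALSE]
    if (nrow(det))
      templates <- rbind(templates, data.frame(
        template = paste0(det$event_id, ".p", det$product),
        bc1 = det$bc1, bc2 = det$bc2, stringsAsFactors = FALSE))
  }
  nT <- nrow(templates)
  if (nT == 0L) return(emptyAmpliconReads())
  nMol <- nT * moleculesPerCassette
  mol <- templates[rep(seq_len(nT), each = moleculesPerCassette), ,
                   drop = FALSE]
  mol$umiBase <- seq_len(nMol)
  umis <- randomDnaStrings(nMol * umisPerMolecule, 10L)
  rec <- mol[rep(seq_len(nMol), each = umisPerMolecule), , drop = FALSE]
  rec$umi <- umis
  reads <- rec[rep(seq_len(nrow(rec)), each = readsPerUmi), , drop = FALSE]
  types <- if (dialect == "four_primer") c("top-CS2", "bottom-CS1") else
    "top-CS2"
  reads <- reads[rep(seq_len(nrow(reads)), times = length(types)), ,
                 drop = FALSE]
  reads$amplicon_type <- rep(types, each = nrow(reads) / length(types))
  chim <- runif(nrow(reads)) < chimeraRate
  if (any(chim)) {
    donors <- sample(nrow(reads), sum(chim), replace = TRUE)
    ## resample donors that would reproduce the same template
    same <- reads$template[donors] == reads$template[chim]
    while (any(same) && nT > 1L) {
      donors[same] <- sample(nrow(reads), sum(same), replace = TRUE)
      same <- reads$template[donors] == reads$template[which(chim)]
    }
    reads$bc2[chim] <- reads$bc2[donors]
  }
  out <- data.frame(bc1 = reads$bc1, bc2 = reads$bc2, umi = reads$umi,
                    amplicon_type = reads$amplicon_type,
                    sample_id = sampleId, replicate_id = replicateId,
                    truth_template = reads$template,
                    truth_chimera = chim, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

emptyAmpliconReads <- function() {
  data.frame(bc1 = character(0), bc2 = character(0), umi = character(0),
             amplicon_type = character(0), sample_id = character(0),
             replicate_id = character(0), truth_template = character(0),
             truth_chimera = logical(0), stringsAsFactors = FALSE)
}
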