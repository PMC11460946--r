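#' Annotate the membrane topology of one protein
#'
#' Interprets a per-residue topology string over the alphabet `i`
#' (cytoplasmic), `o` (extracellular), `M` (membrane), `S` (signal
#' peptide) and classifies the protein:
#' \itemize{
#'   \item `no_tm` — no membrane segment;
#'   \item `single_pass_type_I` — one membrane segment, C-terminal side
#'     cytoplasmic, N-terminal side extracellular or signal peptide;
#'   \item `single_pass_type_II` — one membrane segment, N-terminal side
#'     cytoplasmic;
#'   \item `multi_pass` — two or more membrane segments.
#' }
#' The signal-peptide state `S` counts as the non-cytoplasmic side for
#' classification and is never intracellular.
#'
#' @param protein_id Identifier carried into the result.
#' @param residue_states Topology string, same length as `sequence`.
#' @param sequence Amino-acid string.
#' @return An object of class `topology_annotation`: list with
#'   `protein_id`, `residue_states`, `tm_segments` (two-column matrix of
#'   1-based closed intervals, one row per maximal `M` run), and
#'   `protein_class`.
#' @examples
#' annotate_topology("P1", "oooooMMMMMiiiii", "MKWLTAGSDYSELQA")$protein_class
#' @export
annotate_topology <- function(protein_id, residue_states, sequence) {
  if (nchar(residue_states) != nchar(sequence)) {
    stop("topology string length (", nchar(residue_states),
         ") does not match sequence length (", nchar(sequence),
         ") for ", protein_id)
  }
  states <- strsplit(residue_states, "", fixed = TRUE)[[1]]
  bad <- which(!(states %in% c("i", "o", "M", "S")))
  if (length(bad) > 0L) {
    stop("topology string for '", protein_id, "' has invalid character '",
         states[bad[1]], "' at position ", bad[1])
  }
  runs <- rle(states)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  m_runs <- which(runs$values == "M")
  tm <- cbind(start = starts[m_runs], end = ends[m_runs])
  if (length(m_runs) == length(runs$values) && length(m_runs) > 0L) {
    stop("all-membrane topology string for '", protein_id,
         "': no flanking state to classify")
  }
  n_tm <- nrow(tm)
  if (n_tm == 0L) {
    cls <- "no_tm"
  } else if (n_tm >= 2L) {
    cls <- "multi_pass"
  } else {
    # orientation from the state immediately N-terminal of the single TM
    # segment: cytoplasmic N-terminus -> type II, extracellular or signal
    # peptide (or the TM starting at residue 1) -> type I
    n_side <- if (tm[1, "start"] > 1L) states[tm[1, "start"] - 1L] else NA_character_
    cls <- if (identical(n_side, "i")) "single_pass_type_II" else "single_pass_type_I"
  }
  structure(
    list(protein_id = protein_id, residue_states = residue_states,
         tm_segments = tm, protein_class = cls),
    class = "topology_annotation"
  )
}

#' Extract the intracellular domains of a protein
#'
#' Returns one row per maximal run of cytoplasmic (`i`) residues, in N- to
#' C-terminal order, with 1-based closed coordinates and the corresponding
#' subsequence.
#'
#' @param annotation A [annotate_topology()] result.
#' @param sequence The protein sequence the annotation refers to.
#' @return Data.frame with columns `protein_id`, `domain_index`, `start`,
#'   `end`, `sequence`. Zero rows if the protein has no cytoplasmic
#'   residues.
#' @export
extract_intracellular_domains <- function(annotation, sequence) {
  stopifnot(inherits(annotation, "topology_annotation"))
  if (nchar(annotation$residue_states) != nchar(sequence)) {
    stop("sequence length does not match annotation for ",
         annotation$protein_id)
  }
  states <- strsplit(annotation$residue_states, "", fixed = TRUE)[[1]]
  runs <- rle(states)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values == "i")
  if (length(keep) == 0L) {
    return(data.frame(protein_id = character(0), domain_index = integer(0),
                      start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    protein_id = rep(annotation$protein_id, length(keep)),
    domain_index = seq_along(keep),
    start = starts[keep],
    end = ends[keep],
    sequence = substring(sequence, starts[keep], ends[keep]),
    stringsAsFactors = FALSE
  )
}

#' Keep only motif hits that are fully intracellular
#'
#' A hit is retained only when all six of its residues are in cytoplasmic
#' (`i`) state — the strictest reading of "the motif lies in an
#' intracellular section", which excludes membrane-embedded tyrosines.
#'
#' @param hits Data.frame from [scan_motifs()].
#' @param annotation A [annotate_topology()] result for the same protein.
#' @return The subset of `hits` whose residues are all intracellular.
#' @export
filter_intracellular_motifs <- function(hits, annotation) {
  stopifnot(inherits(annotation, "topology_annotation"))
  states <- strsplit(annotation$residue_states, "", fixed = TRUE)[[1]]
  if (nrow(hits) > 0L && max(hits$end) > length(states)) {
    stop("motif hit at ", hits$start[which.max(hits$end)],
         " extends beyond topology annotation for ", annotation$protein_id)
  }
  keep <- vapply(seq_len(nrow(hits)), function(k) {
    all(states[hits$start[k]:hits$end[k]] == "i")
  }, logical(1))
  hits[keep, , drop = FALSE]
}

#' Exclude proteins above a maximum length
#'
#' Very large proteins are not feasible for consensus membrane-topology
#' prediction and are set aside before the scan. The boundary is
#' inclusive: a protein of exactly `max_len` residues is kept.
#'
#' @param records A `protein_set` data.frame.
#' @param max_len Maximum sequence length retained (default 10000).
#' @return List with elements `kept` and `excluded`, both `protein_set`
#'   data.frames.
#' @export
apply_length_filter <- function(records, max_len = 10000L) {
  len <- nchar(records$sequence)
  list(
    kept = records[len <= max_len, , drop = FALSE],
    excluded = records[len > max_len, , drop = FALSE]
  )
}
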