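#' Read per-residue pLDDT values from an AlphaFold-style PDB file
#'
#' AlphaFold writes the per-residue model confidence (pLDDT, 0-100) into
#' the B-factor column of every atom of the residue. This reads the file
#' with \pkg{bio3d}, checks the AlphaFold conventions (single model,
#' single chain, gap-free residue numbering, all atoms of a residue
#' agreeing to within 1e-3) and returns one value per residue, taken from
#' the CA atom (falling back to the residue's first atom, with a warning,
#' if CA is absent).
#'
#' @param path Path to a PDB file with ATOM records.
#' @return Data.frame with columns `residue_index` (1-based, consecutive)
#'   and `plddt`.
#' @export
read_plddt <- function(path) {
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  if (length(unique(atoms$chain)) > 1L) {
    stop("multi-chain structure in ", path,
         " (only AlphaFold monomer models are supported)")
  }
  resno <- atoms$resno
  ures <- unique(resno)
  if (any(diff(ures) != 1L)) {
    stop("residue-number gap in ", path,
         " (AlphaFold models are gap-free)")
  }
  plddt <- numeric(length(ures))
  for (k in seq_along(ures)) {
    ra <- atoms[resno == ures[k], , drop = FALSE]
    if (max(ra$b) - min(ra$b) > 1e-3) {
      stop("atoms of residue ", ures[k], " in ", path,
           " disagree on the B-factor pLDDT (spread > 1e-3)")
    }
    ca <- which(ra$elety == "CA")
    if (length(ca) >= 1L) {
      plddt[k] <- ra$b[ca[1]]
    } else {
      warning("residue ", ures[k], " in ", path,
              " has no CA atom; using its first atom")
      plddt[k] <- ra$b[1]
    }
  }
  if (any(plddt < 0 | plddt > 100)) {
    stop("pLDDT values outside [0, 100] in ", path)
  }
  data.frame(residue_index = seq_along(ures), plddt = plddt)
}

#' Mean structure confidence of a motif
#'
#' The confidence score of an ITIM/ITSM is the arithmetic mean pLDDT of
#' its six residues. Low values indicate the motif lies in a likely
#' intrinsically disordered region — accessible to phosphatase
#' recruitment; a mean below 50 additionally sets `disordered_flag`.
#'
#' @param hit One-row data.frame from [scan_motifs()] (uses `start`,
#'   `end`).
#' @param confidences Data.frame from [read_plddt()].
#' @return List with `hit`, `residue_plddts` (length 6), `mean_plddt`,
#'   `disordered_flag` (`mean_plddt < 50`).
#' @export
motif_confidence <- function(hit, confidences) {
  if (hit$end > nrow(confidences)) {
    stop("motif at ", hit$start, "-", hit$end,
         " exceeds structure length ", nrow(confidences),
         " (isoform/structure mismatch?)")
  }
  vals <- confidences$plddt[hit$start:hit$end]
  m <- mean(vals)
  list(hit = hit, residue_plddts = vals, mean_plddt = m,
       disordered_flag = m < 50)
}

#' Structure-confidence filter over a protein's motifs
#'
#' A protein passes when at least one of its motifs has mean pLDDT
#' strictly below `threshold` (default 80): only motifs in
#' low-confidence, likely disordered regions are considered plausibly
#' functional. A motif whose mean is exactly the threshold does not
#' count.
#'
#' @param hits Data.frame of motif hits for one protein.
#' @param confidences Data.frame from [read_plddt()].
#' @param threshold pLDDT cutoff (default 80).
#' @return List with `protein_id`, `motif_confidences` (list of
#'   [motif_confidence()] results), `min_mean_plddt`, `passed`.
#' @export
structural_filter <- function(hits, confidences, threshold = 80) {
  if (nrow(hits) == 0L) stop("structural_filter requires at least one hit")
  mcs <- lapply(seq_len(nrow(hits)), function(k) {
    motif_confidence(hits[k, , drop = FALSE], confidences)
  })
  means <- vapply(mcs, `[[`, numeric(1), "mean_plddt")
  list(
    protein_id = hits$protein_id[1],
    motif_confidences = mcs,
    min_mean_plddt = min(means),
    passed = any(means < threshold)
  )
}
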