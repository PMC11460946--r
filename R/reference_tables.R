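# Packaged reference tables: the 52 previously described ITIM-bearing
# inhibitory receptors used to validate the pipeline, and the published
# functional-category counts for single-spanning receptors per immune cell
# subset.

known_receptor_symbols <- c(
  "BTLA", "CD22", "CD244", "CD300A", "CD300LF", "CD33", "CD5", "CD72",
  "CEACAM1", "CLEC12A", "CLEC12B", "CLEC4A", "FCGR2B", "FCRL2", "FCRL3",
  "FCRL4", "FCRL5", "KIR2DL1", "KIR2DL2", "KIR2DL3", "KIR2DL4", "KIR3DL1",
  "KIR3DL2", "KIR3DL3", "KLRC1", "KLRG1", "LAIR1", "LILRB1", "LILRB2",
  "LILRB3", "LILRB4", "LILRB5", "MPIG6B", "NCR2", "PDCD1", "PECAM1",
  "PILRA", "PVR", "SIGLEC5", "SIGLEC6", "SIGLEC7", "SIGLEC8", "SIGLEC9",
  "SIGLEC10", "SIGLEC11", "SIRPA", "SIT1", "SLAMF6", "TIGIT", "TREML1",
  "VSIG4", "VSTM1"
)

#' Reference set of known ITIM-bearing inhibitory receptors
#'
#' The 52 genes encoding previously described ITIM-bearing immune
#' inhibitory receptors that serve as the pipeline's positive controls
#' (e.g. `PDCD1` encoding PD-1, `LAIR1`, `TIGIT`). `MPIG6B` — the
#' platelet/megakaryocyte receptor G6B — is flagged: its transmembrane
#' helix is mispredicted by consensus topology prediction in the
#' ITIM-bearing isoforms, so it is the one known receptor the topology
#' filter is expected to lose.
#'
#' @return A list with `gene_symbols` (character vector of length 52) and
#'   `flagged` (symbols known not to be recalled; `"MPIG6B"`).
#' @examples
#' ref <- load_known_receptors()
#' length(ref$gene_symbols)  # 52
#' @export
load_known_receptors <- function() {
  list(
    gene_symbols = known_receptor_symbols,
    flagged = "MPIG6B"
  )
}

category_levels <- function() {
  c("not_expressed", "negative_feedback", "threshold_negative_feedback",
    "threshold_disinhibition", "threshold")
}

#' Reference functional-category counts for single-spanning receptors
#'
#' The published breakdown of the 215 single-spanning known-plus-putative
#' inhibitory receptor genes into functional categories for six immune
#' cell subsets. Each row sums to the same 215-gene universe.
#'
#' @return A data.frame with one row per cell type and columns
#'   `cell_type`, `not_expressed`, `negative_feedback`,
#'   `threshold_negative_feedback`, `threshold_disinhibition`,
#'   `threshold`.
#' @examples
#' ref <- load_category_counts()
#' rowSums(ref[, -1])  # all 215
#' @export
load_category_counts <- function() {
  df <- data.frame(
    cell_type = c("Neutrophils", "Monocytes", "NK cells", "B cells",
                  "CD4 T cells", "CD8 T cells"),
    not_expressed = c(78L, 95L, 104L, 104L, 116L, 109L),
    negative_feedback = c(6L, 26L, 17L, 10L, 8L, 9L),
    threshold_negative_feedback = c(3L, 1L, 2L, 0L, 2L, 4L),
    threshold_disinhibition = c(4L, 21L, 11L, 16L, 16L, 15L),
    threshold = c(124L, 72L, 81L, 85L, 73L, 78L),
    stringsAsFactors = FALSE
  )
  df
}
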