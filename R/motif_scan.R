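#' Motif scanning configuration
#'
#' Bundles the residue sets defining the ITIM/ITSM consensus
#' `(V|L|I|S|T)xYxx(I|L|V)` and the ITAM linker range. The classical ITIM
#' consensus restricts position 1 to `V/L/I/S`; allowing `T` extends the
#' search to ITSM (switch) motifs, which some inhibitory receptors (e.g.
#' PD-1) use for inhibitory signalling. Positions 2, 4 and 5 are wildcards.
#'
#' @param pos1_set Characters accepted at motif position 1. Default
#'   `c("V","L","I","S","T")` (ITIM + ITSM). Must contain the core ITIM set
#'   `V,L,I,S`.
#' @param pos6_set Characters accepted at motif position 6. Default
#'   `c("I","L","V")`.
#' @param itam_linker_range Integer pair: admissible number of residues
#'   between the two `Yxx(I|L)` half-sites of an ITAM. Default `c(6L, 12L)`.
#' @return An object of class `motif_config`.
#' @examples
#' cfg <- motif_config()
#' scan_motifs("SDYSEL", cfg)
#' @export
motif_config <- function(pos1_set = c("V", "L", "I", "S", "T"),
                         pos6_set = c("I", "L", "V"),
                         itam_linker_range = c(6L, 12L)) {
  pos1_set <- toupper(as.character(pos1_set))
  pos6_set <- toupper(as.character(pos6_set))
  if (!all(c("V", "L", "I", "S") %in% pos1_set)) {
    stop("pos1_set must contain the core ITIM residues V, L, I, S")
  }
  if (length(itam_linker_range) != 2L || itam_linker_range[1] > itam_linker_range[2]) {
    stop("itam_linker_range must be a non-empty integer pair (lo, hi)")
  }
  structure(
    list(
      pos1_set = pos1_set,
      pos6_set = pos6_set,
      itam_linker_range = as.integer(itam_linker_range)
    ),
    class = "motif_config"
  )
}

# Internal: scan a character vector for consensus windows.
# Returns 1-based start positions. Constrained positions (1, 3, 6) never
# match ambiguity codes X/U because those letters are not members of the
# residue sets and 'Y' is tested literally; wildcard positions accept
# anything.
scan_chars <- function(chars, config) {
  n <- length(chars)
  if (n < 6L) return(integer(0))
  p <- seq_len(n - 5L)
  which(chars[p] %in% config$pos1_set &
          chars[p + 2L] == "Y" &
          chars[p + 5L] %in% config$pos6_set)
}

#' Scan a protein sequence for ITIM/ITSM motifs
#'
#' Reports every 6-residue window matching the consensus
#' `(V|L|I|S|T)xYxx(I|L|V)`: position 1 in `pos1_set`, a tyrosine at
#' position 3, position 6 in `pos6_set`. Overlapping windows are all
#' reported as distinct hits. A hit is labelled `ITSM` when its first
#' residue is `T`, otherwise `ITIM`; the two classes are treated
#' identically downstream.
#'
#' @param sequence Amino-acid string (uppercase one-letter code; ambiguity
#'   codes `X`/`U` are tolerated but never satisfy a constrained position).
#' @param config A [motif_config()].
#' @param protein_id Optional identifier copied into the result.
#' @return A data.frame with one row per hit, columns `protein_id`, `start`,
#'   `end` (= start + 5), `tyrosine_pos` (= start + 2), `subsequence`,
#'   `motif_class` (`"ITIM"` or `"ITSM"`), `itam_embedded` (initialised
#'   `FALSE`; see [scan_itam_embedded()]). Rows are ordered by `start`.
#'   Coordinates are 1-based closed intervals.
#' @examples
#' scan_motifs("VAYAVLYAAV")  # two overlapping hits
#' @export
scan_motifs <- function(sequence, config = motif_config(), protein_id = NA_character_) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  starts <- scan_chars(chars, config)
  hits <- data.frame(
    protein_id = rep(protein_id, length(starts)),
    start = starts,
    end = starts + 5L,
    tyrosine_pos = starts + 2L,
    subsequence = vapply(starts, function(s) paste(chars[s:(s + 5L)], collapse = ""),
                         character(1)),
    motif_class = ifelse(chars[starts] == "T", "ITSM", "ITIM"),
    itam_embedded = rep(FALSE, length(starts)),
    stringsAsFactors = FALSE
  )
  if (nrow(hits) == 0L) {
    hits$motif_class <- character(0)
    hits$subsequence <- character(0)
  }
  hits[order(hits$start), , drop = FALSE]
}

#' Flag ITIM/ITSM hits embedded in an ITAM
#'
#' An ITAM is `Yxx(I|L) x(6-12) Yxx(I|L)`: two tyrosine half-sites whose
#' third following residue is I or L, separated by 6 to 12 intervening
#' residues (counted between the end of the first half-site and the second
#' tyrosine). A motif hit is flagged when its tyrosine is either tyrosine
#' of a spacing-valid ITAM. The flag is an annotation only — ITAM-bearing
#' molecules are not necessarily inhibitory — and is never used as a
#' filter.
#'
#' @param sequence The amino-acid string the hits were scanned from.
#' @param hits Data.frame from [scan_motifs()] on the same sequence.
#' @param config A [motif_config()]; only `itam_linker_range` is used.
#' @return `hits` with the `itam_embedded` column updated.
#' @export
scan_itam_embedded <- function(sequence, hits, config = motif_config()) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  half <- c("I", "L")
  # tyrosines beginning a valid Yxx(I|L) half-site
  ys <- which(chars == "Y")
  ys <- ys[ys + 3L <= n & chars[pmin(ys + 3L, n)] %in% half]
  itam_y <- integer(0)
  if (length(ys) >= 2L) {
    lo <- config$itam_linker_range[1]
    hi <- config$itam_linker_range[2]
    for (a in seq_len(length(ys) - 1L)) {
      for (b in (a + 1L):length(ys)) {
        linker <- ys[b] - (ys[a] + 3L) - 1L
        if (linker >= lo && linker <= hi) itam_y <- c(itam_y, ys[a], ys[b])
      }
    }
  }
  hits$itam_embedded <- hits$tyrosine_pos %in% itam_y
  hits
}

#' Count consensus motifs across a set of domain sequences
#'
#' Sums the number of consensus windows over the given sequences. Motifs
#' never span a boundary between two sequences: each domain is scanned
#' independently. This is the counter used both for observed intracellular
#' motif counts and inside the permutation null, so the permutation
#' statistic is internally consistent.
#'
#' @param domains Character vector of amino-acid strings (e.g. the
#'   intracellular domains of one protein).
#' @param config A [motif_config()].
#' @return Integer: total number of matching windows.
#' @examples
#' count_motifs_in_domains(c("SDYSEL", "TEYSTV"))  # 2
#' count_motifs_in_domains(c("SDY", "SEL"))        # 0, no window spans
#' @export
count_motifs_in_domains <- function(domains, config = motif_config()) {
  if (length(domains) == 0L) return(0L)
  sum(vapply(domains, function(d) {
    length(scan_chars(strsplit(d, "", fixed = TRUE)[[1]], config))
  }, integer(1), USE.NAMES = FALSE))
}
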