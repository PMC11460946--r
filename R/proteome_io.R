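#' Read a protein FASTA file with optional gene/transcript metadata
#'
#' Parses an amino-acid FASTA into a proteome table. The protein identifier
#' is the first whitespace-delimited token of each header. A trailing stop
#' codon (`*`) is stripped from every sequence. If a metadata TSV is given
#' it is joined on `protein_id`; entries without a metadata row get empty
#' gene fields.
#'
#' @param path Path to the FASTA file.
#' @param metadata Optional path to a TSV with columns `protein_id`,
#'   `transcript_id`, `gene_id`, `gene_symbol` (additional columns such as
#'   `canonical` are carried through).
#' @return A data.frame of class `protein_set` with columns `protein_id`,
#'   `transcript_id`, `gene_id`, `gene_symbol`, `sequence`.
#' @export
read_protein_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && nzchar(trimws(first)) && !grepl("^>", first)) {
    stop("malformed FASTA: sequence data before first header ('",
         substr(first, 1, 40), "')")
  }
  aa <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXU]", seqs)
  if (any(bad)) {
    stop("malformed FASTA: entry '", ids[which(bad)[1]],
         "' contains characters outside the amino-acid alphabet")
  }
  if (any(nchar(seqs) == 0L)) {
    stop("malformed FASTA: entry '", ids[which(nchar(seqs) == 0L)[1]],
         "' has an empty sequence")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in FASTA: ", ids[duplicated(ids)][1])
  }
  recs <- data.frame(protein_id = ids, sequence = unname(seqs),
                     stringsAsFactors = FALSE)
  recs$transcript_id <- ""
  recs$gene_id <- ""
  recs$gene_symbol <- ""
  if (!is.null(metadata)) {
    meta <- utils::read.delim(metadata, stringsAsFactors = FALSE,
                              colClasses = "character")
    need <- c("protein_id", "transcript_id", "gene_id", "gene_symbol")
    if (!all(need %in% names(meta))) {
      stop("metadata TSV must have columns: ", paste(need, collapse = ", "))
    }
    m <- match(recs$protein_id, meta$protein_id)
    for (col in setdiff(names(meta), "protein_id")) {
      vals <- meta[[col]][m]
      vals[is.na(vals)] <- ""
      recs[[col]] <- vals
    }
  }
  recs <- recs[, c("protein_id", "transcript_id", "gene_id", "gene_symbol",
                   "sequence",
                   setdiff(names(recs), c("protein_id", "transcript_id",
                                          "gene_id", "gene_symbol", "sequence")))]
  class(recs) <- c("protein_set", "data.frame")
  recs
}

#' Write a proteome table to FASTA
#'
#' @param records A data.frame with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(records$sequence,
                                                records$protein_id))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read per-residue membrane-topology annotation
#'
#' Accepts either a two-column TSV (`protein_id`, per-residue string) or a
#' FASTA-like block format (`>id` followed by the topology string). The
#' per-residue alphabet is the TOPCONS one: `i` cytoplasmic ("inside"),
#' `o` extracellular, `M` membrane, `S` signal peptide. Other topology
#' dialects must be mapped to this alphabet by the caller.
#'
#' @param path Path to the topology file.
#' @return Named character vector: `protein_id` -> topology string.
#' @export
read_topology_file <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  if (grepl("^>", lines[1])) {
    hdr <- grepl("^>", lines)
    grp <- cumsum(hdr)
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
    strs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
    strs <- unname(strs[as.character(seq_along(ids))])
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L)) {
      stop("topology TSV: line without two tab-separated fields: '",
           lines[which(lengths(parts) < 2L)[1]], "'")
    }
    ids <- vapply(parts, `[`, character(1), 1L)
    strs <- vapply(parts, `[`, character(1), 2L)
    if (identical(ids[1], "protein_id")) {  # optional header row
      ids <- ids[-1]; strs <- strs[-1]
    }
  }
  for (k in seq_along(strs)) {
    bad <- regexpr("[^ioMS]", strs[k])
    if (bad > 0L) {
      stop("topology string for '", ids[k], "' has invalid character '",
           substr(strs[k], bad, bad), "' at position ", bad,
           " (alphabet is {i,o,M,S})")
    }
  }
  stats::setNames(strs, ids)
}

#' Write a topology map as a two-column TSV
#'
#' @param topology Named character vector as returned by
#'   [read_topology_file()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_file <- function(topology, path) {
  utils::write.table(
    data.frame(protein_id = names(topology), topology = unname(topology)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Canonical column order for the candidate table serialisation.
candidate_columns <- function() {
  c("gene_symbol", "gene_id", "protein_id", "protein_class", "n_motifs",
    "motif_starts", "motif_classes", "observed_count", "likelihood",
    "epsilon", "likelihood_passed", "min_motif_plddt", "structure_status",
    "structure_passed", "known_receptor", "final_candidate", "failed_stage")
}

#' Write a candidate table to TSV
#'
#' Serialises a pipeline candidate table with a stable column order and a
#' deterministic row order (by `gene_symbol`, then `protein_id`), so that
#' repeated runs with the same seed are byte-identical.
#'
#' @param candidates A `candidate_table` from [run_pipeline()], or any
#'   data.frame with the candidate columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  df <- as.data.frame(candidates)
  cols <- intersect(candidate_columns(), names(df))
  df <- df[, cols, drop = FALSE]
  o <- order(df$gene_symbol, df$protein_id, method = "radix")
  df <- df[o, , drop = FALSE]
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (col in names(df)[num]) {
    df[[col]] <- vapply(df[[col]], function(x) {
      if (is.na(x)) "NA" else sprintf("%.17g", x)
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by [write_candidate_table()]
#'
#' @param path Path to the TSV.
#' @return A data.frame with the candidate columns.
#' @export
read_candidate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("gene_symbol", "gene_id", "protein_id", "motif_starts",
                "motif_classes", "structure_status", "failed_stage")) {
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  }
  df
}
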