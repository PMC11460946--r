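#' Pipeline configuration
#'
#' Collects every tunable constant of the screening pipeline with its
#' default: proteins longer than 10,000 residues are excluded, the
#' permutation null uses 10,000 shuffles, the chance-likelihood inclusion
#' threshold is 0.25 + epsilon with epsilon ~ Uniform[0, 0.01), motifs
#' count as plausibly functional below 80 pLDDT, and expression dynamics
#' are partitioned at 0.5 log2 fold change.
#'
#' @param motif A [motif_config()].
#' @param max_protein_length Length-filter cap (default 10000).
#' @param n_permutations Shuffles per protein (default 10000).
#' @param likelihood_base Base inclusion threshold (default 0.25).
#' @param epsilon_max Upper bound of the threshold jitter (default 0.01).
#' @param plddt_threshold Structure-confidence cutoff (default 80).
#' @param log2fc_threshold Expression fold-change cutoff (default 0.5).
#' @param seed RNG seed for the run (default 1).
#' @param shuffle_mode Permutation shuffle mode, see
#'   [permutation_likelihood()].
#' @param call_mode Expression call mode, see [classify_expression()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(motif = motif_config(),
                            max_protein_length = 10000L,
                            n_permutations = 10000L,
                            likelihood_base = 0.25,
                            epsilon_max = 0.01,
                            plddt_threshold = 80,
                            log2fc_threshold = 0.5,
                            seed = 1L,
                            shuffle_mode = "per-domain",
                            call_mode = "condition-mean") {
  stopifnot(max_protein_length > 0, n_permutations >= 1,
            likelihood_base > 0, epsilon_max >= 0,
            plddt_threshold > 0, log2fc_threshold > 0)
  structure(
    list(motif = motif, max_protein_length = as.integer(max_protein_length),
         n_permutations = as.integer(n_permutations),
         likelihood_base = likelihood_base, epsilon_max = epsilon_max,
         plddt_threshold = plddt_threshold,
         log2fc_threshold = log2fc_threshold, seed = seed,
         shuffle_mode = shuffle_mode, call_mode = call_mode),
    class = "pipeline_config"
  )
}

stage_names <- function() {
  c("input", "length_filter", "motif_scan", "topology_filter",
    "permutation_filter", "structure_filter")
}

#' Run the inhibitory-receptor discovery pipeline
#'
#' Executes the full screen over a proteome: length filter, ITIM/ITSM
#' motif scan (with ITAM-embedding annotation), membrane-topology filter
#' (integral membrane proteins with at least one fully intracellular
#' motif), composition-preserving permutation filter, structure-
#' confidence filter, and — when expression data are supplied —
#' functional-category classification of the surviving genes.
#'
#' Proteins that pass the permutation filter but have no structure are
#' retained with status `"no-structure"` rather than dropped. A gene is
#' a final candidate when at least one of its isoforms survives every
#' stage; per gene the best isoform is the one with the lowest
#' permutation likelihood (ties broken by lowest minimum motif pLDDT,
#' then by protein id).
#'
#' @param records A `protein_set` data.frame ([read_protein_fasta()] or
#'   [make_synthetic_proteome()]).
#' @param topology Named character vector of per-residue topology strings
#'   ([read_topology_file()]).
#' @param structures Either a directory containing `<protein_id>.pdb`
#'   files, or a named list of [read_plddt()]-style data.frames, or
#'   `NULL` (all proteins carried as `"no-structure"`).
#' @param expression Optional `expression_matrix` for the functional
#'   categories.
#' @param config A [pipeline_config()].
#' @return An object of class `candidate_table`: a data.frame with one
#'   row per protein that reached the motif-scan stage with at least one
#'   hit, plus attributes `stage_counts` (per-stage protein and gene
#'   survivor counts), `expression_calls` (when expression was given)
#'   and `config`.
#' @export
run_pipeline <- function(records, topology, structures = NULL,
                         expression = NULL, config = pipeline_config()) {
  if (nrow(records) == 0L) stop("empty proteome")
  set.seed(config$seed)
  known <- load_known_receptors()$gene_symbols
  notes <- character(0)

  genes_of <- function(ids) {
    unique(records$gene_symbol[records$protein_id %in% ids])
  }
  counts <- list()
  mark <- function(stage, ids) {
    counts[[stage]] <<- c(proteins = length(ids), genes = length(genes_of(ids)))
  }
  mark("input", records$protein_id)

  lf <- apply_length_filter(records, config$max_protein_length)
  kept <- lf$kept
  mark("length_filter", kept$protein_id)

  rows <- list()
  survivors <- character(0)
  for (k in seq_len(nrow(kept))) {
    id <- kept$protein_id[k]
    seqk <- kept$sequence[k]
    hits <- scan_motifs(seqk, config$motif, protein_id = id)
    if (nrow(hits) == 0L) next
    hits <- scan_itam_embedded(seqk, hits, config$motif)
    row <- list(
      gene_symbol = kept$gene_symbol[k], gene_id = kept$gene_id[k],
      protein_id = id, protein_class = NA_character_,
      n_motifs = nrow(hits),
      motif_starts = paste(hits$start, collapse = ","),
      motif_classes = paste(hits$motif_class, collapse = ","),
      observed_count = NA_integer_, likelihood = NA_real_,
      epsilon = NA_real_, likelihood_passed = NA,
      min_motif_plddt = NA_real_, structure_status = "not_reached",
      structure_passed = NA, known_receptor = kept$gene_symbol[k] %in% known,
      final_candidate = FALSE, failed_stage = ""
    )
    if (!(id %in% names(topology))) {
      notes <- c(notes, paste0("no topology for ", id))
      row$failed_stage <- "topology_filter"
      rows[[id]] <- row
      next
    }
    ann <- annotate_topology(id, topology[[id]], seqk)
    row$protein_class <- ann$protein_class
    ic_hits <- filter_intracellular_motifs(hits, ann)
    if (ann$protein_class == "no_tm" || nrow(ic_hits) == 0L) {
      row$failed_stage <- "topology_filter"
      rows[[id]] <- row
      next
    }
    domains <- extract_intracellular_domains(ann, seqk)
    pr <- permutation_likelihood(
      domains$sequence,
      n_permutations = config$n_permutations, config = config$motif,
      shuffle_mode = config$shuffle_mode, protein_id = id,
      threshold_base = config$likelihood_base,
      epsilon_max = config$epsilon_max)
    row$observed_count <- pr$observed_count
    row$likelihood <- pr$likelihood
    row$epsilon <- pr$epsilon
    row$likelihood_passed <- pr$passed
    if (!pr$passed) {
      row$failed_stage <- "permutation_filter"
      rows[[id]] <- row
      next
    }
    conf <- pipeline_structure(id, structures)
    if (is.null(conf)) {
      row$structure_status <- "no-structure"
      survivors <- c(survivors, id)
      row$final_candidate <- TRUE
      rows[[id]] <- row
      next
    }
    sf <- structural_filter(ic_hits, conf, config$plddt_threshold)
    row$structure_status <- "scored"
    row$min_motif_plddt <- sf$min_mean_plddt
    row$structure_passed <- sf$passed
    if (!sf$passed) {
      row$failed_stage <- "structure_filter"
      rows[[id]] <- row
      next
    }
    row$final_candidate <- TRUE
    survivors <- c(survivors, id)
    rows[[id]] <- row
  }
  tbl <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(tbl)) stop("no protein carries any motif; nothing to report")
  rownames(tbl) <- NULL

  scanned <- tbl$protein_id
  mark("motif_scan", scanned)
  mark("topology_filter", tbl$protein_id[tbl$failed_stage != "topology_filter"])
  after_perm <- tbl$protein_id[!(tbl$failed_stage %in%
                                   c("topology_filter", "permutation_filter"))]
  mark("permutation_filter", after_perm)
  mark("structure_filter", survivors)

  expr_calls <- NULL
  if (!is.null(expression)) {
    expr_calls <- classify_expression(
      expression, genes = unique(tbl$gene_symbol[tbl$final_candidate]),
      log2fc_threshold = config$log2fc_threshold,
      call_mode = config$call_mode)
  }

  stage_counts <- do.call(rbind, counts[stage_names()])
  structure(
    tbl,
    stage_counts = stage_counts,
    expression_calls = expr_calls,
    notes = notes,
    config = config,
    class = c("candidate_table", "data.frame")
  )
}

# Resolve a protein's structure confidences from a directory of PDB
# files or a pre-loaded named list; NULL when unavailable.
pipeline_structure <- function(id, structures) {
  if (is.null(structures)) return(NULL)
  if (is.character(structures) && length(structures) == 1L) {
    path <- file.path(structures, paste0(id, ".pdb"))
    if (!file.exists(path)) return(NULL)
    return(read_plddt(path))
  }
  if (id %in% names(structures)) return(structures[[id]])
  NULL
}

#' Per-stage survivor counts
#'
#' @param table A `candidate_table` from [run_pipeline()].
#' @return Matrix with one row per stage and columns `proteins`, `genes`;
#'   counts are monotone non-increasing along the stages.
#' @export
stage_report <- function(table) {
  stopifnot(inherits(table, "candidate_table"))
  attr(table, "stage_counts")
}

#' Gene-level summary of a candidate table
#'
#' Aggregates isoform rows to one row per gene: a gene is a final
#' candidate when any isoform survives all stages; the reported isoform
#' is the best-scoring one (lowest permutation likelihood, then lowest
#' minimum motif pLDDT, then protein id).
#'
#' @param table A `candidate_table`.
#' @return Data.frame with one row per gene.
#' @export
gene_summary <- function(table) {
  stopifnot(inherits(table, "candidate_table"))
  df <- as.data.frame(table)
  out <- lapply(split(df, df$gene_symbol), function(g) {
    cand <- g[g$final_candidate, , drop = FALSE]
    pool <- if (nrow(cand) > 0L) cand else g
    o <- order(pool$likelihood, pool$min_motif_plddt, pool$protein_id,
               na.last = TRUE, method = "radix")
    best <- pool[o[1], , drop = FALSE]
    best$final_candidate <- nrow(cand) > 0L
    best
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene_symbol, method = "radix"), , drop = FALSE]
}

#' @export
print.candidate_table <- function(x, ...) {
  sc <- attr(x, "stage_counts")
  cat("Inhibitory-receptor candidate table\n")
  cat(sprintf("  %d proteins scanned, %d final candidates (%d genes)\n",
              nrow(x), sum(x$final_candidate),
              length(unique(x$gene_symbol[x$final_candidate]))))
  cat("  stage survivors (proteins/genes):\n")
  for (s in rownames(sc)) {
    cat(sprintf("    %-18s %5d / %d\n", s, sc[s, "proteins"], sc[s, "genes"]))
  }
  invisible(x)
}

#' @method summary candidate_table
#' @export
summary.candidate_table <- function(object, ...) {
  print(object)
  calls <- attr(object, "expression_calls")
  if (!is.null(calls)) {
    cat("  functional categories of candidate genes:\n")
    tab <- table(calls$cell_type, calls$category)
    print(tab)
  }
  invisible(object)
}
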