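# Seed-reproducible synthetic fixtures: proteomes with planted motifs and
# known topology, AlphaFold-convention PDB files with prescribed pLDDT
# profiles, and expression matrices with planted functional categories.
# All generators are pure functions of (parameters, seed).

aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Rejection step: replace the tyrosine of any consensus window that is
# not protected (planted) with a non-tyrosine draw, until no accidental
# window remains.
clean_windows <- function(chars, config = motif_config(), protect = integer(0)) {
  non_y <- setdiff(aa_alphabet(), "Y")
  repeat {
    starts <- scan_chars(chars, config)
    starts <- starts[!((starts + 2L) %in% protect)]
    if (length(starts) == 0L) break
    chars[starts + 2L] <- sample(non_y, length(starts), replace = TRUE)
  }
  chars
}

# Background residues: uniform over the 20 amino acids, then the
# rejection step removes accidental consensus windows.
random_background <- function(n, config = motif_config(), protect = integer(0)) {
  clean_windows(sample(aa_alphabet(), n, replace = TRUE), config, protect)
}

# Polar, tyrosine-free residues for cytoplasmic tails: mimics the
# polar/disorder-promoting composition of real cytoplasmic tails and
# guarantees that a planted motif is the only tyrosine (hence the only
# possible consensus window) in the domain.
polar_background <- function(n) {
  sample(c("A", "D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T"),
         n, replace = TRUE)
}

# Deterministic tyrosine/hydrophobic-rich domain with exactly one
# consensus window: a planted motif followed by a block of tyrosines and
# a block of V/L, spaced with glutamates so that no accidental window
# exists in the original arrangement. On shuffling, the composition makes
# consensus windows highly likely, so the permutation likelihood of the
# single observed motif is far above the 0.25 inclusion threshold.
rich_domain <- function(n, config = motif_config()) {
  if (n < 30L) stop("rich domain needs at least 30 residues")
  nb <- round(0.3 * n)
  motif <- c("S", "E", "Y", "E", "E", "L")
  body <- c(motif, "E", "E", rep("Y", nb), "E", "E", "E",
            rep(c("V", "L"), length.out = nb))
  c(body, rep("E", n - length(body)))
}

# One consensus 6-mer; wildcards avoid Y so a planted motif introduces
# exactly one scannable window (its own).
random_motif <- function(config = motif_config(), itsm = FALSE) {
  core1 <- if (itsm) "T" else sample(setdiff(config$pos1_set, "T"), 1)
  wild <- setdiff(aa_alphabet(), c("Y"))
  c(core1, sample(wild, 1), "Y", sample(wild, 1), sample(wild, 1),
    sample(config$pos6_set, 1))
}

topology_segments <- function(class, ic_len, ec_len, tm_len = 21L) {
  switch(class,
    no_tm = list(states = c("i"), lens = c(ic_len)),
    type_I = list(states = c("o", "M", "i"), lens = c(ec_len, tm_len, ic_len)),
    type_II = list(states = c("i", "M", "o"), lens = c(ic_len, tm_len, ec_len)),
    multi_pass = list(states = c("o", "M", "i", "M", "o", "M", "i"),
                      lens = c(ec_len, tm_len, ic_len, tm_len,
                               max(10L, ec_len %/% 2L), tm_len, ic_len)),
    stop("unknown protein class: ", class)
  )
}

#' Generate a synthetic proteome with planted motifs and known topology
#'
#' Builds `n_proteins` proteins whose topology strings are consistent
#' with their membrane class and whose ITIM/ITSM content is known exactly:
#' background residues are drawn uniformly with a rejection step that
#' removes accidental consensus windows, and one motif is planted per
#' protein at a recorded position in the requested compartment. Each
#' protein belongs to its own gene.
#'
#' @param n_proteins Number of proteins.
#' @param seed RNG seed (the generator is a pure function of its
#'   arguments and this seed).
#' @param class_mix Named numeric vector of proportions over
#'   `c("no_tm", "type_I", "type_II", "multi_pass")`; must sum to 1.
#'   Proteins are assigned classes in deterministic proportion.
#' @param planted Per-protein (recycled) motif placement: one of
#'   `"intracellular"`, `"extracellular"`, `"none"`.
#' @param ic_composition Per-protein (recycled): `"clean"` keeps the
#'   intracellular background motif-free; `"motif_rich"` draws the
#'   intracellular domain from a tyrosine/hydrophobic-rich alphabet so
#'   that motifs arise by composition alone and the permutation
#'   likelihood is high (no cleanup, no planting).
#' @param oversize Per-protein (recycled) logical: pad the protein beyond
#'   10000 residues so the length filter removes it.
#' @param ic_len,ec_len Ranges (length-2 integer vectors) for
#'   intracellular and extracellular segment lengths.
#' @param gene_symbols Optional per-protein gene symbols (default
#'   `GENE1..GENEn`).
#' @return List with `records` (a `protein_set` data.frame), `topology`
#'   (named character vector), `truth` (data.frame with per-protein
#'   class, planted motif start, compartment, flags).
#' @export
make_synthetic_proteome <- function(n_proteins,
                                    seed = 1L,
                                    class_mix = c(type_I = 1),
                                    planted = "intracellular",
                                    ic_composition = "clean",
                                    oversize = FALSE,
                                    ic_len = c(40L, 70L),
                                    ec_len = c(30L, 60L),
                                    gene_symbols = NULL) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8)
  set.seed(seed)
  classes <- rep(names(class_mix),
                 times = diff(round(cumsum(c(0, class_mix)) * n_proteins)))
  classes <- rep_len(classes, n_proteins)
  planted <- rep_len(planted, n_proteins)
  ic_composition <- rep_len(ic_composition, n_proteins)
  oversize <- rep_len(oversize, n_proteins)
  if (is.null(gene_symbols)) gene_symbols <- paste0("GENE", seq_len(n_proteins))
  cfg <- motif_config()
  ids <- sprintf("P%03d", seq_len(n_proteins))
  seqs <- character(n_proteins)
  topo <- character(n_proteins)
  truth <- data.frame(
    protein_id = ids, gene_id = sprintf("G%03d", seq_len(n_proteins)),
    gene_symbol = gene_symbols, class = classes, planted = planted,
    planted_start = NA_integer_, ic_motif_rich = ic_composition == "motif_rich",
    oversize = oversize, stringsAsFactors = FALSE
  )
  for (k in seq_len(n_proteins)) {
    icl <- sample(ic_len[1]:ic_len[2], 1)
    ecl <- sample(ec_len[1]:ec_len[2], 1)
    if (oversize[k]) ecl <- 10001L - icl - 21L  # total just over the cap
    seg <- topology_segments(classes[k], icl, ecl)
    states <- rep(seg$states, seg$lens)
    n <- length(states)
    chars <- sample(aa_alphabet(), n, replace = TRUE)
    ic_pos <- which(states == "i")
    protect <- integer(0)
    if (ic_composition[k] == "motif_rich") {
      runs <- split(ic_pos, cumsum(c(1L, diff(ic_pos) != 1L)))
      for (run in runs) {
        if (length(run) >= 30L) {
          chars[run] <- rich_domain(length(run), cfg)
          protect <- c(protect, run[1] + 2L)
          if (is.na(truth$planted_start[k])) truth$planted_start[k] <- run[1]
        } else {
          chars[run] <- "E"
        }
      }
    } else {
      # polar, tyrosine-free cytoplasmic background so a planted motif is
      # the only possible intracellular consensus window
      chars[ic_pos] <- polar_background(length(ic_pos))
      if (planted[k] != "none") {
        comp <- if (planted[k] == "intracellular") "i" else "o"
        pos <- which(states == comp)
        runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
        runs <- runs[lengths(runs) >= 6L]
        if (length(runs) == 0L) stop("no compartment run long enough to plant in")
        run <- runs[[sample.int(length(runs), 1)]]
        start <- run[sample.int(length(run) - 5L, 1)]
        chars[start:(start + 5L)] <- random_motif(cfg)
        truth$planted_start[k] <- start
        protect <- start + 2L
      }
    }
    chars <- clean_windows(chars, cfg, protect)
    seqs[k] <- paste(chars, collapse = "")
    topo[k] <- paste(states, collapse = "")
  }
  records <- data.frame(
    protein_id = ids,
    transcript_id = sprintf("T%03d", seq_len(n_proteins)),
    gene_id = truth$gene_id, gene_symbol = truth$gene_symbol,
    sequence = seqs, stringsAsFactors = FALSE
  )
  class(records) <- c("protein_set", "data.frame")
  list(records = records, topology = stats::setNames(topo, ids), truth = truth)
}

aa_three <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR", X = "UNK", U = "SEC"
)

#' Write a synthetic AlphaFold-convention PDB file
#'
#' Emits a valid single-model, single-chain PDB in which every atom of
#' residue `i` carries `plddt_profile[i]` in the B-factor column at the
#' PDB's `%6.2f` precision — the convention AlphaFold uses to store
#' per-residue confidence. Backbone coordinates follow a simple extended
#' walk (non-self-intersecting); the geometry is irrelevant to pLDDT
#' scoring.
#'
#' @param sequence Amino-acid string.
#' @param plddt_profile Numeric vector, same length as the sequence,
#'   values in \[0, 100\].
#' @param path Optional output path; when `NULL` the PDB text is
#'   returned as a character vector of lines.
#' @return `path` (invisibly) if written, else the lines.
#' @export
make_synthetic_structure <- function(sequence, plddt_profile, path = NULL) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(plddt_profile) != length(chars)) {
    stop("plddt_profile length must equal protein length")
  }
  if (any(plddt_profile < 0 | plddt_profile > 100)) {
    stop("pLDDT values must lie in [0, 100]")
  }
  atoms <- c("N", "CA", "C", "O")
  offs <- list(N = c(0, 0, 0), CA = c(1.46, 0, 0),
               C = c(2.4, 1.1, 0), O = c(2.4, 2.3, 0))
  lines <- character(length(chars) * 4L + 2L)
  serial <- 0L
  li <- 0L
  for (i in seq_along(chars)) {
    res3 <- aa_three[[chars[i]]]
    base <- c((i - 1) * 3.8, 0, 0)
    for (a in atoms) {
      serial <- serial + 1L
      li <- li + 1L
      xyz <- base + offs[[a]]
      lines[li] <- sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, a, res3, "A", i, xyz[1], xyz[2], xyz[3], 1.00,
        plddt_profile[i], substr(a, 1, 1))
    }
  }
  lines[li + 1L] <- sprintf("TER   %5d      %3s %s%4d",
                            serial + 1L, aa_three[[chars[length(chars)]]],
                            "A", length(chars))
  lines[li + 2L] <- "END"
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic count matrix with planted functional categories
#'
#' Emulates the statistical structure the expression classifier assumes:
#' background genes with log-normal baselines (log2 mean 5, sd 2) define
#' the per-condition median; planted genes are placed well above (8) or
#' below (2) that median in each state according to their category, with
#' the planned log2 fold change applied on activation and Gaussian noise
#' (sd `noise_sd`) added on the log2 scale before converting back to
#' counts.
#'
#' @param category_plan Data.frame with columns `gene`, `cell_type`,
#'   `category` (one of the five category labels) and `log2fc` (used for
#'   the threshold-family categories; feedback/disinhibition plans should
#'   keep `|log2fc| >= 0.6`, clear of the 0.5 boundary).
#' @param n_samples Samples per (cell type, state) condition (default 4).
#' @param noise_sd Gaussian noise sd on the log2 scale (default 0.1).
#' @param seed RNG seed.
#' @param n_background Background genes per dataset (default 200).
#' @return List with `em` (an `expression_matrix` on the counts scale)
#'   and `truth` (`category_plan` as planted).
#' @export
make_synthetic_expression <- function(category_plan, n_samples = 4L,
                                      noise_sd = 0.1, seed = 1L,
                                      n_background = 200L) {
  set.seed(seed)
  stopifnot(all(c("gene", "cell_type", "category", "log2fc") %in%
                  names(category_plan)))
  cell_types <- unique(category_plan$cell_type)
  genes <- unique(category_plan$gene)
  bg <- paste0("BG", seq_len(n_background))
  bg_base <- stats::rnorm(n_background, mean = 5, sd = 2)
  all_genes <- c(genes, bg)
  hi <- 8; lo <- 2
  cols <- list(); meta <- list()
  for (ct in cell_types) {
    for (st in c("resting", "activated")) {
      plan <- category_plan[category_plan$cell_type == ct, , drop = FALSE]
      base <- stats::setNames(rep(lo, length(genes)), genes)
      for (j in seq_len(nrow(plan))) {
        g <- plan$gene[j]
        base[g] <- switch(plan$category[j],
          not_expressed = lo,
          negative_feedback = if (st == "resting") lo else hi,
          threshold = ,
          threshold_disinhibition = ,
          threshold_negative_feedback =
            if (st == "resting") hi else hi + plan$log2fc[j],
          stop("unknown category: ", plan$category[j]))
      }
      mu <- c(base, stats::setNames(bg_base, bg))
      for (s in seq_len(n_samples)) {
        sample_id <- sprintf("%s_%s_%d", gsub("\\s+", "_", ct), st, s)
        vals <- mu + stats::rnorm(length(mu), 0, noise_sd)
        cols[[sample_id]] <- pmax(0, round(2^vals - 1))
        meta[[sample_id]] <- data.frame(sample_id = sample_id, cell_type = ct,
                                        state = st, stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- all_genes
  em <- expression_matrix(values, "counts", do.call(rbind, meta))
  list(em = em, truth = category_plan)
}

#' Build the end-to-end demonstration fixture
#'
#' A 10-protein proteome with five clean survivors and one designed
#' failure at each pipeline stage: an oversize protein (length filter), a
#' motif-free protein (motif scan), a protein whose only motif is
#' extracellular and a soluble protein (topology filter), a protein with
#' a tyrosine/hydrophobic-rich intracellular domain (permutation filter),
#' and a protein whose motif sits in a high-confidence region
#' (structure filter). Structures place survivor motifs in low-pLDDT
#' tails; survivor genes get planted expression categories.
#'
#' @param seed RNG seed.
#' @param dir Optional directory: when given, FASTA, metadata TSV,
#'   topology TSV, per-protein PDB files, expression counts TSV, sample
#'   metadata TSV, and a truth JSON are written into it.
#' @return List with `records`, `topology`, `structures` (named list of
#'   pLDDT data.frames), `em` (expression matrix), `truth`,
#'   `expression_truth`, `expected_survivors` (protein ids).
#' @export
make_demo_fixture <- function(seed = 1L, dir = NULL) {
  synth <- make_synthetic_proteome(
    n_proteins = 10L,
    seed = seed,
    class_mix = c(type_I = 0.6, type_II = 0.2, multi_pass = 0.2),
    planted = c(rep("intracellular", 6L), "none", "extracellular",
                "intracellular", "intracellular"),
    ic_composition = c(rep("clean", 8L), "motif_rich", "clean"),
    oversize = c(rep(FALSE, 5L), TRUE, rep(FALSE, 4L))
  )
  # Designed failures: P005 motif in a high-confidence region (structure
  # filter), P006 oversize (length filter), P007 no motif (scan), P008
  # extracellular-only motif (topology filter), P009 tyrosine-rich
  # intracellular domains (permutation filter). Survivors: P001-P004 and
  # P010 (a multi-pass protein with a clean intracellular motif).
  truth <- synth$truth
  structures <- list()
  for (k in seq_len(nrow(truth))) {
    id <- truth$protein_id[k]
    if (truth$oversize[k]) next  # no structure needed (dropped earlier)
    seqk <- synth$records$sequence[synth$records$protein_id == id]
    states <- strsplit(synth$topology[[id]], "", fixed = TRUE)[[1]]
    profile <- ifelse(states == "i", 40, 92)
    if (id == "P005") profile[] <- 95  # all motifs high-confidence
    structures[[id]] <- profile
  }
  expected <- c("P001", "P002", "P003", "P004", "P010")
  plan <- data.frame(
    gene = truth$gene_symbol[truth$protein_id %in% expected],
    cell_type = "Monocytes",
    category = c("threshold", "negative_feedback", "threshold_disinhibition",
                 "threshold_negative_feedback", "not_expressed"),
    log2fc = c(0, 2, -1, 1, 0),
    stringsAsFactors = FALSE
  )
  expr <- make_synthetic_expression(plan, seed = seed + 1L)
  conf <- lapply(names(structures), function(id) {
    data.frame(residue_index = seq_along(structures[[id]]),
               plddt = structures[[id]])
  })
  names(conf) <- names(structures)
  out <- list(records = synth$records, topology = synth$topology,
              structures = conf, plddt_profiles = structures,
              em = expr$em, truth = truth, expression_truth = expr$truth,
              expected_survivors = expected)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_protein_fasta(synth$records, file.path(dir, "proteome.fasta"))
    utils::write.table(
      synth$records[, c("protein_id", "transcript_id", "gene_id", "gene_symbol")],
      file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_topology_file(synth$topology, file.path(dir, "topology.tsv"))
    pdbdir <- file.path(dir, "structures")
    dir.create(pdbdir, showWarnings = FALSE)
    for (id in names(structures)) {
      seqk <- synth$records$sequence[synth$records$protein_id == id]
      make_synthetic_structure(seqk, structures[[id]],
                               file.path(pdbdir, paste0(id, ".pdb")))
    }
    counts <- expr$em$values
    utils::write.table(data.frame(gene = rownames(counts), counts,
                                  check.names = FALSE),
                       file.path(dir, "expression_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expr$em$sample_meta, file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(truth = truth, expression_truth = expr$truth,
           expected_survivors = expected),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
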