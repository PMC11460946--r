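#' Construct an expression matrix with sample metadata
#'
#' @param values Numeric gene x sample matrix with row names (genes) and
#'   column names (sample ids).
#' @param scale One of `"counts"`, `"tpm"`, `"log2"`.
#' @param sample_meta Data.frame with columns `sample_id`, `cell_type`,
#'   `state` (`"resting"` or `"activated"`), one row per column of
#'   `values`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale = c("counts", "tpm", "log2"),
                              sample_meta) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene row names and sample column names")
  }
  need <- c("sample_id", "cell_type", "state")
  if (!all(need %in% names(sample_meta))) {
    stop("sample_meta must have columns: ", paste(need, collapse = ", "))
  }
  m <- match(colnames(values), sample_meta$sample_id)
  if (anyNA(m)) {
    stop("samples missing from metadata: ",
         paste(colnames(values)[is.na(m)], collapse = ", "))
  }
  sample_meta <- sample_meta[m, , drop = FALSE]
  if (!all(sample_meta$state %in% c("resting", "activated"))) {
    stop("sample state must be 'resting' or 'activated'")
  }
  if (scale %in% c("counts", "tpm") && any(values < 0)) {
    stop("negative values are not allowed on the ", scale, " scale")
  }
  structure(list(values = values, scale = scale, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' Log2-scale a TPM matrix
#'
#' Applies `log2(x + 1)` (pseudocount 1, so zeros stay at zero) to a TPM
#' matrix, the normalisation used for datasets distributed as TPM.
#'
#' @param em An `expression_matrix` on the `tpm` scale.
#' @return The matrix on the `log2` scale.
#' @export
log2_scale_tpm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "tpm") stop("log2_scale_tpm expects a TPM-scale matrix")
  em$values <- log2(em$values + 1)
  em$scale <- "log2"
  em
}

#' Median-of-ratios (size factor) normalisation of a count matrix
#'
#' The standard RNA-seq size-factor estimator: for each gene with a
#' positive count in every sample, compute the geometric mean across
#' samples; each sample's size factor is the median over those genes of
#' count / geometric mean. Counts are divided by the sample's size factor
#' and then `log2(x + 1)` transformed.
#'
#' @param em An `expression_matrix` on the `counts` scale with >= 2
#'   samples.
#' @return The normalised matrix on the `log2` scale, with the size
#'   factors in attribute `"size_factors"`.
#' @export
median_of_ratios_normalize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "counts") stop("median_of_ratios_normalize expects counts")
  if (ncol(em$values) < 2L) stop("need at least 2 samples")
  v <- em$values
  pos <- rowSums(v > 0) == ncol(v)
  if (!any(pos)) stop("no gene has a positive count in every sample")
  log_gm <- rowMeans(log(v[pos, , drop = FALSE]))
  sf <- apply(v[pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_gm))
  })
  em$values <- log2(sweep(v, 2, sf, "/") + 1)
  em$scale <- "log2"
  attr(em, "size_factors") <- sf
  em
}

#' Per-condition mean expression
#'
#' Averages log2-scale expression over the samples sharing a
#' (cell type, state) condition.
#'
#' @param em An `expression_matrix` on the `log2` scale.
#' @param gene_set Optional character vector restricting the rows of the
#'   returned matrix (the full universe is still available to
#'   [call_expressed()] via a separate call).
#' @return List with `means` (gene x condition matrix), `conditions`
#'   (data.frame with `cell_type`, `state` per column).
#' @export
condition_means <- function(em, gene_set = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "log2") stop("condition_means expects log2-scale data")
  key <- paste(em$sample_meta$cell_type, em$sample_meta$state, sep = "|")
  ukey <- unique(key)
  means <- vapply(ukey, function(k) {
    rowMeans(em$values[, key == k, drop = FALSE])
  }, numeric(nrow(em$values)))
  means <- matrix(means, nrow = nrow(em$values), dimnames = list(rownames(em$values), ukey))
  if (!is.null(gene_set)) {
    means <- means[intersect(gene_set, rownames(means)), , drop = FALSE]
  }
  parts <- strsplit(ukey, "|", fixed = TRUE)
  list(
    means = means,
    conditions = data.frame(
      cell_type = vapply(parts, `[`, character(1), 1L),
      state = vapply(parts, `[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
  )
}

#' Call genes expressed per condition
#'
#' A gene is called expressed in a condition when its mean expression is
#' strictly above the median of all genes' means in that condition. The
#' median must be taken over the dataset's full gene universe, not just
#' the candidate genes, or the cutoff loses its meaning — passing a
#' candidate-only matrix as `all_gene_means` is an error the caller must
#' avoid.
#'
#' @param mean_table A [condition_means()] result for the genes of
#'   interest.
#' @param all_gene_means A [condition_means()] result over the full gene
#'   universe (defaults to `mean_table`).
#' @return Logical gene x condition matrix.
#' @export
call_expressed <- function(mean_table, all_gene_means = mean_table) {
  if (!identical(colnames(mean_table$means), colnames(all_gene_means$means))) {
    stop("mean_table and all_gene_means must cover the same conditions")
  }
  med <- apply(all_gene_means$means, 2, stats::median)
  sweep(mean_table$means, 2, med, ">")
}

#' Assign a functional category from expression dynamics
#'
#' Implements the four-category functional classification of inhibitory
#' receptors from resting/activated expression:
#' \itemize{
#'   \item not expressed in either state -> `not_expressed`;
#'   \item not expressed resting, expressed activated ->
#'     `negative_feedback` (induced to resolve the response);
#'   \item expressed resting, not expressed activated ->
#'     `threshold_disinhibition` (regardless of fold change);
#'   \item expressed resting with log2 fold change in
#'     `[-threshold, threshold]` -> `threshold`;
#'   \item below `-threshold` -> `threshold_disinhibition`;
#'   \item above `threshold` -> `threshold_negative_feedback`.
#' }
#' The boundary value `0.5` belongs to the closed `threshold` interval.
#' The function is a total, single-valued partition of
#' (logical, logical, real).
#'
#' @param expressed_resting,expressed_activated Logical vectors.
#' @param log2fc Numeric vector: mean activated minus mean resting on the
#'   log2 scale.
#' @param log2fc_threshold Fold-change cutoff (default 0.5).
#' @return Character vector of categories.
#' @examples
#' assign_category(FALSE, TRUE, 2.0)   # negative_feedback
#' assign_category(TRUE, TRUE, 0.5)    # threshold (closed boundary)
#' @export
assign_category <- function(expressed_resting, expressed_activated, log2fc,
                            log2fc_threshold = 0.5) {
  n <- max(length(expressed_resting), length(expressed_activated), length(log2fc))
  er <- rep_len(expressed_resting, n)
  ea <- rep_len(expressed_activated, n)
  fc <- rep_len(log2fc, n)
  if (any(!is.finite(fc) & er & ea)) stop("log2fc must be finite")
  out <- character(n)
  out[!er & !ea] <- "not_expressed"
  out[!er & ea] <- "negative_feedback"
  out[er & !ea] <- "threshold_disinhibition"
  both <- er & ea
  out[both & fc >= -log2fc_threshold & fc <= log2fc_threshold] <- "threshold"
  out[both & fc < -log2fc_threshold] <- "threshold_disinhibition"
  out[both & fc > log2fc_threshold] <- "threshold_negative_feedback"
  out
}

#' Full expression classification for a set of genes
#'
#' Normalises the matrix according to its scale (median-of-ratios for
#' counts, log2(x+1) for TPM), computes per-condition means over the full
#' gene universe, calls expression against the per-condition median, and
#' assigns a functional category per gene and cell type. Genes absent
#' from the matrix are reported with category `"not_detected"` (distinct
#' from `not_expressed`: the gene was not measured at all).
#'
#' @param em An `expression_matrix` (any scale).
#' @param genes Character vector of genes to classify (default: all genes
#'   in the matrix).
#' @param log2fc_threshold Fold-change cutoff (default 0.5).
#' @param call_mode `"condition-mean"` (default) compares the
#'   per-condition mean to the median of all genes' per-condition means;
#'   `"per-sample-majority"` calls a gene expressed in a condition when
#'   it exceeds the within-sample median in a strict majority of that
#'   condition's samples.
#' @return Data.frame of class `expression_calls` with columns `gene`,
#'   `cell_type`, `expressed_resting`, `expressed_activated`, `log2fc`,
#'   `category`.
#' @export
classify_expression <- function(em, genes = NULL, log2fc_threshold = 0.5,
                                call_mode = c("condition-mean",
                                              "per-sample-majority")) {
  call_mode <- match.arg(call_mode)
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale == "counts") em <- median_of_ratios_normalize(em)
  if (em$scale == "tpm") em <- log2_scale_tpm(em)
  if (is.null(genes)) genes <- rownames(em$values)
  cm <- condition_means(em)
  if (call_mode == "condition-mean") {
    expressed <- call_expressed(cm)
  } else {
    key <- paste(em$sample_meta$cell_type, em$sample_meta$state, sep = "|")
    above <- sweep(em$values, 2, apply(em$values, 2, stats::median), ">")
    expressed <- vapply(colnames(cm$means), function(k) {
      cols <- which(key == k)
      rowMeans(above[, cols, drop = FALSE]) > 0.5
    }, logical(nrow(em$values)))
    expressed <- matrix(expressed, nrow = nrow(em$values),
                        dimnames = list(rownames(em$values), colnames(cm$means)))
  }
  cell_types <- unique(cm$conditions$cell_type)
  rows <- list()
  for (ct in cell_types) {
    rk <- paste(ct, "resting", sep = "|")
    ak <- paste(ct, "activated", sep = "|")
    if (!(rk %in% colnames(cm$means)) || !(ak %in% colnames(cm$means))) next
    present <- genes %in% rownames(cm$means)
    g <- genes[present]
    lfc <- cm$means[g, ak] - cm$means[g, rk]
    cat_p <- assign_category(expressed[g, rk], expressed[g, ak], lfc,
                             log2fc_threshold)
    df <- data.frame(
      gene = genes, cell_type = ct,
      expressed_resting = NA, expressed_activated = NA,
      log2fc = NA_real_, category = "not_detected",
      stringsAsFactors = FALSE
    )
    df$expressed_resting[present] <- unname(expressed[g, rk])
    df$expressed_activated[present] <- unname(expressed[g, ak])
    df$log2fc[present] <- unname(lfc)
    df$category[present] <- cat_p
    rows[[ct]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("expression_calls", "data.frame")
  out
}

#' Exclusive sharing of expressed genes across cell types
#'
#' A gene counts as expressed in a cell type when it is expressed in the
#' resting or the activated state. Every gene expressed somewhere is
#' assigned to exactly one combination of cell types (the full set of
#' cell types it is expressed in), as in an upset plot.
#'
#' @param calls An `expression_calls` data.frame.
#' @return Named integer vector; names are `+`-joined sorted cell-type
#'   combinations.
#' @export
subset_sharing_counts <- function(calls) {
  expressed <- (calls$expressed_resting %in% TRUE) |
    (calls$expressed_activated %in% TRUE)
  by_gene <- split(calls$cell_type[expressed], calls$gene[expressed])
  combos <- vapply(by_gene, function(cts) paste(sort(unique(cts)), collapse = "+"),
                   character(1))
  tab <- table(combos)
  stats::setNames(as.integer(tab), names(tab))
}

#' Weighted Z-score expression calls for tumour T-cell subsets
#'
#' For each T-cell subset, the mean Z-scored expression of each gene is
#' computed within every subcluster and combined as a weighted mean using
#' the subclusters' relative contributions. A gene is called expressed in
#' the subset when the weighted mean Z-score is strictly above 0
#' (`rule = "zscore"`), or — as an alternative reading — when it is above
#' the median of the gene's weighted means across all subsets
#' (`rule = "median-across-subsets"`).
#'
#' @param zmatrix Cell x gene matrix of Z-scored expression (cells in
#'   rows).
#' @param cell_meta Data.frame with one row per cell: `subset`,
#'   `subcluster`.
#' @param subcluster_weights Data.frame with columns `subset`,
#'   `subcluster`, `weight`; weights must sum to 1 within each subset.
#' @param rule Expression rule, see above.
#' @return Data.frame with `gene`, `subset`, `weighted_mean_z`,
#'   `expressed`.
#' @export
tumour_subset_expression <- function(zmatrix, cell_meta, subcluster_weights,
                                     rule = c("zscore", "median-across-subsets")) {
  rule <- match.arg(rule)
  zmatrix <- as.matrix(zmatrix)
  if (nrow(zmatrix) != nrow(cell_meta)) {
    stop("cell_meta must have one row per cell (row of zmatrix)")
  }
  ws <- split(subcluster_weights, subcluster_weights$subset)
  for (s in names(ws)) {
    if (abs(sum(ws[[s]]$weight) - 1) > 1e-8) {
      stop("subcluster weights for subset '", s, "' do not sum to 1")
    }
  }
  subsets <- names(ws)
  genes <- colnames(zmatrix)
  wm <- matrix(NA_real_, length(genes), length(subsets),
               dimnames = list(genes, subsets))
  for (s in subsets) {
    acc <- numeric(length(genes))
    for (k in seq_len(nrow(ws[[s]]))) {
      sc <- ws[[s]]$subcluster[k]
      cells <- which(cell_meta$subset == s & cell_meta$subcluster == sc)
      if (length(cells) == 0L) {
        stop("subcluster '", sc, "' of subset '", s, "' has zero cells")
      }
      acc <- acc + ws[[s]]$weight[k] *
        colMeans(zmatrix[cells, , drop = FALSE])
    }
    wm[, s] <- acc
  }
  out <- data.frame(
    gene = rep(genes, times = length(subsets)),
    subset = rep(subsets, each = length(genes)),
    weighted_mean_z = as.vector(wm),
    stringsAsFactors = FALSE
  )
  if (rule == "zscore") {
    out$expressed <- out$weighted_mean_z > 0
  } else {
    med <- apply(wm, 1, stats::median)
    out$expressed <- out$weighted_mean_z > med[out$gene]
  }
  out
}
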