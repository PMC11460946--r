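#' Composition-preserving shuffle of an amino-acid string
#'
#' Returns a uniformly random permutation of the residues of `sequence`
#' (Fisher-Yates / Knuth shuffle, as implemented by R's
#' [sample.int()] index permutation). The residue multiset is preserved
#' exactly, which is the property the permutation null relies on.
#'
#' @param sequence Amino-acid string.
#' @return A string with the same residues in uniformly random order.
#' @examples
#' set.seed(1)
#' fisher_yates_shuffle("SAYAL")
#' @export
fisher_yates_shuffle <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  paste(chars[sample.int(length(chars))], collapse = "")
}

#' Monte-Carlo likelihood of chance motif occurrence
#'
#' Estimates the probability that the intracellular domains of a protein
#' contain at least as many ITIM/ITSM motifs as observed, when the
#' residues of each domain are shuffled uniformly at random
#' (composition-preserving permutation). Each of the `n_permutations`
#' iterations independently re-shuffles every domain, recounts motifs
#' with the same counter used for the observed count
#' ([count_motifs_in_domains()]), and tallies iterations whose count is
#' greater than or equal to `observed_count`. The resulting fraction is a
#' valid permutation p-value: large values mean the protein's residue
#' composition alone (many tyrosines and hydrophobic residues) makes
#' motifs likely, so its observed motifs carry little evidence.
#'
#' The decision threshold is `0.25 + epsilon`, with `epsilon` drawn once
#' per protein from Uniform[0, 0.01) to randomise borderline decisions;
#' the draw is taken from the current RNG stream and recorded in the
#' result so every borderline decision is reproducible from the seed.
#'
#' @param domains Character vector of intracellular domain sequences.
#' @param observed_count Observed motif count (must be >= 1: proteins
#'   enter the test only with at least one intracellular motif). Defaults
#'   to the count computed from `domains`.
#' @param n_permutations Number of shuffles (default 10000).
#' @param config A [motif_config()].
#' @param shuffle_mode `"per-domain"` (default) shuffles each domain
#'   independently, preserving the domain length structure and never
#'   creating cross-boundary motifs; `"concatenated"` pools all domains
#'   into one string before shuffling and re-splitting.
#' @param protein_id Identifier carried into the result.
#' @param threshold_base Base of the inclusion threshold (default 0.25).
#' @param epsilon_max Upper bound of the epsilon jitter (default 0.01).
#' @return An object of class `permutation_result`: list with
#'   `protein_id`, `observed_count`, `n_permutations`, `n_geq`,
#'   `likelihood`, `epsilon`, `threshold`, `passed`.
#' @examples
#' set.seed(7)
#' permutation_likelihood("SAYAAL", n_permutations = 1000)
#' @export
permutation_likelihood <- function(domains,
                                   observed_count = NULL,
                                   n_permutations = 10000L,
                                   config = motif_config(),
                                   shuffle_mode = c("per-domain", "concatenated"),
                                   protein_id = NA_character_,
                                   threshold_base = 0.25,
                                   epsilon_max = 0.01) {
  shuffle_mode <- match.arg(shuffle_mode)
  if (length(domains) == 0L) stop("empty domain list")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  dom_chars <- lapply(domains, function(d) strsplit(d, "", fixed = TRUE)[[1]])
  if (is.null(observed_count)) {
    observed_count <- sum(vapply(dom_chars, function(ch) length(scan_chars(ch, config)),
                                 integer(1)))
  }
  if (observed_count < 1L) {
    stop("observed_count must be >= 1 (proteins enter the permutation test ",
         "only with at least one intracellular motif)")
  }
  lens <- lengths(dom_chars)
  pooled <- unlist(dom_chars, use.names = FALSE)
  bounds <- cumsum(lens)
  n_geq <- 0L
  for (it in seq_len(n_permutations)) {
    if (shuffle_mode == "per-domain") {
      cnt <- 0L
      for (ch in dom_chars) {
        cnt <- cnt + length(scan_chars(ch[sample.int(length(ch))], config))
      }
    } else {
      perm <- pooled[sample.int(length(pooled))]
      cnt <- 0L
      lo <- 1L
      for (k in seq_along(lens)) {
        cnt <- cnt + length(scan_chars(perm[lo:bounds[k]], config))
        lo <- bounds[k] + 1L
      }
    }
    if (cnt >= observed_count) n_geq <- n_geq + 1L
  }
  epsilon <- stats::runif(1, 0, epsilon_max)
  likelihood <- n_geq / n_permutations
  structure(
    list(
      protein_id = protein_id,
      observed_count = as.integer(observed_count),
      n_permutations = as.integer(n_permutations),
      n_geq = n_geq,
      likelihood = likelihood,
      epsilon = epsilon,
      threshold = threshold_base + epsilon,
      passed = likelihood <= threshold_base + epsilon
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation motif-likelihood test\n")
  if (!is.na(x$protein_id)) cat("  protein:   ", x$protein_id, "\n", sep = "")
  cat(sprintf("  observed motifs: %d\n", x$observed_count))
  cat(sprintf("  likelihood:      %.4g  (%d / %d permutations >= observed)\n",
              x$likelihood, x$n_geq, x$n_permutations))
  cat(sprintf("  threshold:       %.4f  (0.25 + eps %.4f)  ->  %s\n",
              x$threshold, x$epsilon, if (x$passed) "PASS" else "EXCLUDE"))
  invisible(x)
}

# Internal: all permutations of 1..n as an (n! x n) index matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    idx <- c(k, setdiff(seq_len(n), k))
    out[row + seq_len(nrow(sub)), 1L] <- k
    out[row + seq_len(nrow(sub)), -1L] <- matrix(idx[-1L][sub], nrow(sub))
    row <- row + nrow(sub)
  }
  out
}

#' Exact chance of motif occurrence by full enumeration
#'
#' Brute-force oracle for the permutation likelihood on short domains:
#' enumerates all `n!` position permutations of the domain (identical
#' letters are weighted naturally by their multiplicity) and returns the
#' exact probability that a permutation contains at least
#' `observed_count` consensus motifs.
#'
#' @param domain A single amino-acid string of length <= 9 (the
#'   enumeration feasibility bound).
#' @param observed_count Count threshold; defaults to the domain's own
#'   motif count (which must then be >= 1).
#' @param config A [motif_config()].
#' @return Exact probability as a double.
#' @examples
#' exact_likelihood("SAYAAL")  # 1/120
#' @export
exact_likelihood <- function(domain, observed_count = NULL,
                             config = motif_config()) {
  chars <- strsplit(domain, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n > 9L) stop("domain too long for exact enumeration (length > 9)")
  if (is.null(observed_count)) {
    observed_count <- length(scan_chars(chars, config))
    if (observed_count < 1L) {
      stop("domain has no motif; supply observed_count explicitly")
    }
  }
  if (n < 6L) return(0)
  perms <- all_permutations(n)
  charmat <- matrix(chars[perms], nrow(perms), n)
  counts <- integer(nrow(perms))
  for (p in seq_len(n - 5L)) {
    counts <- counts + (charmat[, p] %in% config$pos1_set &
                          charmat[, p + 2L] == "Y" &
                          charmat[, p + 5L] %in% config$pos6_set)
  }
  mean(counts >= observed_count)
}

#' Apply the chance-likelihood inclusion threshold
#'
#' Splits permutation results into those kept (likelihood at most
#' `0.25 + epsilon`, with each result's own recorded epsilon) and those
#' excluded. Proteins whose composition makes chance motifs likelier than
#' the threshold are set aside as probable false positives.
#'
#' @param results List of `permutation_result` objects.
#' @return List with `kept` and `excluded` lists.
#' @export
apply_likelihood_filter <- function(results) {
  stopifnot(all(vapply(results, inherits, logical(1), "permutation_result")))
  passed <- vapply(results, `[[`, logical(1), "passed")
  list(kept = results[passed], excluded = results[!passed])
}
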