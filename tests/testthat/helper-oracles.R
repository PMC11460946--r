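# Independent oracles and small generators used across the suite.

# Brute-force consensus scanner: tests every 6-residue window with
# substring comparisons, independently of the package's vectorised
# scanner.
oracle_scan <- function(sequence,
                        pos1 = c("V", "L", "I", "S", "T"),
                        pos6 = c("I", "L", "V")) {
  n <- nchar(sequence)
  starts <- integer(0)
  if (n >= 6L) {
    for (p in 1:(n - 5L)) {
      w <- substring(sequence, p, p + 5L)
      if (substr(w, 1, 1) %in% pos1 &&
          substr(w, 3, 3) == "Y" &&
          substr(w, 6, 6) %in% pos6) {
        starts <- c(starts, p)
      }
    }
  }
  starts
}

# Random amino-acid sequence, occasionally with ambiguity codes.
random_aa_seq <- function(len, with_ambiguity = TRUE) {
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (with_ambiguity) alpha <- c(alpha, "X", "U")
  paste(sample(alpha, len, replace = TRUE), collapse = "")
}

# Random short domain (length 6-8) from a motif-enriched alphabet,
# redrawn until it contains at least one consensus motif.
random_motif_domain <- function() {
  alpha <- c("Y", "V", "L", "I", "S", "T", "A", "E")
  repeat {
    d <- paste(sample(alpha, sample(6:8, 1), replace = TRUE), collapse = "")
    if (count_motifs_in_domains(d) >= 1L) return(d)
  }
}

write_tmp_lines <- function(lines) {
  path <- tempfile()
  writeLines(lines, path)
  path
}
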