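test_that("protein classes follow membrane-segment count and orientation", {
  seq15 <- strrep("A", 15)
  expect_equal(annotate_topology("a", "oooooMMMMMiiiii", seq15)$protein_class,
               "single_pass_type_I")
  expect_equal(annotate_topology("b", "iiiiiMMMMMooooo", seq15)$protein_class,
               "single_pass_type_II")
  ann <- annotate_topology("c", "iiiMMMoooMMMiii", seq15)
  expect_equal(ann$protein_class, "multi_pass")
  expect_equal(nrow(ann$tm_segments), 2L)
  expect_equal(unname(ann$tm_segments[1, ]), c(4L, 6L))
  # signal peptide counts as the non-cytoplasmic N-terminal side
  expect_equal(annotate_topology("d", "SSSSSMMMMMiiiii", seq15)$protein_class,
               "single_pass_type_I")
  expect_equal(annotate_topology("e", "iiiiiiiiiiiiiii", seq15)$protein_class,
               "no_tm")
})

test_that("degenerate topology strings are rejected", {
  expect_error(annotate_topology("p", "iii", "AAAA"), "does not match")
  expect_error(annotate_topology("p", "MMMM", "AAAA"), "all-membrane")
  expect_error(annotate_topology("p", "iiZi", "AAAA"), "'Z' at position 3")
})

test_that("intracellular domains are maximal runs in N-to-C order", {
  seq15 <- "ABCDEFGHIKLMNPQ"
  ann <- annotate_topology("p", "iiiMMMoooMMMiii", seq15)
  dom <- extract_intracellular_domains(ann, seq15)
  expect_equal(dom$start, c(1L, 13L))
  expect_equal(dom$end, c(3L, 15L))
  expect_equal(dom$sequence, c("ABC", "NPQ"))
  expect_equal(dom$domain_index, 1:2)

  ann <- annotate_topology("q", strrep("o", 15), seq15)
  expect_equal(nrow(extract_intracellular_domains(ann, seq15)), 0L)
})

test_that("concatenated domains equal the subsequence of 'i' residues", {
  set.seed(21)
  states_alpha <- c("i", "o", "M", "S")
  for (rep in 1:50) {
    n <- sample(20:120, 1)
    states <- paste(sample(states_alpha, n, replace = TRUE,
                           prob = c(0.4, 0.3, 0.2, 0.1)), collapse = "")
    if (!grepl("[ioS]", states)) next
    if (gsub("[^M]", "", states) == states) next
    s <- random_aa_seq(n, with_ambiguity = FALSE)
    ann <- annotate_topology("p", states, s)
    dom <- extract_intracellular_domains(ann, s)
    ic <- paste(strsplit(s, "")[[1]][strsplit(states, "")[[1]] == "i"],
                collapse = "")
    expect_equal(paste(dom$sequence, collapse = ""), ic)
  }
})

test_that("motif filtering keeps only fully intracellular hits and is idempotent", {
  # motif at 11-16 inside the cytoplasmic tail, another at 1-6 outside
  s <- "SDYSELAAAASDYSELAAAA"
  st <- paste0(strrep("o", 6), strrep("M", 4), strrep("i", 10))
  ann <- annotate_topology("p", st, s)
  hits <- scan_motifs(s, protein_id = "p")
  expect_equal(hits$start, c(1L, 11L))
  kept <- filter_intracellular_motifs(hits, ann)
  expect_equal(kept$start, 11L)
  expect_identical(filter_intracellular_motifs(kept, ann), kept)

  # straddling hit: motif residues cross the i/M boundary
  s2 <- "AAAASDYSELAAAAAAAAAA"
  st2 <- paste0(strrep("M", 8), strrep("i", 12))
  ann2 <- annotate_topology("q", st2, s2)
  hits2 <- scan_motifs(s2, protein_id = "q")
  expect_equal(hits2$start, 5L)
  expect_equal(nrow(filter_intracellular_motifs(hits2, ann2)), 0L)

  expect_error(
    filter_intracellular_motifs(data.frame(protein_id = "q", start = 18L,
                                           end = 23L),
                                ann2),
    "beyond")
})

test_that("type I proteins have all intracellular domains C-terminal to the TM", {
  set.seed(31)
  synth <- make_synthetic_proteome(20, seed = 31, class_mix = c(type_I = 1))
  for (k in 1:20) {
    id <- synth$records$protein_id[k]
    ann <- annotate_topology(id, synth$topology[[id]], synth$records$sequence[k])
    expect_equal(ann$protein_class, "single_pass_type_I")
    dom <- extract_intracellular_domains(ann, synth$records$sequence[k])
    expect_true(all(dom$start > ann$tm_segments[1, "end"]))
  }
})

test_that("length filter is inclusive at the cap", {
  recs <- data.frame(
    protein_id = c("a", "b", "c"),
    sequence = c(strrep("A", 100), strrep("A", 10000), strrep("A", 10001)),
    stringsAsFactors = FALSE
  )
  lf <- apply_length_filter(recs)
  expect_equal(lf$kept$protein_id, c("a", "b"))
  expect_equal(lf$excluded$protein_id, "c")
  lf0 <- apply_length_filter(recs[0, ])
  expect_equal(nrow(lf0$kept), 0L)
  expect_equal(nrow(lf0$excluded), 0L)
})
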