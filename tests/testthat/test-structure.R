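test_that("pLDDT profiles round-trip through synthetic PDB files", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(10:80, 1)
    s <- random_aa_seq(n, with_ambiguity = FALSE)
    profile <- round(runif(n, 0, 100), 2)
    path <- tempfile(fileext = ".pdb")
    make_synthetic_structure(s, profile, path)
    got <- read_plddt(path)
    expect_equal(got$residue_index, seq_len(n))
    expect_lt(max(abs(got$plddt - profile)), 0.01 + 1e-9)
  }
})

test_that("read_plddt enforces AlphaFold file conventions", {
  s <- "MKTAYI"
  path <- tempfile(fileext = ".pdb")
  make_synthetic_structure(s, rep(50, 6), path)

  lines <- readLines(path)
  is_atom <- grepl("^ATOM", lines)
  resno <- ifelse(is_atom, trimws(substr(lines, 23, 26)), "")
  aname <- ifelse(is_atom, trimws(substr(lines, 13, 16)), "")

  # disagreeing atom B-factors within one residue (bump one CA's B-factor)
  bad <- lines
  k <- which(aname == "CA" & resno == "1")[1]
  substr(bad[k], 61, 66) <- " 50.20"
  expect_error(read_plddt(write_tmp_lines(bad)), "disagree")

  # residue-number gap
  p3 <- write_tmp_lines(lines[resno != "3"])
  expect_error(read_plddt(p3), "gap")

  # no ATOM records at all
  p4 <- write_tmp_lines(c("REMARK empty", "END"))
  expect_error(suppressWarnings(read_plddt(p4)))

  # missing CA falls back to the first atom with a warning
  p5 <- write_tmp_lines(lines[!(aname == "CA" & resno == "1")])
  expect_warning(got <- read_plddt(p5), "no CA")
  expect_equal(got$plddt[1], 50)
})

test_that("motif confidence is the arithmetic mean of the six residues", {
  conf <- data.frame(residue_index = 1:10,
                     plddt = c(40, 45, 50, 55, 60, 45, 80, 80, 80, 80))
  hit <- data.frame(protein_id = "p", start = 1L, end = 6L)
  mc <- motif_confidence(hit, conf)
  expect_equal(mc$mean_plddt, mean(c(40, 45, 50, 55, 60, 45)))
  expect_equal(round(mc$mean_plddt, 4), 49.1667)
  expect_true(mc$disordered_flag)

  hit2 <- data.frame(protein_id = "p", start = 5L, end = 10L)
  expect_false(motif_confidence(hit2, conf)$disordered_flag)

  hit3 <- data.frame(protein_id = "p", start = 8L, end = 13L)
  expect_error(motif_confidence(hit3, conf), "exceeds structure length")
})

test_that("structure filter passes on any motif below the cutoff, strictly", {
  conf <- data.frame(residue_index = 1:12,
                     plddt = c(rep(85.2, 6), rep(49.3, 6)))
  hits <- data.frame(protein_id = "p", start = c(1L, 7L), end = c(6L, 12L))
  sf <- structural_filter(hits, conf)
  expect_true(sf$passed)
  expect_equal(sf$min_mean_plddt, 49.3)

  # single motif at 85.2 is excluded
  sf1 <- structural_filter(hits[1, ], conf)
  expect_false(sf1$passed)

  # exactly 80.0 is excluded (strict inequality)
  conf80 <- data.frame(residue_index = 1:6, plddt = rep(80, 6))
  expect_false(structural_filter(hits[1, ], conf80)$passed)
  conf79 <- data.frame(residue_index = 1:6, plddt = rep(79.99, 6))
  expect_true(structural_filter(hits[1, ], conf79)$passed)
})

test_that("mean pLDDT is invariant to atom ordering within the file", {
  s <- "MKTAYILVAG"
  profile <- round(runif(10, 20, 95), 2)
  path <- tempfile(fileext = ".pdb")
  make_synthetic_structure(s, profile, path)
  lines <- readLines(path)
  atoms <- grep("^ATOM", lines)
  # reverse the atom order within every residue
  perm <- unlist(lapply(split(atoms, ceiling(seq_along(atoms) / 4)), rev),
                 use.names = FALSE)
  p2 <- write_tmp_lines(c(lines[perm], lines[-atoms]))
  expect_equal(read_plddt(p2)$plddt, read_plddt(path)$plddt)
})

test_that("lowering the pLDDT threshold never adds passing proteins", {
  set.seed(55)
  hits <- data.frame(protein_id = "p", start = c(1L, 11L), end = c(6L, 16L))
  for (rep in 1:20) {
    conf <- data.frame(residue_index = 1:16, plddt = runif(16, 0, 100))
    passed <- vapply(c(90, 80, 70, 50, 30),
                     function(th) structural_filter(hits, conf, th)$passed,
                     logical(1))
    expect_true(all(diff(as.integer(passed)) <= 0))
  }
})

test_that("multi-chain structures are rejected", {
  s <- "MKTAYI"
  path <- tempfile(fileext = ".pdb")
  make_synthetic_structure(s, rep(50, 6), path)
  lines <- readLines(path)
  atoms <- lines[grepl("^ATOM", lines)]
  other <- atoms
  substr(other, 22, 22) <- "B"
  p2 <- write_tmp_lines(c(atoms, other, "END"))
  suppressWarnings(expect_error(read_plddt(p2), "multi-chain"))
})
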