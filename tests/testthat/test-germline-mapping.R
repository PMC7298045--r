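test_that("identical sequences align without gaps or mismatches", {
  g <- germline_references()$VH
  q <- antibody_sequence("self", "heavy", g$residues)
  al <- align_to_germline(q, g)
  expect_false(any(al$aligned_query == "-"))
  expect_false(any(al$aligned_reference == "-"))
  expect_true(all(al$aligned_query == al$aligned_reference))
  expect_equal(nrow(identify_shm(al)), 0L)
})

test_that("parent heavy chain shows exactly the three framework SHM", {
  p <- parent_sequences(); g <- germline_references()
  shm <- identify_shm(align_to_germline(p$VH, g$VH))
  expect_equal(shm$position, c(14L, 20L, 81L))
  expect_equal(shm$germline_residue, c("P", "L", "Q"))
  expect_equal(shm$observed_residue, c("R", "P", "H"))
})

test_that("parent light chain shows the single position-1 SHM", {
  p <- parent_sequences(); g <- germline_references()
  shm <- identify_shm(align_to_germline(p$VL, g$VL))
  expect_equal(shm$position, 1L)
  expect_equal(shm$germline_residue, "D")
  expect_equal(shm$observed_residue, "A")
})

test_that("alignment score of a gapped pair matches the exhaustive DP oracle", {
  g <- germline_reference("g", "heavy", "EVQLLESGGGLV")
  # internal two-residue deletion
  q <- antibody_sequence("q", "heavy", "EVQLLGGGLV")
  al <- align_to_germline(q, g)
  expect_equal(al$score, nw_oracle_score("EVQLLGGGLV", "EVQLLESGGGLV"))
  # and a mismatching short pair
  g2 <- germline_reference("g2", "heavy", "DIQMTQSPSS")
  q2 <- antibody_sequence("q2", "heavy", "DIKMTQAPSS")
  expect_equal(align_to_germline(q2, g2)$score,
               nw_oracle_score("DIKMTQAPSS", "DIQMTQSPSS"))
})

test_that("alignment score is symmetric and SHM count equals Hamming distance", {
  set.seed(11)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "R", "S")
  for (rep in 1:5) {
    s1 <- paste(sample(aa, 25, TRUE), collapse = "")
    s2chars <- strsplit(s1, "")[[1]]
    flip <- sample(25, 4)
    s2chars[flip] <- sample(aa, 4, TRUE)
    s2 <- paste(s2chars, collapse = "")
    a12 <- align_to_germline(antibody_sequence("a", "heavy", s1),
                             germline_reference("b", "heavy", s2))
    a21 <- align_to_germline(antibody_sequence("b", "heavy", s2),
                             germline_reference("a", "heavy", s1))
    expect_equal(a12$score, a21$score)
    # gap-free equal-length pair: SHM records = positional Hamming distance
    if (!any(a12$aligned_query == "-") && !any(a12$aligned_reference == "-")) {
      hamming <- sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
      expect_equal(nrow(identify_shm(a12)), hamming)
    }
  }
})

test_that("mismatches involving X are not reported as SHM", {
  g <- germline_reference("g", "heavy", "EVQLLESGGG")
  q <- antibody_sequence("q", "heavy", "EVXLLESGGG")
  expect_equal(nrow(identify_shm(align_to_germline(q, g))), 0L)
})

test_that("input validation rejects chain mismatch and empty sequences", {
  g <- germline_references()$VH
  vl <- parent_sequences()$VL
  expect_error(align_to_germline(vl, g), "chain mismatch")
  expect_error(antibody_sequence("bad", "heavy", character(0)), "at least one")
  expect_error(antibody_sequence("bad", "heavy", "EVQZ"), "non-canonical")
})

test_that("FASTA round trip preserves sequences and chain inference works", {
  tmp <- tempfile(fileext = ".fasta")
  p <- parent_sequences()
  write_antibody_fasta(list(p$VH, p$VL), tmp)
  back <- read_antibody_fasta(tmp)
  expect_equal(back[[1]]$residues, p$VH$residues)
  expect_equal(back[[1]]$chain, "heavy")
  expect_equal(back[[2]]$chain, "kappa")
  # packaged synthetic scaffolds load and match the registry
  scaff <- read_antibody_fasta(system.file("extdata",
                                           "germline_scaffolds_synthetic.fasta",
                                           package = "abstab"))
  reg <- fixture_registry()$sequences
  expect_equal(paste(scaff[[1]]$residues, collapse = ""), reg$heavy_germline)
  expect_equal(paste(scaff[[2]]$residues, collapse = ""), reg$light_germline)
})

test_that("alignment report tabulates every column with a match flag", {
  p <- parent_sequences(); g <- germline_references()
  al <- align_to_germline(p$VH, g$VH)
  rep <- alignment_report(al)
  expect_equal(nrow(rep), length(al$aligned_query))
  expect_equal(sum(!rep$match), 3L)
  tmp <- tempfile(fileext = ".tsv")
  alignment_report(al, tmp)
  expect_true(file.exists(tmp))
})
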