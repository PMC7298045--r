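test_that("single-sequence profile assigns frequency 1 to observed residues", {
  s <- antibody_sequence("one", "heavy", "EVQLLESGGG")
  prof <- build_profile(list(s), "heavy", min_coverage = 1)
  expect_true(all(prof$table$frequency == 1))
  expect_equal(nrow(prof$table), 10L)
})

test_that("profile frequencies match hand counts and sum to one", {
  seqs <- lapply(c("AAAAAAA", "AAAAAAA", "AAAAAAA", "AAAAAAC"), function(x)
    antibody_sequence(x, "heavy", x))
  prof <- build_profile(seqs, "heavy", min_coverage = 1)
  expect_equal(abstab:::profile_lookup(prof, 7L, "C"), 0.25)
  expect_equal(abstab:::profile_lookup(prof, 7L, "A"), 0.75)
  sums <- tapply(prof$table$frequency, prof$table$position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("profile recovery error shrinks as 1/sqrt(n) on planted repertoires", {
  spec <- repertoire_spec("EVQLLESGGGLV", "heavy",
                          planted = list("5" = c(L = 0.7, P = 0.2, R = 0.1)))
  errs <- vapply(c(200, 2000, 20000), function(n) {
    prof <- build_profile(generate_repertoire(spec, n, seed = 5), "heavy")
    abs(abstab:::profile_lookup(prof, 5L, "P") - 0.2)
  }, numeric(1))
  # each estimate within 3 multinomial SD of the planted truth
  sds <- sqrt(0.2 * 0.8 / c(200, 2000, 20000))
  expect_true(all(errs < 3 * sds))
  # and the large-n error is far below the small-n bound
  expect_lt(errs[3], 3 * sds[1])
})

test_that("printed-frequency fixture flags the sub-1% positions only", {
  p <- parent_sequences(); g <- germline_references()
  shm <- identify_shm(align_to_germline(p$VH, g$VH))
  flags <- flag_rare(shm, printed_frequency_profile())
  expect_equal(flags$observed_frequency, c(0.0015, 0.0009, 0.016))
  expect_equal(flags$modal_residue, c("P", "L", "Q"))
  expect_equal(flags$modal_frequency, c(0.9503, 0.7302, 0.5758))
  expect_equal(flags$is_rare, c(TRUE, TRUE, FALSE))
  expect_true(all(flags$status == "ok"))
})

test_that("rarity comparison is strict and monotone in the threshold", {
  shm <- data.frame(position = 14L, germline_residue = "P",
                    observed_residue = "R", region = NA_character_)
  prof <- printed_frequency_profile()
  # exactly at the threshold: not rare (strict <)
  at <- flag_rare(shm, prof, threshold = 0.0015)
  expect_false(at$is_rare)
  # monotone: raising the threshold never unflags
  thresholds <- c(0.001, 0.0015, 0.002, 0.01, 0.05)
  rare <- vapply(thresholds, function(th)
    flag_rare(shm, prof, th)$is_rare, logical(1))
  expect_true(all(diff(rare) >= 0))
})

test_that("positions absent from the profile report unknown, never silently drop", {
  shm <- data.frame(position = c(14L, 50L), germline_residue = c("P", "A"),
                    observed_residue = c("R", "G"), region = NA_character_)
  flags <- flag_rare(shm, printed_frequency_profile())
  expect_equal(nrow(flags), 2L)
  expect_equal(flags$status, c("ok", "unknown"))
  expect_true(is.na(flags$is_rare[2]))
})

test_that("unusual-residue counts match the threshold arithmetic and a scan oracle", {
  g <- germline_references()
  p <- parent_sequences()
  # germline-identical antibody counts (0, 0)
  self <- list(name = "germ", VH = antibody_sequence("g_VH", "heavy", g$VH$residues),
               VL = antibody_sequence("g_VL", "kappa", g$VL$residues))
  profiles <- list(heavy = printed_frequency_profile(), light = NULL)
  counts <- count_unusual(list(self), profiles, g)
  expect_equal(counts$heavy_count, 0L)
  # the parent: printed frequencies 0.0015 / 0.0009 / 0.016 at threshold 1%
  counts_p <- count_unusual(list(make_parent_panel()), profiles, g)
  expect_equal(counts_p$heavy_count, 2L)
  # synthetic panel with planted rare residues vs brute-force oracle
  reg <- fixture_registry()$sequences
  spec <- repertoire_spec(reg$heavy_germline, "heavy")
  prof <- build_profile(generate_repertoire(spec, 3000, seed = 9), "heavy")
  germ_chars <- strsplit(reg$heavy_germline, "")[[1]]
  set.seed(21)
  panel <- lapply(1:5, function(i) {
    q <- germ_chars
    k <- sample(0:3, 1)
    if (k > 0) {
      pos <- sample(seq_along(q), k)
      for (p2 in pos) q[p2] <- sample(setdiff(c("W", "C", "M", "H"), q[p2]), 1)
    }
    list(name = paste0("ab", i),
         VH = antibody_sequence(paste0("ab", i, "_VH"), "heavy", q),
         VL = antibody_sequence(paste0("ab", i, "_VL"), "kappa",
                                germline_references()$VL$residues))
  })
  got <- count_unusual(panel, list(heavy = prof, light = NULL), g)
  want <- vapply(panel, function(ab)
    rare_scan_oracle(ab$VH$residues, germ_chars, prof$table), integer(1))
  expect_equal(got$heavy_count, want)
})

test_that("profile TSV round-trips bit-exactly", {
  spec <- repertoire_spec("EVQLLESGG", "heavy")
  prof <- build_profile(generate_repertoire(spec, 500, seed = 2), "heavy")
  tmp <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, tmp)
  back <- read_profile_tsv(tmp)
  expect_identical(back$table$frequency, prof$table$frequency)
  expect_identical(back$table$position, prof$table$position)
  expect_identical(back$table$residue, prof$table$residue)
  # the packaged fixture TSV equals the in-code printed profile
  fix <- read_profile_tsv(system.file("extdata", "hc_positional_frequencies.tsv",
                                      package = "abstab"))
  expect_true(fix$partial)
  expect_equal(fix$table$frequency, printed_frequency_profile()$table$frequency)
})

test_that("low-coverage positions are omitted and empty repertoires rejected", {
  s <- antibody_sequence("one", "heavy", "EVQLL")
  expect_error(build_profile(list(), "heavy"), "empty")
  prof_default <- tryCatch(build_profile(list(s), "heavy"), error = identity)
  expect_true(inherits(prof_default, "error"))  # 1 < default min_coverage 10
})
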