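test_that("FOD counts residues at or above the threshold", {
  expect_equal(fod_from_profile(c(0.6, 0.6, 0.2, 0.2)), 0.5)
  expect_equal(fod_from_profile(rep(0, 10)), 0)
  # threshold is inclusive
  expect_equal(fod_from_profile(c(0.5, 0.49, 0.51)), 2 / 3)
  p <- disorder_profile("x", scores = c(0.1, 0.9))
  expect_equal(fod_from_profile(p), 0.5)
  expect_error(fod_from_profile(disorder_profile("x", whole_score = 0.4)),
               class = "thermidr_unavailable_profile")
})

test_that("FOD is monotone non-increasing in the threshold", {
  set.seed(11)
  for (i in 1:20) {
    scores <- runif(sample(10:200, 1))
    thresholds <- sort(runif(10))
    fods <- vapply(thresholds, function(t) fod_from_profile(scores, t), 0)
    expect_true(all(diff(fods) <= 0))
  }
})

test_that("candidate rules fire exactly as specified", {
  expect_true(is_candidate(0.50, 50, 1)$score_rule)
  expect_true(is_candidate(0.50, 50, 1)$is_candidate)
  m <- is_candidate(0.25, 400, 1) # 400 * 0.25 = 100, boundary inclusive
  expect_true(m$mass_rule)
  expect_false(m$score_rule)
  expect_true(m$is_candidate)
  expect_false(is_candidate(0.10, 50, 2)$is_candidate)
  c5 <- is_candidate(0.10, 50, 5)
  expect_true(c5$class_rule && c5$is_candidate)
  expect_error(is_candidate(0.5, 0, 1), class = "thermidr_invalid_input")
})

test_that("candidate decisions equal a literal rule enumeration on a proteome", {
  cfg <- sim_config(seed = 77, n_proteins_per_species = 150)
  prot <- generate_proteome(cfg, n = 150)
  comp <- compose_proteins(prot)
  comp$whole_score <- ch_heuristic_score(prot$sequence)
  dec <- candidate_decisions(comp)
  manual <- logical(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    manual[i] <- comp$whole_score[i] >= 0.5 ||
      comp$length[i] * comp$whole_score[i] >= 100 ||
      comp$region[i] %in% c(3, 4, 5)
  }
  expect_identical(dec$is_candidate, manual)
  expect_identical(dec$is_candidate,
                   dec$score_rule | dec$mass_rule | dec$class_rule)
})

test_that("charge-hydropathy heuristic separates charged from hydrophobic", {
  expect_gt(ch_heuristic_score("KKKKKKKKKK"), 0.5)
  expect_lt(ch_heuristic_score("IIIIIIIIII"), 0.5)
  # composition-only: invariant under shuffling
  set.seed(33)
  s <- random_peptide(30, 200)
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(ch_heuristic_score(s), ch_heuristic_score(shuffled))
})

test_that("windowed profile matches the per-window heuristic definition", {
  set.seed(44)
  s <- random_peptide(40, 60)
  chars <- strsplit(s, "")[[1]]
  prof <- ch_profile(s, window = 7)
  naive <- vapply(seq_along(chars), function(i) {
    win <- chars[max(1, i - 3):min(length(chars), i + 3)]
    ch_heuristic_score(paste(win, collapse = ""))
  }, 0)
  expect_equal(prof, naive, tolerance = 1e-12)
})

test_that("profile TSV reading validates structure and reports line numbers", {
  good <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tresidue\tscore", "1\tM\t0.9", "2\tK\t0.5",
               "3\tG\t0.1"), good)
  p <- read_profile_tsv(good, protein_id = "p1", sequence = "MKG")
  expect_s3_class(p, "disorder_profile")
  expect_length(p$scores, 3)
  expect_equal(fod_from_profile(p), 2 / 3)

  gap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tresidue\tscore", "1\tM\t0.9", "2\tK\t0.5",
               "4\tG\t0.1"), gap)
  err <- tryCatch(read_profile_tsv(gap), error = identity)
  expect_s3_class(err, "thermidr_format_error")
  expect_match(conditionMessage(err), "line 4")

  range_bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tresidue\tscore", "1\tM\t1.3"), range_bad)
  expect_error(read_profile_tsv(range_bad), class = "thermidr_format_error")

  # tiny numeric fuzz is clipped, not rejected
  fuzz <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tresidue\tscore", "1\tM\t1.0000000001"), fuzz)
  expect_equal(read_profile_tsv(fuzz)$scores, 1)

  mism <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tresidue\tscore", "1\tM\t0.9", "2\tK\t0.5"), mism)
  err <- tryCatch(read_profile_tsv(mism, sequence = "MG"), error = identity)
  expect_s3_class(err, "thermidr_format_error")
  expect_match(conditionMessage(err), "line 3")
})

test_that("profile TSV writing round-trips", {
  seq <- "MKGDE"
  prof <- disorder_profile("p9", scores = c(0.9, 0.8, 0.1, 0.2, 0.7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, seq, path)
  back <- read_profile_tsv(path, protein_id = "p9", sequence = seq)
  expect_equal(back$scores, prof$scores)
})
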