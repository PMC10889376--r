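test_that("composition metrics match hand counts and invariants", {
  m <- compute_composition(c("EEKK", "GGGG", "KKDKKGGGGG"))
  expect_equal(m$f_plus, c(0.5, 0, 0.4))
  expect_equal(m$f_minus, c(0.5, 0, 0.1))
  expect_equal(m$fcr, c(1, 0, 0.5))
  expect_equal(m$ncpr, c(0, 0, 0.3))
  expect_equal(m$fcr, m$f_plus + m$f_minus)
  expect_equal(m$ncpr, m$f_plus - m$f_minus)
  expect_true(all(abs(m$ncpr) <= m$fcr))
  expect_true(all(m$mean_hydropathy >= 0 & m$mean_hydropathy <= 1))
  # X sits at the hydropathy midpoint and carries no charge
  mx <- compute_composition("XXXX")
  expect_equal(mx$mean_hydropathy, 0.5)
  expect_equal(mx$fcr, 0)
})

test_that("mean net charge equals NCPR", {
  expect_equal(mean_net_charge("DDDD"), -1)
  expect_equal(mean_net_charge("EEKK"), 0)
  expect_equal(mean_net_charge("KKDKKGGGGG"), 0.3)
})

test_that("composition is invariant under sequence reversal", {
  set.seed(101)
  for (i in 1:25) {
    s <- random_peptide(5, 80)
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(compute_composition(s), compute_composition(r))
  }
})

test_that("invalid sequences are rejected with position information", {
  expect_error(compute_composition(""), class = "thermidr_invalid_input")
  err <- tryCatch(compute_composition("ACDB"), error = identity)
  expect_s3_class(err, "thermidr_invalid_input")
  expect_match(conditionMessage(err), "'B'")
  expect_match(conditionMessage(err), "position 4")
})

test_that("region assignment follows the five-region conventions", {
  # weakly charged, neutral
  expect_equal(das_pappu_region(0.05, 0.05), 1L)
  # fully charged, balanced -> strong polyampholyte
  expect_equal(das_pappu_region(0.5, 0.5), 3L)
  # pure poly-cation -> positive strong polyelectrolyte
  expect_equal(das_pappu_region(1, 0), 5L)
  expect_equal(das_pappu_region(0, 1), 4L)
  # boundary conventions: FCR = 0.25 and 0.35 are region 2; |NCPR| = 0.35 is 3
  expect_equal(das_pappu_region(0.125, 0.125), 2L)
  expect_equal(das_pappu_region(0.175, 0.175), 2L)
  expect_equal(das_pappu_region(0.45, 0.10), 3L)   # ncpr exactly 0.35, fcr 0.55
  expect_equal(das_pappu_region(0.50, 0.05), 5L)   # ncpr 0.45
  expect_equal(
    das_pappu_label(1:5),
    c("weak polyampholyte/polyelectrolyte", "boundary",
      "strong polyampholyte", "negative strong polyelectrolyte",
      "positive strong polyelectrolyte")
  )
})

test_that("classification agrees with a brute-force oracle on random peptides", {
  set.seed(202)
  seqs <- replicate(1500, random_peptide(5, 120))
  m <- classify_das_pappu(compute_composition(seqs))
  oracle <- mapply(oracle_region, m$f_plus, m$f_minus)
  expect_identical(m$region, as.integer(oracle))
})

test_that("the (f+, f-) grid is fully and disjointly covered", {
  grid <- expand.grid(f_plus = seq(0, 1, by = 0.01),
                      f_minus = seq(0, 1, by = 0.01))
  grid <- grid[grid$f_plus + grid$f_minus <= 1 + 1e-12, ]
  got <- das_pappu_region(grid$f_plus, grid$f_minus)
  oracle <- mapply(oracle_region, grid$f_plus, grid$f_minus)
  expect_false(anyNA(oracle)) # exactly one region predicate per point
  expect_identical(got, as.integer(oracle))
})

test_that("protein FASTA round-trips ids, species and tags", {
  tbl <- tibble::tibble(
    id = c("p1", "p2"),
    species_id = c("spA", "spB"),
    function_tags = list(c("ribosomal_protein", "rRNA-binding"), character(0)),
    sequence = c("MKKDE", "GGSST")
  )
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(tbl, path)
  back <- read_protein_fasta(path)
  expect_equal(back$id, tbl$id)
  expect_equal(back$species_id, tbl$species_id)
  expect_equal(back$function_tags, tbl$function_tags)
  expect_equal(back$sequence, tbl$sequence)
})

test_that("compose_proteins emits the per-protein report columns", {
  prot <- tibble::tibble(id = c("a", "b"), species_id = "s1",
                         sequence = c("KKKKKKKKKK", "GGGGGGGGGG"))
  out <- compose_proteins(prot)
  expect_named(out, c("id", "species_id", "length", "f_plus", "f_minus",
                      "fcr", "ncpr", "mean_hydropathy", "region",
                      "region_label"))
  expect_equal(out$region, c(5L, 1L))
})
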