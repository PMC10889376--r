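test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 42, n_species = 10)
  t1 <- simulate_tree(cfg); t2 <- simulate_tree(cfg)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_identical(evolve_traits(t1, cfg), evolve_traits(t1, cfg))
  expect_identical(evolve_sequences_jc(t1, cfg), evolve_sequences_jc(t1, cfg))
  expect_identical(generate_proteome(cfg, n = 10), generate_proteome(cfg, n = 10))
  expect_identical(simulate_ortholog_proteomes(t1$tip.label, cfg),
                   simulate_ortholog_proteomes(t1$tip.label, cfg))
})

test_that("simulated trees are binary, ultrametric, correctly sized", {
  cfg2 <- sim_config(seed = 1, n_species = 2)
  tr2 <- simulate_tree(cfg2)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(tr2$Nnode, 1)

  cfg50 <- sim_config(seed = 2, n_species = 50, tree_height = 3)
  tr50 <- simulate_tree(cfg50)
  expect_equal(tr50$Nnode, 49)
  expect_true(ape::is.binary(tr50))
  expect_lt(ultrametric_deviation(tr50), 1e-9)
  expect_equal(max(ape::node.depth.edgelength(tr50)), 3)
})

test_that("zero-variance traits stay at the root values", {
  cfg <- sim_config(seed = 3, n_species = 12, bm_sigma_ogt = 0,
                    bm_sigma_fod = 0)
  tr <- simulate_tree(cfg)
  traits <- evolve_traits(tr, cfg)
  expect_equal(traits$ogt, rep(cfg$root_ogt, 12))
  expect_equal(traits$fod, rep(cfg$root_fod, 12))
})

test_that("a clade-level OGT confound shifts exactly one clade", {
  cfg <- sim_config(seed = 4, n_species = 16, bm_sigma_ogt = 0,
                    bm_sigma_fod = 0, confound_shift = 20)
  tr <- simulate_tree(cfg)
  traits <- evolve_traits(tr, cfg)
  clade <- attr(traits, "confound_clade")
  expect_true(length(clade) >= 2 && length(clade) < 16)
  expect_equal(sort(unique(traits$ogt)), c(35, 55))
  expect_setequal(traits$species[traits$ogt == 55], clade)
})

test_that("JC-evolved sequences behave like the model says", {
  cfg0 <- sim_config(seed = 5, n_species = 6, jc_rate = 0)
  tr <- simulate_tree(cfg0)
  s0 <- evolve_sequences_jc(tr, cfg0)
  expect_equal(length(unique(s0)), 1) # rate 0: all identical
  expect_equal(unique(nchar(s0)), cfg0$seq_length_16s)

  # empirical pairwise difference matches the JC expectation on a cherry
  cfg <- sim_config(seed = 6, jc_rate = 0.2, seq_length_16s = 20000)
  cherry <- read_newick("(A:0.5,B:0.5);", text = TRUE)
  seqs <- evolve_sequences_jc(cherry, cfg)
  p_hat <- identity_distance(seqs[["A"]], seqs[["B"]])
  p_exp <- 0.75 * (1 - exp(-4 * 0.2 * 1 / 3))
  expect_lt(abs(p_hat - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / 20000))
})

test_that("proteome generation hits the requested regions", {
  cfg <- sim_config(seed = 8)
  prot <- generate_proteome(cfg, region_mix = c("1" = 1), n = 25)
  comp <- compose_proteins(prot)
  expect_true(all(comp$region == 1L))

  prot_all <- generate_proteome(cfg, n = 600)
  comp_all <- compose_proteins(prot_all)
  # classification recovers the intended region for every sequence
  expect_identical(comp_all$region, as.integer(prot_all$region_intended))
  # empirical mix within 3 binomial SE of the default mix
  mix <- cfg$region_mix
  for (r in names(mix)) {
    p <- mix[[r]]
    se <- sqrt(p * (1 - p) / 600)
    expect_lt(abs(mean(prot_all$region_intended == as.integer(r)) - p), 3 * se)
  }
})

test_that("trait evolution has the prescribed contrast-level slope", {
  set.seed(9)
  slopes <- vapply(1:25, function(i) {
    cfg <- sim_config(seed = 9000 + i, n_species = 32, true_slope = 0.5)
    tr <- simulate_tree(cfg)
    ct <- compute_contrasts(tr, evolve_traits(tr, cfg))
    contrast_regression(ct)$slope
  }, 0)
  expect_lt(abs(mean(slopes) - 0.5), 3 * sd(slopes) / sqrt(25))
})

test_that("point mutation changes the requested number of positions", {
  set.seed(10)
  s <- random_peptide(100, 100)
  m <- mutate_protein(s, 0.1)
  d <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(d, 10)
  expect_identical(mutate_protein(s, 0), s)
})

test_that("outgroup attachment keeps the tree ultrametric", {
  cfg <- sim_config(seed = 11, n_species = 8)
  tr <- simulate_tree(cfg)
  out <- add_outgroup(tr, "OUT")
  expect_true("OUT" %in% out$tip.label)
  expect_equal(ape::Ntip(out), 9)
  expect_lt(ultrametric_deviation(out), 1e-9)
  back <- root_and_prune_outgroup(out, "OUT")
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-9)
})
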