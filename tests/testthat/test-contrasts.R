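test_that("ancestral states solve closed-form small cases", {
  # equal branches: root is the midpoint
  tr <- read_newick("(A:1,B:1);", text = TRUE)
  fit <- infer_ancestral_states(tr, c(A = 0, B = 1))
  expect_equal(unname(fit$states), 0.5)

  # branches 1 and 3: 1/b-weighted mean (0/1 + 1/3) / (1 + 1/3) = 0.25
  tr2 <- read_newick("(A:1,B:3);", text = TRUE)
  fit2 <- infer_ancestral_states(tr2, c(A = 0, B = 1))
  expect_equal(unname(fit2$states), 0.25)

  # constant leaves: exact fit everywhere, RSS 0
  set.seed(12)
  tr3 <- ape::rcoal(9)
  fit3 <- infer_ancestral_states(tr3, setNames(rep(2.5, 9), tr3$tip.label))
  expect_equal(unname(fit3$states), rep(2.5, tr3$Nnode))
  expect_equal(fit3$rss, 0)
})

test_that("reported RSS equals the objective at the returned states", {
  set.seed(13)
  tr <- ape::rcoal(12)
  vals <- setNames(rnorm(12), tr$tip.label)
  fit <- infer_ancestral_states(tr, vals)
  expect_equal(fit$rss, ancestral_rss(tr, vals, fit$states), tolerance = 1e-12)
  expect_lt(max(abs(rss_gradient(tr, vals, fit$states))), 1e-8)
})

test_that("states match a numeric minimizer on random trees", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(4:16, 1)
    tr <- ape::rcoal(n)
    vals <- setNames(runif(n, 0, 10), tr$tip.label)
    fit <- infer_ancestral_states(tr, vals)
    expect_lt(max(abs(oracle_optim_states(tr, vals) - fit$states)), 1e-6)
  }
})

test_that("unweighted variant averages without branch lengths", {
  tr <- read_newick("(A:1,B:3);", text = TRUE)
  fit <- infer_ancestral_states(tr, c(A = 0, B = 1), weighted = FALSE)
  expect_equal(unname(fit$states), 0.5)
})

test_that("cherry contrasts follow the definition and its symmetries", {
  tr <- read_newick("(A:1,B:1);", text = TRUE)
  traits <- tibble::tibble(species = c("A", "B"), fod = c(3, 1))
  ct <- compute_contrasts(tr, traits, vars = "fod")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$delta_fod, 2)
  expect_equal(ct$weight, sqrt(2))
  expect_equal(ct$std_fod, 2 / sqrt(2))

  # swapping the children's values negates the contrast
  swapped <- tibble::tibble(species = c("A", "B"), fod = c(1, 3))
  expect_equal(compute_contrasts(tr, swapped, vars = "fod")$delta_fod, -2)

  # constant traits give zero contrasts everywhere
  set.seed(15)
  tr2 <- ape::rcoal(10)
  const <- tibble::tibble(species = tr2$tip.label, fod = 7)
  expect_equal(compute_contrasts(tr2, const, vars = "fod")$delta_fod,
               rep(0, 9))
})

test_that("binary trees give one contrast per internal node", {
  set.seed(16)
  for (n in c(4, 16, 33)) {
    tr <- ape::rcoal(n)
    traits <- tibble::tibble(species = tr$tip.label, fod = rnorm(n),
                             ogt = rnorm(n))
    ct <- compute_contrasts(tr, traits)
    expect_equal(nrow(ct), n - 1)
    expect_setequal(ct$node, (n + 1):(2 * n - 1))
  }
})

test_that("non-binary nodes are resolved with a warning", {
  tr <- read_newick("(A:1,B:1,C:1);", text = TRUE)
  traits <- tibble::tibble(species = c("A", "B", "C"), fod = c(1, 2, 3))
  expect_warning(ct <- compute_contrasts(tr, traits, vars = "fod"),
                 "non-binary")
  expect_equal(nrow(ct), 2)
})

test_that("BM contrasts are centred, calibrated on cherries, homogeneous", {
  cfg0 <- sim_config(seed = 170, n_species = 64, bm_sigma_ogt = 1,
                     bm_sigma_fod = 0)
  tr <- simulate_tree(cfg0)
  n <- ape::Ntip(tr)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  cherries <- as.integer(names(kids))[vapply(kids, function(k) all(k <= n),
                                             TRUE)]
  ct_all <- purrr::map_dfr(1:60, function(i) {
    cfg <- sim_config(seed = 5000 + i, n_species = 64, bm_sigma_ogt = 1)
    compute_contrasts(tr, evolve_traits(tr, cfg), vars = "ogt")
  })
  std <- ct_all$std_ogt
  # mean zero within Monte-Carlo error
  expect_lt(abs(mean(std)) / (sd(std) / sqrt(length(std))), 4)
  # cherry contrasts (both children observed) have variance sigma^2 exactly
  cherry_std <- std[ct_all$node %in% cherries]
  expect_lt(abs(var(cherry_std) - 1), 0.1)
  # smoothing of inferred states shrinks the rest, but boundedly
  expect_gt(var(std), 0.7)
  expect_lt(var(std), 1.05)
  # homogeneity across branch-length strata (Fligner-Killeen on weight terciles)
  strata <- cut(ct_all$weight, quantile(ct_all$weight, c(0, 1/3, 2/3, 1)),
                include.lowest = TRUE)
  expect_gt(stats::fligner.test(cherry_std,
                                strata[ct_all$node %in% cherries])$p.value,
            0.001)
})

test_that("origin regression matches closed forms and lm", {
  fit <- origin_regression(c(1, 2), c(2, 4))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$p_value, 0)

  expect_equal(origin_regression(c(1, 2, 3), c(0, 0, 0))$slope, 0)
  expect_error(origin_regression(c(0, 0, 0), c(1, 2, 3)),
               class = "thermidr_undefined_slope")

  set.seed(18)
  x <- rnorm(40); y <- 0.7 * x + rnorm(40, 0, 0.3)
  fit <- origin_regression(x, y)
  ref <- summary(lm(y ~ 0 + x))
  expect_equal(fit$slope, unname(ref$coefficients[1, 1]), tolerance = 1e-12)
  expect_equal(fit$se, unname(ref$coefficients[1, 2]), tolerance = 1e-12)
  expect_equal(fit$p_value, unname(ref$coefficients[1, 4]), tolerance = 1e-12)
  expect_equal(fit$r_squared, ref$r.squared, tolerance = 1e-12)

  td <- tidy(fit)
  expect_equal(td$estimate, fit$slope)
  gl <- glance(fit)
  expect_equal(gl$nobs, 40)
})

test_that("origin regression recovers a known slope from noisy contrasts", {
  set.seed(19)
  x <- rnorm(100)
  y <- 0.5 * x + rnorm(100, 0, 0.1)
  fit <- origin_regression(x, y)
  expect_lt(abs(fit$slope - 0.5), 3 * fit$se)
})
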