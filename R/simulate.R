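# Synthetic-data generators with known ground truth: ultrametric species
# trees, Brownian-motion OGT/FOD traits with a tunable evolutionary slope
# and a tunable clade-level confound, Jukes-Cantor 16S-like sequences, and
# composition-templated proteomes spanning the five diagram-of-states
# regions.
#
# Reproducibility: every generator seeds the RNG from `config$seed` plus a
# fixed per-generator offset (tree +0, traits +1, sequences +2, flat
# proteome +3, ortholog proteomes +4), so each output is bit-reproducible
# on its own and independent of call order.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' Defaults describe the reference study conditions: 32 species, tree
#' height 1, OGT Brownian motion with sd 10 degrees C per unit branch
#' around a 35 degrees C root (so both mesophiles and thermophiles occur),
#' FOD Brownian noise with sd 0.05 around a 0.15 root, no evolutionary
#' OGT-FOD relationship (`true_slope = 0`), no
#' confounding, 16S-like sequences of 1200 bp at 0.2 substitutions per
#' site per unit height.
#'
#' @param seed Integer RNG seed.
#' @param n_species Number of species (>= 2).
#' @param n_proteins_per_species Proteins per species for the flat proteome
#'   generator.
#' @param n_families Ortholog families for [simulate_ortholog_proteomes()].
#' @param n_unique_per_species Species-private (unclustered) proteins.
#' @param tree_height Height of the ultrametric species tree.
#' @param bm_sigma_ogt Brownian sd of OGT per unit branch length
#'   (degrees C).
#' @param bm_sigma_fod Brownian sd of the FOD noise per unit branch length.
#' @param true_slope Evolutionary regression coefficient of FOD on OGT:
#'   each FOD increment equals `true_slope` times the OGT increment plus
#'   independent Brownian noise.
#' @param confound_shift OGT offset (degrees C) added to one clade
#'   (the clade closest to half the leaves) after trait evolution; with
#'   `true_slope = 0` this creates a leaf-level OGT-FOD association that is
#'   purely phylogenetic.
#' @param root_ogt,root_fod Root trait values.
#' @param seq_length_16s Length of the simulated 16S-like marker (bp).
#' @param jc_rate Jukes-Cantor substitution rate per site per unit branch.
#' @param protein_length Length range (min, max) for generated proteins.
#' @param family_divergence Per-copy point-mutation fraction within an
#'   ortholog family.
#' @param region_mix Named numeric distribution over diagram-of-states
#'   regions `"1"`..`"5"` for generated proteins.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 32L,
                       n_proteins_per_species = 25L,
                       n_families = 20L,
                       n_unique_per_species = 4L,
                       tree_height = 1,
                       bm_sigma_ogt = 10,
                       bm_sigma_fod = 0.05,
                       true_slope = 0,
                       confound_shift = 0,
                       root_ogt = 35,
                       root_fod = 0.15,
                       seq_length_16s = 1200L,
                       jc_rate = 0.2,
                       protein_length = c(60L, 150L),
                       family_divergence = 0.1,
                       region_mix = c("1" = 0.55, "2" = 0.25, "3" = 0.15,
                                      "4" = 0.025, "5" = 0.025)) {
  cfg <- list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    n_proteins_per_species = as.integer(n_proteins_per_species),
    n_families = as.integer(n_families),
    n_unique_per_species = as.integer(n_unique_per_species),
    tree_height = tree_height, bm_sigma_ogt = bm_sigma_ogt,
    bm_sigma_fod = bm_sigma_fod, true_slope = true_slope,
    confound_shift = confound_shift, root_ogt = root_ogt,
    root_fod = root_fod, seq_length_16s = as.integer(seq_length_16s),
    jc_rate = jc_rate, protein_length = as.integer(protein_length),
    family_divergence = family_divergence,
    region_mix = region_mix / sum(region_mix)
  )
  if (cfg$n_species < 2) stop_invalid("n_species must be >= 2")
  if (cfg$tree_height <= 0) stop_invalid("tree_height must be positive")
  nonneg <- c("bm_sigma_ogt", "bm_sigma_fod", "jc_rate")
  for (f in nonneg) {
    if (cfg[[f]] < 0) stop_invalid(sprintf("%s must be >= 0", f))
  }
  if (!all(names(cfg$region_mix) %in% as.character(1:5))) {
    stop_invalid("region_mix must be named by regions 1..5")
  }
  if (cfg$family_divergence < 0 || cfg$family_divergence > 1) {
    stop_invalid("family_divergence must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric species tree
#'
#' Draws a random binary coalescent tree and rescales it to
#' `config$tree_height`. Leaves are labeled `sp001`, `sp002`, ...
#'
#' @param config A [sim_config()].
#' @return A rooted binary ultrametric `phylo`.
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  tree <- ape::rcoal(config$n_species,
                     tip.label = sprintf("sp%03d", seq_len(config$n_species)))
  height <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * config$tree_height / height
  tree
}

# tip labels of the clade whose leaf count is closest to half the tree
# (ties to the smallest node number): the clade receiving the confound
balanced_clade <- function(tree) {
  n <- ape::Ntip(tree)
  parts <- ape::prop.part(tree)
  sizes <- lengths(parts)
  target <- n / 2
  # skip the root (all leaves)
  cand <- which(sizes < n)
  best <- cand[which.min(abs(sizes[cand] - target))]
  tree$tip.label[parts[[best]]]
}

#' Evolve OGT and FOD traits along a tree
#'
#' Brownian-motion trait evolution: along each branch of length `b`, the
#' OGT increment is `N(0, bm_sigma_ogt^2 * b)` and the FOD increment is
#' `true_slope` times the OGT increment plus independent
#' `N(0, bm_sigma_fod^2 * b)` noise, so contrast-level regression of FOD on
#' OGT has expectation `true_slope`. When `confound_shift != 0`, the shift
#' is added to the OGT of every leaf in the balanced clade after
#' evolution, creating a purely clade-level OGT-FOD association.
#'
#' @param tree A rooted binary `phylo` (e.g. from [simulate_tree()]).
#' @param config A [sim_config()].
#' @return Tibble with columns `species`, `ogt`, `fod`; the shifted clade's
#'   tip labels are attached as attribute `"confound_clade"` when
#'   confounding is on.
#' @export
evolve_traits <- function(tree, config) {
  set.seed(config$seed + 1L)
  n <- ape::Ntip(tree)
  ogt <- fod <- numeric(n + tree$Nnode)
  root <- n + 1L
  ogt[root] <- config$root_ogt
  fod[root] <- config$root_fod
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  b <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (e in rev(seq_len(nrow(edge)))) { # reverse postorder: parents first
    p <- edge[e, 1]; child <- edge[e, 2]
    d_ogt <- rnorm(1, 0, config$bm_sigma_ogt * sqrt(b[e]))
    d_fod <- config$true_slope * d_ogt + rnorm(1, 0, config$bm_sigma_fod * sqrt(b[e]))
    ogt[child] <- ogt[p] + d_ogt
    fod[child] <- fod[p] + d_fod
  }
  out <- tibble(species = tree$tip.label,
                ogt = ogt[seq_len(n)], fod = fod[seq_len(n)])
  if (config$confound_shift != 0) {
    clade <- balanced_clade(tree)
    out$ogt[out$species %in% clade] <- out$ogt[out$species %in% clade] +
      config$confound_shift
    attr(out, "confound_clade") <- clade
  }
  out
}

#' Evolve aligned 16S-like sequences under Jukes-Cantor
#'
#' A uniform-random root sequence of length `seq_length_16s` evolves along
#' the tree; on a branch of length `b` each site substitutes with
#' probability `3/4 * (1 - exp(-4 * jc_rate * b / 3))`, uniformly to one of
#' the other three nucleotides. Leaves are returned as equal-length
#' (ungapped, i.e. trivially aligned) sequences.
#'
#' @param tree A rooted `phylo`.
#' @param config A [sim_config()].
#' @return Named character vector of leaf sequences.
#' @export
evolve_sequences_jc <- function(tree, config) {
  set.seed(config$seed + 2L)
  nt <- c("A", "C", "G", "T")
  L <- config$seq_length_16s
  n <- ape::Ntip(tree)
  seqs <- vector("list", n + tree$Nnode)
  root <- n + 1L
  seqs[[root]] <- sample(nt, L, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "postorder")
  edge <- ord$edge
  b <- ord$edge.length
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; child <- edge[e, 2]
    s <- seqs[[p]]
    prob <- 0.75 * (1 - exp(-4 * config$jc_rate * b[e] / 3))
    hit <- which(runif(L) < prob)
    if (length(hit) > 0) {
      # substitute to one of the three other nucleotides, uniformly
      shift <- sample.int(3, length(hit), replace = TRUE)
      s[hit] <- nt[(match(s[hit], nt) - 1L + shift) %% 4L + 1L]
    }
    seqs[[child]] <- s
  }
  setNames(
    purrr::map_chr(seq_len(n), ~ paste(seqs[[.x]], collapse = "")),
    tree$tip.label
  )
}

# per-region (f+, f-) sampling boxes; interiors of the five regions so
# finite-length composition noise rarely crosses a boundary (non-conforming
# draws are resampled, making the post-hoc classification exact)
sample_charge_fractions <- function(region) {
  switch(as.character(region),
    "1" = c(runif(1, 0, 0.10), runif(1, 0, 0.10)),
    "2" = {
      fcr <- runif(1, 0.27, 0.33)
      ncpr <- runif(1, -0.05, 0.05)
      c((fcr + ncpr) / 2, (fcr - ncpr) / 2)
    },
    "3" = {
      fcr <- runif(1, 0.45, 0.65)
      ncpr <- runif(1, -0.15, 0.15)
      c((fcr + ncpr) / 2, (fcr - ncpr) / 2)
    },
    "4" = c(runif(1, 0.02, 0.06), runif(1, 0.48, 0.60)),
    "5" = c(runif(1, 0.48, 0.60), runif(1, 0.02, 0.06)),
    stop_invalid("region must be in 1..5")
  )
}

# uncharged background enriched in polar/small residues, as in disordered
# sequences; H is neutral under the pH-7 charge convention
NEUTRAL_POOL <- c(
  G = 0.12, S = 0.12, T = 0.08, N = 0.08, Q = 0.08, P = 0.10, A = 0.10,
  H = 0.04, V = 0.06, L = 0.06, I = 0.04, M = 0.02, F = 0.03, Y = 0.03,
  W = 0.01, C = 0.03
)

sample_region_sequence <- function(region, length) {
  for (try in 1:200) {
    f <- sample_charge_fractions(region)
    n_pos <- round(f[1] * length)
    n_neg <- round(f[2] * length)
    n_neu <- length - n_pos - n_neg
    chars <- c(
      sample(POSITIVE_AA, n_pos, replace = TRUE),
      sample(NEGATIVE_AA, n_neg, replace = TRUE),
      sample(names(NEUTRAL_POOL), n_neu, replace = TRUE, prob = NEUTRAL_POOL)
    )
    seq <- paste(sample(chars), collapse = "")
    m <- compute_composition(seq)
    if (das_pappu_region(m$f_plus, m$f_minus) == region) return(seq)
  }
  stop_invalid(sprintf("could not realize a region-%s sequence of length %d",
                       region, length))
}

# small vocabulary of molecular-function tags for synthetic proteins
TAG_POOL <- c("ribosomal_protein", "rRNA-binding", "tRNA-binding",
              "chaperone", "transferase", "DNA-binding", "hydrolase",
              "oxidoreductase", "activator", "nuclease", "ligase",
              "sigma_factor")

#' Generate a composition-templated proteome
#'
#' Samples proteins whose charge composition is drawn from per-region
#' templates so that the diagram-of-states classification recovers the
#' intended region for every sequence (non-conforming draws are resampled).
#'
#' @param config A [sim_config()] (supplies seed, lengths, and the default
#'   region mix).
#' @param region_mix Optional named distribution over regions `"1"`..`"5"`
#'   overriding `config$region_mix`.
#' @param n Number of proteins; default `config$n_proteins_per_species`.
#' @param species_id Species id recorded on every protein.
#' @return Tibble with columns `id`, `species_id`, `sequence`,
#'   `function_tags` (list-column) and `region_intended`.
#' @export
generate_proteome <- function(config, region_mix = NULL,
                              n = config$n_proteins_per_species,
                              species_id = "sp001") {
  set.seed(config$seed + 3L)
  mix <- region_mix %||% config$region_mix
  mix <- mix / sum(mix)
  if (!all(names(mix) %in% as.character(1:5))) {
    stop_invalid("region_mix must be named by regions 1..5")
  }
  regions <- sample(as.integer(names(mix)), n, replace = TRUE, prob = mix)
  lengths <- sample(config$protein_length[1]:config$protein_length[2], n,
                    replace = TRUE)
  tibble(
    id = sprintf("%s_p%04d", species_id, seq_len(n)),
    species_id = species_id,
    sequence = purrr::map2_chr(regions, lengths, sample_region_sequence),
    function_tags = purrr::map(seq_len(n), ~ sample(TAG_POOL, 1)),
    region_intended = regions
  )
}

#' Point-mutate a protein sequence
#'
#' Substitutes `ceiling(divergence * length)` randomly chosen positions
#' with random different residues (uniform over the 20 canonical letters).
#'
#' @param seq A single amino-acid sequence.
#' @param divergence Fraction of positions to mutate, in `[0, 1]`.
#' @return The mutated sequence.
#' @export
mutate_protein <- function(seq, divergence) {
  chars <- strsplit(validate_sequence(seq), "", fixed = TRUE)[[1]]
  n_mut <- ceiling(divergence * length(chars))
  if (n_mut == 0) return(paste(chars, collapse = ""))
  pos <- sample(length(chars), n_mut)
  alphabet <- setdiff(AA_ALPHABET, "X")
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate ortholog-structured proteomes for a set of species
#'
#' Builds `n_families` ortholog families (one region-templated founder
#' each, copied into every species with `family_divergence` point
#' mutations and a family-level function tag) plus `n_unique_per_species`
#' species-private proteins, emulating proteomes in which orthologs
#' cluster across species.
#'
#' @param species Character vector of species ids (e.g. tree tip labels).
#' @param config A [sim_config()].
#' @return Tibble with `id`, `species_id`, `sequence`, `function_tags`,
#'   `family` (founding family id, `NA` for private proteins) and
#'   `region_intended` (founder's region).
#' @export
simulate_ortholog_proteomes <- function(species, config) {
  set.seed(config$seed + 4L)
  mix <- config$region_mix
  len_range <- config$protein_length
  fam_regions <- sample(as.integer(names(mix)), config$n_families,
                        replace = TRUE, prob = mix)
  fam_lengths <- sample(len_range[1]:len_range[2], config$n_families,
                        replace = TRUE)
  fam_tags <- sample(TAG_POOL, config$n_families, replace = TRUE)
  founders <- purrr::map2_chr(fam_regions, fam_lengths, sample_region_sequence)

  fam_rows <- purrr::map(seq_len(config$n_families), function(f) {
    tibble(
      id = sprintf("%s_fam%03d", species, f),
      species_id = species,
      sequence = purrr::map_chr(species,
                                ~ mutate_protein(founders[f], config$family_divergence)),
      function_tags = purrr::map(species, ~ fam_tags[f]),
      family = sprintf("fam%03d", f),
      region_intended = fam_regions[f]
    )
  })

  unique_rows <- purrr::map(species, function(sp) {
    k <- config$n_unique_per_species
    if (k == 0) return(NULL)
    regions <- sample(as.integer(names(mix)), k, replace = TRUE, prob = mix)
    lens <- sample(len_range[1]:len_range[2], k, replace = TRUE)
    tibble(
      id = sprintf("%s_uniq%03d", sp, seq_len(k)),
      species_id = sp,
      sequence = purrr::map2_chr(regions, lens, sample_region_sequence),
      function_tags = purrr::map(seq_len(k), ~ sample(TAG_POOL, 1)),
      family = NA_character_,
      region_intended = regions
    )
  })

  dplyr::bind_rows(c(fam_rows, unique_rows))
}

#' Attach an outgroup leaf to an ultrametric tree
#'
#' Adds a single outgroup leaf as sister to the whole ingroup, keeping the
#' combined tree ultrametric: the new root sits at `stem_factor` times the
#' ingroup height.
#'
#' @param tree A rooted ultrametric `phylo`.
#' @param label Outgroup leaf label.
#' @param stem_factor New root height as a multiple of the ingroup height;
#'   default 1.5.
#' @return The combined `phylo`.
#' @export
add_outgroup <- function(tree, label = "outgroup", stem_factor = 1.5) {
  if (label %in% tree$tip.label) stop_invalid("outgroup label already in tree")
  h <- max(ape::node.depth.edgelength(tree))
  newick <- sprintf("(%s:%.10g,ingroup_placeholder:%.10g);",
                    label, stem_factor * h, (stem_factor - 1) * h)
  shell <- ape::read.tree(text = newick)
  ape::bind.tree(shell, tree, where = which(shell$tip.label == "ingroup_placeholder"))
}
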