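# End-to-end synthetic pipeline: simulate inputs, run composition /
# filtering / clustering / group statistics / tree building / contrasts,
# and write every output table plus a provenance record. This is the
# programmatic entry point behind scripts/run_pipeline.R.

#' Run the full synthetic analysis pipeline
#'
#' Simulates a species tree with OGT/FOD traits, 16S-like marker sequences
#' (with an outgroup) and ortholog-structured proteomes; computes
#' composition metrics, diagram-of-states classes, disorder-heuristic
#' scores and IDP candidate calls; clusters proteins and applies the
#' retention conditions; summarizes FOD by class, function tag and cluster
#' per thermophile/mesophile group; fits the naive leaf-level OLS of FOD
#' on OGT; builds the UPGMA tree from 16S identity distances, prunes the
#' outgroup, computes quasi-independent contrasts and the origin-fixed
#' contrast regression; and writes aligned disorder tracks for the most
#' FOD-divergent retained cluster. All outputs are plain-text tables whose
#' bytes depend only on `config` (notably its seed).
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Convenience seed used when `config` is not supplied.
#' @param config A [sim_config()]; default `sim_config(seed = seed)`.
#' @param min_species Cluster-retention species threshold; default 10.
#' @return Invisibly, a list with the main in-memory results (`tree`,
#'   `traits`, `proteins`, `candidates`, `clusters_kept`, `contrasts`,
#'   `fits`, `divergence`, `files`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = sim_config(seed = seed),
                         min_species = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  # --- simulate inputs -----------------------------------------------------
  tree <- simulate_tree(config)
  traits <- evolve_traits(tree, config)
  tree16 <- add_outgroup(tree, "outgroup")
  seqs16 <- evolve_sequences_jc(tree16, config)
  proteins <- simulate_ortholog_proteomes(traits$species, config)

  species_tbl <- split_thermo_meso(traits) |>
    dplyr::mutate(accession_16s = paste0("SYN16S_", .data$species))
  readr::write_tsv(species_tbl, path("species.tsv"))
  write_newick(tree, path("tree_true.nwk"))
  write_aligned_fasta(seqs16, path("aligned_16s.fasta"))
  write_protein_fasta(proteins, path("proteome.fasta"))

  # --- composition, disorder heuristic, candidate filter -------------------
  comp <- compose_proteins(proteins)
  comp$whole_score <- ch_heuristic_score(proteins$sequence)
  candidates <- candidate_decisions(comp)
  write_composition_tsv(comp, path("composition.tsv"))
  readr::write_tsv(
    dplyr::select(candidates, "id", "species_id", "length", "region",
                  "whole_score", "score_rule", "mass_rule", "class_rule",
                  "is_candidate"),
    path("candidates.tsv")
  )
  candidate_ids <- candidates$id[candidates$is_candidate]

  # --- clustering and retention -------------------------------------------
  clusters <- greedy_cluster(proteins)
  clusters_kept <- filter_clusters(clusters, candidate_ids,
                                   min_species = min_species)
  write_cluster_tsv(clusters, candidate_ids, path("clusters.tsv"))
  write_cluster_tsv(clusters_kept, candidate_ids, path("clusters_kept.tsv"))

  # --- group statistics ----------------------------------------------------
  per_protein <- candidates |>
    dplyr::mutate(fod = .data$whole_score,
                  tag = purrr::map_chr(proteins$function_tags, 1)) |>
    dplyr::left_join(dplyr::select(species_tbl, species = "species",
                                   "group"),
                     by = c(species_id = "species"))
  by_class <- summarize_by(per_protein, "region_label")
  by_tag <- summarize_by(per_protein, "tag")
  readr::write_tsv(format_group_table(by_class), path("group_by_class.tsv"))
  readr::write_tsv(format_group_table(by_tag), path("group_by_tag.tsv"))

  leaf_ols <- ols_fit(traits$ogt, traits$fod)
  welch <- {
    ns <- table(species_tbl$group)
    groups <- split(traits$fod, species_tbl$group)
    if (all(ns >= 2)) {
      welch_t(groups$thermophile, groups$mesophile)
    } else {
      tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
             mean_a = NA_real_, mean_b = NA_real_)
    }
  }

  # --- tree from 16S, contrasts, origin regression -------------------------
  d16 <- aligned_distance_matrix(seqs16)
  write_distance_tsv(d16, path("distance_16s.tsv"))
  tree_hat <- root_and_prune_outgroup(upgma_tree(d16), "outgroup")
  write_newick(tree_hat, path("tree_16s.nwk"))
  contrasts <- compute_contrasts(tree_hat, traits, vars = c("fod", "ogt"))
  write_contrasts_tsv(contrasts, path("contrasts.tsv"))
  cfit <- contrast_regression(contrasts)

  stats_tbl <- tibble(
    analysis = c("leaf_ols_fod_on_ogt", "contrast_origin_fod_on_ogt",
                 "welch_fod_thermo_vs_meso"),
    estimate = c(leaf_ols$slope, cfit$slope, welch$statistic),
    r_squared = c(leaf_ols$r_squared, cfit$r_squared, NA_real_),
    p_value = c(leaf_ols$p_value, cfit$p_value, welch$p_value),
    n = c(leaf_ols$n, cfit$n, sum(!is.na(traits$fod)))
  )
  readr::write_tsv(stats_tbl, path("stats.tsv"))

  # --- divergent clusters and aligned tracks -------------------------------
  cluster_fod <- clusters_kept |>
    dplyr::left_join(dplyr::select(per_protein, "id", "fod", "group"),
                     by = c(member_id = "id")) |>
    dplyr::rename(fod_value = "fod")
  cluster_group_means <- cluster_fod |>
    dplyr::rename(fod = "fod_value") |>
    summarize_by("cluster_id") |>
    dplyr::rename(cluster_id = "key")
  divergence <- rank_divergent_clusters(cluster_group_means)
  readr::write_tsv(divergence, path("cluster_divergence.tsv"))

  tracks <- NULL
  if (nrow(divergence) > 0) {
    top <- divergence$cluster_id[1]
    members <- clusters_kept$member_id[clusters_kept$cluster_id == top]
    aln <- setNames(proteins$sequence[match(members, proteins$id)], members)
    # family copies differ by point mutations only, so rows are equal-length
    # and already aligned
    profiles <- purrr::map(aln, ch_profile)
    tracks <- aligned_profile_table(aln, profiles)
    write_tracks_tsv(tracks, path("tracks.tsv"))
  }

  # --- provenance -----------------------------------------------------------
  jsonlite::write_json(
    list(
      package = "thermidr",
      package_version = as.character(utils::packageVersion("thermidr")),
      r_version = R.version.string,
      seed = config$seed,
      min_species = min_species,
      config = unclass(config)
    ),
    path("provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    tree = tree, traits = traits, proteins = proteins,
    candidates = candidates, clusters = clusters,
    clusters_kept = clusters_kept, contrasts = contrasts,
    fits = list(leaf_ols = leaf_ols, contrast = cfit, welch = welch),
    divergence = divergence, tracks = tracks,
    files = list.files(out_dir)
  ))
}
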