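# Greedy global-identity clustering of proteins (incremental, longest
# sequence first, in the style of CD-HIT) and the two cluster-retention
# conditions (species breadth + at least one IDP candidate).

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and a linear
#' gap penalty of -0.5; the identity is the number of identical aligned
#' positions on the (diagonal-preferring) traceback divided by the length
#' of the shorter sequence. Symmetric in its arguments.
#'
#' @param a,b Amino-acid (or nucleotide) sequences as single strings.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' global_identity("AAAA", "AATA") # 0.75
#' @export
global_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1) {
    stop_invalid("a and b must be single strings")
  }
  if (nchar(a) == 0 || nchar(b) == 0) stop_invalid("sequences must be non-empty")
  res <- nw_align_stats(a, b, match = 1, mismatch = 0, gap = -0.5)
  res$matches / min(nchar(a), nchar(b))
}

#' Raw global alignment score between two sequences
#'
#' The optimal Needleman-Wunsch score under the same scoring as
#' [global_identity()] (match +1, mismatch 0, linear gap -0.5); exposed for
#' verification against independent alignment implementations.
#'
#' @inheritParams global_identity
#' @return Numeric alignment score.
#' @export
global_alignment_score <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) stop_invalid("sequences must be non-empty")
  nw_align_stats(a, b, match = 1, mismatch = 0, gap = -0.5)$score
}

#' Greedy incremental identity clustering
#'
#' Proteins are sorted by decreasing length (ties broken by id) and
#' processed in order: each protein joins the first existing cluster whose
#' representative it matches at identity >= `threshold`, otherwise it
#' founds a new cluster with itself as representative. Deterministic given
#' the input.
#'
#' @param proteins Tibble with columns `id`, `species_id`, `sequence`.
#' @param threshold Minimum global identity to the cluster representative;
#'   default 0.7.
#' @return Tibble with one row per protein: `cluster_id` (integer, in
#'   founding order), `representative_id`, `member_id`, `species_id`,
#'   `length`.
#' @export
greedy_cluster <- function(proteins, threshold = 0.7) {
  stopifnot(all(c("id", "species_id", "sequence") %in% names(proteins)))
  if (nrow(proteins) < 1) stop_invalid("at least one protein is required")
  if (anyDuplicated(proteins$id)) stop_invalid("protein ids must be unique")
  seqs <- validate_sequence(proteins$sequence)
  ord <- order(-nchar(seqs), proteins$id, method = "radix")
  ids <- proteins$id[ord]
  species <- proteins$species_id[ord]
  seqs <- seqs[ord]

  rep_seq <- character(0)
  rep_id <- character(0)
  assignment <- integer(length(ids))
  for (k in seq_along(ids)) {
    placed <- 0L
    for (cl in seq_along(rep_seq)) {
      if (global_identity(seqs[k], rep_seq[cl]) >= threshold) {
        placed <- cl
        break
      }
    }
    if (placed == 0L) {
      rep_seq <- c(rep_seq, seqs[k])
      rep_id <- c(rep_id, ids[k])
      placed <- length(rep_seq)
    }
    assignment[k] <- placed
  }

  tibble(
    cluster_id = assignment,
    representative_id = rep_id[assignment],
    member_id = ids,
    species_id = species,
    length = nchar(seqs)
  ) |>
    dplyr::arrange(.data$cluster_id, .data$member_id)
}

#' Per-cluster summary
#'
#' @param clusters Tibble from [greedy_cluster()].
#' @param candidate_ids Character vector of protein ids flagged as IDP
#'   candidates.
#' @return Tibble with one row per cluster: `cluster_id`,
#'   `representative_id`, `n_members`, `n_species`, `contains_candidate`.
#' @export
cluster_summary <- function(clusters, candidate_ids = character(0)) {
  clusters |>
    dplyr::group_by(.data$cluster_id, .data$representative_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species_id),
      contains_candidate = any(.data$member_id %in% candidate_ids),
      .groups = "drop"
    )
}

#' Apply the cluster-retention conditions
#'
#' Keeps exactly the clusters that span at least `min_species` distinct
#' species and contain at least one IDP candidate.
#'
#' @param clusters Tibble from [greedy_cluster()].
#' @param candidate_ids Character vector of candidate protein ids (e.g.
#'   from [candidate_decisions()]).
#' @param min_species Minimum number of distinct species per cluster;
#'   default 10.
#' @return The rows of `clusters` belonging to retained clusters.
#' @export
filter_clusters <- function(clusters, candidate_ids, min_species = 10) {
  keep <- cluster_summary(clusters, candidate_ids) |>
    dplyr::filter(.data$n_species >= min_species, .data$contains_candidate)
  dplyr::semi_join(clusters, keep, by = "cluster_id")
}

#' Write a cluster membership table to TSV
#'
#' @param clusters Tibble from [greedy_cluster()].
#' @param candidate_ids Candidate protein ids used to flag members.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, candidate_ids, path) {
  out <- dplyr::mutate(clusters, is_candidate = .data$member_id %in% candidate_ids)
  readr::write_tsv(out, path)
  invisible(path)
}
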