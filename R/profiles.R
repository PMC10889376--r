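# Aligned disorder tracks: moving-average smoothing of per-residue scores
# (on the ungapped sequence), projection through alignment gaps, and
# ranking of the most FOD-divergent ortholog clusters.

#' Project per-residue scores through an aligned sequence
#'
#' Maps the k-th raw score onto the k-th non-gap column of the aligned row;
#' gap columns receive `NA`.
#'
#' @param aligned_seq One aligned sequence (string, gaps `-` or `.`).
#' @param raw_scores Numeric vector with one score per (ungapped) residue.
#' @return Numeric vector of alignment length with `NA` at gap columns.
#' @export
project_scores <- function(aligned_seq, raw_scores) {
  chars <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  is_res <- !(chars %in% c("-", "."))
  if (sum(is_res) == 0) stop_invalid("aligned row contains no residues")
  if (sum(is_res) != length(raw_scores)) {
    stop_invalid(sprintf("row has %d residues but %d scores were given",
                         sum(is_res), length(raw_scores)))
  }
  out <- rep(NA_real_, length(chars))
  out[is_res] <- raw_scores
  out
}

#' Centered moving average with truncated edges
#'
#' Smooths per-residue scores with a centered window whose default width is
#' the protein length divided by 30 (floored, clamped to at least 1, and
#' forced odd by adding 1 when even). At the edges the window is truncated
#' and the divisor is the actual neighborhood size, so constant inputs are
#' unchanged.
#'
#' @param scores Numeric vector of per-residue scores (ungapped).
#' @param window Window width; default `max(1, floor(length(scores) / 30))`.
#' @return Numeric vector of smoothed scores, same length as `scores`.
#' @export
moving_average <- function(scores, window = NULL) {
  n <- length(scores)
  if (n < 1) stop_invalid("scores must be non-empty")
  if (any(!is.finite(scores))) stop_invalid("scores must be finite")
  if (is.null(window)) window <- max(1L, floor(n / 30))
  if (window < 1) stop_invalid("window must be >= 1")
  if (window %% 2 == 0) window <- window + 1
  if (window == 1) return(scores)
  half <- (window - 1) / 2
  cs <- c(0, cumsum(scores))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smoothed, projected disorder tracks for an aligned cluster
#'
#' For each member of a cluster alignment, smooths its per-residue scores
#' on the ungapped sequence (window = length / 30) and projects both raw
#' and smoothed scores through the alignment gaps, giving directly
#' plottable per-column tracks.
#'
#' @param aln Named character vector: the cluster alignment (equal-length
#'   gapped rows).
#' @param profiles Named list of numeric per-residue score vectors, one per
#'   alignment row (names matching `aln`).
#' @param window Smoothing window; `NULL` (default) uses length / 30 per
#'   member.
#' @return Tibble with columns `member`, `column`, `residue`, `score`,
#'   `smoothed` (`NA` at gap columns).
#' @export
aligned_profile_table <- function(aln, profiles, window = NULL) {
  if (!setequal(names(aln), names(profiles))) {
    stop_invalid("aln and profiles must carry the same member names")
  }
  purrr::map(names(aln), function(id) {
    raw <- profiles[[id]]
    smoothed <- moving_average(raw, window = window)
    chars <- strsplit(aln[[id]], "", fixed = TRUE)[[1]]
    tibble(
      member = id,
      column = seq_along(chars),
      residue = chars,
      score = project_scores(aln[[id]], raw),
      smoothed = project_scores(aln[[id]], smoothed)
    )
  }) |>
    dplyr::bind_rows()
}

#' Rank clusters by thermophile/mesophile FOD divergence
#'
#' Orders clusters by the absolute difference between their mean
#' thermophilic and mean mesophilic FOD, descending. Clusters missing
#' either group are excluded.
#'
#' @param cluster_summaries Tibble with columns `cluster_id`, `group`
#'   (`"thermophile"`/`"mesophile"`) and `mean_fod` (e.g. from
#'   [summarize_by()] keyed by cluster, with `key` renamed `cluster_id`).
#' @return Tibble with `cluster_id`, `fod_thermophile`, `fod_mesophile`,
#'   `abs_difference`, sorted descending by `abs_difference`.
#' @export
rank_divergent_clusters <- function(cluster_summaries) {
  stopifnot(all(c("cluster_id", "group", "mean_fod") %in% names(cluster_summaries)))
  wide <- cluster_summaries |>
    dplyr::filter(!is.na(.data$mean_fod)) |>
    dplyr::select("cluster_id", "group", "mean_fod") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_fod",
                       names_prefix = "fod_")
  for (col in c("fod_thermophile", "fod_mesophile")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide |>
    dplyr::filter(!is.na(.data$fod_thermophile), !is.na(.data$fod_mesophile)) |>
    dplyr::mutate(abs_difference = abs(.data$fod_thermophile - .data$fod_mesophile)) |>
    dplyr::arrange(dplyr::desc(.data$abs_difference))
}

#' Write per-cluster aligned score tracks to TSV
#'
#' @param tracks Tibble from [aligned_profile_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks_tsv <- function(tracks, path) {
  readr::write_tsv(tracks, path)
  invisible(path)
}
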