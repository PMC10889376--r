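# Charge/hydropathy composition metrics and the five-region
# diagram-of-states classification of disordered sequences.

# Kyte-Doolittle hydropathy; X is the unknown-residue code and sits at the
# scale midpoint (0), i.e. 0.5 after normalization to [0, 1].
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
  X = 0
)

# pH-7 convention of the diagram-of-states framework: K and R carry +1,
# D and E carry -1, histidine is neutral.
POSITIVE_AA <- c("K", "R")
NEGATIVE_AA <- c("D", "E")

AA_ALPHABET <- names(KD_SCALE)

DAS_PAPPU_LABELS <- c(
  "weak polyampholyte/polyelectrolyte",
  "boundary",
  "strong polyampholyte",
  "negative strong polyelectrolyte",
  "positive strong polyelectrolyte"
)

#' Validate amino-acid sequences
#'
#' Checks that each sequence is non-empty and uses only the 20 canonical
#' amino-acid letters plus `X` (unknown). Lower-case input is accepted and
#' upper-cased.
#'
#' @param seq Character vector of amino-acid sequences.
#' @return The validated (upper-cased) character vector, invisibly usable
#'   downstream.
#' @export
validate_sequence <- function(seq) {
  if (length(seq) == 0) stop_invalid("no sequences supplied")
  seq <- toupper(as.character(seq))
  if (anyNA(seq) || any(nchar(seq) == 0)) {
    stop_invalid("empty sequence: every sequence must have length >= 1")
  }
  for (k in seq_along(seq)) {
    chars <- strsplit(seq[[k]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0) {
      stop_invalid(sprintf(
        "invalid residue '%s' at position %d of sequence %d (allowed: %s)",
        chars[bad[1]], bad[1], k, paste(AA_ALPHABET, collapse = "")
      ))
    }
  }
  seq
}

#' Charge and hydropathy composition of amino-acid sequences
#'
#' Computes, per sequence, the fraction of positive residues (K, R), the
#' fraction of negative residues (D, E), the fraction of charged residues
#' FCR = f+ + f-, the net charge per residue NCPR = f+ - f-, and the mean
#' Kyte-Doolittle hydropathy normalized to `[0, 1]` via `(KD + 4.5) / 9`.
#' Histidine is treated as neutral; `X` contributes zero charge and the
#' hydropathy midpoint.
#'
#' @param seq Character vector of amino-acid sequences.
#' @return A tibble with one row per sequence and columns `length`,
#'   `f_plus`, `f_minus`, `fcr`, `ncpr`, `mean_hydropathy`.
#' @examples
#' compute_composition(c("EEKK", "KKDKKGGGGG"))
#' @export
compute_composition <- function(seq) {
  seq <- validate_sequence(seq)
  rows <- purrr::map(seq, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    f_plus <- sum(chars %in% POSITIVE_AA) / n
    f_minus <- sum(chars %in% NEGATIVE_AA) / n
    tibble(
      length = n,
      f_plus = f_plus,
      f_minus = f_minus,
      fcr = f_plus + f_minus,
      ncpr = f_plus - f_minus,
      mean_hydropathy = mean((KD_SCALE[chars] + 4.5) / 9)
    )
  })
  dplyr::bind_rows(rows)
}

#' Mean net charge per residue
#'
#' Convenience wrapper returning the NCPR of [compute_composition()]; the
#' absolute mean charge used in charge-hydropathy plots is `abs()` of this.
#'
#' @inheritParams compute_composition
#' @return Numeric vector of signed net charge per residue in `[-1, 1]`.
#' @export
mean_net_charge <- function(seq) {
  compute_composition(seq)$ncpr
}

#' Five-region diagram-of-states region from charge fractions
#'
#' Assigns the Das-Pappu region from the positive and negative charged
#' residue fractions:
#' region 1 (weak polyampholytes/polyelectrolytes) for FCR < 0.25;
#' region 2 (boundary/Janus) for 0.25 <= FCR <= 0.35;
#' region 3 (strong polyampholytes) for FCR > 0.35 with |NCPR| <= 0.35;
#' regions 4/5 (negative/positive strong polyelectrolytes) for |NCPR| > 0.35
#' dominated by acidic or basic residues respectively. Exact boundaries
#' resolve to the lower-numbered qualifying region (FCR = 0.25 and 0.35 are
#' region 2; |NCPR| = 0.35 is region 3).
#'
#' @param f_plus,f_minus Numeric vectors of positive/negative residue
#'   fractions with `f_plus + f_minus <= 1`.
#' @return Integer vector of regions in 1..5.
#' @export
das_pappu_region <- function(f_plus, f_minus) {
  if (length(f_plus) != length(f_minus)) {
    stop_invalid("f_plus and f_minus must have equal length")
  }
  ok <- is.finite(f_plus) & is.finite(f_minus) &
    f_plus >= 0 & f_minus >= 0 & (f_plus + f_minus) <= 1 + 1e-12
  if (!all(ok)) {
    stop_invalid("f_plus/f_minus must be fractions with f_plus + f_minus <= 1")
  }
  fcr <- f_plus + f_minus
  ncpr <- f_plus - f_minus
  region <- integer(length(fcr))
  region[fcr < 0.25] <- 1L
  region[fcr >= 0.25 & fcr <= 0.35] <- 2L
  r3plus <- fcr > 0.35
  region[r3plus & abs(ncpr) <= 0.35] <- 3L
  region[r3plus & abs(ncpr) > 0.35 & f_minus > 0.35 & f_plus <= 0.35] <- 4L
  region[r3plus & abs(ncpr) > 0.35 & f_plus > 0.35 & f_minus <= 0.35] <- 5L
  stopifnot(all(region %in% 1:5))
  region
}

#' Human-readable label for a diagram-of-states region
#'
#' @param region Integer vector in 1..5.
#' @return Character vector of region labels.
#' @export
das_pappu_label <- function(region) {
  if (!all(region %in% 1:5)) stop_invalid("region must be in 1..5")
  DAS_PAPPU_LABELS[region]
}

#' Classify composition metrics into diagram-of-states regions
#'
#' Data-frame-in, data-frame-out wrapper around [das_pappu_region()]:
#' appends `region` and `region_label` columns to a table carrying
#' `f_plus` and `f_minus` (as produced by [compute_composition()]).
#'
#' @param metrics Data frame with columns `f_plus` and `f_minus`.
#' @return The input as a tibble with `region` (integer) and
#'   `region_label` (character) appended.
#' @export
classify_das_pappu <- function(metrics) {
  if (!all(c("f_plus", "f_minus") %in% names(metrics))) {
    stop_invalid("metrics must contain columns f_plus and f_minus")
  }
  metrics <- as_tibble(metrics)
  metrics$region <- das_pappu_region(metrics$f_plus, metrics$f_minus)
  metrics$region_label <- das_pappu_label(metrics$region)
  metrics
}

#' Composition and classification table for a set of proteins
#'
#' Runs [compute_composition()] and [classify_das_pappu()] over a protein
#' table, producing the per-protein composition report.
#'
#' @param proteins Tibble with columns `id`, `species_id`, `sequence` (as
#'   returned by [read_protein_fasta()] or [generate_proteome()]).
#' @return Tibble with one row per protein: `id`, `species_id`, `length`,
#'   `f_plus`, `f_minus`, `fcr`, `ncpr`, `mean_hydropathy`, `region`,
#'   `region_label`.
#' @export
compose_proteins <- function(proteins) {
  stopifnot(all(c("id", "species_id", "sequence") %in% names(proteins)))
  metrics <- compute_composition(proteins$sequence)
  dplyr::bind_cols(
    dplyr::select(as_tibble(proteins), "id", "species_id"),
    classify_das_pappu(metrics)
  )
}

#' Write a composition table to TSV
#'
#' @param tbl Tibble from [compose_proteins()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}
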