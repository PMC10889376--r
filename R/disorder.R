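# Per-residue disorder profiles, fraction of disorder (FOD), the bundled
# charge-hydropathy disorder heuristic, and the three-rule IDP candidate
# filter.

#' Construct a disorder profile
#'
#' A disorder profile carries optional per-residue disorder scores in
#' `[0, 1]` and an always-present whole-protein score. When per-residue
#' scores are given and no whole-protein score is supplied, the mean score
#' is used.
#'
#' @param protein_id Protein identifier.
#' @param scores Optional numeric vector of per-residue scores in `[0, 1]`.
#' @param whole_score Whole-protein disorder score in `[0, 1]`.
#' @return An object of class `disorder_profile`.
#' @export
disorder_profile <- function(protein_id, scores = NULL,
                             whole_score = if (!is.null(scores)) mean(scores) else NULL) {
  if (is.null(whole_score)) {
    stop_invalid("a whole-protein score is required when no per-residue scores are given")
  }
  if (!is.null(scores)) {
    if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
      stop_invalid("per-residue scores must lie in [0, 1]")
    }
  }
  if (!is.finite(whole_score) || whole_score < 0 || whole_score > 1) {
    stop_invalid("whole-protein score must lie in [0, 1]")
  }
  structure(
    list(protein_id = as.character(protein_id), scores = scores,
         whole_score = whole_score),
    class = "disorder_profile"
  )
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat(sprintf(
    "<disorder_profile %s: %s residues, whole-protein score %.3f>\n",
    x$protein_id,
    if (is.null(x$scores)) "no per-residue" else length(x$scores),
    x$whole_score
  ))
  invisible(x)
}

#' Fraction of disorder from a per-residue profile
#'
#' FOD is the fraction of residues whose disorder score is at or above the
#' threshold (inclusive).
#'
#' @param profile A [disorder_profile()] with per-residue scores, or a bare
#'   numeric vector of per-residue scores.
#' @param threshold Disorder call threshold in `[0, 1]`; default 0.5.
#' @return Fraction of disordered residues in `[0, 1]`.
#' @export
fod_from_profile <- function(profile, threshold = 0.5) {
  scores <- if (inherits(profile, "disorder_profile")) profile$scores else profile
  if (is.null(scores) || length(scores) == 0) {
    abort("per-residue scores unavailable: cannot compute FOD from profile",
          class = "thermidr_unavailable_profile")
  }
  if (!is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop_invalid("threshold must lie in [0, 1]")
  }
  mean(scores >= threshold)
}

#' Rule-based IDP candidate decisions
#'
#' A protein is an IDP candidate when at least one of three rules fires:
#' whole-protein disorder score >= 0.5 (`score_rule`); residue count times
#' whole-protein score >= 100 (`mass_rule`, a disordered-mass rule); or
#' diagram-of-states region 3, 4 or 5 (`class_rule`).
#'
#' @param tbl Tibble with columns `whole_score` (numeric in `[0, 1]`),
#'   `length` (positive integer) and `region` (integer 1..5).
#' @param score_threshold Whole-score rule threshold; default 0.5.
#' @param mass_threshold Length-times-score rule threshold; default 100.
#' @return The input with logical columns `score_rule`, `mass_rule`,
#'   `class_rule` and `is_candidate` appended.
#' @export
candidate_decisions <- function(tbl, score_threshold = 0.5, mass_threshold = 100) {
  stopifnot(all(c("whole_score", "length", "region") %in% names(tbl)))
  if (any(tbl$length < 1)) stop_invalid("protein length must be >= 1")
  tbl <- as_tibble(tbl)
  tbl$score_rule <- tbl$whole_score >= score_threshold
  tbl$mass_rule <- tbl$length * tbl$whole_score >= mass_threshold
  tbl$class_rule <- tbl$region %in% c(3L, 4L, 5L)
  tbl$is_candidate <- tbl$score_rule | tbl$mass_rule | tbl$class_rule
  tbl
}

#' Single-protein candidate decision
#'
#' Scalar convenience form of [candidate_decisions()].
#'
#' @param whole_score Whole-protein disorder score.
#' @param length Number of residues.
#' @param region Diagram-of-states region (1..5).
#' @return One-row tibble with the rule flags and `is_candidate`.
#' @export
is_candidate <- function(whole_score, length, region) {
  candidate_decisions(tibble(
    whole_score = whole_score, length = length, region = region
  ))
}

# logistic steepness for the charge-hydropathy heuristic; only the ordering
# of scores and the 0.5 crossing at the boundary are meaningful
CH_LOGISTIC_K <- 10

#' Charge-hydropathy disorder heuristic
#'
#' A composition-only whole-protein disorder score: the signed distance of
#' a sequence from the charge-hydropathy boundary
#' `|NCPR| = 2.785 * <H> - 1.151` (disordered side = higher net charge,
#' lower hydropathy), mapped through a logistic so that sequences exactly
#' on the boundary score 0.5. Deterministic and invariant under residue
#' shuffling; it stands in for an external whole-protein disorder predictor
#' so the pipeline runs offline.
#'
#' @inheritParams compute_composition
#' @return Numeric vector of scores in `(0, 1)`.
#' @export
ch_heuristic_score <- function(seq) {
  m <- compute_composition(seq)
  d <- abs(m$ncpr) - (2.785 * m$mean_hydropathy - 1.151)
  1 / (1 + exp(-CH_LOGISTIC_K * d))
}

#' Windowed charge-hydropathy disorder profile
#'
#' Applies [ch_heuristic_score()] in a centered sliding window (truncated
#' at the edges) to produce a per-residue disorder score track for one
#' sequence.
#'
#' @param seq A single amino-acid sequence.
#' @param window Window width in residues (forced odd); default 15.
#' @return Numeric vector of per-residue scores, one per residue.
#' @export
ch_profile <- function(seq, window = 15) {
  seq <- validate_sequence(seq)
  if (length(seq) != 1) stop_invalid("ch_profile takes a single sequence")
  if (window < 1) stop_invalid("window must be >= 1")
  if (window %% 2 == 0) window <- window + 1
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  half <- (window - 1) / 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  width <- hi - lo + 1
  winsum <- function(v) { cs <- c(0, cumsum(v)); cs[hi + 1] - cs[lo] }
  f_plus <- winsum(chars %in% POSITIVE_AA) / width
  f_minus <- winsum(chars %in% NEGATIVE_AA) / width
  hyd <- winsum((KD_SCALE[chars] + 4.5) / 9) / width
  d <- abs(f_plus - f_minus) - (2.785 * hyd - 1.151)
  unname(1 / (1 + exp(-CH_LOGISTIC_K * d)))
}

#' Read a per-residue disorder score TSV
#'
#' Expects columns `position` (1-based, contiguous from 1), `residue` and
#' `score`. Scores outside `[0, 1]` by at most 1e-9 are clipped; larger
#' excursions, non-contiguous positions, and residue mismatches against an
#' optionally supplied sequence are format errors reported with the
#' offending line number (header = line 1).
#'
#' @param path Path to the TSV file.
#' @param protein_id Protein id for the profile; defaults to the file name
#'   without extension.
#' @param sequence Optional amino-acid sequence to validate residues
#'   against.
#' @return A [disorder_profile()].
#' @export
read_profile_tsv <- function(path, protein_id = NULL, sequence = NULL) {
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           position = readr::col_integer(),
                           residue = readr::col_character(),
                           score = readr::col_double()
                         ))
  if (nrow(tbl) == 0) {
    abort(sprintf("%s: empty profile", path), class = "thermidr_format_error")
  }
  fail <- function(row, msg) {
    abort(sprintf("%s, line %d: %s", path, row + 1L, msg),
          class = "thermidr_format_error")
  }
  bad <- which(tbl$position != seq_len(nrow(tbl)))
  if (length(bad) > 0) {
    fail(bad[1], sprintf("positions must be contiguous from 1 (found %s)",
                         tbl$position[bad[1]]))
  }
  tol <- 1e-9
  bad <- which(!is.finite(tbl$score) | tbl$score < -tol | tbl$score > 1 + tol)
  if (length(bad) > 0) {
    fail(bad[1], sprintf("score %s outside [0, 1]", format(tbl$score[bad[1]])))
  }
  scores <- pmin(pmax(tbl$score, 0), 1)
  if (!is.null(sequence)) {
    sequence <- validate_sequence(sequence)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    if (length(chars) != nrow(tbl)) {
      fail(nrow(tbl), sprintf("profile has %d rows but sequence has %d residues",
                              nrow(tbl), length(chars)))
    }
    bad <- which(toupper(tbl$residue) != chars)
    if (length(bad) > 0) {
      fail(bad[1], sprintf("residue '%s' does not match sequence residue '%s'",
                           tbl$residue[bad[1]], chars[bad[1]]))
    }
  }
  disorder_profile(protein_id, scores = scores)
}

#' Write a per-residue disorder profile to TSV
#'
#' @param profile A [disorder_profile()] with per-residue scores.
#' @param sequence Amino-acid sequence supplying the `residue` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, sequence, path) {
  if (is.null(profile$scores)) {
    abort("profile has no per-residue scores", class = "thermidr_unavailable_profile")
  }
  chars <- strsplit(validate_sequence(sequence), "", fixed = TRUE)[[1]]
  stopifnot(length(chars) == length(profile$scores))
  readr::write_tsv(
    tibble(position = seq_along(chars), residue = chars, score = profile$scores),
    path
  )
  invisible(path)
}
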