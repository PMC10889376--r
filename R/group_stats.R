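# Thermophile/mesophile partitioning, group FOD summaries by class or
# function tag, and the Welch/OLS comparisons used on them.

#' Thermophile/mesophile split
#'
#' Partitions species by optimal growth temperature: species with
#' OGT >= 40 degrees C (boundary inclusive) are thermophiles, all others
#' mesophiles.
#'
#' @param records Tibble with a numeric `ogt` column (degrees C).
#' @param threshold OGT split point; default 40.
#' @return The input with a `group` factor column
#'   (`"thermophile"`/`"mesophile"`) appended.
#' @export
split_thermo_meso <- function(records, threshold = 40) {
  stopifnot("ogt" %in% names(records))
  if (any(!is.finite(records$ogt))) stop_invalid("OGT values must be finite")
  dplyr::mutate(
    as_tibble(records),
    group = factor(ifelse(.data$ogt >= threshold, "thermophile", "mesophile"),
                   levels = c("thermophile", "mesophile"))
  )
}

#' Group FOD summaries by a key
#'
#' Per key (diagram-of-states class, function tag, cluster, ...) and per
#' species group, computes the mean FOD, its standard error (sample
#' standard deviation over `sqrt(n)`; reported as 0 with `se_defined =
#' FALSE` when `n = 1`) and the group size. Key levels absent from a group
#' are emitted explicitly with `n = 0` and `NA` mean (the "-" rows of a
#' class-by-group table).
#'
#' @param proteins Tibble with columns `fod`, `group`, and the key column.
#' @param key Name of the key column (string).
#' @return Tibble with columns `key`, `group`, `mean_fod`, `se_fod`, `n`,
#'   `se_defined`, one row per key x group.
#' @export
summarize_by <- function(proteins, key) {
  stopifnot(all(c("fod", "group", key) %in% names(proteins)))
  groups <- levels(factor(proteins$group))
  proteins |>
    dplyr::group_by(key = .data[[key]], group = factor(.data$group, levels = groups)) |>
    dplyr::summarise(
      mean_fod = mean(.data$fod),
      se_fod = if (dplyr::n() > 1) sd(.data$fod) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      se_defined = dplyr::n() > 1,
      .groups = "drop"
    ) |>
    tidyr::complete(.data$key, .data$group,
                    fill = list(mean_fod = NA_real_, se_fod = NA_real_,
                                n = 0L, se_defined = FALSE)) |>
    dplyr::arrange(.data$key, .data$group)
}

#' Wide class-by-group summary table
#'
#' Reshapes [summarize_by()] output into one row per key with
#' `mean +/- SE; n = ...` text per group and `-` for absent combinations,
#' mirroring the layout of published class/tag FOD tables.
#'
#' @param summary Tibble from [summarize_by()].
#' @param digits Digits for mean and SE formatting; default 3.
#' @return Tibble with columns `key` and one character column per group.
#' @export
format_group_table <- function(summary, digits = 3) {
  fmt <- function(mean_fod, se_fod, n) {
    ifelse(n == 0, "-",
           sprintf(paste0("%.", digits, "f ± %.", digits, "f; n = %d"),
                   mean_fod, se_fod, n))
  }
  summary |>
    dplyr::mutate(cell = fmt(.data$mean_fod, .data$se_fod, .data$n)) |>
    dplyr::select("key", "group", "cell") |>
    tidyr::pivot_wider(names_from = "group", values_from = "cell")
}

#' Welch two-sample comparison
#'
#' Two-sided t-test with Welch-Satterthwaite degrees of freedom (the
#' default), or the pooled-variance Student variant. Inputs where both
#' groups have zero variance are rejected as degenerate.
#'
#' @param a,b Numeric vectors (each `n >= 2`).
#' @param var_equal Use the pooled Student t instead of Welch; default
#'   `FALSE`.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop_invalid("each group needs at least two observations")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    abort("both groups have zero variance: t-test undefined",
          class = "thermidr_degenerate_input")
  }
  ht <- t.test(a, b, var.equal = var_equal)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}

#' Ordinary least squares fit with intercept
#'
#' Simple linear regression of `y` on `x`; the p-value is the two-sided
#' test of the slope.
#'
#' @param x,y Numeric vectors of equal length (>= 3); `x` must not be
#'   constant.
#' @return One-row tibble with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 3) stop_invalid("at least three points are required")
  if (sd(x) == 0) {
    abort("x is constant: slope undefined", class = "thermidr_degenerate_input")
  }
  if (sd(y) == 0) {
    # exact fit to a flat response: zero slope and no explained variance
    return(tibble(slope = 0, intercept = y[1], r_squared = 0,
                  p_value = NA_real_, n = length(x)))
  }
  fit <- lm(y ~ x)
  s <- summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = s$coefficients[2, 4],
    n = length(x)
  )
}
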