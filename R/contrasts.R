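# Least-squares (RSS-minimizing) ancestral trait states, quasi-independent
# sibling contrasts, and the origin-fixed contrast regression.
#
# The ancestral-state objective is
#   RSS(x) = sum over branches (x_child - x_parent)^2 / b_branch
# (or with unit weights when weighted = FALSE), a positive-definite
# quadratic in the internal states with the leaves fixed at observations.
# The minimizer satisfies, at every internal node, x = the 1/b-weighted
# mean of its tree neighbors, a sparse linear system solved exactly here.

# replace zero/near-zero branch lengths (UPGMA tie merges) by a small
# fraction of the tree height so 1/b weights stay finite
adjusted_branch_lengths <- function(tree) {
  b <- tree$edge.length
  if (is.null(b)) stop_invalid("tree has no branch lengths")
  height <- max(ape::node.depth.edgelength(tree))
  if (height <= 0) stop_invalid("tree height must be positive")
  eps <- 1e-8 * height
  if (any(b < 0)) stop_invalid("negative branch length")
  pmax(b, eps)
}

#' RSS of a set of ancestral states
#'
#' Evaluates the residual sum of squares objective for given internal-node
#' states: the sum over branches of the squared state change divided by the
#' branch length (or unweighted). Used to verify that reconstructed states
#' minimize the objective.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_values Named numeric vector of observed leaf values (names =
#'   tip labels).
#' @param internal_states Numeric vector of internal-node states ordered by
#'   ape node number (`Ntip+1`, `Ntip+2`, ...).
#' @param weighted Divide squared changes by branch lengths (default TRUE).
#' @return The scalar RSS.
#' @export
ancestral_rss <- function(tree, tip_values, internal_states, weighted = TRUE) {
  n <- ape::Ntip(tree)
  stopifnot(length(internal_states) == tree$Nnode)
  x <- c(tip_values[tree$tip.label], internal_states)
  b <- if (weighted) adjusted_branch_lengths(tree) else rep(1, nrow(tree$edge))
  sum((x[tree$edge[, 2]] - x[tree$edge[, 1]])^2 / b)
}

#' Least-squares ancestral state reconstruction
#'
#' Computes the internal-node trait states minimizing the branch-weighted
#' residual sum of squares with leaf states fixed at the observed values.
#' The quadratic objective is solved exactly via its normal equations
#' (each internal state equals the 1/b-weighted mean of its neighbors).
#'
#' @param tree A rooted `phylo` with strictly positive branch lengths
#'   (zero-length branches are replaced by `1e-8 *` tree height).
#' @param traits Tibble with a `species` column matching the tip labels and
#'   one numeric column per trait, or a named numeric vector for a single
#'   trait.
#' @param trait Name of the trait column to reconstruct (ignored for a
#'   named-vector input).
#' @param weighted Use 1/branch-length weights in the objective (default);
#'   `FALSE` gives the unweighted least-squares variant.
#' @return An object of class `ancestral_states`: list with `states`
#'   (numeric, named by ape node number), `rss`, `trait`, `weighted` and
#'   the `tree`.
#' @export
infer_ancestral_states <- function(tree, traits, trait = NULL, weighted = TRUE) {
  tip_values <- trait_vector(tree, traits, trait)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  if (m < 1) stop_invalid("tree has no internal nodes")
  b <- if (weighted) adjusted_branch_lengths(tree) else rep(1, nrow(tree$edge))
  w <- 1 / b
  total <- n + m
  # weighted graph Laplacian, internal block solved against the leaf block
  L <- matrix(0, total, total)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    L[i, j] <- L[i, j] - w[e]
    L[j, i] <- L[j, i] - w[e]
    L[i, i] <- L[i, i] + w[e]
    L[j, j] <- L[j, j] + w[e]
  }
  internal <- (n + 1):total
  xL <- tip_values[tree$tip.label]
  states <- drop(solve(L[internal, internal, drop = FALSE],
                       -L[internal, seq_len(n), drop = FALSE] %*% xL))
  names(states) <- as.character(internal)
  structure(
    list(
      states = states,
      rss = ancestral_rss(tree, tip_values, states, weighted = weighted),
      trait = trait %||% "trait",
      weighted = weighted,
      tree = tree,
      tip_values = xL
    ),
    class = "ancestral_states"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

trait_vector <- function(tree, traits, trait) {
  if (is.numeric(traits) && !is.null(names(traits))) {
    v <- traits
  } else {
    traits <- as_tibble(traits)
    if (!"species" %in% names(traits)) {
      stop_invalid("traits must contain a 'species' column")
    }
    if (is.null(trait) || !trait %in% names(traits)) {
      stop_invalid("trait column not found in traits table")
    }
    v <- setNames(traits[[trait]], traits$species)
  }
  missing <- setdiff(tree$tip.label, names(v))
  if (length(missing) > 0) {
    stop_invalid(sprintf("missing trait values for leaves: %s",
                         paste(head(missing, 5), collapse = ", ")))
  }
  if (any(!is.finite(v[tree$tip.label]))) {
    stop_invalid("trait values must be finite")
  }
  v[tree$tip.label]
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf("<ancestral_states '%s': %d internal nodes, RSS = %.6g (%s)>\n",
              x$trait, length(x$states), x$rss,
              if (x$weighted) "1/branch weights" else "unweighted"))
  invisible(x)
}

#' @describeIn infer_ancestral_states Tidy the reconstructed states into a
#'   tibble with columns `node` and `estimate`.
#' @param x An `ancestral_states` object.
#' @param ... Unused.
#' @export
tidy.ancestral_states <- function(x, ...) {
  tibble(node = as.integer(names(x$states)), estimate = unname(x$states))
}

#' Quasi-independent contrasts at internal nodes
#'
#' For every internal node of a binary tree, the contrast is the difference
#' between its two children's trait values (observed values at leaves,
#' RSS-reconstructed states at internal children), with children ordered
#' deterministically (left = child whose subtree contains the
#' lexicographically smallest leaf label). The standardization weight is
#' `sqrt(b_left + b_right)`; both raw and standardized contrasts are
#' returned. Non-binary nodes are resolved into a caterpillar with
#' zero-length internal branches first, with a warning.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param traits Tibble with `species` plus one numeric column per trait.
#' @param vars Trait columns to contrast; defaults to all numeric columns.
#' @param weighted Passed to [infer_ancestral_states()].
#' @return Tibble with one row per internal node: `node`, `weight`, and per
#'   trait `delta_<var>` (raw) and `std_<var>` (raw / weight).
#' @export
compute_contrasts <- function(tree, traits, vars = NULL, weighted = TRUE) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    warn("non-binary tree: resolving multifurcations into zero-length caterpillars")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  traits <- as_tibble(traits)
  if (is.null(vars)) {
    vars <- setdiff(names(traits)[purrr::map_lgl(traits, is.numeric)], "species")
  }
  if (length(vars) == 0) stop_invalid("no numeric trait columns to contrast")

  n <- ape::Ntip(tree)
  b <- adjusted_branch_lengths(tree)
  # smallest leaf label below each node, for deterministic child ordering
  min_leaf <- character(n + tree$Nnode)
  min_leaf[seq_len(n)] <- tree$tip.label
  edge_post <- ape::reorder.phylo(tree, "postorder")$edge
  b_post <- b[match(paste(edge_post[, 1], edge_post[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))]
  for (e in seq_len(nrow(edge_post))) {
    p <- edge_post[e, 1]; child <- edge_post[e, 2]
    if (min_leaf[p] == "" || min_leaf[child] < min_leaf[p]) {
      min_leaf[p] <- min_leaf[child]
    }
  }

  states <- purrr::map(vars, ~ infer_ancestral_states(tree, traits, .x,
                                                      weighted = weighted))
  names(states) <- vars
  values <- purrr::map(vars, function(v) {
    c(trait_vector(tree, traits, v), states[[v]]$states)
  })
  names(values) <- vars

  internal_nodes <- sort(unique(tree$edge[, 1]))
  rows <- purrr::map(internal_nodes, function(node) {
    kids_e <- which(tree$edge[, 1] == node)
    kids <- tree$edge[kids_e, 2]
    if (length(kids) != 2) {
      stop_invalid("internal node with != 2 children after resolution")
    }
    ord <- order(min_leaf[kids], method = "radix")
    kids <- kids[ord]; kids_e <- kids_e[ord]
    wgt <- sqrt(b[kids_e[1]] + b[kids_e[2]])
    out <- tibble(node = node, weight = wgt)
    for (v in vars) {
      delta <- values[[v]][[kids[1]]] - values[[v]][[kids[2]]]
      out[[paste0("delta_", v)]] <- delta
      out[[paste0("std_", v)]] <- delta / wgt
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Regression through the origin
#'
#' Fits `y = slope * x` with no intercept: `slope = sum(xy) / sum(x^2)`,
#' with R-squared computed about zero (`1 - RSS / sum(y^2)`) and a
#' two-sided p-value from `t = slope / SE` on `n - 1` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 2), e.g. standardized
#'   OGT and FOD contrasts.
#' @return An object of class `origin_fit` with components `slope`, `se`,
#'   `statistic`, `df`, `p_value`, `r_squared`, `n` and the data.
#' @examples
#' fit <- origin_regression(c(1, 2, 3), c(2.1, 3.9, 6.2))
#' tidy(fit)
#' @export
origin_regression <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 2) stop_invalid("at least two contrast pairs are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("x and y must be finite")
  }
  sxx <- sum(x^2)
  if (sxx == 0) {
    abort("all x are zero: slope through the origin is undefined",
          class = "thermidr_undefined_slope")
  }
  n <- length(x)
  slope <- sum(x * y) / sxx
  fitted <- slope * x
  rss <- sum((y - fitted)^2)
  syy <- sum(y^2)
  se <- sqrt(rss / (n - 1) / sxx)
  statistic <- if (se > 0) slope / se else if (slope == 0) NA_real_ else sign(slope) * Inf
  p_value <- if (is.na(statistic)) NA_real_ else 2 * pt(-abs(statistic), df = n - 1)
  structure(
    list(
      slope = slope, se = se, statistic = statistic, df = n - 1,
      p_value = p_value,
      r_squared = if (syy > 0) 1 - rss / syy else NA_real_,
      n = n, x = x, y = y, fitted = fitted, residuals = y - fitted
    ),
    class = "origin_fit"
  )
}

#' Contrast regression of disorder on growth temperature
#'
#' Convenience wrapper fitting the origin-fixed regression of FOD contrasts
#' on OGT contrasts from a [compute_contrasts()] table.
#'
#' @param contrasts Tibble from [compute_contrasts()].
#' @param x,y Trait names (default `"ogt"` and `"fod"`).
#' @param standardized Use standardized (`std_`) contrasts (default) or raw
#'   (`delta_`) contrasts.
#' @return An `origin_fit`.
#' @export
contrast_regression <- function(contrasts, x = "ogt", y = "fod",
                                standardized = TRUE) {
  prefix <- if (standardized) "std_" else "delta_"
  xs <- contrasts[[paste0(prefix, x)]]
  ys <- contrasts[[paste0(prefix, y)]]
  if (is.null(xs) || is.null(ys)) {
    stop_invalid("contrast columns not found for the requested traits")
  }
  origin_regression(xs, ys)
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf(
    "<origin_fit: slope = %.6g (SE %.3g), R2 = %.4g, t(%d) = %.3g, p = %.4g, n = %d>\n",
    x$slope, x$se, x$r_squared, x$df, x$statistic, x$p_value, x$n
  ))
  invisible(x)
}

#' @describeIn origin_regression One-row tibble of the slope estimate.
#' @param x An `origin_fit`.
#' @param ... Unused.
#' @export
tidy.origin_fit <- function(x, ...) {
  tibble(
    term = "slope", estimate = x$slope, std.error = x$se,
    statistic = x$statistic, p.value = x$p_value
  )
}

#' @describeIn origin_regression One-row tibble of fit-level summaries.
#' @export
glance.origin_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, df = x$df, p.value = x$p_value, nobs = x$n)
}

#' Write a contrast table to TSV
#'
#' @param contrasts Tibble from [compute_contrasts()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contrasts_tsv <- function(contrasts, path) {
  readr::write_tsv(contrasts, path)
  invisible(path)
}
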