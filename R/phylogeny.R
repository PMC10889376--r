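# Species-tree construction: identity distances from aligned 16S
# sequences, UPGMA, outgroup pruning, Newick round-trip. Trees are
# `ape::phylo` objects throughout.

#' Identity distance between two aligned sequences
#'
#' Pairwise-deletion identity distance: columns where either sequence has a
#' gap (`-` or `.`) are excluded, and the distance is one minus the
#' fraction of identical residues among the remaining comparable columns.
#'
#' @param a,b Aligned sequences (equal length, gaps allowed) as single
#'   strings.
#' @return Distance in `[0, 1]`.
#' @examples
#' identity_distance("AC-GT", "ACAGA") # 0.25
#' @export
identity_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop_invalid("aligned sequences must have equal length")
  }
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  gap <- c("-", ".")
  comparable <- !(ca %in% gap) & !(cb %in% gap)
  n <- sum(comparable)
  if (n == 0) {
    abort("no comparable (gap-free) columns: distance undefined",
          class = "thermidr_undefined_distance")
  }
  1 - sum(ca[comparable] == cb[comparable]) / n
}

#' Identity distance matrix from an alignment
#'
#' Applies [identity_distance()] to all pairs of an alignment, optionally
#' transforming to Jukes-Cantor corrected distances
#' `d = -3/4 log(1 - 4p/3)`.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param correction `"none"` (raw identity distance, the default) or
#'   `"jc"`.
#' @return Symmetric labeled distance matrix with zero diagonal.
#' @export
aligned_distance_matrix <- function(aln, correction = c("none", "jc")) {
  correction <- match.arg(correction)
  n <- length(aln)
  if (n < 2) stop_invalid("at least two sequences are required")
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    stop_invalid("aln must be uniquely named")
  }
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- identity_distance(aln[[i]], aln[[j]])
      if (correction == "jc") {
        if (p >= 0.75) {
          abort(sprintf("p-distance %.3f >= 0.75: JC correction undefined", p),
                class = "thermidr_undefined_distance")
        }
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Unweighted pair group method with arithmetic mean: average-linkage
#' agglomeration where each merge places the new node at half the
#' between-cluster average distance, yielding an ultrametric rooted tree.
#' Built on `stats::hclust(method = "average")` and converted to a rooted
#' `phylo`.
#'
#' @param d Symmetric distance matrix with labels, or a `dist` object.
#' @return A rooted, ultrametric `ape::phylo` tree.
#' @export
upgma_tree <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
      stop_invalid("d must be a symmetric matrix with zero diagonal")
    }
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2) stop_invalid("at least two taxa are required")
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_invalid("distances must be finite and non-negative")
  }
  hc <- stats::hclust(d, method = "average")
  tree <- ape::as.phylo(hc)
  # as.phylo.hclust places nodes at half the merge height (ultrametric)
  stats::reorder(tree)
}

#' Maximum deviation from ultrametricity
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Max absolute difference between root-to-leaf path lengths.
#' @export
ultrametric_deviation <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  max(depths) - min(depths)
}

#' Remove an outgroup leaf from a rooted tree
#'
#' Drops the outgroup leaf and suppresses the resulting degree-2 node by
#' summing its two incident branch lengths, returning the ingroup subtree.
#'
#' @param tree A rooted `phylo`.
#' @param outgroup_label Label of the outgroup leaf.
#' @return The pruned `phylo`.
#' @export
root_and_prune_outgroup <- function(tree, outgroup_label) {
  if (!outgroup_label %in% tree$tip.label) {
    stop_invalid(sprintf("unknown outgroup label '%s'", outgroup_label))
  }
  ape::drop.tip(tree, outgroup_label, collapse.singles = TRUE)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file, or a Newick string when `text = TRUE`.
#' @param text Treat `path` as Newick text rather than a file path.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path, text = FALSE) {
  tree <- tryCatch(
    if (text) ape::read.tree(text = path) else ape::read.tree(path),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort(sprintf("malformed Newick input: %s",
                  if (text) substr(path, 1, 60) else path),
          class = "thermidr_parse_error")
  }
  tree
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` tree.
#' @param path Output file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Write a labeled square distance matrix to TSV
#'
#' @param d Labeled symmetric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  tbl <- as_tibble(d, rownames = "species_id")
  readr::write_tsv(tbl, path)
  invisible(path)
}
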