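# Independent oracles, written against the definitions rather than the
# package's code paths.

AAS20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(min_len = 5, max_len = 500) {
  len <- if (min_len == max_len) min_len else sample(min_len:max_len, 1)
  paste(sample(AAS20, len, replace = TRUE), collapse = "")
}

# brute-force diagram-of-states classifier: evaluates each region's
# predicate separately and checks exactly one fires
oracle_region <- function(f_plus, f_minus) {
  fcr <- f_plus + f_minus
  ncpr <- f_plus - f_minus
  hits <- c(
    r1 = fcr < 0.25,
    r2 = fcr >= 0.25 && fcr <= 0.35,
    r3 = fcr > 0.35 && abs(ncpr) <= 0.35,
    r4 = fcr > 0.35 && abs(ncpr) > 0.35 && f_minus > 0.35 && f_plus <= 0.35,
    r5 = fcr > 0.35 && abs(ncpr) > 0.35 && f_plus > 0.35 && f_minus <= 0.35
  )
  if (sum(hits) != 1) return(NA_integer_)
  which(hits)
}

# exhaustive global-alignment score by recursion over all alignments
# (exponential: only for very short strings)
oracle_nw_score <- function(a, b, match = 1, mismatch = 0, gap = -0.5) {
  rec <- function(i, j) {
    if (i > nchar(a) && j > nchar(b)) return(0)
    if (i > nchar(a)) return(gap * (nchar(b) - j + 1))
    if (j > nchar(b)) return(gap * (nchar(a) - i + 1))
    sub <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
    max(rec(i + 1, j + 1) + sub, rec(i + 1, j) + gap, rec(i, j + 1) + gap)
  }
  rec(1, 1)
}

# naive UPGMA from the definition: average distances computed directly over
# original-matrix entries; returns the implied cophenetic (merge-distance)
# matrix
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best[1]) best <- c(avg, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# textbook Welch statistic / Welch-Satterthwaite df / two-sided p
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  c(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# generic numeric minimizer of the ancestral-state RSS (BFGS with the
# objective's gradient), started from the trait average
oracle_optim_states <- function(tree, tip_values) {
  obj <- function(x) ancestral_rss(tree, tip_values, x)
  gr <- function(x) rss_gradient(tree, tip_values, x)
  optim(rep(mean(tip_values), tree$Nnode), obj, gr, method = "BFGS",
        control = list(maxit = 5000, reltol = 1e-16))$par
}

# analytic RSS gradient with respect to the internal states
rss_gradient <- function(tree, tip_values, internal_states) {
  ntip <- ape::Ntip(tree)
  x <- c(tip_values[tree$tip.label], internal_states)
  height <- max(ape::node.depth.edgelength(tree))
  b <- pmax(tree$edge.length, 1e-8 * height)
  g <- numeric(tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    d <- 2 * (x[ch] - x[p]) / b[e]
    if (ch > ntip) g[ch - ntip] <- g[ch - ntip] + d
    g[p - ntip] <- g[p - ntip] - d
  }
  g
}

# planted ortholog families: n_fam founders, each copied n_var times with a
# fixed point-mutation fraction; returns a protein table plus the true
# family of each protein
planted_families <- function(n_fam = 3, n_var = 8, len = 120,
                             divergence = 0.1) {
  founders <- replicate(n_fam, paste(sample(AAS20, len, TRUE), collapse = ""))
  purrr::map_dfr(seq_len(n_fam), function(f) {
    tibble::tibble(
      id = sprintf("fam%d_v%02d", f, seq_len(n_var)),
      species_id = sprintf("sp%02d", seq_len(n_var)),
      sequence = purrr::map_chr(seq_len(n_var),
                                ~ thermidr::mutate_protein(founders[f], divergence)),
      family = f
    )
  })
}
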