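# fixtures and independent oracles used across the suite

make_aln <- function(...) coi_alignment(c(...))

make_tax <- function(ids, species, group = "G1", ingroup = TRUE) {
  taxon_map(data.frame(specimen_id = ids, species = species,
                       group = group, ingroup = ingroup,
                       stringsAsFactors = FALSE))
}

random_aln <- function(n_seq, n_col, p_gap = 0, alphabet = c("A", "C", "G", "T")) {
  seqs <- vapply(seq_len(n_seq), function(i) {
    chars <- sample(alphabet, n_col, replace = TRUE)
    if (p_gap > 0) {
      g <- runif(n_col) < p_gap
      chars[g] <- "-"
    }
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%03d", seq_len(n_seq))
  coi_alignment(seqs)
}

# brute-force per-column transition/transversion oracle
naive_pair_counts <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  pur <- c("A", "G")
  pyr <- c("C", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(a)) {
    x <- a[k]; y <- b[k]
    if (!(x %in% c(pur, pyr)) || !(y %in% c(pur, pyr))) next
    n <- n + 1L
    if (x == y) next
    same_class <- (x %in% pur && y %in% pur) || (x %in% pyr && y %in% pyr)
    if (same_class) ts <- ts + 1L else tv <- tv + 1L
  }
  list(n = n, P = ts / n, Q = tv / n)
}

# brute-force site classification oracle
naive_classify <- function(mat) {
  res <- c(analyzed = 0L, constant = 0L, variable = 0L,
           parsimony_informative = 0L, singleton = 0L, excluded = 0L)
  for (r in seq_len(nrow(mat))) {
    cells <- mat[r, ]
    cells <- cells[cells %in% c("A", "C", "G", "T")]
    if (length(cells) < 2) {
      res["excluded"] <- res["excluded"] + 1L
      next
    }
    res["analyzed"] <- res["analyzed"] + 1L
    tab <- table(cells)
    if (length(tab) == 1) {
      res["constant"] <- res["constant"] + 1L
    } else {
      res["variable"] <- res["variable"] + 1L
      if (sum(tab >= 2) >= 2) {
        res["parsimony_informative"] <- res["parsimony_informative"] + 1L
      } else {
        res["singleton"] <- res["singleton"] + 1L
      }
    }
  }
  as.list(res)
}

# closed-form expected transition/transversion proportions for a K2P
# branch of length t (expected substitutions/site) with rate ratio kappa
expected_PQ <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  P <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  Q <- 0.5 - 0.5 * exp(-4 * beta * t)
  c(P = P, Q = Q)
}

# large-sample standard error of the K2P estimator (delta method)
k2p_se <- function(P, Q, L) {
  a <- 1 / (1 - 2 * P - Q)
  b <- 0.5 * (1 / (1 - 2 * P - Q) + 1 / (1 - 2 * Q))
  sqrt((a^2 * P + b^2 * Q - (a * P + b * Q)^2) / L)
}

# random additive (tree-metric) distance matrix plus its generating tree
random_additive <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = ape::unroot(tr), dm = d[ord, ord])
}
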