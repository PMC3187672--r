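#' Neighbor joining with deterministic tie-breaking
#'
#' Standard Saitou–Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` is joined (with `R` the row sums of
#' the current matrix) and limb lengths follow the usual formulas. Two
#' details are pinned down for reproducibility:
#'
#' * Ties in the Q criterion are broken by the lexicographically smallest
#'   sorted label pair, so the result is identical across platforms.
#' * A negative limb length is clamped to zero and the deficit transferred
#'   to the sibling limb (standard practice); every clamp is recorded in
#'   the `"clamped"` attribute. Downstream cohesion diagnostics assume
#'   non-negative branch lengths.
#'
#' The result is used as a similarity profile, not as an estimate of deep
#' phylogeny: it is an unrooted binary tree returned as an [ape::phylo]
#' object whose arbitrary degree-3 "root" is only a serialization anchor.
#'
#' @param dm symmetric distance matrix with unique id dimnames, at least
#'   3 taxa, no `NA` entries (impute or drop undefined pairs first).
#' @return an unrooted `phylo` tree with `2n-3` edges; attribute
#'   `"clamped"` lists any clamped limbs.
#' @export
neighbor_joining <- function(dm) {
  if (!is.matrix(dm)) stop("`dm` must be a matrix")
  ids <- rownames(dm)
  if (is.null(ids) || is.null(colnames(dm)) || !identical(ids, colnames(dm))) {
    stop("`dm` needs identical row and column id names")
  }
  n <- length(ids)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(dm)) {
    bad <- which(is.na(dm) & upper.tri(dm), arr.ind = TRUE)
    stop("undefined distances for pair(s): ",
         paste(paste(ids[bad[, 1]], ids[bad[, 2]], sep = "--"), collapse = ", "))
  }
  if (max(abs(dm - t(dm))) > 1e-8) stop("`dm` is not symmetric")

  labs <- ids
  D <- dm
  children <- list()   # internal label -> list(labels=, lengths=)
  clamped <- character(0)
  k <- 0L
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Qm <- (r - 2) * D - outer(R, R, `+`)
    diag(Qm) <- Inf
    qmin <- min(Qm)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Qm <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lo <- pmin(labs[cand[, 1]], labs[cand[, 2]])
    hi <- pmax(labs[cand[, 1]], labs[cand[, 2]])
    pick <- order(lo, hi)[1]
    i <- cand[pick, 1]
    j <- cand[pick, 2]
    dij <- D[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) {
      clamped <- c(clamped, labs[i])
      lj <- lj + li
      li <- 0
    } else if (lj < 0) {
      clamped <- c(clamped, labs[j])
      li <- li + lj
      lj <- 0
    }
    k <- k + 1L
    new_lab <- sprintf("__nj%04d", k)
    children[[new_lab]] <- list(labels = c(labs[i], labs[j]),
                                lengths = c(li, lj))
    keep <- setdiff(seq_len(r), c(i, j))
    dnew <- (D[i, keep] + D[j, keep] - dij) / 2
    m <- length(keep)
    D2 <- matrix(0, m + 1, m + 1)
    D2[seq_len(m), seq_len(m)] <- D[keep, keep]
    D2[m + 1, seq_len(m)] <- dnew
    D2[seq_len(m), m + 1] <- dnew
    labs <- c(labs[keep], new_lab)
    dimnames(D2) <- list(labs, labs)
    D <- D2
  }
  # final three nodes join at the unresolved central node
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  limbs <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
             (d13 + d23 - d12) / 2)
  neg <- limbs < 0
  if (any(neg)) {
    clamped <- c(clamped, labs[neg])
    limbs[neg] <- 0
  }
  root_lab <- "__njroot"
  children[[root_lab]] <- list(labels = labs, lengths = limbs)

  # convert the label/children representation into an ape phylo object
  n_int <- n - 2L
  tip_num <- stats::setNames(seq_len(n), ids)
  edge_par <- integer(2 * n - 3)
  edge_chi <- integer(2 * n - 3)
  edge_len <- numeric(2 * n - 3)
  e <- 0L
  # iterative preorder to avoid deep recursion on caterpillar trees
  stack <- list(list(lab = root_lab, num = n + 1L))
  next_int <- n + 2L
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ch <- children[[top$lab]]
    for (ci in seq_along(ch$labels)) {
      clab <- ch$labels[ci]
      if (clab %in% names(children)) {
        cnum <- next_int
        next_int <- next_int + 1L
        stack[[length(stack) + 1]] <- list(lab = clab, num = cnum)
      } else {
        cnum <- tip_num[[clab]]
      }
      e <- e + 1L
      edge_par[e] <- top$num
      edge_chi[e] <- cnum
      edge_len[e] <- ch$lengths[ci]
    }
  }
  tree <- list(edge = cbind(edge_par, edge_chi), edge.length = edge_len,
               tip.label = ids, Nnode = n_int)
  dimnames(tree$edge) <- NULL
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "clamped") <- clamped
  tree
}

newick_quote <- function(lab) {
  if (grepl("[][ \t(),:;']", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else {
    lab
  }
}

#' Serialize a tree to Newick
#'
#' Writes a `phylo` tree with branch lengths as a Newick string. Leaf
#' labels containing spaces or Newick metacharacters are single-quoted.
#' The trifurcation used as serialization root is arbitrary; parsing the
#' string back yields a tree with the identical bipartition set and branch
#' lengths.
#'
#' @param tree a `phylo` object with `edge.length`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string terminated by `;`.
#' @export
to_newick <- function(tree, digits = 10) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  rec <- function(node) {
    es <- kids[[as.character(node)]]
    parts <- vapply(es, function(ei) {
      child <- tree$edge[ei, 2]
      sub <- if (child <= n) newick_quote(tree$tip.label[child]) else rec(child)
      paste0(sub, ":", fmt(tree$edge.length[ei]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

# descendant tip labels of every node, as a list indexed by node number
node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nn)
  desc[seq_len(n)] <- as.list(tree$tip.label)
  for (ei in seq_len(nrow(po$edge))) {
    p <- po$edge[ei, 1]
    c_ <- po$edge[ei, 2]
    desc[[p]] <- c(desc[[p]], desc[[c_]])
  }
  lapply(desc, sort)
}

#' Bipartitions of an unrooted tree
#'
#' Each edge of an unrooted tree splits the leaves in two; this returns
#' one side per edge (the tip set on the child side, with the conventional
#' degree-3 root as anchor). For a binary unrooted tree of `n` leaves
#' there are `n - 3` nontrivial splits -- those whose edge joins two
#' internal nodes. Trivial splits (single leaves) are included only on
#' request; the complement of any returned side is implied.
#'
#' @param tree a `phylo` object.
#' @param include_trivial also return the single-leaf sides of terminal
#'   edges.
#' @return list of character vectors (sorted tip labels), with attribute
#'   `"tips"` holding the full leaf set.
#' @export
bipartitions <- function(tree, include_trivial = FALSE) {
  n <- length(tree$tip.label)
  desc <- node_tip_sets(tree)
  sides <- list()
  for (ei in seq_len(nrow(tree$edge))) {
    child <- tree$edge[ei, 2]
    if (child > n || include_trivial) {
      sides[[length(sides) + 1]] <- desc[[child]]
    }
  }
  attr(sides, "tips") <- sort(tree$tip.label)
  sides
}

# canonical key of a bipartition: the side not containing the first tip
# (alphabetically), serialized
split_key <- function(side, tips) {
  anchor <- tips[1]
  s <- if (anchor %in% side) setdiff(tips, side) else side
  paste(sort(s), collapse = "\r")
}

#' Compare the nontrivial split sets of two trees on the same leaves
#'
#' @param t1,t2 `phylo` objects on identical leaf sets.
#' @return `TRUE` iff the nontrivial bipartition sets are equal.
#' @export
same_splits <- function(t1, t2) {
  tips <- sort(t1$tip.label)
  if (!identical(tips, sort(t2$tip.label))) return(FALSE)
  k1 <- sort(vapply(bipartitions(t1), split_key, character(1), tips = tips))
  k2 <- sort(vapply(bipartitions(t2), split_key, character(1), tips = tips))
  identical(k1, k2)
}
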