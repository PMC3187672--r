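mat_from <- function(ids, ...) {
  v <- c(...)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("three-taxon trees use the closed-form limb lengths", {
  dm <- mat_from(c("A", "B", "C"), 2, 3, 3)  # AB, AC, BC
  tr <- neighbor_joining(dm)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 1)
  limb <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(limb, c(A = 1, B = 1, C = 2))
})

test_that("the 4-taxon additive example is recovered exactly", {
  dm <- mat_from(LETTERS[1:4], 3, 5, 6, 6, 7, 7)  # AB AC AD BC BD CD
  tr <- neighbor_joining(dm)
  splits <- bipartitions(tr)
  expect_equal(length(splits), 1)
  key <- sort(splits[[1]])
  expect_true(identical(key, c("A", "B")) || identical(key, c("C", "D")))
  limb <- setNames(tr$edge.length[match(1:4, tr$edge[, 2])], tr$tip.label)
  expect_equal(limb, c(A = 1, B = 2, C = 3, D = 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm)
})

test_that("Q ties break on the lexicographically smallest id pair", {
  dm <- mat_from(LETTERS[1:4], 1, 1, 1, 1, 1, 1)
  tr <- neighbor_joining(dm)
  splits <- bipartitions(tr)
  expect_equal(length(splits), 1)
  side <- splits[[1]]
  if ("A" %in% side) expect_setequal(side, c("A", "B"))
  else expect_setequal(side, c("C", "D"))
})

test_that("input validation rejects small, NA and asymmetric matrices", {
  dm <- mat_from(c("A", "B"), 1)
  expect_error(neighbor_joining(dm), "at least 3")
  dm3 <- mat_from(c("A", "B", "C"), 1, NA, 1)
  expect_error(neighbor_joining(dm3), "undefined distances.*A--C")
  bad <- mat_from(c("A", "B", "C"), 1, 2, 3)
  bad[2, 1] <- 9
  expect_error(neighbor_joining(bad), "not symmetric")
})

test_that("NJ is exact on random additive matrices", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    ra <- random_additive(n)
    tr <- neighbor_joining(ra$dm)
    expect_true(same_splits(tr, ra$tree))
    got <- ape::cophenetic.phylo(tr)[rownames(ra$dm), colnames(ra$dm)]
    expect_lt(max(abs(got - ra$dm)), 1e-9)
  }
})

test_that("NJ is invariant to taxon order (same split set)", {
  set.seed(13)
  ra <- random_additive(8)
  tr1 <- neighbor_joining(ra$dm)
  perm <- sample(rownames(ra$dm))
  tr2 <- neighbor_joining(ra$dm[perm, perm])
  expect_true(same_splits(tr1, tr2))
})

test_that("negative limbs are clamped to zero and logged", {
  # strong triangle-inequality violation forces a negative NJ branch
  dm <- mat_from(LETTERS[1:4], 0.1, 5, 5, 5, 5, 0.1)
  dm["A", "B"] <- 3; dm["B", "A"] <- 3
  tr <- neighbor_joining(dm)
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ matches the exhaustive least-squares topology near additivity", {
  # oracle: enumerate all unrooted 5-taxon topologies, fit branch lengths
  # by OLS, pick the minimum-RSS topology
  ols_best <- function(dm) {
    ids <- rownames(dm)
    topos <- phangorn::allTrees(length(ids), rooted = FALSE, tip.label = ids)
    pair_idx <- t(combn(length(ids), 2))
    y <- dm[pair_idx]
    best <- NULL; best_rss <- Inf
    # index via [[ so the compressed multiPhylo reattaches tip labels
    for (ti in seq_along(topos)) {
      tp <- topos[[ti]]
      tp$edge.length <- rep(1, nrow(tp$edge))
      # design matrix: which edges lie on the path between each pair
      tipno <- match(ids, tp$tip.label)
      X <- matrix(0, nrow(pair_idx), nrow(tp$edge))
      for (r in seq_len(nrow(pair_idx))) {
        np <- ape::nodepath(tp, tipno[pair_idx[r, 1]], tipno[pair_idx[r, 2]])
        for (k in seq_len(length(np) - 1)) {
          e <- which((tp$edge[, 1] == np[k] & tp$edge[, 2] == np[k + 1]) |
                       (tp$edge[, 1] == np[k + 1] & tp$edge[, 2] == np[k]))
          X[r, e] <- 1
        }
      }
      fit <- lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (rss < best_rss) { best_rss <- rss; best <- tp }
    }
    best
  }
  set.seed(31)
  for (i in 1:5) {
    ra <- random_additive(5)
    noise <- matrix(runif(25, -0.005, 0.005), 5)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    dm <- ra$dm * (1 + noise)
    tr <- neighbor_joining(dm)
    expect_true(same_splits(tr, ols_best(dm)))
  }
})

test_that("to_newick round-trips splits and branch lengths", {
  set.seed(5)
  ra <- random_additive(7)
  tr <- neighbor_joining(ra$dm)
  back <- ape::read.tree(text = to_newick(tr))
  expect_true(same_splits(tr, back))
  ids <- sort(tr$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[ids, ids],
               ape::cophenetic.phylo(tr)[ids, ids], tolerance = 1e-8)
})

test_that("labels with spaces are quoted in Newick output", {
  dm <- mat_from(c("tax one", "tax two", "tax three"), 2, 3, 3)
  nwk <- to_newick(neighbor_joining(dm))
  expect_match(nwk, "'tax one'", fixed = TRUE)
})

test_that("bipartitions counts nontrivial splits", {
  dm4 <- mat_from(LETTERS[1:4], 3, 5, 6, 6, 7, 7)
  expect_equal(length(bipartitions(neighbor_joining(dm4))), 1)
  dm3 <- mat_from(LETTERS[1:3], 2, 3, 3)
  expect_equal(length(bipartitions(neighbor_joining(dm3))), 0)
  # 5-leaf caterpillar: 5 - 3 = 2 nontrivial splits
  cat5 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  d <- ape::cophenetic.phylo(cat5)
  ord <- sort(rownames(d))
  expect_equal(length(bipartitions(neighbor_joining(d[ord, ord]))), 2)
})
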