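# build a distance matrix directly from a vector of upper-triangle values
dm_of <- function(ids, ...) {
  v <- c(...)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("divergence_pairs partitions ingroup pairs exhaustively", {
  ids <- c("a1", "a2", "b1", "c1", "out1")
  tax <- make_tax(ids, c("A", "A", "B", "C", "Z"),
                  group = c("G1", "G1", "G1", "G2", "OUT"),
                  ingroup = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  dm <- dm_of(ids, runif(10))
  pr <- divergence_pairs(dm, tax)
  expect_equal(nrow(pr), choose(4, 2))  # outgroup excluded
  expect_equal(sum(pr$class == "intraspecific"), 1)  # a1-a2
  expect_equal(sum(pr$class == "interspecific"), 2)  # a?-b1
  expect_equal(sum(pr$class == "cross-group"), 3)
})

test_that("intraspecific summary reproduces hand-computed rows", {
  ids <- c("a1", "a2", "a3", "b1", "b2", "c1")
  tax <- make_tax(ids, c("A", "A", "A", "B", "B", "C"))
  dm <- matrix(0.9, 6, 6, dimnames = list(ids, ids)); diag(dm) <- 0
  dm["a1", "a2"] <- dm["a2", "a1"] <- 0
  dm["a1", "a3"] <- dm["a3", "a1"] <- 0.0001
  dm["a2", "a3"] <- dm["a3", "a2"] <- 0.0002
  dm["b1", "b2"] <- dm["b2", "b1"] <- 0
  tab <- intraspecific_summary(dm, tax)
  A <- tab[tab$taxon == "A", ]
  expect_equal(A$n_individuals, 3L)
  expect_equal(A$n_pairs, 3L)
  expect_equal(A$mean, 0.01)
  expect_equal(c(A$range_min, A$range_max), c(0, 0.02))
  expect_equal(A$sd, sd(c(0, 0.01, 0.02)))
  B <- tab[tab$taxon == "B", ]
  expect_equal(B$mean, 0)
  expect_true(is.na(B$sd))  # single pair: SD undefined, printed "/"
  expect_equal(attr(tab, "skipped"), "C")
  All <- tab[tab$taxon == "All", ]
  expect_equal(All$n_individuals, 5L)
  expect_equal(All$n_pairs, 4L)
})

test_that("pooled intraspecific mean is the pair-weighted mean of species means", {
  set.seed(17)
  n_sp <- 5
  ids <- unlist(lapply(1:n_sp, function(i) sprintf("s%d_%d", i, 1:sample(2:6, 1))))
  sp <- sub("_.*", "", ids)
  tax <- make_tax(ids, sp)
  dm <- dm_of(ids, runif(choose(length(ids), 2), 0, 0.1))
  tab <- intraspecific_summary(dm, tax)
  per <- tab[tab$taxon != "All", ]
  all_row <- tab[tab$taxon == "All", ]
  expect_equal(all_row$mean,
               sum(per$mean * per$n_pairs) / sum(per$n_pairs))
})

test_that("interspecific summary handles representative and all-pairs modes", {
  ids <- c("a1", "b1")
  tax <- make_tax(ids, c("A", "B"))
  dm <- dm_of(ids, 0.05)
  tab <- interspecific_summary(dm, tax, seed = 1)
  g <- tab[tab$taxon == "g1" | tab$taxon == "G1", ]
  expect_equal(g$mean, 5)
  expect_equal(c(g$range_min, g$range_max), c(5, 5))
  expect_true(is.na(g$sd))

  ids3 <- c("a1", "b1", "c1")
  tax3 <- make_tax(ids3, c("A", "B", "C"))
  dm3 <- dm_of(ids3, 0.03, 0.04, 0.05)
  t3 <- interspecific_summary(dm3, tax3, seed = 1)
  g3 <- t3[t3$taxon == "G1", ]
  expect_equal(g3$mean, 4)
  expect_equal(c(g3$range_min, g3$range_max), c(3, 5))

  # representative draw is reproducible and seed-sensitive
  ids4 <- c("a1", "a2", "a3", "b1")
  tax4 <- make_tax(ids4, c("A", "A", "A", "B"))
  # column-major upper triangle: a1a2 a1a3 a2a3 a1b1 a2b1 a3b1
  dm4 <- dm_of(ids4, 0.001, 0.002, 0.003, 0.03, 0.04, 0.05)
  r1 <- interspecific_summary(dm4, tax4, seed = 7)
  r2 <- interspecific_summary(dm4, tax4, seed = 7)
  expect_identical(attr(r1, "representatives"), attr(r2, "representatives"))
  expect_equal(r1$mean, r2$mean)

  # all-pairs mode uses every cross-species individual pair
  ap <- interspecific_summary(dm4, tax4, mode = "all-pairs")
  expect_equal(ap[ap$taxon == "G1", "n_pairs"], 3L)
  expect_equal(ap[ap$taxon == "G1", "mean"], mean(c(0.03, 0.04, 0.05)) * 100)
})

test_that("representative mode converges to species-level all-pairs mean over seeds", {
  set.seed(23)
  ids <- unlist(lapply(1:4, function(i) sprintf("sp%d_%d", i, 1:4)))
  sp <- sub("_.*", "", ids)
  tax <- make_tax(ids, sp)
  base <- outer(match(sp, unique(sp)), match(sp, unique(sp)),
                function(i, j) ifelse(i == j, 0.002, 0.05 + 0.01 * (i + j)))
  noise <- matrix(runif(length(ids)^2, -0.002, 0.002), length(ids))
  dm <- base + (noise + t(noise)) / 2
  diag(dm) <- 0
  dm[lower.tri(dm)] <- t(dm)[lower.tri(dm)]
  dimnames(dm) <- list(ids, ids)
  ap_mean <- interspecific_summary(dm, tax, mode = "all-pairs")
  ap_mean <- ap_mean[ap_mean$taxon == "All", "mean"]
  rep_means <- vapply(1:100, function(s) {
    t <- interspecific_summary(dm, tax, seed = s)
    t[t$taxon == "All", "mean"]
  }, numeric(1))
  expect_lt(abs(mean(rep_means) - ap_mean), 0.05)
})

test_that("pooled_pair_stats counts combinatorial pairs", {
  ids <- c("x", "y")
  dm <- dm_of(ids, 0)
  s <- pooled_pair_stats(dm)
  expect_equal(unlist(s[c("n_pairs", "mean", "min", "max")]),
               c(n_pairs = 1, mean = 0, min = 0, max = 0))
  expect_error(pooled_pair_stats(dm, include = "x"), "at least 2")
  expect_error(pooled_pair_stats(dm, include = c("x", "zz")), "not in matrix")
})

test_that("histogram bins are half-open, conserving and zero-safe", {
  h <- divergence_histogram(c(0.001, 0.003), c(0.052), bin_width = 0.5)
  expect_equal(h$intra_count[h$bin_lo == 0], 2)
  expect_equal(h$inter_count[h$bin_lo == 5], 1)
  expect_equal(sum(h$intra_count), 2)
  expect_equal(sum(h$inter_count), 1)

  h0 <- divergence_histogram(c(0.001, 0.004), numeric(0))
  expect_equal(sum(h0$inter_count), 0)
  expect_error(divergence_histogram(c(-0.01), c(0.05)), "negative")

  # boundary value lands in the upper bin (half-open [lo, lo+w))
  hb <- divergence_histogram(c(0.005), numeric(0), bin_width = 0.5)
  expect_equal(hb$intra_count[hb$bin_lo == 0.5], 1)
})

test_that("pair classes are conserved: intra + inter + cross = all ingroup pairs", {
  set.seed(41)
  ds <- simulate_coi_dataset(sim_config(n_species = 6, seed = 12,
                                        seq_length = 120, n_groups = 2))
  dm <- k2p_distances(ds$alignment)
  pr <- divergence_pairs(dm, ds$taxonomy)
  m <- sum(ds$taxonomy$ingroup)
  expect_equal(nrow(pr), m * (m - 1) / 2)
  expect_equal(sum(table(pr$class)), m * (m - 1) / 2)
})
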