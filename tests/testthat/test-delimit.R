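tree_of <- function(nwk) ape::read.tree(text = nwk)

test_that("cohesion is bipartition membership on the unrooted tree", {
  tax <- make_tax(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  coh <- cohesion_report(tree_of("((a1:1,a2:1):1,(b1:1,b2:1):1);"), tax)
  expect_true(all(coh$cohesive))
  expect_equal(coh$n_clades, c(1L, 1L))

  coh2 <- cohesion_report(tree_of("((a1:1,b1:1):1,(a2:1,b2:1):1);"), tax)
  expect_false(any(coh2$cohesive))
  expect_true(all(nzchar(coh2$intruders)))

  # singleton species are cohesive by convention
  tax3 <- make_tax(c("a1", "b1", "c1"), c("A", "B", "C"))
  coh3 <- cohesion_report(tree_of("(a1:1,b1:1,c1:1);"), tax3)
  expect_true(all(coh3$cohesive))

  expect_error(
    cohesion_report(tree_of("(a1:1,b1:1,zz:1);"), tax3),
    "without taxonomy entry: zz")
})

test_that("every specimen its own species is always fully cohesive", {
  set.seed(19)
  for (i in 1:5) {
    ra <- random_additive(sample(5:10, 1))
    tr <- neighbor_joining(ra$dm)
    tax <- make_tax(tr$tip.label, tr$tip.label)
    expect_true(all(cohesion_report(tr, tax)$cohesive))
  }
})

test_that("conspecific clades partition the species deterministically", {
  # note: without the extra leaf o, {a1..a4} would be the complement of
  # the single leaf x and so itself one side of the unrooted tree
  tax <- make_tax(c("a1", "a2", "x", "a3", "a4", "o"),
                  c("A", "A", "X", "A", "A", "O"))
  tr <- tree_of("((a1:1,a2:1):1,(x:1,(a3:1,a4:1):1):1,o:1);")
  cl <- conspecific_clades(tr, tax, "A")
  expect_equal(cl, list(c("a1", "a2"), c("a3", "a4")))

  # cohesive species: one clade
  tr2 <- tree_of("((a1:1,a2:1):1,(x:1,a3:1):1);")
  tax2 <- make_tax(c("a1", "a2", "x", "a3"), c("A", "A", "X", "A"))
  expect_equal(length(conspecific_clades(tree_of(
    "(((a1:1,a2:1):1,a3:1):1,x:1,y:1);"),
    make_tax(c("a1", "a2", "a3", "x", "y"), c("A", "A", "A", "X", "Y")),
    "A")), 1)

  # fully interleaved: one clade per individual
  tr3 <- tree_of("((a1:1,b1:1):1,((a2:1,b2:1):1,(a3:1,b3:1):1):1);")
  tax3 <- make_tax(c("a1", "b1", "a2", "b2", "a3", "b3"),
                   rep(c("A", "B"), 3))
  cl3 <- conspecific_clades(tr3, tax3, "A")
  expect_equal(length(cl3), 3)

  # partition properties on random trees/labelings
  set.seed(29)
  for (i in 1:10) {
    ra <- random_additive(8)
    tr <- neighbor_joining(ra$dm)
    sp <- sample(c("A", "B"), 8, replace = TRUE)
    sp[1:2] <- "A"
    tax <- make_tax(tr$tip.label, sp)
    mine <- sort(tr$tip.label[sp == "A"])
    cl <- conspecific_clades(tr, tax, "A")
    expect_identical(sort(unlist(cl)), mine)
    expect_equal(sum(lengths(cl)), length(mine))  # pairwise disjoint
  }

  expect_error(conspecific_clades(tr3, tax3, "nope"), "unknown species")
})

test_that("threshold flags catch deep splits and shallow species pairs", {
  ids <- c("t1", "t2", "u1", "v1", "w1")
  tax <- make_tax(ids, c("T", "T", "U", "V", "W"))
  dm <- matrix(0.06, 5, 5, dimnames = list(ids, ids)); diag(dm) <- 0
  dm["t1", "t2"] <- dm["t2", "t1"] <- 0.0295   # deep intraspecific
  dm["v1", "w1"] <- dm["w1", "v1"] <- 0.0083   # shallow species pair
  fl <- flag_candidates(dm, tax)
  expect_equal(fl$deep_intraspecific$species, "T")
  expect_equal(fl$deep_intraspecific$max_intra, 2.95)
  expect_equal(nrow(fl$low_interspecific), 1)
  expect_equal(sort(c(fl$low_interspecific$species_a,
                      fl$low_interspecific$species_b)), c("V", "W"))
  expect_equal(fl$low_interspecific$mean_d, 0.83)

  # all-zero matrix: no deep flags, every same-group pair merge-flagged
  dm0 <- matrix(0, 5, 5, dimnames = list(ids, ids))
  fl0 <- flag_candidates(dm0, tax)
  expect_equal(nrow(fl0$deep_intraspecific), 0)
  expect_equal(nrow(fl0$low_interspecific), choose(4, 2))  # 4 species, one group

  expect_error(flag_candidates(dm, tax, split_threshold = 0.01,
                               merge_threshold = 0.015), "exceed")
  expect_error(flag_candidates(dm, tax, split_threshold = -1), "positive")
})

test_that("cohesive species nested in a foreign group are flagged misplaced", {
  ids <- c("a1", "a2", "m1", "m2", "m3", "m4", "b1", "b2", "c1", "c2")
  # species A (assigned GB) sits inside group GM's clade; B and C are
  # correctly placed GB sisters
  tax <- taxon_map(data.frame(
    specimen_id = ids,
    species = c("A", "A", "M1", "M1", "M2", "M2", "B", "B", "C", "C"),
    group = c("GB", "GB", "GM", "GM", "GM", "GM", "GB", "GB", "GB", "GB"),
    ingroup = TRUE, stringsAsFactors = FALSE))
  tr <- tree_of(paste0("(((a1:1,a2:1):1,(m1:1,m2:1):1):1,(m3:1,m4:1):2,",
                       "((b1:1,b2:1):1,(c1:1,c2:1):1):2);"))
  dm <- matrix(0.05, 10, 10, dimnames = list(ids, ids)); diag(dm) <- 0
  fl <- flag_candidates(dm, tax, tree = tr)
  expect_true("A" %in% fl$misplaced$species)
  expect_equal(fl$misplaced$own_group[fl$misplaced$species == "A"], "GB")
  expect_false("B" %in% fl$misplaced$species)
  expect_false("C" %in% fl$misplaced$species)
})
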