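#' Simulation configuration
#'
#' Describes a synthetic barcode study whose statistical structure mirrors
#' a typical aphid COI survey: a modest number of congeneric species,
#' uneven individual sampling, within-species divergence well under 1%,
#' between-species divergence of roughly 3.5--8%, a strongly AT-biased
#' composition, and optionally a few species carrying a planted deep
#' ("cryptic") intraspecific split of barcode-gap magnitude.
#'
#' All randomness flows from the single `seed` through named substreams
#' (tree / individuals / sequences), so the same configuration always
#' yields the same data set.
#'
#' @param n_species number of ingroup species (default 12).
#' @param individuals_per_species scalar or length-2 range; per-species
#'   counts are drawn uniformly from the range (default 5).
#' @param seq_length alignment columns (default 591, a typical barcode
#'   fragment).
#' @param interspecific_range range of between-species tree depths in
#'   expected substitutions per site (default `c(0.035, 0.08)`).
#' @param intraspecific_depth maximum within-species pairwise tree depth
#'   (default 0.01).
#' @param kappa transition/transversion *rate* ratio of the substitution
#'   process (default 4, a realistic value for insect mitochondrial DNA).
#' @param base_weights root-sequence sampling weights for A, C, G, T
#'   (default the AT-rich composition typical of insect mtDNA:
#'   A 0.345, C 0.139, G 0.122, T 0.394).
#' @param n_groups number of higher groups ("genera") the species are
#'   clustered into from the species tree (default 3).
#' @param cryptic_fraction fraction of species planted with a deep
#'   intraspecific split (default 0).
#' @param cryptic_depth between-clade depth of a planted split (default
#'   0.028, i.e. ~2.8%, the magnitude reported for cryptic aphid
#'   lineages).
#' @param seed master seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 12,
                       individuals_per_species = 5,
                       seq_length = 591,
                       interspecific_range = c(0.035, 0.08),
                       intraspecific_depth = 0.01,
                       kappa = 4,
                       base_weights = c(A = 0.345, C = 0.139,
                                        G = 0.122, T = 0.394),
                       n_groups = 3,
                       cryptic_fraction = 0,
                       cryptic_depth = 0.028,
                       seed = 1L) {
  stopifnot(n_species >= 2, seq_length >= 1, kappa > 0,
            length(interspecific_range) == 2,
            interspecific_range[1] > 0,
            interspecific_range[2] >= interspecific_range[1],
            intraspecific_depth >= 0,
            cryptic_fraction >= 0, cryptic_fraction <= 1,
            cryptic_depth >= 0, n_groups >= 1)
  ind <- individuals_per_species
  if (!length(ind) %in% c(1, 2) || any(ind < 1)) {
    stop("individuals_per_species must be a positive scalar or range")
  }
  bw <- base_weights[c("A", "C", "G", "T")]
  if (anyNA(bw) || any(bw < 0) || abs(sum(bw) - 1) > 1e-6) {
    stop("base_weights must be named A/C/G/T proportions summing to 1")
  }
  structure(list(
    n_species = as.integer(n_species),
    individuals_per_species = as.integer(ind),
    seq_length = as.integer(seq_length),
    interspecific_range = as.numeric(interspecific_range),
    intraspecific_depth = as.numeric(intraspecific_depth),
    kappa = as.numeric(kappa),
    base_weights = bw / sum(bw),
    n_groups = as.integer(min(n_groups, n_species)),
    cryptic_fraction = as.numeric(cryptic_fraction),
    cryptic_depth = as.numeric(cryptic_depth),
    seed = as.integer(seed)
  ), class = "sim_config")
}

species_label <- function(i) sprintf("sp%03d", i)

#' Simulate an ultrametric species tree
#'
#' Draws a random binary species tree by successive random joins at node
#' heights sampled uniformly so that every between-species path depth
#' falls inside `cfg$interspecific_range` (a pair's depth is twice its
#' most-recent-common-ancestor height). Reproducible from the tree
#' substream of `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return ground-truth skeleton: list with `species_tree` (ultrametric
#'   `phylo`), `species` labels, and the `cfg`.
#' @export
simulate_species_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_species
  lohi <- cfg$interspecific_range / 2
  with_seed(sub_seed(cfg$seed, "tree"), {
    heights <- sort(stats::runif(n - 1, lohi[1], lohi[2]))
    nodes <- lapply(seq_len(n), function(i) {
      list(nwk = species_label(i), h = 0)
    })
    for (k in seq_len(n - 1)) {
      pick <- sample(length(nodes), 2)
      a <- nodes[[pick[1]]]
      b <- nodes[[pick[2]]]
      h <- heights[k]
      joined <- list(
        nwk = sprintf("(%s:%.10f,%s:%.10f)", a$nwk, h - a$h, b$nwk, h - b$h),
        h = h)
      nodes <- c(nodes[-pick], list(joined))
    }
    nwk <- paste0(nodes[[1]]$nwk, ";")
    tree <- ape::read.tree(text = nwk)
    list(species_tree = tree, species = species_label(seq_len(n)), cfg = cfg)
  })
}

#' Attach individuals to a species tree
#'
#' Expands each species tip into a shallow within-species subtree:
#' ordinary species get a star of individuals whose pairwise depths stay
#' below `cfg$intraspecific_depth`; planted cryptic species get two
#' subclades separated by `cfg$cryptic_depth`. Reproducible from the
#' individuals substream.
#'
#' @param gt skeleton from [simulate_species_tree()].
#' @return full ground truth: list with `full_tree` (`phylo` over
#'   specimens), `taxonomy` ([taxon_map]), `true_distances` (path-length
#'   matrix over specimens), `cryptic_species`, `species_tree`, `cfg`.
#' @export
attach_individuals <- function(gt) {
  cfg <- gt$cfg
  n <- cfg$n_species
  with_seed(sub_seed(cfg$seed, "individuals"), {
    m_range <- cfg$individuals_per_species
    m_per <- if (length(m_range) == 1 || m_range[1] == m_range[2]) {
      rep(m_range[1], n)
    } else {
      sample(seq(m_range[1], m_range[2]), n, replace = TRUE)
    }
    n_cryptic <- round(cfg$cryptic_fraction * n)
    elig <- which(m_per >= 2)
    cryptic <- sort(elig[sample.int(length(elig),
                                    min(n_cryptic, length(elig)))])
    nwk <- ape::write.tree(gt$species_tree)
    tax_rows <- list()
    star <- function(ids, lens) {
      paste0("(", paste(sprintf("%s:%.10f", ids, lens), collapse = ","), ")")
    }
    for (i in seq_len(n)) {
      sp <- species_label(i)
      m <- m_per[i]
      ids <- sprintf("%s_%02d", sp, seq_len(m))
      tax_rows[[i]] <- data.frame(specimen_id = ids, species = sp,
                                  group = NA_character_, ingroup = TRUE,
                                  stringsAsFactors = FALSE)
      u <- stats::runif(m, 0, cfg$intraspecific_depth / 2)
      if (m == 1) {
        rep_str <- ids  # leaf only; the species branch is kept as-is
      } else if (i %in% cryptic) {
        half <- ceiling(m / 2)
        g1 <- seq_len(half)
        g2 <- setdiff(seq_len(m), g1)
        stalk <- cfg$cryptic_depth / 2
        c1 <- if (length(g1) == 1) sprintf("%s:%.10f", ids[g1], stalk + u[g1])
              else sprintf("%s:%.10f", star(ids[g1], u[g1]), stalk)
        c2 <- if (length(g2) == 1) sprintf("%s:%.10f", ids[g2], stalk + u[g2])
              else sprintf("%s:%.10f", star(ids[g2], u[g2]), stalk)
        rep_str <- sprintf("(%s,%s)", c1, c2)
      } else {
        rep_str <- star(ids, u)
      }
      nwk <- sub(paste0(sp, ":"), paste0(rep_str, ":"), nwk, fixed = TRUE)
    }
    full_tree <- ape::read.tree(text = nwk)
    tax <- do.call(rbind, tax_rows)
    # higher groups = single-linkage clusters of the ultrametric species
    # tree, so each group is a clade
    sp_d <- ape::cophenetic.phylo(gt$species_tree)
    cl <- stats::cutree(stats::hclust(stats::as.dist(sp_d), method = "single"),
                        k = cfg$n_groups)
    grp <- sprintf("g%02d", cl[tax$species])
    tax$group <- grp
    tax <- taxon_map(tax)
    true_d <- ape::cophenetic.phylo(full_tree)
    list(full_tree = full_tree, taxonomy = tax, true_distances = true_d,
         cryptic_species = species_label(cryptic),
         species_tree = gt$species_tree, cfg = cfg)
  })
}

# K2P per-branch change probabilities for branch length t (expected
# substitutions/site) and rate ratio kappa = alpha/beta:
#   P(transition)        = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta) t}
#   P(each transversion) = 1/4 - 1/4 e^{-4 beta t}
# with alpha + 2 beta = 1 so that t is in substitutions/site.
k2p_branch_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1  # each of the two transversion targets
  c(ts = p_ts, tv = p_tv)
}

# evolve an integer-coded sequence (1=A 2=C 3=G 4=T) along one branch
mutate_branch <- function(seq_code, t, kappa) {
  if (t <= 0) return(seq_code)
  pr <- k2p_branch_probs(t, kappa)
  ts_map <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)      # first transversion target
  tv2 <- c(4L, 3L, 4L, 3L)      # second transversion target
  u <- stats::runif(length(seq_code))
  out <- seq_code
  sel <- u < pr["ts"]
  out[sel] <- ts_map[seq_code[sel]]
  sel <- u >= pr["ts"] & u < pr["ts"] + pr["tv"]
  out[sel] <- tv1[seq_code[sel]]
  sel <- u >= pr["ts"] + pr["tv"] & u < pr["ts"] + 2 * pr["tv"]
  out[sel] <- tv2[seq_code[sel]]
  out
}

#' Evolve sequences over the ground-truth tree
#'
#' Samples a root sequence from `cfg$base_weights` and evolves it along
#' every branch under the Kimura two-parameter process, using the exact
#' per-branch change probabilities (closed-form transition matrix, not
#' event simulation). Sites are independent; no indels. Reproducible from
#' the sequences substream.
#'
#' @param gt full ground truth from [attach_individuals()].
#' @return list with `alignment` ([coi_alignment]) and `taxonomy`
#'   ([taxon_map]).
#' @export
evolve_sequences <- function(gt) {
  cfg <- gt$cfg
  tree <- gt$full_tree
  n <- length(tree$tip.label)
  with_seed(sub_seed(cfg$seed, "sequences"), {
    root_code <- sample.int(4, cfg$seq_length, replace = TRUE,
                            prob = gt$cfg$base_weights)
    nn <- n + tree$Nnode
    seqs <- vector("list", nn)
    root <- n + 1L
    seqs[[root]] <- root_code
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (ei in seq_len(nrow(pre$edge))) {
      p <- pre$edge[ei, 1]
      child <- pre$edge[ei, 2]
      seqs[[child]] <- mutate_branch(seqs[[p]], pre$edge.length[ei], cfg$kappa)
    }
    bases <- c("A", "C", "G", "T")
    out <- vapply(seq_len(n), function(i) {
      paste(bases[seqs[[i]]], collapse = "")
    }, character(1))
    names(out) <- tree$tip.label
    # stable specimen order: taxonomy order
    out <- out[gt$taxonomy$specimen_id]
    list(alignment = coi_alignment(out), taxonomy = gt$taxonomy)
  })
}

#' One-call synthetic data set
#'
#' Runs [simulate_species_tree()], [attach_individuals()] and
#' [evolve_sequences()] and returns data plus full ground truth.
#'
#' @param cfg a [sim_config].
#' @return list: `alignment`, `taxonomy`, `truth` (list with
#'   `species_tree`, `full_tree`, `true_distances`, `cryptic_species`),
#'   `cfg`.
#' @export
simulate_coi_dataset <- function(cfg = sim_config()) {
  gt <- attach_individuals(simulate_species_tree(cfg))
  ev <- evolve_sequences(gt)
  list(alignment = ev$alignment, taxonomy = ev$taxonomy,
       truth = list(species_tree = gt$species_tree,
                    full_tree = gt$full_tree,
                    true_distances = gt$true_distances,
                    cryptic_species = gt$cryptic_species),
       cfg = cfg)
}
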