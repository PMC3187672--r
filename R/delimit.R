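# species-delimitation diagnostics on the NJ profile

# every side of every edge of the tree, as sorted tip-label vectors
all_sides <- function(tree) {
  tips <- sort(tree$tip.label)
  sides <- bipartitions(tree, include_trivial = TRUE)
  comp <- lapply(sides, function(s) setdiff(tips, s))
  c(sides, comp)
}

#' Per-species cohesion report
#'
#' A species is *cohesive* when its specimens form one side of some
#' bipartition of the unrooted tree (a single leaf counts by convention)
#' -- the tree-based formalization of "possessing a distinct barcode
#' cluster". Working on the unrooted split set avoids any rooting choice.
#' For non-cohesive species the report gives the foreign leaves
#' ("intruders") inside the smallest split side that still covers the
#' species, and the number of clades its specimens fall apart into.
#'
#' @param tree an unrooted `phylo` tree (leaves are specimen ids).
#' @param tax a [taxon_map] covering every leaf.
#' @return data frame: `species`, `n_individuals`, `cohesive`, `n_clades`,
#'   `intruders` (comma-separated ids, empty when cohesive).
#' @export
cohesion_report <- function(tree, tax) {
  tips <- tree$tip.label
  tt <- tax[match(tips, tax$specimen_id), ]
  if (anyNA(tt$specimen_id)) {
    stop("leaf without taxonomy entry: ",
         paste(tips[is.na(tt$specimen_id)], collapse = ", "))
  }
  sides <- all_sides(tree)
  side_keys <- vapply(sides, paste, character(1), collapse = "\r")
  species <- sort(unique(tt$species))
  rows <- lapply(species, function(sp) {
    mine <- sort(tips[tt$species == sp])
    cohesive <- length(mine) == 1 || length(mine) == length(tips) ||
      paste(mine, collapse = "\r") %in% side_keys
    clades <- conspecific_clades_impl(sides, mine, tips = sort(tips))
    intruders <- character(0)
    if (!cohesive) {
      covering <- sides[vapply(sides, function(s) all(mine %in% s), logical(1))]
      if (length(covering)) {
        best <- covering[[which.min(lengths(covering))]]
        intruders <- setdiff(best, mine)
      }
    }
    data.frame(species = sp, n_individuals = length(mine),
               cohesive = cohesive, n_clades = length(clades),
               intruders = paste(intruders, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# maximal tree sides that contain only `mine`; they partition `mine`
# (when `mine` is the whole leaf set the species is trivially one clade)
conspecific_clades_impl <- function(sides, mine, tips = NULL) {
  if (!is.null(tips) && length(mine) == length(tips)) return(list(mine))
  inside <- sides[vapply(sides, function(s) all(s %in% mine), logical(1))]
  inside <- unique(lapply(inside, sort))
  if (length(inside) == 0) return(lapply(mine, identity))
  keep <- vapply(seq_along(inside), function(i) {
    !any(vapply(seq_along(inside), function(j) {
      i != j && length(inside[[i]]) < length(inside[[j]]) &&
        all(inside[[i]] %in% inside[[j]])
    }, logical(1)))
  }, logical(1))
  out <- inside[keep]
  # drop duplicates of equal sets, order deterministically by first member
  out <- out[!duplicated(vapply(out, paste, character(1), collapse = "\r"))]
  out[order(vapply(out, `[`, character(1), 1))]
}

#' Maximal single-species clades
#'
#' Partitions the specimens of one species into the minimal number of
#' clades, each being a maximal bipartition side containing only that
#' species. A cohesive species yields one clade; a fully interleaved one
#' yields one clade per individual. Deterministic: clades are ordered by
#' their first specimen id.
#'
#' @param tree an unrooted `phylo` tree.
#' @param tax a [taxon_map].
#' @param species species label to analyze.
#' @return list of character vectors partitioning the species' specimens.
#' @export
conspecific_clades <- function(tree, tax, species) {
  tips <- tree$tip.label
  tt <- tax[match(tips, tax$specimen_id), ]
  if (anyNA(tt$specimen_id)) {
    stop("leaf without taxonomy entry: ",
         paste(tips[is.na(tt$specimen_id)], collapse = ", "))
  }
  mine <- sort(tips[tt$species == species])
  if (length(mine) == 0) stop("unknown species: ", species)
  if (length(mine) == 1) return(list(mine))
  conspecific_clades_impl(all_sides(tree), mine, tips = sort(tips))
}

#' Flag candidate splits, merges and misplaced taxa
#'
#' Distance-threshold diagnostics for taxonomic review:
#'
#' * `deep_intraspecific`: species whose maximum conspecific divergence
#'   reaches `split_threshold` -- cryptic-species candidates;
#' * `low_interspecific`: same-group species pairs whose mean cross-species
#'   divergence is at most `merge_threshold` -- synonymy/subspecies
#'   candidates;
#' * `misplaced` (only when a tree is supplied): species that are cohesive
#'   but whose nearest split neighbors all belong to a different declared
#'   group.
#'
#' Flags are advisory output for a taxonomist; nothing is renamed.
#'
#' @param dm K2P distance matrix (proportions).
#' @param tax a [taxon_map].
#' @param split_threshold deep-divergence threshold as a proportion
#'   (default 0.02, i.e. 2%).
#' @param merge_threshold low-divergence threshold as a proportion
#'   (default 0.015); must be below `split_threshold`.
#' @param tree optional unrooted `phylo` tree enabling the misplaced-taxon
#'   check.
#' @return list of data frames `deep_intraspecific` (`species`,
#'   `max_intra`), `low_interspecific` (`species_a`, `species_b`, `group`,
#'   `mean_d`), `misplaced` (`species`, `own_group`, `neighbor_groups`);
#'   percent columns.
#' @export
flag_candidates <- function(dm, tax, split_threshold = 0.02,
                            merge_threshold = 0.015, tree = NULL) {
  if (split_threshold <= 0 || merge_threshold <= 0) {
    stop("thresholds must be positive")
  }
  if (split_threshold <= merge_threshold) {
    stop("split_threshold must exceed merge_threshold")
  }
  pr <- divergence_pairs(dm, tax, ingroup_only = TRUE)

  intra <- pr[pr$class == "intraspecific" & !is.na(pr$d), ]
  deep <- do.call(rbind, lapply(sort(unique(intra$species_a)), function(sp) {
    mx <- max(intra$d[intra$species_a == sp])
    if (mx >= split_threshold) {
      data.frame(species = sp, max_intra = mx * 100, stringsAsFactors = FALSE)
    }
  }))
  if (is.null(deep)) {
    deep <- data.frame(species = character(0), max_intra = numeric(0),
                       stringsAsFactors = FALSE)
  }

  inter <- pr[pr$class == "interspecific" & !is.na(pr$d), ]
  low <- NULL
  if (nrow(inter)) {
    key <- paste(pmin(inter$species_a, inter$species_b),
                 pmax(inter$species_a, inter$species_b), sep = "\r")
    agg <- tapply(inter$d, key, mean)
    grp <- tapply(inter$group_a, key, `[`, 1)
    flagged <- names(agg)[agg <= merge_threshold]
    if (length(flagged)) {
      parts <- strsplit(flagged, "\r", fixed = TRUE)
      low <- data.frame(
        species_a = vapply(parts, `[`, character(1), 1),
        species_b = vapply(parts, `[`, character(1), 2),
        group = unname(grp[flagged]),
        mean_d = unname(agg[flagged]) * 100,
        stringsAsFactors = FALSE)
      low <- low[order(low$species_a, low$species_b), ]
      rownames(low) <- NULL
    }
  }
  if (is.null(low)) {
    low <- data.frame(species_a = character(0), species_b = character(0),
                      group = character(0), mean_d = numeric(0),
                      stringsAsFactors = FALSE)
  }

  misplaced <- data.frame(species = character(0), own_group = character(0),
                          neighbor_groups = character(0),
                          stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    misplaced <- misplaced_taxa(tree, tax)
  }
  list(deep_intraspecific = deep, low_interspecific = low,
       misplaced = misplaced)
}

# cohesive species whose nearest non-conspecific split neighbors all lie
# in a different group
misplaced_taxa <- function(tree, tax) {
  tips <- tree$tip.label
  tt <- tax[match(tips, tax$specimen_id), ]
  if (anyNA(tt$specimen_id)) {
    stop("leaf without taxonomy entry: ",
         paste(tips[is.na(tt$specimen_id)], collapse = ", "))
  }
  sides <- all_sides(tree)
  side_keys <- vapply(sides, paste, character(1), collapse = "\r")
  group_of_tip <- stats::setNames(tt$group, tt$specimen_id)
  out <- list()
  for (sp in sort(unique(tt$species[tt$ingroup]))) {
    mine <- sort(tips[tt$species == sp])
    own_group <- tt$group[tt$species == sp][1]
    cohesive <- length(mine) == 1 ||
      paste(mine, collapse = "\r") %in% side_keys
    if (!cohesive) next
    supers <- sides[vapply(sides, function(s) {
      all(mine %in% s) && length(s) > length(mine)
    }, logical(1))]
    if (length(supers) == 0) next
    # nearest neighbors: union over all minimal covering splits (ties are
    # possible around the serialization root)
    msz <- min(lengths(supers))
    neigh <- setdiff(unique(unlist(supers[lengths(supers) == msz])), mine)
    ngroups <- unique(group_of_tip[neigh])
    if (length(neigh) > 0 && !any(ngroups == own_group)) {
      out[[length(out) + 1]] <- data.frame(
        species = sp, own_group = own_group,
        neighbor_groups = paste(sort(ngroups), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(species = character(0), own_group = character(0),
               neighbor_groups = character(0), stringsAsFactors = FALSE)
}
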