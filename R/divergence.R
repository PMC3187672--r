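#' Label every specimen pair of a distance matrix
#'
#' Enumerates the unordered specimen pairs of `dm` restricted to specimens
#' present in the taxonomy (optionally ingroup only) and classifies each
#' as `"intraspecific"` (same species), `"interspecific"` (different
#' species, same group) or `"cross-group"`. This partition underlies the
#' divergence tables and the barcode-gap histogram; the three classes are
#' exhaustive and disjoint, so their counts sum to `m(m-1)/2`.
#'
#' @param dm K2P distance matrix (proportions) from [k2p_distances()].
#' @param tax a [taxon_map].
#' @param ingroup_only restrict to ingroup specimens (default `TRUE`).
#' @return data frame with columns `id_a`, `id_b`, `species_a`,
#'   `species_b`, `group_a`, `group_b`, `class`, `d` (proportion; `NA` for
#'   undefined pairs).
#' @export
divergence_pairs <- function(dm, tax, ingroup_only = TRUE) {
  ids <- rownames(dm)
  tt <- tax[match(ids, tax$specimen_id), ]
  if (anyNA(tt$specimen_id)) {
    stop("specimens missing from taxonomy: ",
         paste(ids[is.na(tt$specimen_id)], collapse = ", "))
  }
  keep <- if (ingroup_only) which(tt$ingroup) else seq_along(ids)
  m <- length(keep)
  if (m < 2) stop("fewer than 2 specimens selected")
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  ia <- keep[idx[, 1]]
  ib <- keep[idx[, 2]]
  sa <- tt$species[ia]; sb <- tt$species[ib]
  ga <- tt$group[ia]; gb <- tt$group[ib]
  cls <- ifelse(sa == sb, "intraspecific",
                ifelse(ga == gb, "interspecific", "cross-group"))
  data.frame(id_a = ids[ia], id_b = ids[ib],
             species_a = sa, species_b = sb,
             group_a = ga, group_b = gb,
             class = cls, d = dm[cbind(ia, ib)],
             stringsAsFactors = FALSE)
}

# summary row over a vector of divergences (proportions); percent output
summarize_pairs <- function(d) {
  d <- d[!is.na(d)]
  npr <- length(d)
  if (npr == 0) {
    return(list(n_pairs = 0L, mean = NA_real_, min = NA_real_,
                max = NA_real_, sd = NA_real_))
  }
  list(n_pairs = npr,
       mean = mean(d) * 100,
       min = min(d) * 100,
       max = max(d) * 100,
       sd = if (npr >= 2) stats::sd(d) * 100 else NA_real_)
}

#' Intraspecific divergence table
#'
#' One row per species with two or more sampled individuals: number of
#' individuals, number of conspecific pairs, and mean / range / sample SD
#' of their pairwise K2P divergences, in percent. A pooled `All` row
#' aggregates every conspecific pair across species. SD is the sample
#' standard deviation over pairwise divergences and is undefined (`NA`,
#' printed `/`) for a single pair. Species with fewer than two individuals
#' are omitted and listed in the `"skipped"` attribute; saturated pairs
#' are excluded and counted in `"n_excluded"`.
#'
#' @param dm K2P distance matrix (proportions).
#' @param tax a [taxon_map].
#' @param ingroup_only restrict to ingroup specimens.
#' @return data frame of class rows (`taxon`, `n_individuals`, `n_pairs`,
#'   `mean`, `range_min`, `range_max`, `sd`; percent units) with
#'   attributes `skipped` and `n_excluded`.
#' @export
intraspecific_summary <- function(dm, tax, ingroup_only = TRUE) {
  pr <- divergence_pairs(dm, tax, ingroup_only = ingroup_only)
  ids <- rownames(dm)
  tt <- tax[match(ids, tax$specimen_id), ]
  if (ingroup_only) tt <- tt[tt$ingroup, ]
  n_by_species <- table(tt$species)
  eligible <- names(n_by_species)[n_by_species >= 2]
  skipped <- names(n_by_species)[n_by_species < 2]
  if (length(eligible) == 0) stop("no species with >= 2 individuals")
  intra <- pr[pr$class == "intraspecific", ]
  rows <- lapply(sort(eligible), function(sp) {
    d <- intra$d[intra$species_a == sp]
    s <- summarize_pairs(d)
    data.frame(taxon = sp,
               n_individuals = as.integer(n_by_species[[sp]]),
               n_pairs = s$n_pairs, mean = s$mean,
               range_min = s$min, range_max = s$max, sd = s$sd,
               stringsAsFactors = FALSE)
  })
  pooled <- summarize_pairs(intra$d[intra$species_a %in% eligible])
  rows[[length(rows) + 1]] <- data.frame(
    taxon = "All",
    n_individuals = sum(n_by_species[eligible]),
    n_pairs = pooled$n_pairs, mean = pooled$mean,
    range_min = pooled$min, range_max = pooled$max, sd = pooled$sd,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  attr(out, "n_excluded") <- sum(is.na(intra$d))
  out
}

#' Interspecific divergence table
#'
#' One row per group (genus, subgenus or "group of species") with two or
#' more species, plus an `All` row across every ingroup species. In
#' `"representative"` mode one individual per species is chosen by a
#' seeded random draw and between-species divergences are measured on the
#' representatives -- the classic protocol when species are unevenly
#' sampled. In `"all-pairs"` mode every cross-species individual pair
#' contributes. Units are percent; SD as in [intraspecific_summary()].
#'
#' @param dm K2P distance matrix (proportions).
#' @param tax a [taxon_map].
#' @param mode `"representative"` (default) or `"all-pairs"`.
#' @param seed integer seed for the representative draw (recorded in the
#'   `"seed"` attribute); ignored in all-pairs mode.
#' @return data frame (`taxon`, `n_species`, `n_individuals`, `n_pairs`,
#'   `mean`, `range_min`, `range_max`, `sd`) with attributes `mode`,
#'   `seed`, `skipped` (groups with one species) and `representatives`.
#' @export
interspecific_summary <- function(dm, tax,
                                  mode = c("representative", "all-pairs"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  ids <- rownames(dm)
  tt <- tax[match(ids, tax$specimen_id), ]
  if (anyNA(tt$specimen_id)) {
    stop("specimens missing from taxonomy: ",
         paste(ids[is.na(tt$specimen_id)], collapse = ", "))
  }
  tt <- tt[tt$ingroup, ]
  if (nrow(tt) < 2) stop("fewer than 2 ingroup specimens")
  species <- sort(unique(tt$species))
  group_of <- vapply(species, function(sp) tt$group[tt$species == sp][1],
                     character(1))
  reps <- NULL
  if (mode == "representative") {
    reps <- with_seed(seed, {
      vapply(species, function(sp) {
        cand <- sort(tt$specimen_id[tt$species == sp])
        if (length(cand) == 1) cand else sample(cand, 1)
      }, character(1))
    })
  }
  species_pair_d <- function(spa, spb) {
    if (mode == "representative") {
      dm[reps[[spa]], reps[[spb]]]
    } else {
      a <- tt$specimen_id[tt$species == spa]
      b <- tt$specimen_id[tt$species == spb]
      dm[a, b, drop = FALSE]
    }
  }
  collect <- function(spp) {
    if (length(spp) < 2) return(numeric(0))
    cmb <- utils::combn(spp, 2)
    unlist(lapply(seq_len(ncol(cmb)), function(k) {
      as.numeric(species_pair_d(cmb[1, k], cmb[2, k]))
    }))
  }
  groups <- sort(unique(group_of))
  n_sp <- table(group_of)
  eligible <- groups[n_sp[groups] >= 2]
  skipped <- groups[n_sp[groups] < 2]
  if (length(eligible) == 0 && length(species) < 2) {
    stop("no group with >= 2 species")
  }
  rows <- lapply(eligible, function(g) {
    spp <- species[group_of == g]
    s <- summarize_pairs(collect(spp))
    data.frame(taxon = g, n_species = length(spp),
               n_individuals = sum(tt$group == g),
               n_pairs = s$n_pairs, mean = s$mean,
               range_min = s$min, range_max = s$max, sd = s$sd,
               stringsAsFactors = FALSE)
  })
  s_all <- summarize_pairs(collect(species))
  rows[[length(rows) + 1]] <- data.frame(
    taxon = "All", n_species = length(species), n_individuals = nrow(tt),
    n_pairs = s_all$n_pairs, mean = s_all$mean,
    range_min = s_all$min, range_max = s_all$max, sd = s_all$sd,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  attr(out, "seed") <- if (mode == "representative") as.integer(seed) else NA_integer_
  attr(out, "skipped") <- skipped
  attr(out, "representatives") <- reps
  out
}

#' Pooled pairwise divergence statistics
#'
#' Mean, minimum and maximum K2P divergence over all unordered pairs of a
#' specimen set, the "grand" summary usually quoted alongside the
#' per-taxon tables. `n_pairs` is the combinatorial `m(m-1)/2`; undefined
#' (saturated) pairs are excluded from the statistics and counted in
#' `n_excluded`.
#'
#' @param dm K2P distance matrix (proportions).
#' @param include character vector of specimen ids to pool (default: all
#'   ids in `dm`).
#' @return one-row data frame: `n_specimens`, `n_pairs`, `n_excluded`,
#'   `mean`, `min`, `max` (percent).
#' @export
pooled_pair_stats <- function(dm, include = NULL) {
  ids <- rownames(dm)
  if (is.null(include)) include <- ids
  miss <- setdiff(include, ids)
  if (length(miss)) stop("ids not in matrix: ", paste(miss, collapse = ", "))
  m <- length(include)
  if (m < 2) stop("need at least 2 specimens")
  sub <- dm[include, include]
  d <- sub[upper.tri(sub)]
  s <- summarize_pairs(d)
  data.frame(n_specimens = m,
             n_pairs = m * (m - 1) / 2,
             n_excluded = sum(is.na(d)),
             mean = s$mean, min = s$min, max = s$max,
             stringsAsFactors = FALSE)
}

#' Barcode-gap histogram
#'
#' Bins intraspecific and interspecific divergences into shared half-open
#' bins `[lo, lo + w)` starting at zero, on the percent scale. A positive
#' barcode gap shows as the two series occupying disjoint bins.
#'
#' @param intra,inter numeric vectors of divergences as proportions
#'   (`NA`s dropped).
#' @param bin_width bin width in percent (default 0.5).
#' @return data frame: `bin_lo`, `bin_hi` (percent), `intra_count`,
#'   `inter_count`.
#' @export
divergence_histogram <- function(intra, inter, bin_width = 0.5) {
  if (bin_width <= 0) stop("bin_width must be positive")
  intra <- intra[!is.na(intra)] * 100
  inter <- inter[!is.na(inter)] * 100
  if (any(c(intra, inter) < 0)) stop("negative divergence")
  top <- max(c(intra, inter, 0))
  nb <- max(1L, as.integer(floor(top / bin_width)) + 1L)
  lo <- (seq_len(nb) - 1) * bin_width
  bin_of <- function(x) pmin(as.integer(floor(x / bin_width)) + 1L, nb)
  data.frame(bin_lo = lo, bin_hi = lo + bin_width,
             intra_count = tabulate(bin_of(intra), nbins = nb),
             inter_count = tabulate(bin_of(inter), nbins = nb))
}
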