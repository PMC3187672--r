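#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end profile run. Exactly one input
#' source must be given: an alignment + taxonomy file pair, or a
#' [sim_config]. The analysis window uses 0-based half-open coordinates
#' (`NULL` keeps the full alignment).
#'
#' @param alignment,taxonomy input file paths (FASTA / delimited table).
#' @param sim a [sim_config] to generate the input instead.
#' @param window `NULL` or `c(start, end)`, 0-based half-open.
#' @param deletion `"pairwise"` or `"complete"` (see [k2p_distances()]).
#' @param table2_mode `"representative"` or `"all-pairs"` (see
#'   [interspecific_summary()]).
#' @param table2_seed seed for the representative draw.
#' @param bin_width histogram bin width in percent.
#' @param split_threshold,merge_threshold delimitation thresholds as
#'   proportions (see [flag_candidates()]).
#' @param out_dir output directory (created if missing).
#' @return list of class `run_config`.
#' @export
run_config <- function(alignment = NULL, taxonomy = NULL, sim = NULL,
                       window = NULL,
                       deletion = c("pairwise", "complete"),
                       table2_mode = c("representative", "all-pairs"),
                       table2_seed = 1L, bin_width = 0.5,
                       split_threshold = 0.02, merge_threshold = 0.015,
                       out_dir = "coiprofile_out") {
  deletion <- match.arg(deletion)
  table2_mode <- match.arg(table2_mode)
  from_files <- !is.null(alignment) || !is.null(taxonomy)
  from_sim <- !is.null(sim)
  if (from_files == from_sim) {
    stop("give exactly one input source: alignment+taxonomy files, or sim")
  }
  if (from_files && (is.null(alignment) || is.null(taxonomy))) {
    stop("both alignment and taxonomy paths are required")
  }
  if (from_sim && !inherits(sim, "sim_config")) {
    stop("`sim` must be a sim_config")
  }
  if (!is.null(window) &&
      (length(window) != 2 || window[1] < 0 || window[2] <= window[1])) {
    stop("window must be c(start, end), 0-based half-open")
  }
  structure(list(alignment = alignment, taxonomy = taxonomy, sim = sim,
                 window = window, deletion = deletion,
                 table2_mode = table2_mode,
                 table2_seed = as.integer(table2_seed),
                 bin_width = bin_width,
                 split_threshold = split_threshold,
                 merge_threshold = merge_threshold,
                 out_dir = out_dir),
            class = "run_config")
}

write_summary_table <- function(df, path) {
  out <- df
  for (cn in intersect(c("mean", "range_min", "range_max", "sd"), colnames(out))) {
    out[[cn]] <- fmt_pct(out[[cn]])
  }
  write_tsv_atomic(out, path)
}

#' Run the full barcode profile pipeline
#'
#' Executes the complete analysis chain -- input (or simulation), optional
#' window trim, K2P distance matrix, NJ profile, intraspecific and
#' interspecific divergence tables, pooled statistics, barcode-gap
#' histogram, site statistics, cohesion report and delimitation flags --
#' and writes each product as a TSV (plus Newick tree and run log) into
#' `cfg$out_dir`. All files are written atomically and contain no
#' timestamps, so a rerun with the same configuration reproduces the
#' bundle byte for byte. Tables are percent-scaled views; the distance
#' matrix on disk keeps full-precision proportions.
#'
#' @param cfg a [run_config].
#' @return invisibly, a list with the in-memory objects (`alignment`,
#'   `taxonomy`, `dm`, `tree`, `table1`, `table2`, `summary`, `histogram`,
#'   `sitestats`, `cohesion`, `flags`) and `files` (named paths).
#' @export
run_profile <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(cfg$out_dir, name)
  files <- character(0)
  log_lines <- c("coiprofile run log",
                 paste0("package_version\t",
                        as.character(utils::packageVersion("coiprofile"))))

  if (!is.null(cfg$sim)) {
    ds <- simulate_coi_dataset(cfg$sim)
    aln <- ds$alignment
    tax <- ds$taxonomy
    write_fasta(aln, fp("alignment.fasta"))
    write_taxonomy(tax, fp("taxonomy.tsv"))
    write_atomic(ape::write.tree(ds$truth$full_tree), fp("true_tree.nwk"))
    truth_meta <- list(seed = cfg$sim$seed,
                       n_species = cfg$sim$n_species,
                       cryptic_species = ds$truth$cryptic_species)
    write_atomic(jsonlite::toJSON(truth_meta, auto_unbox = TRUE, pretty = TRUE),
                 fp("ground_truth.json"))
    files <- c(files, alignment = fp("alignment.fasta"),
               taxonomy = fp("taxonomy.tsv"),
               true_tree = fp("true_tree.nwk"),
               ground_truth = fp("ground_truth.json"))
    log_lines <- c(log_lines, paste0("input\tsimulation seed=", cfg$sim$seed))
  } else {
    aln <- read_fasta(cfg$alignment)
    tax <- read_taxonomy(cfg$taxonomy)
    log_lines <- c(log_lines,
                   paste0("input\t", cfg$alignment, " + ", cfg$taxonomy))
  }

  if (!is.null(cfg$window)) {
    aln <- trim_window(aln, cfg$window[1], cfg$window[2])
    log_lines <- c(log_lines, paste0("window\t[", cfg$window[1], ",",
                                     cfg$window[2], ")"))
  }

  miss <- setdiff(aln_ids(aln), tax$specimen_id)
  if (length(miss)) {
    stop("specimens without taxonomy entry: ", paste(miss, collapse = ", "))
  }

  dm <- withCallingHandlers(
    k2p_distances(aln, deletion = cfg$deletion),
    warning = function(w) invokeRestart("muffleWarning"))
  undef <- attr(dm, "undefined")
  log_lines <- c(log_lines,
                 paste0("deletion\t", cfg$deletion),
                 paste0("undefined_pairs\t", nrow(undef)))
  write_distmat(dm, fp("matrix.tsv"))
  files <- c(files, matrix = fp("matrix.tsv"))

  if (nrow(undef) > 0) {
    stop("cannot build NJ profile: ", nrow(undef),
         " undefined (saturated) pair(s); inspect matrix.tsv")
  }
  tree <- neighbor_joining(dm)
  write_atomic(to_newick(tree), fp("tree.nwk"))
  files <- c(files, tree = fp("tree.nwk"))
  log_lines <- c(log_lines,
                 paste0("nj_clamped_branches\t", length(attr(tree, "clamped"))))

  table1 <- intraspecific_summary(dm, tax)
  write_summary_table(table1, fp("table1.tsv"))
  table2 <- interspecific_summary(dm, tax, mode = cfg$table2_mode,
                                  seed = cfg$table2_seed)
  write_summary_table(table2, fp("table2.tsv"))
  log_lines <- c(log_lines,
                 paste0("table2_mode\t", cfg$table2_mode),
                 paste0("table2_seed\t", cfg$table2_seed))

  ing <- tax$specimen_id[tax$ingroup & tax$specimen_id %in% rownames(dm)]
  summ <- rbind(cbind(scope = "all", pooled_pair_stats(dm)),
                cbind(scope = "ingroup", pooled_pair_stats(dm, include = ing)))
  summ$mean <- fmt_pct(summ$mean)
  summ$min <- fmt_pct(summ$min)
  summ$max <- fmt_pct(summ$max)
  write_tsv_atomic(summ, fp("summary.tsv"))

  pr <- divergence_pairs(dm, tax, ingroup_only = TRUE)
  hist_df <- divergence_histogram(pr$d[pr$class == "intraspecific"],
                                  pr$d[pr$class == "interspecific"],
                                  bin_width = cfg$bin_width)
  write_tsv_atomic(hist_df, fp("histogram.tsv"))

  ss_all <- classify_sites(aln)
  ss_ing <- classify_sites(aln, scope = ing)
  comp <- composition_means(aln)
  ss <- data.frame(scope = c("all", "ingroup"),
                   analyzed = c(ss_all$analyzed, ss_ing$analyzed),
                   constant = c(ss_all$constant, ss_ing$constant),
                   variable = c(ss_all$variable, ss_ing$variable),
                   parsimony_informative = c(ss_all$parsimony_informative,
                                             ss_ing$parsimony_informative),
                   singleton = c(ss_all$singleton, ss_ing$singleton),
                   excluded = c(ss_all$excluded, ss_ing$excluded))
  ss$mean_A <- fmt_pct(comp[["A"]] * 100)
  ss$mean_C <- fmt_pct(comp[["C"]] * 100)
  ss$mean_G <- fmt_pct(comp[["G"]] * 100)
  ss$mean_T <- fmt_pct(comp[["T"]] * 100)
  write_tsv_atomic(ss, fp("sitestats.tsv"))

  coh <- cohesion_report(tree, tax)
  write_tsv_atomic(coh, fp("delimit.tsv"))
  flags <- flag_candidates(dm, tax, split_threshold = cfg$split_threshold,
                           merge_threshold = cfg$merge_threshold, tree = tree)
  flag_rows <- rbind(
    if (nrow(flags$deep_intraspecific)) data.frame(
      flag = "deep_intraspecific",
      taxon_a = flags$deep_intraspecific$species, taxon_b = "",
      statistic = fmt_pct(flags$deep_intraspecific$max_intra),
      stringsAsFactors = FALSE),
    if (nrow(flags$low_interspecific)) data.frame(
      flag = "low_interspecific",
      taxon_a = flags$low_interspecific$species_a,
      taxon_b = flags$low_interspecific$species_b,
      statistic = fmt_pct(flags$low_interspecific$mean_d),
      stringsAsFactors = FALSE),
    if (nrow(flags$misplaced)) data.frame(
      flag = "misplaced",
      taxon_a = flags$misplaced$species,
      taxon_b = flags$misplaced$neighbor_groups,
      statistic = "",
      stringsAsFactors = FALSE))
  if (is.null(flag_rows)) {
    flag_rows <- data.frame(flag = character(0), taxon_a = character(0),
                            taxon_b = character(0), statistic = character(0),
                            stringsAsFactors = FALSE)
  }
  write_tsv_atomic(flag_rows, fp("flags.tsv"))
  log_lines <- c(log_lines,
                 paste0("split_threshold\t", cfg$split_threshold),
                 paste0("merge_threshold\t", cfg$merge_threshold))
  write_atomic(log_lines, fp("run.log"))
  files <- c(files, table1 = fp("table1.tsv"), table2 = fp("table2.tsv"),
             summary = fp("summary.tsv"), histogram = fp("histogram.tsv"),
             sitestats = fp("sitestats.tsv"), delimit = fp("delimit.tsv"),
             flags = fp("flags.tsv"), log = fp("run.log"))

  invisible(list(alignment = aln, taxonomy = tax, dm = dm, tree = tree,
                 table1 = table1, table2 = table2, summary = summ,
                 histogram = hist_df, sitestats = ss, cohesion = coh,
                 flags = flags, files = files))
}
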