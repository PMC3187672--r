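#' Aligned sequence sets
#'
#' A `coi_alignment` holds equal-length nucleotide sequences keyed by a
#' unique specimen id. Sequences are normalized to upper case on
#' construction; the admitted alphabet is `A C G T N`, the IUPAC ambiguity
#' codes and the gap character `-`. Internally the alignment is stored as a
#' sites-by-specimens character matrix, which every downstream module
#' (distances, site statistics, simulation) operates on column-wise.
#'
#' @param seqs named character vector of sequence strings, one per
#'   specimen; names are the specimen ids.
#' @return an object of class `coi_alignment`.
#' @examples
#' aln <- coi_alignment(c(a = "ACGT", b = "ACGA"))
#' n_sequences(aln)
#' aln_length(aln)
#' @export
coi_alignment <- function(seqs) {
  if (!is.character(seqs) || length(seqs) == 0) {
    stop("`seqs` must be a non-empty character vector")
  }
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop("every sequence needs a nonempty specimen id")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate id: ", paste(dup, collapse = ", "))
  }
  if (length(seqs) < 2) {
    stop("an alignment needs at least 2 sequences")
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (any(lens == 0)) {
    stop("empty sequence for id: ", paste(ids[lens == 0], collapse = ", "))
  }
  ref <- lens[1]
  if (any(lens != ref)) {
    tab <- table(lens)
    cand <- as.integer(names(tab)[tab == max(tab)])
    modal <- if (ref %in% cand) ref else cand[1]
    bad <- ids[lens != modal]
    stop("unequal lengths: sequences are not aligned (offending ids: ",
         paste(bad, collapse = ", "), ")")
  }
  mat <- vapply(strsplit(seqs, "", fixed = TRUE), identity, character(ref))
  if (ref == 1) mat <- matrix(mat, nrow = 1)
  colnames(mat) <- ids
  bad <- which(!(mat %in% ALN_ALPHABET))
  if (length(bad)) {
    site <- (bad[1] - 1) %% ref + 1
    spec <- (bad[1] - 1) %/% ref + 1
    stop("illegal character '", mat[bad[1]], "' in sequence '", ids[spec],
         "' at position ", site)
  }
  structure(list(mat = mat), class = "coi_alignment")
}

#' @rdname coi_alignment
#' @param x,aln a `coi_alignment`.
#' @export
n_sequences <- function(aln) ncol(aln$mat)

#' @rdname coi_alignment
#' @export
aln_length <- function(aln) nrow(aln$mat)

#' @rdname coi_alignment
#' @export
aln_ids <- function(aln) colnames(aln$mat)

#' @rdname coi_alignment
#' @param ... unused.
#' @export
as.character.coi_alignment <- function(x, ...) {
  stats::setNames(apply(x$mat, 2, paste, collapse = ""), colnames(x$mat))
}

#' @rdname coi_alignment
#' @export
print.coi_alignment <- function(x, ...) {
  cat("coi_alignment:", ncol(x$mat), "sequences x", nrow(x$mat), "sites\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Parses an aligned FASTA file (gap character `-`) into a
#' [coi_alignment]. The specimen id is the first whitespace-delimited token
#' of each header; file order is preserved and sequences are upper-cased.
#' Unequal lengths, duplicate ids and characters outside the nucleotide /
#' IUPAC / gap alphabet are errors.
#'
#' @param path path to a FASTA file.
#' @return a [coi_alignment].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("no FASTA records in ", path)
  seqs <- as.character(x)
  ids <- vapply(strsplit(names(x), "[ \t]+"), `[`, character(1), 1)
  names(seqs) <- ids
  coi_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln a [coi_alignment].
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70) {
  seqs <- as.character(aln)
  lines <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  write_atomic(lines, path)
}

#' Specimen taxonomy tables
#'
#' A `taxon_map` links each specimen id to its species, its higher group
#' (genus, subgenus or "group of species" label) and an ingroup flag. All
#' divergence partitioning and delimitation diagnostics are driven by this
#' table.
#'
#' @param df data frame with columns `specimen_id`, `species`, `group`,
#'   `ingroup`.
#' @return a validated data frame of class `taxon_map`.
#' @export
taxon_map <- function(df) {
  need <- c("specimen_id", "species", "group", "ingroup")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  blank <- function(x) is.na(x) | !nzchar(x)
  df$specimen_id <- trimws(as.character(df$specimen_id))
  df$species <- trimws(as.character(df$species))
  df$group <- trimws(as.character(df$group))
  if (any(blank(df$specimen_id))) stop("blank specimen_id")
  dup <- unique(df$specimen_id[duplicated(df$specimen_id)])
  if (length(dup)) stop("duplicate specimen_id: ", paste(dup, collapse = ", "))
  if (any(blank(df$species))) {
    stop("blank species for specimen(s): ",
         paste(df$specimen_id[blank(df$species)], collapse = ", "))
  }
  if (any(blank(df$group))) {
    stop("blank group for specimen(s): ",
         paste(df$specimen_id[blank(df$group)], collapse = ", "))
  }
  if (!is.logical(df$ingroup)) {
    v <- tolower(trimws(as.character(df$ingroup)))
    parsed <- rep(NA, length(v))
    parsed[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
    parsed[v %in% c("false", "f", "0", "no", "n")] <- FALSE
    if (any(is.na(parsed))) {
      stop("unparseable ingroup value(s): ",
           paste(unique(v[is.na(parsed)]), collapse = ", "))
    }
    df$ingroup <- parsed
  }
  rownames(df) <- NULL
  class(df) <- c("taxon_map", "data.frame")
  df
}

#' Read a taxonomy table
#'
#' Reads a delimited text file (TSV or CSV, autodetected from the header
#' line) with columns `specimen_id`, `species`, `group`, `ingroup`.
#'
#' @param path path to the table.
#' @param sep field separator; `NULL` autodetects tab vs comma.
#' @return a [taxon_map].
#' @export
read_taxonomy <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          strip.white = TRUE, stringsAsFactors = FALSE,
                          comment.char = "")
  taxon_map(df)
}

#' Write a taxonomy table as TSV
#'
#' @param tax a [taxon_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  out <- as.data.frame(tax)
  out$ingroup <- ifelse(out$ingroup, "true", "false")
  write_tsv_atomic(out, path)
}

#' Trim an alignment to an analysis window
#'
#' Slices every sequence to the column window `[start, end)`. Coordinates
#' are 0-based and half-open, so `trim_window(aln, 0, aln_length(aln))` is
#' the identity. The analysis window (e.g. a 591-bp barcode fragment inside
#' a longer pruned alignment) is deliberately a parameter, not a constant.
#'
#' @param aln a [coi_alignment].
#' @param start first column to keep, 0-based.
#' @param end one past the last column to keep.
#' @return the trimmed [coi_alignment].
#' @export
trim_window <- function(aln, start, end) {
  L <- aln_length(aln)
  if (!is.numeric(start) || !is.numeric(end) ||
      start != floor(start) || end != floor(end)) {
    stop("window coordinates must be integers")
  }
  if (start < 0 || end > L || start >= end) {
    stop("invalid window [", start, ",", end, ") for alignment of length ", L)
  }
  out <- aln
  out$mat <- aln$mat[(start + 1):end, , drop = FALSE]
  out
}

#' Screen sequences for protein-coding integrity
#'
#' Translates each sequence in a chosen reading frame and reports whether
#' the translation is free of internal stop codons, the usual sanity check
#' that a mitochondrial protein-coding fragment was assembled and aligned
#' correctly. Codons containing a gap, `N` or ambiguity code are skipped
#' whole. A stop codon is *internal* unless it is the last translated
#' (non-skipped) codon of the sequence, so appending gap-only columns never
#' changes the verdict. With `frame = "auto"` the frame minimizing the
#' total internal-stop count across the whole set is chosen (ties go to the
#' lowest frame), since all sequences of one alignment share a frame.
#'
#' @param aln a [coi_alignment].
#' @param code NCBI genetic-code id; defaults to `"5"`, the invertebrate
#'   mitochondrial code appropriate for insect COI.
#' @param frame `0`, `1`, `2` (columns skipped before the first codon) or
#'   `"auto"`.
#' @return data frame with one row per sequence: `specimen_id`, `frame`,
#'   `n_codons` (complete codons in frame), `n_translated` (codons actually
#'   translated after skipping), `n_internal_stops`, `pass`.
#' @export
translation_screen <- function(aln, code = "5", frame = "auto") {
  gc_tab <- Biostrings::getGeneticCode(code)
  screen_frame <- function(f) {
    res <- lapply(seq_len(n_sequences(aln)), function(i) {
      chars <- aln$mat[, i]
      s <- if (f + 1 > length(chars)) character(0) else
        chars[seq.int(f + 1, length(chars))]
      ncod <- as.integer(length(s) %/% 3)
      if (ncod == 0) {
        return(list(n_codons = 0L, n_translated = 0L, stops = 0L))
      }
      cm <- matrix(s[seq_len(3 * ncod)], nrow = 3)
      clean <- colSums(matrix(cm %in% c("A", "C", "G", "T"), nrow = 3)) == 3
      codons <- apply(cm[, clean, drop = FALSE], 2, paste, collapse = "")
      aa <- if (length(codons)) unname(gc_tab[codons]) else character(0)
      stops <- which(aa == "*")
      # terminal stop (last translated codon) is tolerated
      internal <- sum(stops < length(aa))
      list(n_codons = ncod, n_translated = length(aa),
           stops = as.integer(internal))
    })
    res
  }
  frames <- if (identical(frame, "auto")) 0:2 else as.integer(frame)
  if (!all(frames %in% 0:2)) stop("frame must be 0, 1, 2 or \"auto\"")
  per_frame <- lapply(frames, screen_frame)
  totals <- vapply(per_frame, function(r) sum(vapply(r, `[[`, integer(1), "stops")),
                   integer(1))
  pick <- which.min(totals)  # ties -> lowest frame
  chosen <- per_frame[[pick]]
  data.frame(
    specimen_id = aln_ids(aln),
    frame = frames[pick],
    n_codons = vapply(chosen, `[[`, integer(1), "n_codons"),
    n_translated = vapply(chosen, `[[`, integer(1), "n_translated"),
    n_internal_stops = vapply(chosen, `[[`, integer(1), "stops"),
    pass = vapply(chosen, `[[`, integer(1), "stops") == 0L,
    stringsAsFactors = FALSE
  )
}
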