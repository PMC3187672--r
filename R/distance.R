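#' Transition/transversion counts for one sequence pair
#'
#' Classifies the differing sites of two aligned sequences into
#' transitions (A<->G, C<->T) and transversions (all other base
#' mismatches), the two observed proportions the Kimura two-parameter
#' distance is built from. Under `deletion = "pairwise"` any column where
#' either sequence carries a gap, `N` or ambiguity code is skipped for this
#' pair only; under `deletion = "complete-mask"` such columns are assumed
#' to have been removed set-wide beforehand and their presence is an error.
#'
#' @param seq_a,seq_b aligned sequences of equal length, as strings or
#'   character vectors of single characters.
#' @param deletion `"pairwise"` (default) or `"complete-mask"`.
#' @return list with `n` (compared sites), `P` (transition proportion) and
#'   `Q` (transversion proportion).
#' @examples
#' pair_counts("ACGT", "GCGT")  # n=4, P=0.25, Q=0
#' @export
pair_counts <- function(seq_a, seq_b, deletion = c("pairwise", "complete-mask")) {
  deletion <- match.arg(deletion)
  to_chars <- function(s) {
    if (length(s) == 1 && nchar(s) > 1) s <- strsplit(s, "", fixed = TRUE)[[1]]
    toupper(s)
  }
  a <- to_chars(seq_a)
  b <- to_chars(seq_b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ca <- encode_bases(a)
  cb <- encode_bases(b)
  valid <- !is.na(ca) & !is.na(cb)
  if (deletion == "complete-mask" && !all(valid)) {
    stop("gap/ambiguous characters present under complete-mask deletion; ",
         "mask columns set-wide first")
  }
  n <- sum(valid)
  if (n == 0) stop("no comparable sites")
  diff <- valid & ca != cb
  s <- ca + cb
  ts <- diff & (s == 4L | s == 6L)  # {A,G} codes 1+3; {C,T} codes 2+4
  list(n = n, P = sum(ts) / n, Q = sum(diff & !ts) / n)
}

#' Kimura two-parameter distance from observed proportions
#'
#' Evaluates `d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)`, the K2P
#' divergence for observed transition proportion `P` and transversion
#' proportion `Q`. Outside the model's domain (either log argument
#' non-positive, i.e. saturation) the result is `NA`, never silently
#' clamped; callers that need diagnostics keep their own `P`, `Q`.
#'
#' @param P,Q observed transition and transversion proportions
#'   (vectorized).
#' @return numeric vector of divergences as proportions; `NA` where
#'   saturated.
#' @examples
#' k2p(0.1, 0.05)
#' @export
k2p <- function(P, Q) {
  if (any(P < 0 | Q < 0, na.rm = TRUE)) stop("P and Q must be non-negative")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  out <- rep(NA_real_, length(w1))
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  out[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  out
}

#' Pairwise K2P distance matrix
#'
#' Computes all `n(n-1)/2` pairwise K2P divergences of an alignment.
#' Saturated pairs (and pairs with no comparable sites) become `NA` entries
#' -- explicitly marked, never zeroed -- and are listed in the
#' `"undefined"` attribute with their `P`, `Q` for diagnosis; a single
#' summary warning is emitted when any occur.
#'
#' @param aln a [coi_alignment].
#' @param deletion `"pairwise"` (default; per-pair column skipping,
#'   appropriate for unevenly trimmed records) or `"complete"` (columns
#'   containing any gap/`N`/ambiguity in any sequence are removed set-wide
#'   first, matching tools that default to complete deletion).
#' @return symmetric numeric matrix of divergences (proportions) with
#'   specimen ids as dimnames; attributes `deletion` and `undefined` (a
#'   data frame of marked pairs, zero rows when clean).
#' @export
k2p_distances <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (n_sequences(aln) < 2) stop("need at least 2 sequences")
  ids <- aln_ids(aln)
  n <- length(ids)
  M <- matrix(encode_bases(aln$mat), nrow = nrow(aln$mat))
  if (deletion == "complete") {
    keep <- rowSums(is.na(M)) == 0
    if (!any(keep)) stop("no comparable sites after complete deletion")
    M <- M[keep, , drop = FALSE]
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  und <- list()
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    A <- M[, i]
    B <- M[, js, drop = FALSE]
    valid <- !is.na(A) & !is.na(B)
    nn <- colSums(valid)
    diff <- valid & (A != B)
    diff[is.na(diff)] <- FALSE
    s <- A + B
    ts <- diff & (s == 4L | s == 6L)
    P <- ifelse(nn > 0, colSums(ts) / nn, NA_real_)
    Q <- ifelse(nn > 0, (colSums(diff) - colSums(ts)) / nn, NA_real_)
    d <- rep(NA_real_, length(js))
    ok <- nn > 0
    d[ok] <- k2p(P[ok], Q[ok])
    bad <- which(is.na(d))
    for (b in bad) {
      und[[length(und) + 1]] <- data.frame(
        id_a = ids[i], id_b = ids[js[b]], n = nn[b],
        P = P[b], Q = Q[b],
        reason = if (nn[b] == 0) "no comparable sites" else "saturated",
        stringsAsFactors = FALSE)
    }
    D[i, js] <- d
    D[js, i] <- d
  }
  undef <- if (length(und)) do.call(rbind, und) else
    data.frame(id_a = character(0), id_b = character(0), n = integer(0),
               P = numeric(0), Q = numeric(0), reason = character(0),
               stringsAsFactors = FALSE)
  if (nrow(undef) > 0) {
    warning(nrow(undef), " pair(s) undefined (saturated or no comparable sites); ",
            "see attr(., \"undefined\")")
  }
  attr(D, "deletion") <- deletion
  attr(D, "undefined") <- undef
  D
}

#' Distance matrix readers and writers
#'
#' `write_distmat()` writes a square TSV with an id header row and column;
#' `read_distmat()` reads it back. `write_distmat_phylip()` writes the
#' lower-triangle PHYLIP-style format. Values are proportions at full
#' precision; the percent scale is a report-layer concern.
#'
#' @param dm symmetric distance matrix with id dimnames.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_distmat()` returns the
#'   matrix.
#' @export
write_distmat <- function(dm, path) {
  ids <- rownames(dm)
  header <- paste(c("id", ids), collapse = "\t")
  body <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], sprintf("%.10g", dm[i, ])), collapse = "\t")
  }, character(1))
  write_atomic(c(header, body), path)
}

#' @rdname write_distmat
#' @export
read_distmat <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  dimnames(m) <- list(rownames(df), colnames(df))
  m
}

#' @rdname write_distmat
#' @export
write_distmat_phylip <- function(dm, path) {
  ids <- rownames(dm)
  lines <- c(sprintf("%5d", length(ids)),
             vapply(seq_along(ids), function(i) {
               row <- if (i == 1) character(0) else
                 sprintf("%.6f", dm[i, seq_len(i - 1)])
               paste(c(sprintf("%-10s", ids[i]), row), collapse = "  ")
             }, character(1)))
  write_atomic(lines, path)
}
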