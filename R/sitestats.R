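#' Site classification counts
#'
#' Classifies each alignment column over its unambiguous bases (A/C/G/T;
#' gaps, N and ambiguity codes are ignored within the column):
#'
#' * *constant*: exactly one base state present;
#' * *variable*: two or more states;
#' * *parsimony-informative*: at least two states each carried by at least
#'   two sequences;
#' * *singleton*: variable but not informative.
#'
#' Columns with fewer than two unambiguous cells carry no comparison and
#' are excluded from the tally (counted in `excluded`). By construction
#' `constant + variable = analyzed` and
#' `parsimony_informative + singleton = variable`.
#'
#' @param aln a [coi_alignment].
#' @param scope optional character vector of specimen ids to restrict to
#'   (e.g. the ingroup).
#' @return list: `analyzed`, `constant`, `variable`,
#'   `parsimony_informative`, `singleton`, `excluded`.
#' @export
classify_sites <- function(aln, scope = NULL) {
  ids <- aln_ids(aln)
  if (!is.null(scope)) {
    miss <- setdiff(scope, ids)
    if (length(miss)) stop("ids not in alignment: ", paste(miss, collapse = ", "))
    if (length(scope) == 0) stop("empty scope")
    mat <- aln$mat[, scope, drop = FALSE]
  } else {
    mat <- aln$mat
  }
  if (ncol(mat) < 2) stop("need at least 2 sequences in scope")
  counts <- sapply(c("A", "C", "G", "T"), function(b) rowSums(mat == b))
  if (nrow(mat) == 1) counts <- matrix(counts, nrow = 1,
                                       dimnames = list(NULL, c("A", "C", "G", "T")))
  tot <- rowSums(counts)
  states <- rowSums(counts > 0)
  states2 <- rowSums(counts >= 2)
  usable <- tot >= 2
  constant <- usable & states == 1
  variable <- usable & states >= 2
  informative <- variable & states2 >= 2
  list(analyzed = sum(usable),
       constant = sum(constant),
       variable = sum(variable),
       parsimony_informative = sum(informative),
       singleton = sum(variable & !informative),
       excluded = sum(!usable))
}

#' Mean base composition across sequences
#'
#' Computes each sequence's A/C/G/T frequencies over its own unambiguous
#' bases and reports the arithmetic mean of those per-sequence
#' frequencies (not pooled counts) -- the convention behind "mean"
#' composition figures. Sequences with no unambiguous base are excluded
#' with a warning.
#'
#' @param aln a [coi_alignment].
#' @param scope optional character vector of specimen ids.
#' @return named numeric vector of proportions (`A`, `C`, `G`, `T`)
#'   summing to 1, with attribute `n_sequences`.
#' @export
composition_means <- function(aln, scope = NULL) {
  ids <- aln_ids(aln)
  if (!is.null(scope)) {
    miss <- setdiff(scope, ids)
    if (length(miss)) stop("ids not in alignment: ", paste(miss, collapse = ", "))
    mat <- aln$mat[, scope, drop = FALSE]
  } else {
    mat <- aln$mat
  }
  freqs <- apply(mat, 2, function(col) {
    cnt <- c(A = sum(col == "A"), C = sum(col == "C"),
             G = sum(col == "G"), T = sum(col == "T"))
    tot <- sum(cnt)
    if (tot == 0) rep(NA_real_, 4) else cnt / tot
  })
  ok <- !is.na(freqs[1, ])
  if (!all(ok)) {
    warning("excluded sequence(s) without unambiguous bases: ",
            paste(colnames(mat)[!ok], collapse = ", "))
  }
  if (!any(ok)) stop("no sequence with unambiguous bases")
  out <- rowMeans(freqs[, ok, drop = FALSE])
  names(out) <- c("A", "C", "G", "T")
  attr(out, "n_sequences") <- sum(ok)
  out
}
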