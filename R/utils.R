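# internal helpers shared across modules

# Characters admitted in an aligned nucleotide sequence: plain bases, N,
# the full IUPAC ambiguity set and the gap character.
ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# Integer encoding used by the distance layer: A=1 C=2 G=3 T=4, everything
# else (gap, N, ambiguity) NA so it is skipped under pairwise deletion.
BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_bases <- function(chars) {
  out <- BASE_CODE[chars]
  names(out) <- NULL
  out
}

#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percent formatting used by all table writers: 2 decimals, half-up,
# undefined printed "/"
fmt_pct <- function(x) {
  ifelse(is.na(x), "/", sprintf("%.2f", round_half_up(x, 2)))
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps seeded operations from perturbing the
# global RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a named substream seed from a master seed; stays below 2^31-1.
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483646 + 1)
}

# atomic-ish write: write to a sibling temp file, then rename over target
write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file onto ", path)
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  header <- paste(colnames(df), collapse = "\t")
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  write_atomic(c(header, body), path)
}
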