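## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

## IUPAC nucleotide codes -> permitted bases
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_acgt <- function(x) !grepl("[^ACGT]", x)

#' Levenshtein distance between character vectors
#'
#' Thin wrapper around [utils::adist()] with unit substitution, insertion and
#' deletion costs, i.e. plain Levenshtein distance.
#'
#' @param a,b Character vectors; distances are computed for all pairs.
#' @return An integer matrix of dimension `length(a)` by `length(b)`.
#' @export
levenshtein <- function(a, b) {
  unname(adist(a, b))
}

## Deterministic 31-bit hash of strings/numbers, used to derive independent
## RNG streams from (seed, motif_id, spacer_set, rotation) tuples.
str_hash <- function(...) {
  parts <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                        character(1)), collapse = "|")
  h <- 2166136261
  for (code in utf8ToInt(parts)) {
    h <- (h * 16777619 + code) %% 2147483647
  }
  as.integer(h)
}

## Evaluate `code` under a local RNG seed without disturbing the caller's
## random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
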