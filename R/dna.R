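#' @useDynLib crisprseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# DNA string helpers shared across modules. Sequences are plain upper-case
# character scalars/vectors; coordinates are 0-based, half-open everywhere.

#' Validate and normalize a DNA string
#'
#' Upper-cases the input and checks the alphabet. The position (1-based, for
#' human-readable messages only) of the first offending character is named in
#' the error.
#'
#' @param x Character vector of sequences.
#' @param what Label used in error messages.
#' @param allow_n Permit `N` in addition to `ACGT`.
#' @return The upper-cased sequences.
#' @export
dna_norm <- function(x, what = "sequence", allow_n = FALSE) {
  if (!is.character(x) || anyNA(x)) {
    stop(what, " must be a character vector without NAs", call. = FALSE)
  }
  x <- toupper(x)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(pat, x)
  hit <- which(bad > 0L)
  if (length(hit)) {
    stop(sprintf("invalid alphabet in %s: character '%s' at position %d",
                 what, substr(x[hit[1L]], bad[hit[1L]], bad[hit[1L]]),
                 bad[hit[1L]]), call. = FALSE)
  }
  x
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (`ACGTN`).
#' @return Reverse complements, same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# 0-based substring [start, end)
substr0 <- function(x, start, end) substr(x, start + 1L, end)

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
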