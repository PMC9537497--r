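# Internal helpers shared across modules.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#' @param x character scalar over A,C,G,T,N
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Derive a stable sub-seed from a base seed and a counter, kept inside the
# 32-bit integer range. Per-item sub-seeds mean adding items never perturbs
# the random stream of earlier items.
subseed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629L)
}

with_subseed <- function(seed, i, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(subseed(seed, i))
  force(expr)
}

# Random DNA of length n using the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}
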