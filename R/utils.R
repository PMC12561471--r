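#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Plain-character helper used throughout the package for strand arithmetic
#' on short queries; whole-genome operations go through Biostrings.
#'
#' @param x character vector of DNA strings over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    bad <- !ch %in% names(DNA_COMP)
    if (any(bad)) stop("non-DNA character in sequence: ", ch[which(bad)[1]])
    paste(DNA_COMP[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Run code with a temporarily-set RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 1-based inclusive <-> 0-based half-open. Conversion happens only at file
# boundaries; everything internal is 0-based half-open.
to_zero_based <- function(start1, end1) {
  cbind(start = start1 - 1L, end = end1)
}

to_one_based <- function(start0, end0) {
  cbind(start = start0 + 1L, end = end0)
}
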