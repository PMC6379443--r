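#' @useDynLib bystanderscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats median rnorm runif rbinom setNames
#' @importFrom utils head tail write.table read.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Seeded random DNA sequence
#'
#' @param n length in bp.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# 0-based half-open substring: seq[start, end)
substr0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

# run an expression under a locally-set seed without clobbering global RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  invisible(x)
}

# interval [start, end) sanity against a sequence of length L
check_interval <- function(start, end, L, name = "interval") {
  if (!(start >= 0 && start < end && end <= L)) {
    stop(sprintf("%s [%d,%d) out of range for length %d", name, start, end, L),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
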