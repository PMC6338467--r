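# Internal sequence helpers. Sequences are plain upper-case character
# strings internally; Biostrings is used at the I/O boundary and for
# pattern matching. All coordinates are 0-based half-open.

DNA_ALPHABET <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substring with 0-based half-open coordinates
subseq0 <- function(x, start, end) {
  substr(x, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_interval <- function(x) {
  is.numeric(x) && length(x) == 2L && !anyNA(x) && x[2] >= x[1]
}

check_interval <- function(x, len, what = "interval") {
  if (!is_interval(x)) stop(what, " must be a numeric (start, end) pair with end >= start")
  if (x[1] < 0 || x[2] > len) {
    stop(sprintf("%s [%d, %d) outside sequence of length %d", what, x[1], x[2], len))
  }
  invisible(x)
}

interval_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

#' Derive a per-stage seed from a pipeline seed
#'
#' Deterministically maps a master seed and a fixed stage offset to a
#' child seed within 32-bit integer range, so every stochastic stage of
#' a pipeline draws from its own reproducible stream.
#'
#' @param seed Master seed (integer).
#' @param offset Fixed per-stage offset (integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a random multi-chromosome genome
#'
#' Generates uniform-random DNA chromosomes, used as the host genome in
#' simulations. Chromosome names default to `chr1..chrN`.
#'
#' @param lengths Integer vector of chromosome lengths (bp).
#' @param names Optional chromosome names.
#' @param seed Optional integer seed for reproducibility.
#' @return Named character vector of chromosome sequences.
#' @examples
#' g <- simulate_genome(c(5000, 3000), seed = 1)
#' nchar(g)
#' @export
simulate_genome <- function(lengths, names = NULL, seed = NULL) {
  stopifnot(all(lengths > 0))
  if (is.null(names)) names <- paste0("chr", seq_along(lengths))
  with_seed(seed, {
    g <- vapply(lengths, random_dna, character(1))
    names(g) <- names
    g
  })
}

#' Read and write FASTA sequences
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] returning/accepting
#' the plain named character vectors used throughout the package.
#'
#' @param path File path.
#' @param x Named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
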