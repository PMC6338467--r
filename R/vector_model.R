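#' Construct a transformation-vector model
#'
#' A `vector_model` describes the plasmid used for Agrobacterium
#' transformation: its sequence, the left/right border repeats (LB/RB),
#' the T-strand (the LB-to-RB span intended for transfer), and named
#' functional elements (promoters, genes, terminators). All coordinates
#' are 0-based half-open plasmid coordinates.
#'
#' The default layout places the T-strand at the start of the plasmid,
#' `[0, t_strand)`, with LB occupying its first `border_len` bases and RB
#' its last, followed by the backbone `[t_strand, t_strand + backbone)`.
#'
#' @param t_strand T-strand length in bp (e.g. 4400 for a pROK2-like
#'   vector, 7100 for a pCSA110-like vector).
#' @param backbone Backbone length in bp.
#' @param elements Optional `data.frame` with columns `name`, `start`,
#'   `end` (0-based half-open plasmid coords), `strand` (`"+"`/`"-"`), and
#'   optionally `region` (`"t_strand"` or `"backbone"`; inferred from the
#'   coordinates when absent). Elements must lie inside their region.
#' @param sequence Optional explicit plasmid sequence; random seeded DNA
#'   otherwise.
#' @param border_len Border repeat length in bp (default 25).
#' @param name Vector name.
#' @param circular Is the plasmid circular (informational).
#' @param seed Optional seed for the random sequence.
#' @return An object of class `vector_model` with fields `name`,
#'   `sequence`, `circular`, `lb`, `rb`, `t_strand`, `elements`.
#' @examples
#' v <- build_vector(t_strand = 4400, backbone = 4600, seed = 1)
#' v
#' @export
build_vector <- function(t_strand = 4400, backbone = 4600, elements = NULL,
                         sequence = NULL, border_len = 25, name = "vector",
                         circular = TRUE, seed = NULL) {
  stopifnot(t_strand > 2 * border_len, backbone >= 0)
  total <- t_strand + backbone
  if (is.null(sequence)) {
    sequence <- with_seed(seed, random_dna(total))
  } else {
    sequence <- toupper(sequence)
    if (nchar(sequence) != total) {
      stop("explicit sequence length must equal t_strand + backbone")
    }
  }
  ts <- c(0, t_strand)
  lb <- c(0, border_len)
  rb <- c(t_strand - border_len, t_strand)
  if (is.null(elements)) {
    elements <- data.frame(name = character(), start = integer(),
                           end = integer(), strand = character(),
                           region = character(), stringsAsFactors = FALSE)
  } else {
    elements <- as.data.frame(elements)
    req <- c("name", "start", "end")
    if (!all(req %in% names(elements))) {
      stop("elements needs columns name, start, end")
    }
    if (is.null(elements$strand)) elements$strand <- "+"
    if (is.null(elements$region)) {
      elements$region <- ifelse(elements$end <= t_strand, "t_strand", "backbone")
    }
    for (i in seq_len(nrow(elements))) {
      e <- elements[i, ]
      check_interval(c(e$start, e$end), total, paste0("element '", e$name, "'"))
      span <- if (e$region == "t_strand") ts else c(t_strand, total)
      if (e$start < span[1] || e$end > span[2]) {
        stop(sprintf("element '%s' [%d, %d) outside its %s span [%d, %d)",
                     e$name, e$start, e$end, e$region, span[1], span[2]))
      }
    }
  }
  structure(list(name = name, sequence = sequence, circular = circular,
                 lb = lb, rb = rb, t_strand = ts, elements = elements),
            class = "vector_model")
}

#' @export
print.vector_model <- function(x, ...) {
  cat(sprintf("<vector_model> %s: %d bp%s\n", x$name, nchar(x$sequence),
              if (x$circular) " (circular)" else ""))
  cat(sprintf("  T-strand [%d, %d) (%d bp), LB [%d, %d), RB [%d, %d)\n",
              x$t_strand[1], x$t_strand[2], diff(x$t_strand),
              x$lb[1], x$lb[2], x$rb[1], x$rb[2]))
  cat(sprintf("  backbone: %d bp, elements: %d\n",
              nchar(x$sequence) - diff(x$t_strand), nrow(x$elements)))
  if (nrow(x$elements)) {
    for (i in seq_len(nrow(x$elements))) {
      e <- x$elements[i, ]
      cat(sprintf("    %-10s [%5d, %5d) %s %s\n", e$name, e$start, e$end,
                  e$strand, e$region))
    }
  }
  invisible(x)
}

#' Length of the T-strand interval
#' @param vector A `vector_model`.
#' @return Length in bp.
#' @export
t_strand_length <- function(vector) {
  stopifnot(inherits(vector, "vector_model"))
  unname(diff(vector$t_strand))
}

#' A pROK2-like example vector
#'
#' Convenience constructor for a vector with the element layout of the
#' pROK2 SALK transformation plasmid: a 4.4 kb T-strand carrying NOSp,
#' nptII, a duplicated NOSt, and the CaMV 35S promoter, plus a 4.6 kb
#' backbone. Coordinates are schematic, not the true pROK2 map.
#'
#' @param seed Seed for the random sequence.
#' @return A `vector_model`.
#' @export
prok2_like_vector <- function(seed = NULL) {
  el <- data.frame(
    name   = c("NOSp", "nptII", "NOSt", "CaMV35S", "NOSt2"),
    start  = c(150L, 600L, 1650L, 2200L, 3900L),
    end    = c(550L, 1600L, 1950L, 3600L, 4200L),
    strand = c("+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE
  )
  build_vector(t_strand = 4400, backbone = 4600, elements = el,
               name = "pROK2like", seed = seed)
}

#' Write vector elements as BED6
#'
#' @param vector A `vector_model`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_elements_bed <- function(vector, path) {
  stopifnot(inherits(vector, "vector_model"))
  el <- vector$elements
  bed <- data.frame(chrom = vector$name, start = el$start, end = el$end,
                    name = el$name, score = 0L, strand = el$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
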