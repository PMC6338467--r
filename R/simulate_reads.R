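# Long-read, optical-molecule, small-RNA and bisulfite simulators.

mutate_sequence <- function(seq, sub_rate, indel_rate) {
  if (sub_rate == 0 && indel_rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sub <- stats::runif(n) < sub_rate
  if (any(sub)) {
    # substitute with a uniformly drawn different base
    k <- sum(sub)
    shift <- sample(1:3, k, replace = TRUE)
    idx <- match(chars[sub], DNA_ALPHABET)
    idx[is.na(idx)] <- 1L
    chars[sub] <- DNA_ALPHABET[((idx - 1L + shift) %% 4L) + 1L]
  }
  if (indel_rate > 0) {
    u <- stats::runif(n)
    del <- u < indel_rate / 2
    ins <- u >= indel_rate / 2 & u < indel_rate
    kept <- ifelse(del, "", chars)
    extra <- character(n)
    if (any(ins)) extra[ins] <- sample(DNA_ALPHABET, sum(ins), replace = TRUE)
    chars <- paste0(kept, extra)
  }
  paste(chars, collapse = "")
}

#' Simulate long reads with provenance
#'
#' Draws reads from a genome with chromosome choice proportional to
#' length, normal read lengths, uniform start positions and random
#' strand, then applies the substitution/indel noise of a
#' [noise_model()]. With zero noise every read is an exact substring (or
#' reverse complement of one) of the genome, and the returned provenance
#' records the exact source interval.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param n Number of reads (> 0).
#' @param mean_length,sd_length Read length distribution (bp); lengths are
#'   truncated below at `min_length` and clipped (with a warning) at the
#'   chromosome length.
#' @param min_length Minimum read length.
#' @param noise A [noise_model()] (only `read_sub_rate` and
#'   `read_indel_rate` are used).
#' @param seed Optional seed.
#' @return A list with `reads` (named character vector) and `provenance`
#'   (`data.frame` with `read_id`, `chrom`, `start`, `end`, `strand`:
#'   0-based half-open source intervals on the input genome).
#' @export
simulate_reads <- function(genome, n, mean_length = 10000,
                           sd_length = mean_length / 4, min_length = 500,
                           noise = noise_model(), seed = NULL) {
  stopifnot(n > 0, is.character(genome), !is.null(names(genome)))
  lens <- nchar(genome)
  with_seed(seed, {
    chroms <- sample(names(genome), n, replace = TRUE, prob = lens)
    rlen <- pmax(min_length, round(stats::rnorm(n, mean_length, sd_length)))
    clipped <- rlen > lens[chroms]
    if (any(clipped)) {
      warning(sum(clipped), " read(s) longer than their chromosome; clipped")
      rlen[clipped] <- lens[chroms][clipped]
    }
    start <- floor(stats::runif(n) * (lens[chroms] - rlen + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads <- character(n)
    for (i in seq_len(n)) {
      s <- subseq0(genome[[chroms[i]]], start[i], start[i] + rlen[i])
      if (strand[i] == "-") s <- revcomp(s)
      reads[i] <- mutate_sequence(s, noise$read_sub_rate, noise$read_indel_rate)
    }
    ids <- sprintf("read_%05d", seq_len(n))
    names(reads) <- ids
    list(reads = reads,
         provenance = data.frame(read_id = ids, chrom = chroms,
                                 start = start, end = start + rlen,
                                 strand = strand, stringsAsFactors = FALSE))
  })
}

#' Simulate nick-labelled optical molecules
#'
#' Draws long molecules from the genome, labels them at every occurrence
#' of the nicking site (both strands, as in single-enzyme chemistry),
#' then applies label false negatives, false positives and inter-label
#' sizing noise. Molecules shorter than `noise$min_molecule_len` after
#' sizing noise are dropped, emulating the molecule length filter.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param n Number of molecules drawn (the number returned may be smaller
#'   after the length filter).
#' @param site Nicking recognition site (default Nt.BspQI, `GCTCTTC`).
#' @param mean_length,sd_length Molecule length distribution (bp).
#' @param noise A [noise_model()]; uses `label_fp` (per 100 kb),
#'   `label_fn`, `sizing_rel_sd` and `min_molecule_len`.
#' @param seed Optional seed.
#' @return List with `molecules` (list of [label_map()] objects) and
#'   `provenance` (`data.frame` of source intervals).
#' @export
simulate_molecules <- function(genome, n, site = "GCTCTTC",
                               mean_length = 250000, sd_length = 50000,
                               noise = noise_model(), seed = NULL) {
  stopifnot(n > 0, nzchar(site))
  lens <- nchar(genome)
  with_seed(seed, {
    chroms <- sample(names(genome), n, replace = TRUE, prob = lens)
    mlen <- pmax(1000, round(stats::rnorm(n, mean_length, sd_length)))
    mlen <- pmin(mlen, lens[chroms])
    start <- floor(stats::runif(n) * (lens[chroms] - mlen + 1))
    molecules <- list()
    prov <- list()
    for (i in seq_len(n)) {
      frag <- subseq0(genome[[chroms[i]]], start[i], start[i] + mlen[i])
      labels <- digest(frag, site)$labels
      if (noise$label_fn > 0 && length(labels)) {
        labels <- labels[stats::runif(length(labels)) >= noise$label_fn]
      }
      if (noise$label_fp > 0) {
        nfp <- stats::rpois(1, noise$label_fp * mlen[i] / 1e5)
        if (nfp > 0) labels <- c(labels, floor(stats::runif(nfp) * mlen[i]))
      }
      labels <- sort(unique(labels))
      length_i <- mlen[i]
      if (noise$sizing_rel_sd > 0 && length(labels)) {
        gaps <- diff(c(0, labels, length_i))
        factors <- pmax(0.01, stats::rnorm(length(gaps), 1, noise$sizing_rel_sd))
        resized <- cumsum(gaps * factors)
        labels <- utils::head(resized, -1)
        length_i <- resized[length(resized)]
      }
      if (length_i < noise$min_molecule_len) next
      id <- sprintf("mol_%05d", i)
      molecules[[id]] <- label_map(id, length_i, labels)
      prov[[id]] <- data.frame(molecule_id = id, chrom = chroms[i],
                               start = start[i], end = start[i] + mlen[i],
                               stringsAsFactors = FALSE)
    }
    list(molecules = molecules, provenance = do.call(rbind, prov))
  })
}

SIRNA_CLASSES <- c("15-20", "21", "22", "23", "24")

#' Simulate element-targeted small-RNA reads
#'
#' Draws small-RNA reads as exact substrings of the vector (either
#' strand), confined to the vector's annotated elements, with read length
#' drawn from the standard plant size classes (pooled 15-20 nt, and 21,
#' 22, 23, 24 nt).
#'
#' @param vector A `vector_model` with at least one element.
#' @param n Number of reads.
#' @param class_weights Either a named numeric vector of weights over
#'   `c("15-20","21","22","23","24")` applied to every element, or a
#'   matrix/data.frame with one row per element (rownames = element
#'   names) of such weights. Normalized per element.
#' @param element_weights Optional weights over elements (default equal).
#' @param strand_bias Probability of drawing a plus-strand read.
#' @param seed Optional seed.
#' @return List with `reads` (named character vector) and `truth`
#'   (`data.frame`: `read_id`, `element`, `class`, `length`, `start`,
#'   `strand`).
#' @export
simulate_small_rna <- function(vector, n, class_weights = NULL,
                               element_weights = NULL, strand_bias = 0.5,
                               seed = NULL) {
  stopifnot(inherits(vector, "vector_model"), n > 0)
  el <- vector$elements
  if (nrow(el) == 0) stop("vector has no annotated elements")
  if (any(el$end - el$start < 24)) {
    stop("element shorter than the maximum size class (24 nt): ",
         paste(el$name[el$end - el$start < 24], collapse = ", "))
  }
  if (is.null(class_weights)) {
    class_weights <- stats::setNames(rep(1, 5), SIRNA_CLASSES)
  }
  if (is.null(dim(class_weights))) {
    stopifnot(all(SIRNA_CLASSES %in% names(class_weights)))
    w <- matrix(rep(as.numeric(class_weights[SIRNA_CLASSES]), each = nrow(el)),
                nrow = nrow(el), dimnames = list(el$name, SIRNA_CLASSES))
  } else {
    w <- as.matrix(class_weights)[el$name, SIRNA_CLASSES, drop = FALSE]
  }
  if (any(rowSums(w) <= 0)) stop("class weights must have positive sum per element")
  w <- w / rowSums(w)
  if (is.null(element_weights)) element_weights <- rep(1, nrow(el))
  with_seed(seed, {
    ei <- sample(nrow(el), n, replace = TRUE, prob = element_weights)
    cls <- character(n); len <- integer(n); start <- integer(n)
    strand <- ifelse(stats::runif(n) < strand_bias, "+", "-")
    reads <- character(n)
    for (i in seq_len(n)) {
      cls[i] <- sample(SIRNA_CLASSES, 1, prob = w[ei[i], ])
      len[i] <- if (cls[i] == "15-20") sample(15:20, 1) else as.integer(cls[i])
      e <- el[ei[i], ]
      start[i] <- e$start + sample(0:(e$end - e$start - len[i]), 1)
      s <- subseq0(vector$sequence, start[i], start[i] + len[i])
      reads[i] <- if (strand[i] == "-") revcomp(s) else s
    }
    ids <- sprintf("srna_%05d", seq_len(n))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, element = el$name[ei],
                            class = cls, length = len, start = start,
                            strand = strand, stringsAsFactors = FALSE))
  })
}

#' Simulate per-site bisulfite counts
#'
#' For every cytosine (both strands) of a sequence, draws the methylated
#' read count as Binomial(depth, level + (1 - level) * non_conversion),
#' where `level` is the true methylation level of the site's context and
#' `non_conversion` the bisulfite non-conversion rate (unconverted
#' unmethylated cytosines read as methylated). Sites too close to the
#' sequence end to have a full context are skipped.
#'
#' @param sequence DNA string (e.g. the inserted vector sequence).
#' @param levels Named numeric vector of true methylation levels per
#'   context, e.g. `c(CG = 0.9, CHG = 0.7, CHH = 0.3)`; values in [0, 1].
#' @param depth Read depth per site (> 0).
#' @param non_conversion Non-conversion probability (default 0.0035,
#'   matching a < 0.35\% control-estimated bound).
#' @param name Sequence name recorded in the output.
#' @param seed Optional seed.
#' @return `data.frame` with `chrom`, `pos` (0-based), `strand`,
#'   `context`, `count_meth`, `count_total`.
#' @export
simulate_bisulfite <- function(sequence, levels = c(CG = 0.9, CHG = 0.7, CHH = 0.3),
                               depth = 30, non_conversion = 0.0035,
                               name = "seq", seed = NULL) {
  stopifnot(depth > 0, all(levels >= 0 & levels <= 1),
            non_conversion >= 0, non_conversion < 1)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  plus <- which(chars == "C") - 1L
  minus <- which(chars == "G") - 1L
  sites <- rbind(
    data.frame(pos = plus, strand = rep("+", length(plus))),
    data.frame(pos = minus, strand = rep("-", length(minus)))
  )
  if (nrow(sites) == 0) {
    return(data.frame(chrom = character(), pos = integer(), strand = character(),
                      context = character(), count_meth = integer(),
                      count_total = integer()))
  }
  sites$context <- classify_context(sequence, sites$pos, sites$strand)
  sites <- sites[sites$context != "none", , drop = FALSE]
  sites <- sites[order(sites$pos, sites$strand), , drop = FALSE]
  with_seed(seed, {
    lev <- as.numeric(levels[sites$context])
    p <- lev + (1 - lev) * non_conversion
    data.frame(chrom = name, pos = sites$pos, strand = sites$strand,
               context = sites$context,
               count_meth = stats::rbinom(nrow(sites), depth, p),
               count_total = rep(as.integer(depth), nrow(sites)),
               stringsAsFactors = FALSE)
  })
}
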