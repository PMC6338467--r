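#' Noise model for simulated data
#'
#' Bundles the noise parameters shared by the read, optical-molecule and
#' bisulfite simulators.
#'
#' @param read_sub_rate Per-base substitution probability in long reads.
#' @param read_indel_rate Per-base indel probability (split evenly between
#'   insertions and deletions).
#' @param label_fp False labels per 100 kb of molecule.
#' @param label_fn Probability that a true nick label is missed.
#' @param sizing_rel_sd Relative standard deviation applied to inter-label
#'   distances (optical sizing noise).
#' @param min_molecule_len Minimum emitted molecule length in bp (the
#'   length component of the molecule quality filter; 100000 reproduces a
#'   100 kb cutoff).
#' @param non_conversion Probability that an unmethylated cytosine escapes
#'   bisulfite conversion and reads as methylated.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(read_sub_rate = 0, read_indel_rate = 0,
                        label_fp = 0, label_fn = 0, sizing_rel_sd = 0,
                        min_molecule_len = 0, non_conversion = 0) {
  probs <- c(read_sub_rate = read_sub_rate, read_indel_rate = read_indel_rate,
             label_fn = label_fn, non_conversion = non_conversion)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must be in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (label_fp < 0) stop("label_fp must be >= 0")
  if (sizing_rel_sd < 0) stop("sizing_rel_sd must be >= 0")
  if (min_molecule_len < 0) stop("min_molecule_len must be >= 0")
  structure(list(read_sub_rate = read_sub_rate,
                 read_indel_rate = read_indel_rate,
                 label_fp = label_fp, label_fn = label_fn,
                 sizing_rel_sd = sizing_rel_sd,
                 min_molecule_len = min_molecule_len,
                 non_conversion = non_conversion),
            class = "noise_model")
}

#' Construct a concatemer specification
#'
#' Describes the internal architecture of one insertion: an ordered list
#' of vector-derived segments (T-strand or backbone, with orientation and
#' plasmid coordinates) optionally separated by linker filler sequences.
#'
#' @param segments `data.frame` with columns `source`
#'   (`"t_strand"`/`"backbone"`), `vstart`, `vend` (0-based half-open
#'   plasmid coords) and `orientation` (`"+"`/`"-"`).
#' @param linkers Character vector of linker sequences between adjacent
#'   segments (length `nrow(segments) - 1`; `""` for direct joins).
#' @param trunc_left,trunc_right Border truncation (bp) applied at the
#'   outward-facing end of the first/last segment, `NA` when that end is
#'   not T-strand-derived.
#' @param vector_len Plasmid length used for validation (optional).
#' @return An object of class `concatemer_spec`.
#' @export
concatemer_spec <- function(segments, linkers = NULL, trunc_left = NA,
                            trunc_right = NA, vector_len = NULL) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("source", "vstart", "vend", "orientation") %in% names(segments)))
  if (nrow(segments) == 0) stop("concatemer needs at least one segment")
  if (any(segments$vend <= segments$vstart)) stop("empty segment interval")
  if (!all(segments$source %in% c("t_strand", "backbone"))) {
    stop("segment source must be t_strand or backbone")
  }
  if (!all(segments$orientation %in% c("+", "-"))) {
    stop("segment orientation must be '+' or '-'")
  }
  if (!is.null(vector_len) && any(segments$vstart < 0 | segments$vend > vector_len)) {
    stop("segment interval outside vector length")
  }
  if (is.null(linkers)) linkers <- rep("", max(0L, nrow(segments) - 1L))
  if (length(linkers) != max(0L, nrow(segments) - 1L)) {
    stop("need one linker slot (possibly \"\") per adjacent segment pair")
  }
  structure(list(segments = segments, linkers = as.character(linkers),
                 trunc_left = trunc_left, trunc_right = trunc_right),
            class = "concatemer_spec")
}

#' @export
print.concatemer_spec <- function(x, ...) {
  cat(sprintf("<concatemer_spec> %d segment(s), %d bp total\n",
              nrow(x$segments), concatemer_length(x)))
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat(sprintf("  %d: %-8s [%5d, %5d) %s (%d bp)\n", i, s$source,
                s$vstart, s$vend, s$orientation, s$vend - s$vstart))
    if (i < nrow(x$segments) && nzchar(x$linkers[i])) {
      cat(sprintf("     linker %d bp\n", nchar(x$linkers[i])))
    }
  }
  invisible(x)
}

#' Total length of a concatemer (segments plus linkers)
#' @param spec A `concatemer_spec`.
#' @return Length in bp.
#' @export
concatemer_length <- function(spec) {
  sum(spec$segments$vend - spec$segments$vstart) + sum(nchar(spec$linkers))
}

#' Realize a concatemer specification as a DNA sequence
#' @param vector A `vector_model`.
#' @param spec A `concatemer_spec`.
#' @return DNA string of length `concatemer_length(spec)`.
#' @export
concatemer_sequence <- function(vector, spec) {
  stopifnot(inherits(vector, "vector_model"), inherits(spec, "concatemer_spec"))
  segs <- spec$segments
  pieces <- character(0)
  for (i in seq_len(nrow(segs))) {
    s <- subseq0(vector$sequence, segs$vstart[i], segs$vend[i])
    if (segs$orientation[i] == "-") s <- revcomp(s)
    pieces <- c(pieces, s)
    if (i < nrow(segs)) pieces <- c(pieces, spec$linkers[i])
  }
  paste(pieces, collapse = "")
}

# G-rich linker: `g_bases` guanines plus random filler, shuffled
make_linker <- function(len = 55, g_bases = 26) {
  stopifnot(g_bases <= len)
  chars <- c(rep("G", g_bases), sample(DNA_ALPHABET, len - g_bases, replace = TRUE))
  paste(sample(chars), collapse = "")
}

#' Simulate a concatemer architecture
#'
#' Draws the segment structure of one insertion: a number of T-strand /
#' backbone copies (geometric by default), each possibly internally broken
#' and orientation-flipped, with border-side truncations at the two
#' outward-facing ends drawn uniformly from `trunc_range` when those ends
#' are T-strand-derived. Terminal copies are always T-strand, emulating
#' insertions that begin and end with border sequence.
#'
#' @param vector A `vector_model`.
#' @param copies Fixed number of vector copies; when `NULL`, drawn as
#'   1 + geometric(`copy_p`).
#' @param copy_p Success probability of the geometric copy-number draw.
#' @param breakpoint_prob Probability that a copy is internally broken
#'   (replaced by a random sub-interval of itself).
#' @param flip_prob Probability that a copy is reverse-oriented.
#' @param backbone_prob Probability that an interior copy is backbone
#'   rather than T-strand.
#' @param trunc_range Integer range (bp) for border truncation draws;
#'   the default 73–113 bp models the typical loss observed inward from
#'   the left border.
#' @param linker_prob Probability of a G-rich linker between adjacent
#'   segments (default 0: direct joins).
#' @param linker_len,linker_g Linker length and minimum G content.
#' @param min_fragment Minimum length of an internally broken fragment.
#' @param seed Optional seed.
#' @return A `concatemer_spec`.
#' @examples
#' v <- build_vector(seed = 1)
#' simulate_concatemer(v, copies = 2, seed = 42)
#' @export
simulate_concatemer <- function(vector, copies = NULL, copy_p = 0.5,
                                breakpoint_prob = 0.3, flip_prob = 0.3,
                                backbone_prob = 0.3,
                                trunc_range = c(73, 113),
                                linker_prob = 0, linker_len = 55,
                                linker_g = 26, min_fragment = 200,
                                seed = NULL) {
  stopifnot(inherits(vector, "vector_model"))
  for (p in c(copy_p, breakpoint_prob, flip_prob, backbone_prob, linker_prob)) {
    if (is.na(p) || p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  }
  if (copy_p == 0 && is.null(copies)) stop("empty copy distribution (copy_p = 0)")
  ts <- vector$t_strand
  bb <- c(vector$t_strand[2], nchar(vector$sequence))
  if (trunc_range[1] < 0 || trunc_range[2] >= diff(ts)) {
    stop("trunc_range must lie within the T-strand length")
  }
  with_seed(seed, {
    n <- if (is.null(copies)) 1L + stats::rgeom(1, copy_p) else as.integer(copies)
    if (n < 1) stop("copies must be >= 1")
    src <- rep("t_strand", n)
    if (n > 2) {
      mid <- 2:(n - 1)
      src[mid] <- ifelse(stats::runif(n - 2) < backbone_prob, "backbone", "t_strand")
    }
    segs <- data.frame(source = src, vstart = NA_integer_, vend = NA_integer_,
                       orientation = "+", stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      span <- if (src[i] == "t_strand") ts else bb
      iv <- span
      if (stats::runif(1) < breakpoint_prob && diff(span) > min_fragment + 1) {
        len <- sample(min_fragment:(diff(span) - 1), 1)
        a <- span[1] + sample(0:(diff(span) - len), 1)
        iv <- c(a, a + len)
      }
      segs$vstart[i] <- iv[1]
      segs$vend[i] <- iv[2]
      if (stats::runif(1) < flip_prob) segs$orientation[i] <- "-"
    }
    # border-side truncations at the two outward ends
    trunc_left <- trunc_right <- NA_integer_
    if (segs$source[1] == "t_strand") {
      trunc_left <- sample(trunc_range[1]:trunc_range[2], 1)
      if (segs$orientation[1] == "+") {
        segs$vstart[1] <- segs$vstart[1] + trunc_left
      } else {
        segs$vend[1] <- segs$vend[1] - trunc_left
      }
    }
    if (segs$source[n] == "t_strand") {
      trunc_right <- sample(trunc_range[1]:trunc_range[2], 1)
      if (segs$orientation[n] == "+") {
        segs$vend[n] <- segs$vend[n] - trunc_right
      } else {
        segs$vstart[n] <- segs$vstart[n] + trunc_right
      }
    }
    linkers <- rep("", max(0L, n - 1L))
    if (n > 1 && linker_prob > 0) {
      use <- stats::runif(n - 1) < linker_prob
      linkers[use] <- vapply(which(use),
                             function(i) make_linker(linker_len, linker_g),
                             character(1))
    }
    concatemer_spec(segs, linkers, trunc_left, trunc_right,
                    vector_len = nchar(vector$sequence))
  })
}

# ---- genome events ---------------------------------------------------------

#' Genome event constructors
#'
#' Events implanted into a source genome by [implant_events()]. All
#' coordinates are 0-based half-open on the source genome.
#'
#' * `insertion_event()`: insert a realized concatemer at `point`,
#'   deleting `deletion` bp of genomic sequence starting at `point`.
#' * `inversion_event()`: reverse-complement `[start, end)` in place.
#' * `excision_event()`: delete `[start, end)`.
#' * `translocation_event()`: move `[start, end)` to `destination` on the
#'   same chromosome, optionally inverted.
#' * `arm_swap_event()`: exchange the distal arms `[pos1, end)` of
#'   `chrom1` and `[pos2, end)` of `chrom2`.
#'
#' @param chrom,chrom1,chrom2 Chromosome names.
#' @param point,start,end,destination,pos1,pos2 Coordinates (bp).
#' @param concatemer A `concatemer_spec` describing the inserted sequence.
#' @param vector The `vector_model` the concatemer derives from.
#' @param deletion Insertion-site deletion length (bp).
#' @param inverted Should the translocated fragment be inverted?
#' @return An object of class `genome_event`.
#' @name genome_events
NULL

new_event <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = c(paste0(kind, "_event"), "genome_event"))
}

#' @rdname genome_events
#' @export
insertion_event <- function(chrom, point, concatemer, vector, deletion = 0) {
  stopifnot(inherits(concatemer, "concatemer_spec"), inherits(vector, "vector_model"),
            point >= 0, deletion >= 0)
  new_event("insertion", list(chrom = chrom, point = point, deletion = deletion,
                              concatemer = concatemer, vector = vector))
}

#' @rdname genome_events
#' @export
inversion_event <- function(chrom, start, end) {
  stopifnot(end > start, start >= 0)
  new_event("inversion", list(chrom = chrom, start = start, end = end))
}

#' @rdname genome_events
#' @export
excision_event <- function(chrom, start, end) {
  stopifnot(end > start, start >= 0)
  new_event("excision", list(chrom = chrom, start = start, end = end))
}

#' @rdname genome_events
#' @export
translocation_event <- function(chrom, start, end, destination, inverted = FALSE) {
  stopifnot(end > start, start >= 0, destination >= 0)
  if (destination > start && destination < end) {
    stop("destination lies inside the translocated interval")
  }
  new_event("translocation", list(chrom = chrom, start = start, end = end,
                                  destination = destination, inverted = inverted))
}

#' @rdname genome_events
#' @export
arm_swap_event <- function(chrom1, pos1, chrom2, pos2) {
  stopifnot(pos1 >= 0, pos2 >= 0, chrom1 != chrom2)
  new_event("arm_swap", list(chrom1 = chrom1, pos1 = pos1,
                             chrom2 = chrom2, pos2 = pos2))
}

# source-genome footprint of an event, for overlap checking
event_footprint <- function(ev, genome) {
  switch(ev$kind,
    insertion = data.frame(chrom = ev$chrom, start = ev$point,
                           end = ev$point + ev$deletion),
    inversion = ,
    excision = data.frame(chrom = ev$chrom, start = ev$start, end = ev$end),
    translocation = data.frame(chrom = ev$chrom,
                               start = c(ev$start, ev$destination),
                               end = c(ev$end, ev$destination)),
    arm_swap = data.frame(chrom = c(ev$chrom1, ev$chrom2),
                          start = c(ev$pos1, ev$pos2),
                          end = c(nchar(genome[[ev$chrom1]]),
                                  nchar(genome[[ev$chrom2]]))),
    stop("unknown event kind: ", ev$kind)
  )
}

# Expand events into replacement operations (src interval -> new sequence)
event_ops <- function(ev, id, genome) {
  g <- function(chrom) genome[[chrom]]
  switch(ev$kind,
    insertion = {
      ins <- concatemer_sequence(ev$vector, ev$concatemer)
      data.frame(event_id = id, kind = "insertion", chrom = ev$chrom,
                 src_start = ev$point, src_end = ev$point + ev$deletion,
                 replacement = ins, stringsAsFactors = FALSE)
    },
    inversion = data.frame(event_id = id, kind = "inversion", chrom = ev$chrom,
                           src_start = ev$start, src_end = ev$end,
                           replacement = revcomp(subseq0(g(ev$chrom), ev$start, ev$end)),
                           stringsAsFactors = FALSE),
    excision = data.frame(event_id = id, kind = "excision", chrom = ev$chrom,
                          src_start = ev$start, src_end = ev$end,
                          replacement = "", stringsAsFactors = FALSE),
    translocation = {
      frag <- subseq0(g(ev$chrom), ev$start, ev$end)
      if (isTRUE(ev$inverted)) frag <- revcomp(frag)
      data.frame(event_id = id,
                 kind = c("translocation_cut", "translocation_paste"),
                 chrom = ev$chrom,
                 src_start = c(ev$start, ev$destination),
                 src_end = c(ev$end, ev$destination),
                 replacement = c("", frag), stringsAsFactors = FALSE)
    },
    arm_swap = {
      l1 <- nchar(g(ev$chrom1)); l2 <- nchar(g(ev$chrom2))
      tail1 <- subseq0(g(ev$chrom1), ev$pos1, l1)
      tail2 <- subseq0(g(ev$chrom2), ev$pos2, l2)
      data.frame(event_id = id, kind = "arm_swap",
                 chrom = c(ev$chrom1, ev$chrom2),
                 src_start = c(ev$pos1, ev$pos2),
                 src_end = c(l1, l2),
                 replacement = c(tail2, tail1), stringsAsFactors = FALSE)
    }
  )
}

#' Implant insertion and rearrangement events into a genome
#'
#' Applies a list of [genome_events] to a source genome and returns the
#' derived genome together with a truth ledger recording, for every
#' replacement operation, its source and derived coordinates and the
#' implanted sequence. The ledger round-trips: extracting the recorded
#' derived intervals from the derived genome reproduces the implanted
#' sequences byte-for-byte, and re-applying the ledger's events to the
#' source genome reproduces the derived genome.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param events List of events built with the [genome_events]
#'   constructors. Events must not overlap on the source genome.
#' @param seed Recorded in the ledger (the implanting itself is
#'   deterministic).
#' @return A list with components `genome` (derived, named character
#'   vector) and `ledger` (class `truth_ledger`).
#' @examples
#' g <- simulate_genome(20000, seed = 1)
#' v <- build_vector(seed = 2)
#' cc <- simulate_concatemer(v, copies = 1, flip_prob = 0, seed = 3)
#' res <- implant_events(g, list(insertion_event("chr1", 10000, cc, v, deletion = 500)))
#' nchar(res$genome) - nchar(g)  # insert length minus deletion
#' @export
implant_events <- function(genome, events, seed = NULL) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  if (!is.list(events)) events <- list(events)
  if (!all(vapply(events, inherits, logical(1), "genome_event"))) {
    stop("events must be genome_event objects")
  }
  # overlap check on the source genome
  fp <- do.call(rbind, lapply(seq_along(events), function(i) {
    f <- event_footprint(events[[i]], as.list(genome))
    f$idx <- i
    f
  }))
  for (chrom in unique(fp$chrom)) {
    if (!chrom %in% names(genome)) stop("event on unknown chromosome: ", chrom)
    f <- fp[fp$chrom == chrom, , drop = FALSE]
    if (any(f$end > nchar(genome[[chrom]]))) {
      stop("event interval beyond end of ", chrom)
    }
    if (nrow(f) > 1) {
      o <- order(f$start, f$end)
      f <- f[o, , drop = FALSE]
      for (i in seq_len(nrow(f) - 1)) {
        # zero-length footprints (translocation destinations) may touch
        if (f$start[i + 1] < f$end[i]) {
          stop(sprintf("overlapping events on %s: event %d [%d,%d) and event %d [%d,%d)",
                       chrom, f$idx[i], f$start[i], f$end[i],
                       f$idx[i + 1], f$start[i + 1], f$end[i + 1]))
        }
      }
    }
  }
  ops <- do.call(rbind, lapply(seq_along(events), function(i) {
    event_ops(events[[i]], i, as.list(genome))
  }))
  ops$op_id <- seq_len(nrow(ops))
  derived <- genome
  ops$der_start <- NA_real_; ops$der_end <- NA_real_
  for (chrom in unique(ops$chrom)) {
    idx <- which(ops$chrom == chrom)
    idx <- idx[order(ops$src_start[idx], ops$src_end[idx])]
    src <- genome[[chrom]]
    pieces <- character(0)
    cursor <- 0
    offset <- 0
    for (i in idx) {
      s <- ops$src_start[i]; e <- ops$src_end[i]
      pieces <- c(pieces, subseq0(src, cursor, s), ops$replacement[i])
      ops$der_start[i] <- s + offset
      ops$der_end[i] <- s + offset + nchar(ops$replacement[i])
      offset <- offset + nchar(ops$replacement[i]) - (e - s)
      cursor <- e
    }
    pieces <- c(pieces, subseq0(src, cursor, nchar(src)))
    derived[[chrom]] <- paste(pieces, collapse = "")
  }
  ledger <- structure(
    list(ops = ops[, c("op_id", "event_id", "kind", "chrom", "src_start",
                       "src_end", "der_start", "der_end", "replacement")],
         events = events,
         src_lengths = nchar(genome),
         der_lengths = nchar(derived),
         seed = seed),
    class = "truth_ledger")
  list(genome = derived, ledger = ledger)
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat(sprintf("<truth_ledger> %d event(s), %d operation(s)\n",
              length(x$events), nrow(x$ops)))
  print(x$ops[, setdiff(names(x$ops), "replacement")])
  invisible(x)
}

#' Re-apply a truth ledger's events to a source genome
#'
#' @param genome The source genome the ledger was built from.
#' @param ledger A `truth_ledger`.
#' @return The derived genome (named character vector).
#' @export
apply_ledger <- function(genome, ledger) {
  stopifnot(inherits(ledger, "truth_ledger"))
  implant_events(genome, ledger$events)$genome
}

#' Verify that a derived genome matches its truth ledger
#'
#' Checks that every ledger operation's derived interval contains exactly
#' the implanted sequence.
#'
#' @param derived Derived genome (named character vector).
#' @param ledger A `truth_ledger`.
#' @return `TRUE` invisibly; otherwise stops with the first mismatch.
#' @export
check_ledger <- function(derived, ledger) {
  stopifnot(inherits(ledger, "truth_ledger"))
  ops <- ledger$ops
  for (i in seq_len(nrow(ops))) {
    got <- subseq0(derived[[ops$chrom[i]]], ops$der_start[i], ops$der_end[i])
    if (!identical(got, ops$replacement[i])) {
      stop(sprintf("ledger mismatch at op %d (%s on %s)", ops$op_id[i],
                   ops$kind[i], ops$chrom[i]))
    }
  }
  invisible(TRUE)
}

#' Write a truth ledger as TSV and JSON
#'
#' @param ledger A `truth_ledger`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Paths of the written files, invisibly.
#' @export
write_ledger <- function(ledger, prefix) {
  stopifnot(inherits(ledger, "truth_ledger"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(ledger$ops, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = ledger$seed,
         src_lengths = as.list(ledger$src_lengths),
         der_lengths = as.list(ledger$der_lengths),
         ops = ledger$ops),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
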