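# Locus clustering, deletion calls, rearrangement classification and the
# coordinate arithmetic used in reporting.

#' Cluster per-query insertion evidence into loci
#'
#' Merges genomic anchors that lie within `merge_window` of each other on
#' the same chromosome into one insertion locus, counting supporting
#' queries and a zygosity hint (the fraction of locus-spanning queries
#' that carry no vector sequence).
#'
#' @param evidence `data.frame` with one row per query carrying columns
#'   `query_id`, `chrom`, `left_anchor`, `right_anchor` (either may be
#'   `NA`) and optionally `has_vector` (default `TRUE`). Architectures
#'   from [summarize_architecture()] can be converted with
#'   [architecture_evidence()].
#' @param merge_window Anchors closer than this are merged (bp).
#' @return `data.frame` of loci: `chrom`, `left_anchor`, `right_anchor`,
#'   `insert_len` (medians across supporting queries), `n_support`,
#'   `zygosity_hint`, `queries` (comma-separated ids).
#' @export
cluster_to_loci <- function(evidence, merge_window = 500) {
  evidence <- as.data.frame(evidence)
  stopifnot(all(c("query_id", "chrom") %in% names(evidence)))
  if (is.null(evidence$has_vector)) evidence$has_vector <- TRUE
  pos <- ifelse(is.na(evidence$left_anchor), evidence$right_anchor,
                ifelse(is.na(evidence$right_anchor), evidence$left_anchor,
                       (evidence$left_anchor + evidence$right_anchor) / 2))
  keep <- !is.na(pos)
  evidence <- evidence[keep, , drop = FALSE]
  pos <- pos[keep]
  if (!nrow(evidence)) {
    return(data.frame(chrom = character(), left_anchor = numeric(),
                      right_anchor = numeric(), insert_len = numeric(),
                      n_support = integer(), zygosity_hint = numeric(),
                      queries = character()))
  }
  out <- list()
  for (chrom in unique(evidence$chrom)) {
    idx <- which(evidence$chrom == chrom)
    idx <- idx[order(pos[idx])]
    grp <- cumsum(c(1, diff(pos[idx]) > merge_window))
    for (g in split(idx, grp)) {
      e <- evidence[g, , drop = FALSE]
      vecq <- e[e$has_vector, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom,
        left_anchor = stats::median(vecq$left_anchor, na.rm = TRUE),
        right_anchor = stats::median(vecq$right_anchor, na.rm = TRUE),
        insert_len = if (is.null(vecq$insert_len)) NA_real_ else {
          stats::median(vecq$insert_len, na.rm = TRUE)
        },
        n_support = nrow(vecq),
        zygosity_hint = mean(!e$has_vector),
        queries = paste(e$query_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$left_anchor), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Convert architectures to locus evidence rows
#'
#' @param architectures List of `insertion_architecture` objects.
#' @return `data.frame` suitable for [cluster_to_loci()].
#' @export
architecture_evidence <- function(architectures) {
  if (inherits(architectures, "insertion_architecture")) {
    architectures <- list(architectures)
  }
  do.call(rbind, lapply(architectures, function(a) {
    data.frame(query_id = a$query_id, chrom = a$chrom,
               left_anchor = a$left_anchor, right_anchor = a$right_anchor,
               insert_len = if (a$open_ended) NA_real_ else a$total_insert_len,
               has_vector = TRUE, stringsAsFactors = FALSE)
  }))
}

#' Insertion-site deletion length of a locus
#'
#' The deletion is the distance between the two genomic anchors
#' (0-based): 0 means a clean insertion; a negative distance is reported
#' as a target-site duplication of that size (attribute `tsd`).
#'
#' @param locus One row of the [cluster_to_loci()] output (or any list
#'   with `left_anchor` and `right_anchor`).
#' @return Deletion length in bp (`NA` with attribute `open_ended` for
#'   single-anchor loci).
#' @examples
#' call_deletion(list(left_anchor = 18864678, right_anchor = 18870175))
#' @export
call_deletion <- function(locus) {
  la <- locus$left_anchor; ra <- locus$right_anchor
  if (is.null(la) || is.null(ra) || is.na(la) || is.na(ra)) {
    return(structure(NA_real_, open_ended = TRUE))
  }
  d <- ra - la
  if (d < 0) structure(d, tsd = abs(d)) else d
}

#' Genomic span length in the printed unit
#'
#' Computes `end - start` (the convention under which a printed pair of
#' 1-based coordinates yields the printed length) and converts to the
#' requested unit with the reporting precision: integer bp, nearest
#' integer kb, two-decimal Mb.
#'
#' @param start,end Coordinates with `end >= start` (either both 1-based
#'   printed or both 0-based internal; the difference is invariant).
#' @param unit `"bp"`, `"kb"` or `"Mb"`.
#' @return Length in the requested unit.
#' @examples
#' span_length(18864678, 18870175)          # 5497
#' span_length(11703634, 12215749, "kb")    # 512
#' span_length(8902305, 10095395, "Mb")     # 1.19
#' @export
span_length <- function(start, end, unit = c("bp", "kb", "Mb")) {
  unit <- match.arg(unit)
  if (any(end < start)) stop("end must be >= start")
  len <- end - start
  switch(unit,
         bp = len,
         kb = round(len / 1e3),
         Mb = round(len / 1e6, 2))
}

#' Percentage as printed in summary text
#'
#' @param k,n Numerator and denominator counts.
#' @return `100 * k / n` rounded to the nearest integer.
#' @examples
#' report_percent(38, 46)  # 83
#' @export
report_percent <- function(k, n) {
  stopifnot(n > 0, k >= 0)
  round(100 * k / n)
}

#' Classify large rearrangements from split contig alignments
#'
#' Walks the ordered genomic blocks of each contig annotation and
#' classifies non-colinear joins:
#' * a same-chromosome block in reversed orientation whose interval is
#'   contiguous with both flanks: `inversion`;
#' * a same-chromosome displaced block framed by flanks that are
#'   contiguous with each other: `intra_translocation` (with `inverted`
#'   flag and `destination`);
#' * a join between two chromosomes where the contig's outermost blocks
#'   reach both chromosome ends: `arm_swap`; otherwise
#'   `inter_translocation`;
#' * a single-block contig whose interval matches (within `tol`) a
#'   fragment skipped at another contig's join: `unplaced_fragment`.
#'
#' @param annotations List of `segment_annotation` objects (contigs).
#' @param chrom_lengths Named numeric vector of reference chromosome
#'   lengths (required for the arm-swap terminal test).
#' @param tol Coordinate tolerance for contiguity tests (bp).
#' @param terminal_tol How close (bp) a block must reach a chromosome
#'   end to count as terminal.
#' @return `data.frame` of calls: `kind`, `chrom`, `start`, `end`,
#'   `chrom2`, `pos2`, `destination`, `inverted`, `query_id`.
#' @export
classify_rearrangement <- function(annotations, chrom_lengths = NULL,
                                   tol = 1000, terminal_tol = 10000) {
  if (inherits(annotations, "segment_annotation")) annotations <- list(annotations)
  calls <- list()
  gaps <- list()   # fragments skipped at joins, for unplaced matching
  singles <- list()
  emit <- function(kind, chrom, start = NA, end = NA, chrom2 = NA,
                   pos2 = NA, destination = NA, inverted = FALSE, query_id) {
    calls[[length(calls) + 1]] <<- data.frame(
      kind = kind, chrom = chrom, start = start, end = end, chrom2 = chrom2,
      pos2 = pos2, destination = destination, inverted = inverted,
      query_id = query_id, stringsAsFactors = FALSE)
  }
  for (ann in annotations) {
    ann <- normalize_annotation(ann)
    g <- ann$blocks[ann$blocks$label == "genomic", , drop = FALSE]
    if (nrow(g) == 1) {
      singles[[length(singles) + 1]] <-
        data.frame(chrom = g$target, start = g$tstart, end = g$tend,
                   query_id = ann$query_id, stringsAsFactors = FALSE)
      next
    }
    if (nrow(g) < 2) next
    i <- 1
    while (i < nrow(g)) {
      a <- g[i, ]; b <- g[i + 1, ]
      if (a$target == b$target && a$orientation == b$orientation &&
          abs(join_gap(a, b)) <= tol) { i <- i + 1; next }   # colinear
      # inversion: middle block flipped, contiguous with both flanks
      if (i + 2 <= nrow(g)) {
        cc <- g[i + 2, ]
        if (a$target == b$target && b$target == cc$target &&
            a$orientation == cc$orientation && b$orientation != a$orientation &&
            abs(b$tstart - a$tend) <= tol && abs(cc$tstart - b$tend) <= tol) {
          emit("inversion", a$target, b$tstart, b$tend, query_id = ann$query_id)
          i <- i + 2; next
        }
        # intra-chromosomal translocation: displaced middle block, flanks
        # contiguous with each other
        if (a$target == b$target && b$target == cc$target &&
            a$orientation == cc$orientation &&
            abs(cc$tstart - a$tend) <= tol &&
            (abs(b$tstart - a$tend) > tol || b$orientation != a$orientation)) {
          emit("intra_translocation", a$target, b$tstart, b$tend,
               destination = a$tend, inverted = b$orientation != a$orientation,
               query_id = ann$query_id)
          gaps[[length(gaps) + 1]] <- data.frame(chrom = b$target,
                                                 start = b$tstart, end = b$tend)
          i <- i + 2; next
        }
      }
      if (a$target != b$target) {
        # inter-chromosomal join at a$tend (on a's chrom) / b$tstart (b's)
        terminal <- FALSE
        if (!is.null(chrom_lengths)) {
          first <- g[1, ]; last <- g[nrow(g), ]
          reach_start <- first$tstart <= terminal_tol
          reach_end <- abs(last$tend - chrom_lengths[[last$target]]) <= terminal_tol
          terminal <- isTRUE(reach_start && reach_end)
        }
        kind <- if (terminal) "arm_swap" else "inter_translocation"
        emit(kind, a$target, start = a$tend, chrom2 = b$target,
             pos2 = b$tstart, query_id = ann$query_id)
        i <- i + 1; next
      }
      # same chromosome, colinear but with a skipped fragment: excision
      # gap (not itself a rearrangement call; recorded for unplaced
      # fragment matching), or displaced 2-block join
      if (a$orientation == b$orientation && join_gap(a, b) > tol) {
        gaps[[length(gaps) + 1]] <- data.frame(chrom = a$target,
                                               start = a$tend, end = b$tstart)
      } else {
        emit("intra_translocation", a$target, b$tstart, b$tend,
             destination = a$tend, inverted = b$orientation != a$orientation,
             query_id = ann$query_id)
      }
      i <- i + 1
    }
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else NULL
  for (s in singles) {
    if (is.null(gaps)) next
    hit <- gaps$chrom == s$chrom &
      abs(gaps$start - s$start) <= tol & abs(gaps$end - s$end) <= tol
    if (any(hit)) {
      emit("unplaced_fragment", s$chrom, s$start, s$end, query_id = s$query_id)
    }
  }
  if (!length(calls)) {
    return(data.frame(kind = character(), chrom = character(), start = numeric(),
                      end = numeric(), chrom2 = character(), pos2 = numeric(),
                      destination = numeric(), inverted = logical(),
                      query_id = character()))
  }
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}

# signed reference gap between consecutive same-orientation blocks
join_gap <- function(a, b) {
  if (a$orientation == "+") b$tstart - a$tend else a$tstart - b$tend
}

# deduplication key: kind plus the unordered set of breakpoint coords
call_key <- function(calls) {
  vapply(seq_len(nrow(calls)), function(i) {
    cc <- calls[i, ]
    coords <- sort(stats::na.omit(c(cc$start, cc$end, cc$pos2, cc$destination)))
    chroms <- sort(stats::na.omit(c(cc$chrom, cc$chrom2)))
    paste(cc$kind, paste(chroms, collapse = "|"),
          paste(round(coords / 100), collapse = "|"))
  }, character(1))
}

#' Count insertions and rearrangements per sample
#'
#' Totals the summary statistics reported per line: number of insertion
#' loci, number of distinct rearrangements (reciprocal contigs of the
#' same arm swap count once; deduplication keys on the unordered set of
#' breakpoints), and the maximum insertion size over assembled
#' architectures and optical size estimates.
#'
#' @param loci Locus table from [cluster_to_loci()].
#' @param calls Rearrangement calls from [classify_rearrangement()].
#' @param insert_sizes Numeric vector of insertion sizes (bp) from
#'   architectures and/or optical estimates.
#' @return List with `n_insertions`, `n_rearrangements`,
#'   `max_insertion_size`.
#' @export
count_events <- function(loci, calls, insert_sizes = numeric(0)) {
  n_ins <- if (is.null(loci)) 0L else nrow(loci)
  n_re <- if (is.null(calls) || nrow(calls) == 0) 0L else {
    length(unique(call_key(calls)))
  }
  list(n_insertions = n_ins, n_rearrangements = n_re,
       max_insertion_size = if (length(insert_sizes)) max(insert_sizes) else 0)
}

#' Write rearrangement calls as minimal VCF-like records
#'
#' Emits one record per call with `SVTYPE` (`INS`/`INV`/`BND`), `END`
#' and `SVLEN` INFO keys, for interoperability with SV tooling.
#'
#' @param loci Insertion loci (may be `NULL`).
#' @param calls Rearrangement calls (may be `NULL`).
#' @param path Output path.
#' @param insert_sizes Optional insert sizes matching `loci` rows.
#' @return The path, invisibly.
#' @export
write_sv_vcf <- function(loci, calls, path, insert_sizes = NULL) {
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
             "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  n <- 0
  if (!is.null(loci) && nrow(loci)) {
    for (i in seq_len(nrow(loci))) {
      n <- n + 1
      svlen <- if (!is.null(insert_sizes) && length(insert_sizes) >= i) {
        round(insert_sizes[i])
      } else NA
      info <- sprintf("SVTYPE=INS;END=%d%s", round(loci$right_anchor[i]),
                      if (is.na(svlen)) "" else sprintf(";SVLEN=%d", svlen))
      lines <- c(lines, sprintf("%s\t%d\tins%d\tN\t<INS>\t.\tPASS\t%s",
                                loci$chrom[i], round(loci$left_anchor[i]) + 1L,
                                n, info))
    }
  }
  if (!is.null(calls) && nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      n <- n + 1
      cc <- calls[i, ]
      if (cc$kind == "inversion") {
        lines <- c(lines, sprintf(
          "%s\t%d\tinv%d\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=%d;SVLEN=%d",
          cc$chrom, round(cc$start) + 1L, n, round(cc$end),
          round(cc$end - cc$start)))
      } else {
        pos2 <- c(cc$pos2, cc$destination, cc$end, 0)
        pos2 <- pos2[!is.na(pos2)][1]
        alt <- sprintf("N[%s:%d[", if (!is.na(cc$chrom2)) cc$chrom2 else cc$chrom,
                       round(pos2) + 1L)
        lines <- c(lines, sprintf("%s\t%d\tbnd%d\tN\t%s\t.\tPASS\tSVTYPE=BND",
                                  cc$chrom, round(cc$start) + 1L, n, alt))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
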