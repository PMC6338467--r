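# Segmentation of reads/contigs into genomic / T-strand / backbone /
# linker blocks and per-locus insertion architecture summaries.

#' Segment a query into labelled blocks
#'
#' Resolves overlapping alignment blocks (higher identity wins, then
#' longer block, then vector-coordinate contiguity with the neighbouring
#' block, then lowest target coordinate), relabels vector-derived blocks
#' as `t_strand` or `backbone` by majority overlap with the T-strand
#' interval (blocks straddling the border are cut at it), absorbs
#' inter-block gaps up to `gap_tol` and labels larger gaps `linker`, and
#' records breakpoints where adjacent vector-derived blocks are
#' non-contiguous in vector coordinates by more than `contig_tol` or flip
#' orientation.
#'
#' @param blocks Alignment blocks from [anchor_blocks()] for one query.
#' @param query_len Query length (bp).
#' @param vector The `vector_model` (needed to place the T-strand
#'   boundary); may be `NULL` when no vector blocks are present.
#' @param gap_tol Maximum gap absorbed into the preceding block (bp).
#' @param contig_tol Vector-coordinate contiguity tolerance (bp).
#' @param query_id Identifier recorded in the annotation.
#' @return An object of class `segment_annotation` with fields
#'   `query_id`, `query_len`, `blocks` (tiling `data.frame` with `label`
#'   in genomic/t_strand/backbone/linker), `breakpoints` (query
#'   positions) and `n_breakpoints`.
#' @export
segment_sequence <- function(blocks, query_len, vector = NULL,
                             gap_tol = 25, contig_tol = 25,
                             query_id = "query") {
  blocks <- as.data.frame(blocks)
  if (nrow(blocks) == 0) {
    tiles <- data.frame(qstart = 0, qend = query_len, label = "linker",
                        target = NA_character_, tstart = NA_real_,
                        tend = NA_real_, orientation = NA_character_,
                        identity = NA_real_, stringsAsFactors = FALSE)
    if (query_len == 0) tiles <- tiles[0, ]
    return(structure(list(query_id = query_id, query_len = query_len,
                          blocks = tiles, breakpoints = numeric(0),
                          n_breakpoints = 0L),
                     class = "segment_annotation"))
  }
  sel <- resolve_overlaps(blocks, contig_tol)
  sel <- relabel_vector_blocks(sel, vector, contig_tol)
  sel <- sel[order(sel$qstart), , drop = FALSE]
  tiles <- tile_query(sel, query_len, gap_tol)
  bp <- vector_breakpoints(tiles, contig_tol)
  structure(list(query_id = query_id, query_len = query_len, blocks = tiles,
                 breakpoints = bp, n_breakpoints = length(bp)),
            class = "segment_annotation")
}

# Greedy selection of non-overlapping blocks by (identity, length,
# contiguity with already-chosen neighbours, lowest target coordinate).
resolve_overlaps <- function(blocks, contig_tol) {
  blocks$len <- blocks$qend - blocks$qstart
  o <- order(-round(blocks$identity, 6), -blocks$len, blocks$tstart)
  blocks <- blocks[o, , drop = FALSE]
  # among candidates equal on (identity, length) covering the same query
  # span, prefer the one contiguous in target coordinates with an
  # already-accepted neighbour (handles exact repeats such as a
  # duplicated terminator)
  accepted <- blocks[0, , drop = FALSE]
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, , drop = FALSE]
    ties <- which(blocks$qstart == b$qstart & blocks$qend == b$qend &
                    round(blocks$identity, 6) == round(b$identity, 6) &
                    blocks$target == b$target)
    if (length(ties) > 1 && nrow(accepted) > 0) {
      contig <- vapply(ties, function(j) {
        any(abs(blocks$tstart[j] - accepted$tend) <= contig_tol |
              abs(accepted$tstart - blocks$tend[j]) <= contig_tol)
      }, logical(1))
      if (any(contig)) b <- blocks[ties[which(contig)[1]], , drop = FALSE]
    }
    if (nrow(accepted) > 0) {
      ov <- interval_overlap(b$qstart, b$qend, accepted$qstart, accepted$qend)
      if (sum(ov) > 0.5 * b$len) next
      # trim the lower-priority block away from accepted ones
      for (j in which(ov > 0)) {
        a <- accepted[j, ]
        if (b$qstart < a$qstart) {
          d <- b$qend - a$qstart
          b <- shrink_block(b, right = d)
        } else {
          d <- a$qend - b$qstart
          b <- shrink_block(b, left = d)
        }
        if (b$qend - b$qstart <= 0) break
      }
      if (b$qend - b$qstart <= 0) next
      if (any(interval_overlap(b$qstart, b$qend, accepted$qstart, accepted$qend) > 0)) next
    }
    accepted <- rbind(accepted, b)
  }
  accepted$len <- NULL
  accepted
}

shrink_block <- function(b, left = 0, right = 0) {
  left <- max(0, left); right <- max(0, right)
  b$qstart <- b$qstart + left
  b$qend <- b$qend - right
  if (b$orientation == "+") {
    b$tstart <- b$tstart + left
    b$tend <- b$tend - right
  } else {
    b$tstart <- b$tstart + right
    b$tend <- b$tend - left
  }
  b
}

relabel_vector_blocks <- function(blocks, vector, contig_tol) {
  blocks$label <- ifelse(blocks$side == "genome", "genomic", NA_character_)
  vb <- which(blocks$side == "vector")
  if (!length(vb)) return(blocks)
  if (is.null(vector)) stop("vector model required to label vector-derived blocks")
  ts <- vector$t_strand
  boundary <- ts[2]
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, , drop = FALSE]
    if (b$side != "vector") { out[[length(out) + 1]] <- b; next }
    straddle <- b$tstart < boundary && b$tend > boundary &&
      min(boundary - b$tstart, b$tend - boundary) > contig_tol
    if (straddle) {
      left_len <- boundary - b$tstart
      b1 <- b; b2 <- b
      b1$tend <- boundary; b2$tstart <- boundary
      if (b$orientation == "+") {
        b1$qend <- b$qstart + left_len
        b2$qstart <- b1$qend
      } else {
        b2$qend <- b$qstart + (b$tend - boundary)
        b1$qstart <- b2$qend
        # query order: the piece with higher vector coords comes first
        tmp <- b1; b1 <- b2; b2 <- tmp
      }
      b1$label <- if (mid(b1$tstart, b1$tend) < boundary) "t_strand" else "backbone"
      b2$label <- if (mid(b2$tstart, b2$tend) < boundary) "t_strand" else "backbone"
      out[[length(out) + 1]] <- b1
      out[[length(out) + 1]] <- b2
    } else {
      ov <- interval_overlap(b$tstart, b$tend, ts[1], ts[2])
      b$label <- if (ov >= (b$tend - b$tstart) / 2) "t_strand" else "backbone"
      out[[length(out) + 1]] <- b
    }
  }
  do.call(rbind, out)
}

mid <- function(a, b) (a + b) / 2

tile_query <- function(sel, query_len, gap_tol) {
  sel <- sel[order(sel$qstart), , drop = FALSE]
  tiles <- list()
  cursor <- 0
  for (i in seq_len(nrow(sel))) {
    b <- sel[i, , drop = FALSE]
    gap <- b$qstart - cursor
    if (gap > gap_tol) {
      tiles[[length(tiles) + 1]] <-
        data.frame(qstart = cursor, qend = b$qstart, label = "linker",
                   target = NA_character_, tstart = NA_real_, tend = NA_real_,
                   orientation = NA_character_, identity = NA_real_,
                   stringsAsFactors = FALSE)
    } else if (gap > 0) {
      b$qstart <- cursor  # absorb small gap into this block's query span
    }
    tiles[[length(tiles) + 1]] <-
      b[, c("qstart", "qend", "label", "target", "tstart", "tend",
            "orientation", "identity")]
    cursor <- b$qend
  }
  tail_gap <- query_len - cursor
  if (tail_gap > gap_tol) {
    tiles[[length(tiles) + 1]] <-
      data.frame(qstart = cursor, qend = query_len, label = "linker",
                 target = NA_character_, tstart = NA_real_, tend = NA_real_,
                 orientation = NA_character_, identity = NA_real_,
                 stringsAsFactors = FALSE)
  } else if (tail_gap > 0) {
    tiles[[length(tiles)]]$qend <- query_len
  }
  res <- do.call(rbind, tiles)
  rownames(res) <- NULL
  res
}

vector_breakpoints <- function(tiles, contig_tol) {
  vec <- which(tiles$label %in% c("t_strand", "backbone"))
  if (length(vec) < 2) return(numeric(0))
  bp <- numeric(0)
  for (j in seq_len(length(vec) - 1)) {
    i1 <- vec[j]; i2 <- vec[j + 1]
    # only linker tiles may intervene between "adjacent" vector blocks
    between <- if (i2 - i1 > 1) (i1 + 1):(i2 - 1) else integer(0)
    if (length(between) && any(tiles$label[between] != "linker")) next
    a <- tiles[i1, ]; b <- tiles[i2, ]
    if (a$orientation != b$orientation) {
      bp <- c(bp, b$qstart)
      next
    }
    vgap <- if (a$orientation == "+") b$tstart - a$tend else a$tstart - b$tend
    if (abs(vgap) > contig_tol) bp <- c(bp, b$qstart)
  }
  bp
}

#' @export
print.segment_annotation <- function(x, ...) {
  cat(sprintf("<segment_annotation> %s (%d bp), %d block(s), %d breakpoint(s)\n",
              x$query_id, x$query_len, nrow(x$blocks), x$n_breakpoints))
  print(x$blocks)
  invisible(x)
}

#' Write segment annotations as a BED-like TSV
#'
#' @param annotations A `segment_annotation` or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  if (inherits(annotations, "segment_annotation")) annotations <- list(annotations)
  rows <- lapply(annotations, function(a) {
    cbind(query = a$query_id, a$blocks)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# flip an annotation so that its genomic blocks read plus-strand
normalize_annotation <- function(ann) {
  g <- ann$blocks$label == "genomic"
  if (!any(g)) return(ann)
  if (sum(ann$blocks$orientation[g] == "-", na.rm = TRUE) <=
      sum(ann$blocks$orientation[g] == "+", na.rm = TRUE)) {
    return(ann)
  }
  b <- ann$blocks
  L <- ann$query_len
  qs <- L - b$qend
  b$qend <- L - b$qstart
  b$qstart <- qs
  b$orientation <- c("+" = "-", "-" = "+")[b$orientation]
  b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  rownames(b) <- NULL
  ann$blocks <- b
  ann$breakpoints <- sort(L - ann$breakpoints)
  ann
}

#' Summarize the insertion architecture at one locus
#'
#' Combines the segment annotation of a read/contig spanning (or
#' reaching into) an insertion locus into an architecture record: the
#' genomic anchors on both sides, the insertion-site deletion, the
#' ordered vector-derived segments with orientation, the total insert
#' length, and the border identity and truncation at each junction.
#' Annotations with only one genomic flank are flagged open-ended.
#'
#' @param annotations A `segment_annotation`, or a list of them from the
#'   same locus (the most informative one — both flanks, most vector
#'   sequence — is used).
#' @param vector The `vector_model`.
#' @return An object of class `insertion_architecture`.
#' @export
summarize_architecture <- function(annotations, vector) {
  if (inherits(annotations, "segment_annotation")) annotations <- list(annotations)
  stopifnot(length(annotations) > 0, inherits(vector, "vector_model"))
  anns <- lapply(annotations, normalize_annotation)
  score <- vapply(anns, function(a) {
    v <- a$blocks$label %in% c("t_strand", "backbone")
    if (!any(v)) return(-Inf)
    flanks <- n_flanks(a)
    1e9 * flanks + sum(a$blocks$qend[v] - a$blocks$qstart[v])
  }, numeric(1))
  if (all(!is.finite(score))) stop("not an insertion locus: no vector-derived block")
  ann <- anns[[which.max(score)]]
  b <- ann$blocks
  vec_idx <- which(b$label %in% c("t_strand", "backbone"))
  first_v <- min(vec_idx); last_v <- max(vec_idx)
  gen_before <- which(b$label == "genomic" & seq_len(nrow(b)) < first_v)
  gen_after <- which(b$label == "genomic" & seq_len(nrow(b)) > last_v)
  left <- if (length(gen_before)) b[max(gen_before), ] else NULL
  right <- if (length(gen_after)) b[min(gen_after), ] else NULL
  anchor_of <- function(fl, side) {
    if (is.null(fl)) return(NA_real_)
    if (side == "left") {
      if (fl$orientation == "+") fl$tend else fl$tstart
    } else {
      if (fl$orientation == "+") fl$tstart else fl$tend
    }
  }
  left_anchor <- anchor_of(left, "left")
  right_anchor <- anchor_of(right, "right")
  chrom <- if (!is.null(left)) left$target else if (!is.null(right)) right$target else NA
  open_ended <- is.null(left) || is.null(right)
  # insert span on the query: between the inner flank edges
  span_lo <- if (!is.null(left)) left$qend else min(b$qstart[vec_idx])
  span_hi <- if (!is.null(right)) right$qstart else max(b$qend[vec_idx])
  inner <- b[b$qstart >= span_lo & b$qend <= span_hi, , drop = FALSE]
  seg_rows <- inner[inner$label %in% c("t_strand", "backbone"), , drop = FALSE]
  linker_len <- sum(inner$qend[inner$label == "linker"] -
                      inner$qstart[inner$label == "linker"])
  segments <- data.frame(source = seg_rows$label,
                         vstart = seg_rows$tstart, vend = seg_rows$tend,
                         orientation = seg_rows$orientation,
                         length = seg_rows$qend - seg_rows$qstart,
                         stringsAsFactors = FALSE)
  total <- span_hi - span_lo
  stopifnot(total == sum(segments$length) + linker_len)
  bl <- junction_border(seg_rows[1, , drop = FALSE], vector, side = "left")
  br <- junction_border(seg_rows[nrow(seg_rows), , drop = FALSE], vector, side = "right")
  deletion_len <- if (open_ended) NA_real_ else right_anchor - left_anchor
  structure(list(chrom = chrom, left_anchor = left_anchor,
                 right_anchor = right_anchor, deletion_len = deletion_len,
                 segments = segments, linker_len = linker_len,
                 total_insert_len = total,
                 border_at_left = bl$border, lb_truncation_left = bl$missing,
                 border_at_right = br$border, lb_truncation_right = br$missing,
                 n_breakpoints = sum(ann$breakpoints > span_lo & ann$breakpoints <= span_hi),
                 open_ended = open_ended,
                 query_id = ann$query_id),
            class = "insertion_architecture")
}

n_flanks <- function(a) {
  b <- a$blocks
  v <- which(b$label %in% c("t_strand", "backbone"))
  if (!length(v)) return(0L)
  sum(any(b$label == "genomic" & seq_len(nrow(b)) < min(v)),
      any(b$label == "genomic" & seq_len(nrow(b)) > max(v)))
}

# border identity and truncation at a junction-adjacent segment
junction_border <- function(seg, vector, side) {
  if (nrow(seg) == 0 || seg$label != "t_strand") {
    return(list(border = "none", missing = NA_real_))
  }
  outward <- if (side == "left") {
    if (seg$orientation == "+") seg$tstart else seg$tend
  } else {
    if (seg$orientation == "+") seg$tend else seg$tstart
  }
  d_lb <- abs(outward - vector$lb[1])
  d_rb <- abs(vector$rb[2] - outward)
  if (d_lb <= d_rb) {
    list(border = "LB", missing = outward - vector$lb[1])
  } else {
    list(border = "RB", missing = vector$rb[2] - outward)
  }
}

#' @export
print.insertion_architecture <- function(x, ...) {
  cat(sprintf("<insertion_architecture> %s:%s-%s%s\n", x$chrom,
              format(x$left_anchor, big.mark = ","),
              format(x$right_anchor, big.mark = ","),
              if (x$open_ended) " (open-ended)" else ""))
  cat(sprintf("  deletion: %s bp, insert: %s bp (%d segment(s) + %d bp linker), %d breakpoint(s)\n",
              format(x$deletion_len, big.mark = ","),
              format(x$total_insert_len, big.mark = ","),
              nrow(x$segments), x$linker_len, x$n_breakpoints))
  cat(sprintf("  borders: left %s (%s bp missing), right %s (%s bp missing)\n",
              x$border_at_left, format(x$lb_truncation_left),
              x$border_at_right, format(x$lb_truncation_right)))
  print(x$segments)
  invisible(x)
}

#' Border truncation at each junction of an architecture
#'
#' Reports, for the left and right genome/insert junction, which border
#' repeat (LB or RB) the junction-adjacent T-strand segment terminates
#' at and how many bases are missing from that border's outer edge
#' inward. Backbone-adjacent junctions report border `none`.
#'
#' @param architecture An `insertion_architecture`.
#' @param vector The `vector_model` (used to re-derive from the segment
#'   table; defaults to the values stored at summary time).
#' @return `data.frame` with columns `junction`, `border`, `missing`.
#' @export
measure_border_truncation <- function(architecture, vector = NULL) {
  stopifnot(inherits(architecture, "insertion_architecture"))
  if (!is.null(vector)) {
    seg <- architecture$segments
    seg$label <- seg$source
    seg$tstart <- seg$vstart; seg$tend <- seg$vend
    bl <- junction_border(seg[1, , drop = FALSE], vector, "left")
    br <- junction_border(seg[nrow(seg), , drop = FALSE], vector, "right")
  } else {
    bl <- list(border = architecture$border_at_left,
               missing = architecture$lb_truncation_left)
    br <- list(border = architecture$border_at_right,
               missing = architecture$lb_truncation_right)
  }
  data.frame(junction = c("left", "right"),
             border = c(bl$border, br$border),
             missing = c(bl$missing, br$missing),
             stringsAsFactors = FALSE)
}
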