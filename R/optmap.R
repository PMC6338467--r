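# Optical label maps: in-silico nicking, dynamic-programming alignment
# of label patterns with an explicit sizing-error cost model, insertion
# sizing from alignment gap discrepancies, and CMAP/XMAP I/O.

#' Construct a label map
#'
#' An ordered set of nick-label positions along a molecule or assembled
#' map. Positions are 0-based bp offsets, strictly increasing, within
#' `[0, length)`.
#'
#' @param id Map identifier.
#' @param length Molecule/map length in bp.
#' @param labels Numeric vector of label positions.
#' @return An object of class `label_map`.
#' @export
label_map <- function(id, length, labels = numeric(0)) {
  labels <- as.numeric(labels)
  if (any(is.na(labels))) stop("label positions must not be NA")
  if (is.unsorted(labels, strictly = TRUE)) {
    stop("label positions must be strictly increasing")
  }
  if (length(labels) && (labels[1] < 0 || labels[length(labels)] >= length)) {
    stop("label positions must lie in [0, length)")
  }
  structure(list(id = as.character(id), length = as.numeric(length),
                 labels = labels), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s: %.0f bp, %d label(s)\n", x$id, x$length,
              length(x$labels)))
  invisible(x)
}

#' In-silico nicking digest
#'
#' Labels every occurrence of the recognition site on either strand
#' (single-enzyme chemistry labels both orientations); positions are the
#' motif starts, deduplicated and sorted. The fixed nick offset within
#' the site cancels in all inter-label distance arithmetic.
#'
#' @param sequence DNA string.
#' @param site Recognition site (default Nt.BspQI, `GCTCTTC`).
#' @param id Identifier for the returned map.
#' @return A [label_map()].
#' @examples
#' digest("GCTCTTC")$labels  # 0
#' @export
digest <- function(sequence, site = "GCTCTTC", id = "map") {
  if (!nzchar(site)) stop("site must be non-empty")
  subj <- Biostrings::DNAString(sequence)
  fwd <- BiocGenerics::start(Biostrings::matchPattern(site, subj))
  rc <- revcomp(site)
  rev <- BiocGenerics::start(Biostrings::matchPattern(rc, subj))
  pos <- sort(unique(c(fwd, rev))) - 1  # to 0-based
  label_map(id, nchar(sequence), pos)
}

#' Disrupt every occurrence of a nicking site in a sequence
#'
#' Replaces the middle base of each occurrence (either strand) until the
#' sequence carries no label site. Used to build insert sequences that
#' are label-free, emulating transformation vectors that lack the
#' nicking enzyme's recognition site.
#'
#' @param sequence DNA string.
#' @param site Recognition site (default `GCTCTTC`).
#' @return The masked sequence.
#' @export
mask_sites <- function(sequence, site = "GCTCTTC") {
  repeat {
    pos <- digest(sequence, site)$labels
    if (!length(pos)) return(sequence)
    mid <- pos + ceiling(nchar(site) / 2)
    for (p in mid) {
      old <- substr(sequence, p, p)
      new <- c(A = "C", C = "A", G = "T", T = "G")[[old]]
      substr(sequence, p, p) <- new
    }
  }
}

# interval sizing cost: squared relative discrepancy on the larger
# span, capped at the outlier penalty (a robust loss: a true insertion
# or deletion between two labels costs at most `outlier`, so alignments
# bridge real structural variants instead of truncating at them)
sizing_cost <- function(dq, dr, sizing_scale, outlier = Inf) {
  min(((abs(dq - dr)) / (sizing_scale * max(dq, dr, 1)))^2, outlier)
}

#' Align two label maps by dynamic programming
#'
#' Finds the monotone matching of query to reference labels minimizing
#' an explicit cost: for each adjacent matched pair, the squared
#' inter-label distance discrepancy relative to the larger span (scaled
#' by `sizing_scale`), capped at `outlier` so that genuine insertions or
#' deletions between two labels cost a bounded amount and the alignment
#' bridges them; plus `miss_q` per unmatched query label (anywhere: the
#' whole molecule is expected to align) and `miss_r` per unmatched
#' reference label inside the aligned reference span (reference labels
#' outside the span are free: the molecule covers a window of the
#' reference). Skips are bounded at `max_skip` labels per step. Ties are
#' broken deterministically toward more matched pairs, then the smallest
#' pair indices.
#'
#' @param query,ref [label_map()] objects.
#' @param penalties List with `miss_q`, `miss_r`, `sizing_scale`,
#'   `outlier`.
#' @param max_skip Maximum consecutive unmatched labels bridged by one
#'   step (bounds DP complexity at `O(n m max_skip^2)`).
#' @param try_reverse Also align the reversed query (molecules have no
#'   inherent orientation) and keep the better of the two.
#' @return An object of class `map_alignment`: `pairs` (two-column
#'   matrix of 1-based label indices), `cost`, `orientation`,
#'   `unmatched_query`, `unmatched_ref` (indices within the aligned
#'   span), plus the two map ids.
#' @export
align_label_maps <- function(query, ref,
                             penalties = list(miss_q = 10, miss_r = 10,
                                              sizing_scale = 0.05,
                                              outlier = 30),
                             max_skip = 5, try_reverse = FALSE) {
  stopifnot(inherits(query, "label_map"), inherits(ref, "label_map"))
  fwd <- align_label_maps_one(query$labels, ref$labels, penalties, max_skip)
  best <- fwd; orientation <- "+"
  if (try_reverse && length(query$labels) >= 2) {
    qrev <- sort(query$length - rev(query$labels))
    rev_al <- align_label_maps_one(qrev, ref$labels, penalties, max_skip)
    if (rev_al$cost < fwd$cost - 1e-9 ||
        (abs(rev_al$cost - fwd$cost) <= 1e-9 &&
           nrow(rev_al$pairs) > nrow(fwd$pairs))) {
      # map reversed indices back to original query labels
      n <- length(query$labels)
      rev_al$pairs[, 1] <- n + 1L - rev_al$pairs[, 1]
      rev_al$pairs <- rev_al$pairs[rev(seq_len(nrow(rev_al$pairs))), , drop = FALSE]
      best <- rev_al; orientation <- "-"
    }
  }
  structure(list(query_id = query$id, ref_id = ref$id, pairs = best$pairs,
                 cost = best$cost, orientation = orientation,
                 unmatched_query = best$unmatched_query,
                 unmatched_ref = best$unmatched_ref),
            class = "map_alignment")
}

align_label_maps_one <- function(q, r, penalties, max_skip) {
  n <- length(q); m <- length(r)
  miss_q <- penalties$miss_q; miss_r <- penalties$miss_r
  ss <- penalties$sizing_scale
  outl <- penalties$outlier %||% Inf
  empty <- list(pairs = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("q", "r"))),
                cost = if (n) n * miss_q else 0,
                unmatched_query = seq_len(n), unmatched_ref = integer(0))
  if (n < 2 || m < 2) return(empty)
  cost <- matrix(Inf, n, m)     # best cost of alignment ending at pair (i,j)
  npair <- matrix(0L, n, m)
  prev_i <- matrix(0L, n, m); prev_j <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    nii <- min(max_skip + 1, i - 1)
    ii_range <- if (nii > 0) (i - 1):(i - nii) else integer(0)
    dq <- q[i] - q[ii_range]
    for (j in seq_len(m)) {
      # start a new alignment at (i, j): unmatched query labels before i
      best_c <- (i - 1) * miss_q
      best_n <- 1L; bi <- 0L; bj <- 0L
      njj <- min(max_skip + 1, j - 1)
      if (nii > 0 && njj > 0) {
        jj_range <- (j - 1):(j - njj)
        dr <- r[j] - r[jj_range]
        dd <- outer(dq, dr, "-")
        denom <- ss * pmax(outer(dq, dr, pmax), 1)
        step <- pmin((dd / denom)^2, outl) +
          (seq_len(nii) - 1) * miss_q +
          rep((seq_len(njj) - 1) * miss_r, each = nii)
        tot <- cost[ii_range, jj_range, drop = FALSE] + step
        sub_n <- npair[ii_range, jj_range, drop = FALSE]
        # best transition: min cost, ties toward more pairs, then the
        # nearest predecessor (deterministic)
        k <- order(tot, -sub_n)[1]
        if (is.finite(tot[k]) &&
            (tot[k] < best_c - 1e-12 ||
               (tot[k] <= best_c + 1e-12 && sub_n[k] + 1L > best_n))) {
          best_c <- tot[k]; best_n <- sub_n[k] + 1L
          bi <- ii_range[((k - 1) %% nii) + 1]
          bj <- jj_range[((k - 1) %/% nii) + 1]
        }
      }
      cost[i, j] <- best_c
      npair[i, j] <- best_n
      prev_i[i, j] <- bi; prev_j[i, j] <- bj
    }
  }
  # closing: unmatched query labels after the last pair
  final <- cost + (n - row(cost)) * miss_q
  best_val <- min(final)
  # the empty matching is kept only when strictly better (ties prefer
  # more matched pairs)
  if (!is.finite(best_val) || best_val > empty$cost + 1e-12) return(empty)
  cand <- which(final <= best_val + 1e-12, arr.ind = TRUE)
  nb <- npair[cand]
  cand <- cand[order(-nb, cand[, 1], cand[, 2]), , drop = FALSE]
  i <- cand[1, 1]; j <- cand[1, 2]
  pairs <- list()
  while (i > 0) {
    pairs[[length(pairs) + 1]] <- c(i, j)
    ii <- prev_i[i, j]; jj <- prev_j[i, j]
    i <- ii; j <- jj
  }
  pairs <- do.call(rbind, rev(pairs))
  colnames(pairs) <- c("q", "r")
  qspan <- range(pairs[, 1]); rspan <- range(pairs[, 2])
  list(pairs = pairs, cost = best_val,
       unmatched_query = setdiff(seq_len(n), pairs[, 1]),
       unmatched_ref = setdiff(seq(rspan[1], rspan[2]), pairs[, 2]))
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(sprintf("<map_alignment> %s vs %s (%s): %d pair(s), cost %.4g\n",
              x$query_id, x$ref_id, x$orientation, nrow(x$pairs), x$cost))
  invisible(x)
}

#' Exhaustive optimum over all monotone label matchings
#'
#' Brute-force reference implementation of the [align_label_maps()] cost
#' model, enumerating every monotone matching. Exponential; intended for
#' validation on maps with at most ~8 labels each.
#'
#' @inheritParams align_label_maps
#' @return List with `cost` and `npairs` at the optimum.
#' @export
enumerate_label_matchings <- function(query, ref,
                                      penalties = list(miss_q = 10, miss_r = 10,
                                                       sizing_scale = 0.05,
                                                       outlier = 30)) {
  q <- query$labels; r <- ref$labels
  n <- length(q); m <- length(r)
  best <- list(cost = n * penalties$miss_q, npairs = 0L)
  if (n < 2 || m < 2) return(best)
  recurse <- function(i, j, last_i, last_j, cost_so_far, npairs) {
    # prune nothing; maps are tiny
    if (i > n || j > m) {
      tot <- cost_so_far + (n - last_i) * penalties$miss_q
      if (npairs >= 1 &&
          (tot < best$cost - 1e-12 ||
             (tot <= best$cost + 1e-12 && npairs > best$npairs))) {
        best <<- list(cost = tot, npairs = npairs)
      }
      return(invisible(NULL))
    }
    for (ii in i:n) {
      for (jj in j:m) {
        add <- if (npairs == 0) {
          (ii - 1) * penalties$miss_q
        } else {
          sizing_cost(q[ii] - q[last_i], r[jj] - r[last_j],
                      penalties$sizing_scale, penalties$outlier %||% Inf) +
            (ii - i) * penalties$miss_q + (jj - j) * penalties$miss_r
        }
        recurse(ii + 1L, jj + 1L, ii, jj, cost_so_far + add, npairs + 1L)
      }
    }
    # also allow ending here
    tot <- cost_so_far + (n - last_i) * penalties$miss_q
    if (npairs >= 1 &&
        (tot < best$cost - 1e-12 ||
           (tot <= best$cost + 1e-12 && npairs > best$npairs))) {
      best <<- list(cost = tot, npairs = npairs)
    }
    invisible(NULL)
  }
  recurse(1L, 1L, 0L, 0L, 0, 0L)
  best
}

#' Call insertion/deletion sizes from a map alignment
#'
#' For each adjacent matched pair, the discrepancy between the query and
#' reference inter-label distances estimates inserted (positive) or
#' deleted (negative) sequence in that interval. Discrepancies exceeding
#' `min_size` are emitted at the midpoint reference coordinate; runs of
#' adjacent discordant intervals are merged (sizes summed).
#'
#' @param alignment A `map_alignment`.
#' @param query,ref The aligned [label_map()] objects.
#' @param min_size Discordance threshold in bp (default 1500, roughly
#'   the sizing noise at typical inter-label distances).
#' @return `data.frame` with `ref_pos`, `size` (bp, signed) and `type`
#'   (`"insertion"`/`"deletion"`).
#' @export
call_insertion_size <- function(alignment, query, ref, min_size = 1500) {
  stopifnot(inherits(alignment, "map_alignment"))
  p <- alignment$pairs
  out <- data.frame(ref_pos = numeric(0), size = numeric(0),
                    type = character(0))
  if (is.null(p) || nrow(p) < 2) return(out)
  qpos <- query$labels[p[, 1]]
  rpos <- ref$labels[p[, 2]]
  dq <- abs(diff(qpos))
  dr <- abs(diff(rpos))
  disc <- dq - dr
  midpt <- (rpos[-length(rpos)] + rpos[-1]) / 2
  hit <- abs(disc) >= min_size
  if (!any(hit)) return(out)
  idx <- which(hit)
  grp <- cumsum(c(1, diff(idx) > 1))
  rows <- lapply(split(idx, grp), function(g) {
    size <- sum(disc[g])
    data.frame(ref_pos = stats::weighted.mean(midpt[g], abs(disc[g])),
               size = size,
               type = if (size > 0) "insertion" else "deletion")
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
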