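# Exact k-mer seed-and-extend annotator: finds local alignment blocks of
# a query read/contig against the host genome and the transformation
# vector. Seeds are exact k-mer matches; collinear seeds (same diagonal
# within a band) are chained into blocks, merged across small gaps, and
# extended base-wise at the edges. Block identity is estimated from
# exact k-mer survival (identity ~ clean_kmer_fraction^(1/k)): 1.0 for
# exact matches, ~0.94 at 5% read error.

new_block_df <- function() {
  data.frame(qstart = integer(), qend = integer(), target = character(),
             side = character(), tstart = integer(), tend = integer(),
             orientation = character(), identity = numeric(),
             stringsAsFactors = FALSE)
}

#' Build a k-mer anchor index over genome and vector targets
#'
#' Pre-computes the exact k-mer position index used by [anchor_blocks()].
#' Build it once and reuse it across reads.
#'
#' @param genome Named character vector of chromosome sequences (may be
#'   `NULL`).
#' @param vector A `vector_model` or single DNA string (may be `NULL`).
#' @param k Anchor length (>= 11; default 14).
#' @param max_occ K-mers occurring more often than this in a target are
#'   skipped as repeats.
#' @return An object of class `anchor_index`.
#' @export
build_anchor_index <- function(genome = NULL, vector = NULL, k = 14,
                               max_occ = 50) {
  if (k < 11) stop("anchor length k must be >= 11")
  targets <- list()
  if (!is.null(genome)) {
    stopifnot(is.character(genome), !is.null(names(genome)))
    for (chrom in names(genome)) {
      targets[[chrom]] <- list(name = chrom, side = "genome",
                               seq = toupper(genome[[chrom]]))
    }
  }
  if (!is.null(vector)) {
    vseq <- if (inherits(vector, "vector_model")) vector$sequence else toupper(vector)
    targets[["vector"]] <- list(name = "vector", side = "vector", seq = vseq)
  }
  if (!length(targets)) stop("need at least one of genome, vector")
  for (nm in names(targets)) {
    s <- targets[[nm]]$seq
    n <- nchar(s)
    if (n < k) {
      targets[[nm]]$index <- new.env(hash = TRUE, parent = emptyenv())
      next
    }
    kmers <- substring(s, 1:(n - k + 1), k:n)
    pos <- split(0:(n - k), kmers)
    pos <- pos[lengths(pos) <= max_occ]
    targets[[nm]]$index <- list2env(pos, hash = TRUE, parent = emptyenv())
  }
  structure(list(targets = targets, k = k, max_occ = max_occ),
            class = "anchor_index")
}

# seeds for one query strand against one target: data.frame(qpos, tpos)
find_seeds <- function(qseq, target_index, k) {
  m <- nchar(qseq)
  if (m < k) return(NULL)
  qk <- substring(qseq, 1:(m - k + 1), k:m)
  found <- mget(qk, envir = target_index, ifnotfound = list(NULL))
  hitlists <- lapply(seq_along(found), function(i) {
    p <- found[[i]]
    if (is.null(p)) NULL else cbind(qpos = i - 1L, tpos = p)
  })
  hits <- do.call(rbind, hitlists)
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  as.data.frame(hits)
}

# chain seeds into blocks on one strand (coords in the given strand space)
chain_seeds <- function(seeds, k, band, chain_gap) {
  d <- seeds$tpos - seeds$qpos
  o <- order(d, seeds$qpos)
  seeds <- seeds[o, ]
  d <- d[o]
  grp <- cumsum(c(1L, diff(d) > band))
  blocks <- list()
  for (g in split(seq_len(nrow(seeds)), grp)) {
    sub <- seeds[g, ]
    sub <- sub[order(sub$qpos), ]
    # drop duplicate qpos (repeat hits within the band)
    sub <- sub[!duplicated(sub$qpos), ]
    piece <- cumsum(c(1L, diff(sub$qpos) > chain_gap))
    for (p in split(seq_len(nrow(sub)), piece)) {
      ss <- sub[p, ]
      qs <- ss$qpos[1]; qe <- ss$qpos[nrow(ss)] + k
      blocks[[length(blocks) + 1]] <-
        data.frame(qstart = qs, qend = qe,
                   tstart = ss$tpos[1], tend = ss$tpos[nrow(ss)] + k,
                   nseed = nrow(ss))
    }
  }
  do.call(rbind, blocks)
}

merge_blocks <- function(blocks, band, merge_gap) {
  if (is.null(blocks) || nrow(blocks) < 2) return(blocks)
  blocks <- blocks[order(blocks$qstart), ]
  out <- blocks[1, ]
  for (i in 2:nrow(blocks)) {
    b <- blocks[i, ]
    last <- out[nrow(out), ]
    qgap <- b$qstart - last$qend
    tgap <- b$tstart - last$tend
    if (qgap <= merge_gap && qgap >= -band && abs(tgap - qgap) <= band &&
        b$tend > last$tend) {
      out$qend[nrow(out)] <- max(last$qend, b$qend)
      out$tend[nrow(out)] <- b$tend
      out$nseed[nrow(out)] <- last$nseed + b$nseed
    } else {
      out <- rbind(out, b)
    }
  }
  out
}

# X-drop edge extension in strand space: walk outward scoring +1 per
# match and -2 per mismatch, stop when the score drops `xdrop` below
# its running maximum, and place the edge at the maximum. Tolerates
# isolated read errors while halting quickly where sequence genuinely
# diverges (random sequence drifts at -1.25/base).
extend_one_side <- function(qseq, tseq, qpos, tpos, dir, max_extend, xdrop,
                            max_indel = 3L) {
  m <- nchar(qseq); n <- nchar(tseq)
  score <- 0; best <- 0; best_steps <- 0L; steps <- 0L
  shift <- 0L; indels <- 0L; miss_run <- 0L; best_shift <- 0L
  repeat {
    qn <- qpos + dir * (steps + 1L)
    tn <- tpos + dir * (steps + 1L) + shift
    if (steps >= max_extend || qn < 1 || qn > m || tn < 1 || tn > n) break
    hit <- substr(qseq, qn, qn) == substr(tseq, tn, tn)
    if (!hit && indels < max_indel) {
      # a frame shift after an indel mismatches persistently; probe a
      # +/- 1 bp hop in the target and take it if it resumes matching
      for (dlt in c(1L, -1L)) {
        tn2 <- tn + dir * dlt
        qn2 <- qn + dir
        if (tn2 >= 1 && tn2 <= n && qn2 >= 1 && qn2 <= m &&
            substr(qseq, qn, qn) == substr(tseq, tn2, tn2) &&
            substr(qseq, qn2, qn2) == substr(tseq, tn2 + dir, tn2 + dir)) {
          shift <- shift + dir * dlt
          indels <- indels + 1L
          score <- score - 2
          hit <- TRUE
          break
        }
      }
    }
    miss_run <- if (hit) 0L else miss_run + 1L
    score <- score + if (hit) 1 else -2
    steps <- steps + 1L
    if (score > best && miss_run == 0L) {
      best <- score; best_steps <- steps; best_shift <- shift
    }
    if (score < best - xdrop) break
  }
  # query bases consumed, and target bases consumed (differ after hops)
  c(q = best_steps, t = best_steps + dir * best_shift)
}

extend_block <- function(b, qseq, tseq, max_extend = 80, xdrop = 16) {
  left <- extend_one_side(qseq, tseq, b$qstart + 1L, b$tstart + 1L, -1L,
                          max_extend, xdrop)
  b$qstart <- b$qstart - left[["q"]]; b$tstart <- b$tstart - left[["t"]]
  right <- extend_one_side(qseq, tseq, b$qend, b$tend, 1L, max_extend, xdrop)
  b$qend <- b$qend + right[["q"]]; b$tend <- b$tend + right[["t"]]
  b$nseed <- b$nseed + left[["q"]] + right[["q"]]
  b
}

#' Find alignment blocks of a query against genome and vector targets
#'
#' The default internal backend chains exact k-mer matches that are
#' collinear in query and target (within a diagonal band), merges chains
#' separated by small gaps, extends block edges with a gapped X-drop
#' scan (tolerating isolated mismatches and single-base indels), and
#' reports maximal local blocks on both strands of every target.
#'
#' @param query DNA string (read or contig).
#' @param index An `anchor_index` from [build_anchor_index()], or a list
#'   with `genome` and/or `vector` entries to index on the fly.
#' @param min_block Minimum reported block length (bp).
#' @param min_identity Minimum estimated per-base identity in [0, 1]
#'   (estimated from the fraction of query k-mers with an exact anchor
#'   in the block, as that fraction to the power 1/k).
#' @param band Diagonal band width for chaining (bp); also the indel
#'   tolerance when merging adjacent chains.
#' @param chain_gap Maximum seed gap within a chain (bp).
#' @return `data.frame` with columns `qstart`, `qend` (0-based half-open
#'   on the query), `target` (chromosome name or `"vector"`), `side`
#'   (`"genome"`/`"vector"`), `tstart`, `tend`, `orientation`
#'   (`"+"`/`"-"`), `identity`. Queries shorter than `k` yield zero rows.
#' @examples
#' g <- simulate_genome(5000, seed = 1)
#' idx <- build_anchor_index(genome = g)
#' q <- substr(g[["chr1"]], 1001, 3000)
#' anchor_blocks(q, idx)
#' @export
anchor_blocks <- function(query, index, min_block = 100, min_identity = 0.8,
                          band = 25, chain_gap = 200) {
  if (!inherits(index, "anchor_index")) {
    index <- build_anchor_index(genome = index$genome, vector = index$vector)
  }
  k <- index$k
  query <- toupper(query)
  m <- nchar(query)
  if (m < k) return(new_block_df())
  strands <- list(`+` = query, `-` = revcomp(query))
  out <- list()
  for (tname in names(index$targets)) {
    tg <- index$targets[[tname]]
    for (strand in names(strands)) {
      qseq <- strands[[strand]]
      seeds <- find_seeds(qseq, tg$index, k)
      if (is.null(seeds)) next
      blocks <- chain_seeds(seeds, k, band, chain_gap)
      blocks <- merge_blocks(blocks, band, merge_gap = chain_gap)
      if (is.null(blocks)) next
      for (i in seq_len(nrow(blocks))) {
        b <- extend_block(blocks[i, ], qseq, tg$seq)
        len <- b$qend - b$qstart
        # per-base identity inferred from exact k-mer survival: with
        # per-base accuracy a, a fraction ~a^k of k-mers anchor, so
        # a ~ (clean fraction)^(1/k)
        f <- min(1, b$nseed / max(1, len - k + 1))
        identity <- f^(1 / k)
        if (len < min_block || identity < min_identity) next
        if (strand == "+") {
          qs <- b$qstart; qe <- b$qend
        } else {
          qs <- m - b$qend; qe <- m - b$qstart
        }
        out[[length(out) + 1]] <-
          data.frame(qstart = qs, qend = qe, target = tname, side = tg$side,
                     tstart = b$tstart, tend = b$tend, orientation = strand,
                     identity = identity, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(new_block_df())
  res <- do.call(rbind, out)
  res <- res[order(res$qstart, -res$identity, res$tstart), ]
  rownames(res) <- NULL
  res
}
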