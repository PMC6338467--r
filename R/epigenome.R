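# Epigenomic profiling of inserted vector sequence: cytosine context
# classification, binomial methylation calling with FDR control, and
# small-RNA size-class tables per vector element.

#' Classify the methylation context of a cytosine
#'
#' On the given strand, a cytosine followed by G is CG; by H then G is
#' CHG; by two H is CHH (H = A, C or T). Minus-strand positions are
#' evaluated on the reverse complement. Non-cytosine positions, and
#' positions without two downstream bases of context on their strand,
#' return `"none"`. Vectorized over `pos`/`strand`.
#'
#' @param sequence DNA string.
#' @param pos 0-based position(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @return Character vector in `c("CG", "CHG", "CHH", "none")`.
#' @examples
#' classify_context("ACGT", 1, "+")   # CG
#' classify_context("ACAGT", 1, "+")  # CHG
#' @export
classify_context <- function(sequence, pos, strand = "+") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  m <- max(length(pos), length(strand))
  pos <- rep_len(pos, m)
  strand <- rep_len(strand, m)
  if (any(pos < 0 | pos >= n)) stop("pos outside sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep("none", m)
  for (i in seq_len(m)) {
    if (strand[i] == "+") {
      if (chars[pos[i] + 1] != "C") next
      if (pos[i] + 3 > n) next  # needs two downstream bases
      b1 <- chars[pos[i] + 2]; b2 <- chars[pos[i] + 3]
    } else {
      if (chars[pos[i] + 1] != "G") next
      if (pos[i] - 2 < 0) next
      b1 <- comp[[chars[pos[i]]]]
      b2 <- comp[[chars[pos[i] - 1]]]
    }
    out[i] <- if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
  }
  out
}

#' Call methylated cytosines with binomial tests and FDR control
#'
#' Per site, tests the methylated count against the bisulfite
#' non-conversion rate with a one-sided (greater) binomial test —
#' non-conversion can only inflate the methylated count — then applies
#' Benjamini-Hochberg correction across all tested sites. A site is
#' called methylated when its q-value is at most `fdr`.
#'
#' @param counts `data.frame` with columns `pos`, `strand`, `context`,
#'   `count_meth`, `count_total` (e.g. from [simulate_bisulfite()]);
#'   optional `chrom`.
#' @param p0 Non-conversion rate in [0, 1) (default 0.0035).
#' @param fdr FDR level (default 0.01).
#' @return The input with added `p_value`, `q_value` and `status`
#'   columns; sites with zero coverage are dropped (untested).
#' @export
call_methylated_sites <- function(counts, p0 = 0.0035, fdr = 0.01) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("pos", "strand", "context", "count_meth", "count_total")
                %in% names(counts)))
  if (p0 < 0 || p0 >= 1) stop("p0 must be in [0, 1)")
  if (any(counts$count_meth > counts$count_total)) {
    stop("count_meth exceeds count_total")
  }
  counts <- counts[counts$count_total > 0, , drop = FALSE]
  if (!nrow(counts)) {
    counts$p_value <- numeric(0); counts$q_value <- numeric(0)
    counts$status <- character(0)
    return(counts)
  }
  counts$p_value <- stats::pbinom(counts$count_meth - 1, counts$count_total,
                                  p0, lower.tail = FALSE)
  counts$q_value <- stats::p.adjust(counts$p_value, method = "BH")
  counts$status <- ifelse(counts$q_value <= fdr, "methylated", "unmethylated")
  rownames(counts) <- NULL
  counts
}

#' Per-element methylation summaries
#'
#' For each element and the requested context, computes the weighted
#' methylation level (total methylated reads over total reads across the
#' element's sites) and the fraction of tested sites called methylated.
#' Elements with no tested site of that context are reported with `NA`
#' (missing, not zero).
#'
#' @param calls Output of [call_methylated_sites()].
#' @param elements `data.frame` with `name`, `start`, `end` (0-based
#'   half-open, same coordinate system as `calls$pos`), e.g.
#'   `vector$elements`.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @return `data.frame` with `element`, `context`, `n_sites`,
#'   `weighted_level`, `fraction_methylated`.
#' @export
element_methylation <- function(calls, elements, context = c("CHH", "CG", "CHG")) {
  context <- match.arg(context)
  elements <- as.data.frame(elements)
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    s <- calls[calls$pos >= e$start & calls$pos < e$end &
                 calls$context == context, , drop = FALSE]
    if (!nrow(s)) {
      return(data.frame(element = e$name, context = context, n_sites = 0L,
                        weighted_level = NA_real_,
                        fraction_methylated = NA_real_))
    }
    data.frame(element = e$name, context = context, n_sites = nrow(s),
               weighted_level = sum(s$count_meth) / sum(s$count_total),
               fraction_methylated = mean(s$status == "methylated"))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Small-RNA size-class table per vector element
#'
#' Counts reads that match the vector exactly, full-length, with no
#' mismatches or gaps, on either strand. Each counted read contributes
#' once: reads matching multiple vector positions are assigned to the
#' lowest-coordinate match and flagged as multimappers. A read is
#' assigned to the element containing the majority of its matched span.
#' Lengths 15-20 nt are pooled into one class; 21, 22, 23 and 24 nt are
#' separate; reads shorter than 15 or longer than 24 nt are ignored.
#'
#' @param reads Character vector of read sequences (a named vector or a
#'   `DNAStringSet` also works).
#' @param vector A `vector_model`.
#' @param elements Element table (default `vector$elements`).
#' @param word_length Minimum exact seed length of the matcher; reads
#'   shorter than this cannot be matched (default 14, below the 15 nt
#'   class minimum, so all considered reads are matchable).
#' @param by_strand Keep plus/minus counts separate.
#' @param per_kb Normalize counts by element length in kb (default raw
#'   counts).
#' @return A `size_class_table`: integer (or numeric, when `per_kb`)
#'   matrix with one row per element and columns
#'   `15-20`, `21`, `22`, `23`, `24`; attributes `n_counted`,
#'   `n_multimapper`, `n_unassigned`.
#' @export
sirna_size_table <- function(reads, vector, elements = vector$elements,
                             word_length = 14, by_strand = FALSE,
                             per_kb = FALSE) {
  stopifnot(inherits(vector, "vector_model"))
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(unname(reads))
  len <- nchar(reads)
  keep <- len >= max(15, word_length + 1) & len <= 24
  reads <- reads[keep]; len <- len[keep]
  el <- as.data.frame(elements)
  classes <- SIRNA_CLASSES
  row_names <- if (by_strand) {
    as.vector(outer(el$name, c("+", "-"), paste, sep = "/"))
  } else el$name
  tab <- matrix(0L, nrow = length(row_names), ncol = length(classes),
                dimnames = list(row_names, classes))
  n_counted <- 0L; n_multi <- 0L; n_unassigned <- 0L
  if (length(reads)) {
    vseq <- Biostrings::DNAString(vector$sequence)
    vrc <- Biostrings::reverseComplement(vseq)
    L <- nchar(vector$sequence)
    for (ll in sort(unique(len))) {
      idx <- which(len == ll)
      uniq <- unique(reads[idx])
      pd <- Biostrings::PDict(uniq)
      fwd <- Biostrings::matchPDict(pd, vseq)
      rev <- Biostrings::matchPDict(pd, vrc)
      fwd_starts <- lapply(seq_along(uniq), function(i) {
        BiocGenerics::start(fwd[[i]]) - 1L
      })
      rev_starts <- lapply(seq_along(uniq), function(i) {
        # convert a hit on the reverse complement to plus-strand coords
        L - (BiocGenerics::start(rev[[i]]) - 1L) - ll
      })
      for (j in idx) {
        u <- match(reads[j], uniq)
        hits <- rbind(
          if (length(fwd_starts[[u]])) cbind(pos = fwd_starts[[u]], strand = 1L),
          if (length(rev_starts[[u]])) cbind(pos = rev_starts[[u]], strand = 2L))
        if (is.null(hits) || nrow(hits) == 0) next
        if (nrow(hits) > 1) n_multi <- n_multi + 1L
        best <- hits[order(hits[, "pos"], hits[, "strand"]), , drop = FALSE][1, ]
        pos <- best[["pos"]]
        ov <- interval_overlap(pos, pos + ll, el$start, el$end)
        if (max(ov) <= ll / 2) { n_unassigned <- n_unassigned + 1L; next }
        ei <- which.max(ov)
        cls <- if (ll <= 20) "15-20" else as.character(ll)
        row <- if (by_strand) {
          paste(el$name[ei], c("+", "-")[best[["strand"]]], sep = "/")
        } else el$name[ei]
        tab[row, cls] <- tab[row, cls] + 1L
        n_counted <- n_counted + 1L
      }
    }
  }
  if (per_kb) {
    kb <- (el$end - el$start) / 1000
    if (by_strand) kb <- rep(kb, 2)
    tab <- tab / kb
  }
  structure(tab, class = c("size_class_table", class(tab)),
            n_counted = n_counted, n_multimapper = n_multi,
            n_unassigned = n_unassigned)
}

#' @export
print.size_class_table <- function(x, ...) {
  cat(sprintf("<size_class_table> %d read(s) counted (%d multimapper, %d unassigned)\n",
              attr(x, "n_counted"), attr(x, "n_multimapper"),
              attr(x, "n_unassigned")))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(y)
  invisible(x)
}
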