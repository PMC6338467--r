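# CMAP 0.1 / XMAP 0.2 dialect readers and writers.
#
# CMAP columns: CMapId ContigLength NumSites SiteID LabelChannel Position
#   One row per label (LabelChannel 1, SiteID 1..N) plus a terminal row
#   (LabelChannel 0, SiteID N+1, Position = ContigLength). Positions are
#   written to 0.1 bp.
# XMAP columns: XmapEntryID QryContigID RefContigID QryStartPos QryEndPos
#   RefStartPos RefEndPos Orientation Confidence Alignment
#   Alignment is the paired-site string "(refSite,qrySite)(...)...".

CMAP_COLS <- c("CMapId", "ContigLength", "NumSites", "SiteID",
               "LabelChannel", "Position")
XMAP_COLS <- c("XmapEntryID", "QryContigID", "RefContigID", "QryStartPos",
               "QryEndPos", "RefStartPos", "RefEndPos", "Orientation",
               "Confidence", "Alignment")

#' Write label maps as CMAP
#'
#' @param maps A [label_map()] or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cmap <- function(maps, path) {
  if (inherits(maps, "label_map")) maps <- list(maps)
  stopifnot(all(vapply(maps, inherits, logical(1), "label_map")))
  lines <- c("# CMAP File Version:\t0.1",
             "# Label Channels:\t1",
             paste0("#h ", paste(CMAP_COLS, collapse = "\t")),
             "#f int\tfloat\tint\tint\tint\tfloat")
  for (i in seq_along(maps)) {
    mp <- maps[[i]]
    n <- length(mp$labels)
    id <- map_numeric_id(mp$id, i)
    rows <- character(0)
    if (n > 0) {
      rows <- sprintf("%d\t%.1f\t%d\t%d\t1\t%.1f", id, mp$length, n,
                      seq_len(n), mp$labels)
    }
    rows <- c(rows, sprintf("%d\t%.1f\t%d\t%d\t0\t%.1f", id, mp$length, n,
                            n + 1L, mp$length))
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

map_numeric_id <- function(id, fallback) {
  x <- suppressWarnings(as.integer(id))
  if (is.na(x)) {
    x <- suppressWarnings(as.integer(sub("^\\D*", "", id)))
  }
  if (is.na(x)) fallback else x
}

parse_body <- function(path, n_cols, what) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < n_cols)
  if (length(bad)) {
    stop(sprintf("malformed %s row at line %d of %s: expected %d columns, got %d",
                 what, body_idx[bad[1]], path, n_cols, lengths(fields)[bad[1]]))
  }
  list(fields = fields, line_no = body_idx)
}

#' Read a CMAP file
#'
#' @param path CMAP path.
#' @return Named list of [label_map()] objects (names are `CMapId`s).
#' @export
read_cmap <- function(path) {
  parsed <- parse_body(path, 6L, "CMAP")
  fields <- parsed$fields
  line_no <- parsed$line_no
  id <- vapply(fields, `[`, character(1), 1)
  len <- as.numeric(vapply(fields, `[`, character(1), 2))
  site_id <- as.integer(vapply(fields, `[`, character(1), 4))
  channel <- as.integer(vapply(fields, `[`, character(1), 5))
  pos <- as.numeric(vapply(fields, `[`, character(1), 6))
  if (anyNA(len) || anyNA(site_id) || anyNA(channel) || anyNA(pos)) {
    bad <- which(is.na(len) | is.na(site_id) | is.na(channel) | is.na(pos))[1]
    stop(sprintf("malformed CMAP numeric field at line %d of %s",
                 line_no[bad], path))
  }
  maps <- list()
  for (mid in unique(id)) {
    rows <- which(id == mid)
    sid <- site_id[rows]
    if (any(diff(sid) <= 0)) {
      bad <- rows[which(diff(sid) <= 0)[1] + 1]
      stop(sprintf("non-increasing SiteID at line %d of %s", line_no[bad], path))
    }
    lab <- pos[rows][channel[rows] == 1L]
    maps[[mid]] <- label_map(mid, len[rows][1], lab)
  }
  maps
}

#' Write map alignments as XMAP
#'
#' @param alignments A `map_alignment` or list of them.
#' @param query_maps,ref_maps Named lists of the aligned [label_map()]s
#'   (keyed by map id), used for the position columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_xmap <- function(alignments, query_maps, ref_maps, path) {
  if (inherits(alignments, "map_alignment")) alignments <- list(alignments)
  if (inherits(query_maps, "label_map")) {
    query_maps <- stats::setNames(list(query_maps), query_maps$id)
  }
  if (inherits(ref_maps, "label_map")) {
    ref_maps <- stats::setNames(list(ref_maps), ref_maps$id)
  }
  lines <- c("# XMAP File Version:\t0.2",
             paste0("#h ", paste(XMAP_COLS, collapse = "\t")),
             "#f int\tint\tint\tfloat\tfloat\tfloat\tfloat\tstring\tfloat\tstring")
  for (i in seq_along(alignments)) {
    al <- alignments[[i]]
    qm <- query_maps[[al$query_id]]
    rm_ <- ref_maps[[al$ref_id]]
    if (is.null(qm) || is.null(rm_)) stop("alignment references unknown map id")
    p <- al$pairs
    if (nrow(p) == 0) next
    qpos <- qm$labels[p[, 1]]
    rpos <- rm_$labels[p[, 2]]
    aln <- paste(sprintf("(%d,%d)", p[, 2], p[, 1]), collapse = "")
    lines <- c(lines, sprintf(
      "%d\t%d\t%d\t%.1f\t%.1f\t%.1f\t%.1f\t%s\t%.2f\t%s",
      i, map_numeric_id(al$query_id, i), map_numeric_id(al$ref_id, i),
      qpos[1], qpos[length(qpos)], min(rpos), max(rpos),
      al$orientation, -al$cost, aln))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an XMAP file
#'
#' @param path XMAP path.
#' @return `data.frame` with the XMAP columns; the parsed pair list of
#'   each record is in the list-column `pairs` (matrix with columns
#'   `q`, `r`, 1-based site indices).
#' @export
read_xmap <- function(path) {
  parsed <- parse_body(path, 10L, "XMAP")
  fields <- parsed$fields
  line_no <- parsed$line_no
  df <- data.frame(
    XmapEntryID = as.integer(vapply(fields, `[`, character(1), 1)),
    QryContigID = vapply(fields, `[`, character(1), 2),
    RefContigID = vapply(fields, `[`, character(1), 3),
    QryStartPos = as.numeric(vapply(fields, `[`, character(1), 4)),
    QryEndPos = as.numeric(vapply(fields, `[`, character(1), 5)),
    RefStartPos = as.numeric(vapply(fields, `[`, character(1), 6)),
    RefEndPos = as.numeric(vapply(fields, `[`, character(1), 7)),
    Orientation = vapply(fields, `[`, character(1), 8),
    Confidence = as.numeric(vapply(fields, `[`, character(1), 9)),
    Alignment = vapply(fields, `[`, character(1), 10),
    stringsAsFactors = FALSE)
  if (anyNA(df$XmapEntryID)) {
    stop(sprintf("malformed XMAP id at line %d of %s",
                 line_no[which(is.na(df$XmapEntryID))[1]], path))
  }
  df$pairs <- lapply(df$Alignment, parse_alignment_string)
  df
}

parse_alignment_string <- function(s) {
  if (!nzchar(s)) return(matrix(integer(0), ncol = 2,
                                dimnames = list(NULL, c("q", "r"))))
  toks <- regmatches(s, gregexpr("\\((\\d+),(\\d+)\\)", s))[[1]]
  if (!length(toks)) stop("malformed XMAP alignment string: ", s)
  nums <- do.call(rbind, lapply(toks, function(t) {
    as.integer(strsplit(gsub("[()]", "", t), ",", fixed = TRUE)[[1]])
  }))
  # stored as (refSite, qrySite); return (q, r)
  out <- cbind(q = nums[, 2], r = nums[, 1])
  out
}
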