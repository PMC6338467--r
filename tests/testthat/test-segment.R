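# Segmentation and insertion-architecture summaries.

make_blocks <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(qstart = r[[1]], qend = r[[2]], target = r[[3]],
               side = if (r[[3]] == "vector") "vector" else "genome",
               tstart = r[[4]], tend = r[[5]], orientation = r[[6]],
               identity = if (length(r) > 6) r[[7]] else 1.0,
               stringsAsFactors = FALSE)
  }))
}

test_that("a single genomic block gives one tile and no breakpoints", {
  b <- make_blocks(list(0, 5000, "chr1", 10000, 15000, "+"))
  ann <- segment_sequence(b, 5000, NULL, query_id = "q")
  expect_equal(nrow(ann$blocks), 1)
  expect_equal(ann$blocks$label, "genomic")
  expect_equal(ann$n_breakpoints, 0)
})

test_that("gaps above the tolerance become linker blocks", {
  v <- build_vector(seed = 1)
  b <- make_blocks(list(0, 2000, "vector", 100, 2100, "+"),
                   list(2055, 4000, "vector", 2100, 4045, "+"))
  ann <- segment_sequence(b, 4000, v, gap_tol = 25)
  linkers <- ann$blocks[ann$blocks$label == "linker", ]
  expect_equal(nrow(linkers), 1)
  expect_equal(linkers$qend - linkers$qstart, 55)
  # vector coordinates remain contiguous across the linker: no breakpoint
  expect_equal(ann$n_breakpoints, 0)
  # tiling covers the query without overlap
  expect_equal(ann$blocks$qstart[-1], ann$blocks$qend[-nrow(ann$blocks)])
  expect_equal(ann$blocks$qstart[1], 0)
  expect_equal(ann$blocks$qend[nrow(ann$blocks)], 4000)
})

test_that("small gaps are absorbed into the neighbouring block", {
  b <- make_blocks(list(0, 1990, "chr1", 0, 1990, "+"),
                   list(2000, 4000, "chr1", 2000, 4000, "+"))
  ann <- segment_sequence(b, 4000, NULL, gap_tol = 25)
  expect_equal(nrow(ann$blocks), 2)
  expect_equal(ann$blocks$qstart[2], 1990)
})

test_that("vector blocks are relabelled and cut at the T-strand border", {
  v <- build_vector(t_strand = 4400, backbone = 4600, seed = 2)
  b <- make_blocks(list(0, 2000, "vector", 3400, 5400, "+"))
  ann <- segment_sequence(b, 2000, v)
  expect_equal(ann$blocks$label, c("t_strand", "backbone"))
  expect_equal(ann$blocks$qend[1], 1000)
  expect_equal(ann$blocks$tend[1], 4400)
  # majority rule when the straddle is marginal
  b2 <- make_blocks(list(0, 2000, "vector", 2410, 4410, "+"))
  ann2 <- segment_sequence(b2, 2000, v)
  expect_equal(ann2$blocks$label, "t_strand")
})

test_that("orientation flips and vector-coordinate jumps are breakpoints", {
  v <- build_vector(seed = 3)
  b <- make_blocks(list(0, 1000, "vector", 0, 1000, "+"),
                   list(1000, 2000, "vector", 1000, 2000, "-"),
                   list(2000, 3000, "vector", 3000, 4000, "+"))
  ann <- segment_sequence(b, 3000, v)
  expect_equal(ann$n_breakpoints, 2)
})

test_that("simulated concatemer reads report the simulated breakpoint count", {
  fx <- fixture_insertion(seed = 141, genome_len = 26000, copies = 3,
                          flip_prob = 1, breakpoint_prob = 0)
  idx <- build_anchor_index(genome = fx$genome, vector = fx$vector)
  op <- fx$ledger$ops[1, ]
  read <- substr(fx$derived[["chr1"]], op$der_start - 2000 + 1,
                 op$der_end + 2000)
  b <- anchor_blocks(read, idx)
  ann <- segment_sequence(b, nchar(read), fx$vector)
  # 3 same-orientation minus copies: each junction jumps in vector coords
  expect_equal(ann$n_breakpoints, 2)
})

test_that("architecture totals obey conservation and match known parts", {
  v <- build_vector(seed = 4)
  b <- make_blocks(list(0, 1000, "chr2", 18863678, 18864678, "+"),
                   list(1000, 12838, "vector", 100, 11938, "+"),
                   list(12893, 29356, "vector", 100, 16563, "-"),
                   list(29356, 30356, "chr2", 18870175, 18871175, "+"))
  # middle gap of 55 bp becomes a linker; vector coords are schematic
  ann <- segment_sequence(b, 30356, v, gap_tol = 25)
  arch <- summarize_architecture(ann, v)
  expect_equal(arch$total_insert_len,
               sum(arch$segments$length) + arch$linker_len)
  expect_equal(arch$total_insert_len, 28356)
  expect_equal(arch$deletion_len, 5497)
  expect_false(arch$open_ended)
})

test_that("a locus without vector sequence is not an insertion", {
  b <- make_blocks(list(0, 5000, "chr1", 0, 5000, "+"))
  ann <- segment_sequence(b, 5000, NULL)
  v <- build_vector(seed = 5)
  expect_error(summarize_architecture(ann, v), "not an insertion locus")
})

test_that("single-flank annotations are summarized open-ended", {
  v <- build_vector(seed = 6)
  b <- make_blocks(list(0, 3000, "chr1", 10000, 13000, "+"),
                   list(3000, 6000, "vector", 100, 3100, "+"))
  ann <- segment_sequence(b, 6000, v)
  arch <- summarize_architecture(ann, v)
  expect_true(arch$open_ended)
  expect_equal(arch$left_anchor, 13000)
  expect_true(is.na(arch$deletion_len))
  expect_equal(arch$total_insert_len, 3000)
})

test_that("border identity and truncation are measured from the outer edge", {
  v <- build_vector(t_strand = 4400, backbone = 4600, seed = 7)
  # junction segment starting exactly at the LB outer edge: 0 bp missing
  b <- make_blocks(list(0, 1000, "chr1", 5000, 6000, "+"),
                   list(1000, 5400, "vector", 0, 4400, "+"),
                   list(5400, 6400, "chr1", 7000, 8000, "+"))
  arch <- summarize_architecture(segment_sequence(b, 6400, v), v)
  expect_equal(arch$border_at_left, "LB")
  expect_equal(arch$lb_truncation_left, 0)
  expect_equal(arch$border_at_right, "RB")
  expect_equal(arch$lb_truncation_right, 0)
  # truncated by 90 bp at both ends, minus-oriented copy at the right:
  b2 <- make_blocks(list(0, 1000, "chr1", 5000, 6000, "+"),
                    list(1000, 3000, "vector", 90, 2090, "+"),
                    list(3000, 5000, "vector", 2000, 4000, "-"),
                    list(5000, 6000, "chr1", 7000, 8000, "+"))
  arch2 <- summarize_architecture(segment_sequence(b2, 6000, v), v)
  expect_equal(arch2$border_at_left, "LB")
  expect_equal(arch2$lb_truncation_left, 90)
  # right junction: outward coord is tstart (minus block) = 2000,
  # closer to LB: truncation measured from LB outer edge
  expect_equal(arch2$border_at_right, "LB")
  expect_equal(arch2$lb_truncation_right, 2000)
  tr <- measure_border_truncation(arch2, v)
  expect_equal(tr$missing, c(90, 2000))
})

test_that("minus-strand spanning reads are normalized before summary", {
  fx <- fixture_insertion(seed = 151, genome_len = 24000)
  idx <- build_anchor_index(genome = fx$genome, vector = fx$vector)
  op <- fx$ledger$ops[1, ]
  read <- substr(fx$derived[["chr1"]], op$der_start - 2500 + 1,
                 op$der_end + 2500)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  a1 <- summarize_architecture(
    segment_sequence(anchor_blocks(read, idx), nchar(read), fx$vector), fx$vector)
  a2 <- summarize_architecture(
    segment_sequence(anchor_blocks(rc, idx), nchar(rc), fx$vector), fx$vector)
  expect_equal(a1$left_anchor, a2$left_anchor)
  expect_equal(a1$right_anchor, a2$right_anchor)
  expect_equal(a1$segments$orientation, a2$segments$orientation)
})
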