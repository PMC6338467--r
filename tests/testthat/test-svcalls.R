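# Locus clustering, deletion arithmetic and rearrangement classification.

test_that("anchors within the merge window collapse into one locus", {
  ev <- data.frame(query_id = c("a", "b", "c"), chrom = "chr1",
                   left_anchor = c(10000, 10030, 60000),
                   right_anchor = c(10500, 10530, 60400))
  loci <- cluster_to_loci(ev, merge_window = 500)
  expect_equal(nrow(loci), 2)
  expect_equal(loci$n_support, c(2, 1))
  expect_equal(loci$left_anchor[1], 10015)
})

test_that("vector-free spanning reads feed the zygosity hint", {
  ev <- data.frame(query_id = c("a", "b", "c", "d"), chrom = "chr1",
                   left_anchor = c(10000, 10010, 10010, 10005),
                   right_anchor = c(10500, 10510, 10490, 10505),
                   has_vector = c(TRUE, TRUE, FALSE, FALSE))
  loci <- cluster_to_loci(ev)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$zygosity_hint, 0.5)
  expect_equal(loci$n_support, 2)
})

test_that("deletion calls reproduce the printed coordinate arithmetic", {
  expect_equal(call_deletion(list(left_anchor = 18864678,
                                  right_anchor = 18870175)), 5497)
  expect_equal(call_deletion(list(left_anchor = 100, right_anchor = 100)), 0)
  tsd <- call_deletion(list(left_anchor = 205, right_anchor = 200))
  expect_equal(as.numeric(tsd), -5)
  expect_equal(attr(tsd, "tsd"), 5)
  open <- call_deletion(list(left_anchor = 100, right_anchor = NA))
  expect_true(is.na(open))
  expect_true(attr(open, "open_ended"))
})

test_that("deletion lengths are translation-invariant", {
  for (shift in c(0, 1000, 12345678)) {
    expect_equal(call_deletion(list(left_anchor = 500 + shift,
                                    right_anchor = 5997 + shift)), 5497)
  }
})

test_that("span_length converts to the printed units and precision", {
  expect_equal(span_length(18864678, 18870175, "bp"), 5497)
  expect_equal(span_length(11703634, 12215749, "kb"), 512)
  expect_equal(span_length(8902305, 10095395, "Mb"), 1.19)
  expect_error(span_length(100, 50), "end must be >= start")
})

test_that("isolated rearrangements of each class are classified exactly", {
  for (seed in 1:6) {
    g <- simulate_genome(c(48000, 40000), seed = seed)
    idx <- build_anchor_index(genome = g)
    annotate <- function(seq, id) {
      segment_sequence(anchor_blocks(seq, idx), nchar(seq), NULL, query_id = id)
    }
    inv <- implant_events(g, list(inversion_event("chr1", 14000, 30000)))
    ci <- classify_rearrangement(annotate(inv$genome[["chr1"]], "i"),
                                 chrom_lengths = nchar(g))
    expect_equal(ci$kind, "inversion")
    expect_lt(abs(ci$start - 14000), 20)
    expect_lt(abs(ci$end - 30000), 20)

    tr <- implant_events(g, list(translocation_event("chr2", 9000, 16000,
                                                     31000)))
    ct <- classify_rearrangement(annotate(tr$genome[["chr2"]], "t"),
                                 chrom_lengths = nchar(g))
    expect_equal(unique(ct$kind), "intra_translocation")
    # the moved segment is reported in one of the two equivalent
    # descriptions of the same derived genome
    len_moved <- ct$end[1] - ct$start[1]
    expect_true(abs(len_moved - 7000) < 30 || abs(len_moved - 15000) < 30)

    sw <- implant_events(g, list(arm_swap_event("chr1", 38000, "chr2", 22000)))
    anns <- lapply(names(sw$genome), function(ch) {
      annotate(sw$genome[[ch]], ch)
    })
    cs <- classify_rearrangement(anns, chrom_lengths = nchar(g))
    expect_equal(cs$kind, c("arm_swap", "arm_swap"))
  }
})

test_that("a colinear contig produces no rearrangement calls", {
  g <- simulate_genome(40000, seed = 7)
  idx <- build_anchor_index(genome = g)
  ann <- segment_sequence(anchor_blocks(g[["chr1"]], idx), 40000, NULL)
  expect_equal(nrow(classify_rearrangement(ann, chrom_lengths = nchar(g))), 0)
})

test_that("an excised fragment found floating is called unplaced", {
  g <- simulate_genome(60000, seed = 8)
  ex <- implant_events(g, list(excision_event("chr1", 25000, 35000)))
  idx <- build_anchor_index(genome = g)
  main <- segment_sequence(anchor_blocks(ex$genome[["chr1"]], idx),
                           nchar(ex$genome[["chr1"]]), NULL, query_id = "main")
  frag <- substr(g[["chr1"]], 25001, 35000)
  fl <- segment_sequence(anchor_blocks(frag, idx), nchar(frag), NULL,
                         query_id = "floating")
  calls <- classify_rearrangement(list(main, fl), chrom_lengths = nchar(g))
  expect_true("unplaced_fragment" %in% calls$kind)
  up <- calls[calls$kind == "unplaced_fragment", ]
  expect_equal(up$query_id, "floating")
})

test_that("event counting deduplicates reciprocal arm-swap contigs", {
  loci <- data.frame(chrom = c("chr1", "chr2"), left_anchor = c(1, 2),
                     right_anchor = c(10, 20), n_support = 1,
                     zygosity_hint = 0, queries = "q")
  calls <- data.frame(kind = "arm_swap", chrom = c("chr1", "chr2"),
                      start = c(80000, 50000), end = NA,
                      chrom2 = c("chr2", "chr1"), pos2 = c(50000, 80000),
                      destination = NA, inverted = FALSE,
                      query_id = c("c1", "c2"))
  cnt <- count_events(loci, calls, insert_sizes = c(28356, 81000))
  expect_equal(cnt$n_insertions, 2)
  expect_equal(cnt$n_rearrangements, 1)
  expect_equal(cnt$max_insertion_size, 81000)
  # order invariance
  cnt2 <- count_events(loci[2:1, ], calls[2:1, ], c(81000, 28356))
  expect_equal(cnt, cnt2)
  empty <- count_events(NULL, NULL)
  expect_equal(unlist(empty), c(n_insertions = 0, n_rearrangements = 0,
                                max_insertion_size = 0))
})

test_that("report_percent reproduces printed percentages", {
  expect_equal(report_percent(38, 46), 83)
  expect_equal(report_percent(0, 10), 0)
})

test_that("SV calls serialize to parseable VCF-like records", {
  loci <- data.frame(chrom = "chr2", left_anchor = 18864678,
                     right_anchor = 18870175, n_support = 3,
                     zygosity_hint = 0, queries = "q")
  calls <- data.frame(kind = "inversion", chrom = "chr1", start = 11703634,
                      end = 12215749, chrom2 = NA, pos2 = NA,
                      destination = NA, inverted = FALSE, query_id = "c")
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(loci, calls, path, insert_sizes = 28356)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2)
  expect_match(body[1], "SVTYPE=INS;END=18870175;SVLEN=28356")
  expect_match(body[2], "SVTYPE=INV")
})
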