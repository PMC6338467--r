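# Context classification, methylation calling with FDR, per-element
# summaries and siRNA size-class tables.

test_that("context classification matches exhaustive triplet enumeration", {
  bases <- c("A", "C", "G", "T")
  # plus strand: every C N1 N2 triplet, hand-enumerated rule
  for (b1 in bases) for (b2 in bases) {
    s <- paste0("A", "C", b1, b2, "A")
    expected <- if (b1 == "G") "CG" else if (b2 == "G") "CHG" else "CHH"
    expect_identical(classify_context(s, 1, "+"), expected)
    # minus strand: same triplet embedded as its reverse complement
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_identical(classify_context(rc, nchar(rc) - 2, "-"), expected)
  }
  # non-cytosine and out-of-context positions
  expect_identical(classify_context("AAGT", 1, "+"), "none")
  expect_identical(classify_context("ACGTC", 4, "+"), "none")
  expect_identical(classify_context("CATTT", 0, "-"), "none")
})

test_that("every full-context cytosine falls in exactly one class", {
  set.seed(10)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    chars <- strsplit(s, "")[[1]]
    plus_c <- which(chars == "C") - 1
    plus_c <- plus_c[plus_c < 298]
    ctx <- classify_context(s, plus_c, "+")
    expect_true(all(ctx %in% c("CG", "CHG", "CHH")))
  }
})

test_that("binomial methylation calls match closed-form tails", {
  counts <- data.frame(pos = c(0, 1), strand = "+", context = "CG",
                       count_meth = c(0, 10), count_total = c(20, 10))
  calls <- call_methylated_sites(counts, p0 = 0.0035, fdr = 0.01)
  expect_equal(calls$p_value[1], 1)
  expect_equal(calls$status[1], "unmethylated")
  expect_equal(calls$p_value[2], 0.0035^10)
  expect_equal(calls$status[2], "methylated")
  # zero-coverage sites are dropped, not called
  counts$count_total[1] <- 0
  expect_equal(nrow(call_methylated_sites(counts)), 1)
  expect_error(call_methylated_sites(data.frame(pos = 0, strand = "+",
                                                context = "CG",
                                                count_meth = 5,
                                                count_total = 3)),
               "exceeds")
})

test_that("q-values are monotone in p-values and control the null", {
  set.seed(20)
  n <- 4000
  counts <- data.frame(pos = seq_len(n) - 1, strand = "+", context = "CHH",
                       count_meth = rbinom(n, 30, 0.0035), count_total = 30)
  calls <- call_methylated_sites(counts, p0 = 0.0035, fdr = 0.01)
  o <- order(calls$p_value)
  expect_true(!is.unsorted(calls$q_value[o]))
  expect_lte(mean(calls$status == "methylated"), 0.01)
})

test_that("element summaries conserve the count-weighted mean", {
  v <- build_vector(t_strand = 2000, backbone = 0, seed = 30)
  el <- data.frame(name = c("left", "right"), start = c(0, 1000),
                   end = c(1000, 2000))
  bs <- simulate_bisulfite(v$sequence, levels = c(CG = 0.8, CHG = 0.5,
                                                  CHH = 0.3),
                           depth = 50, seed = 31)
  calls <- call_methylated_sites(bs)
  em <- element_methylation(calls, el, "CHH")
  s <- calls[calls$context == "CHH", ]
  whole <- sum(s$count_meth) / sum(s$count_total)
  recon <- sum(em$weighted_level * vapply(seq_len(2), function(i) {
    sum(s$count_total[s$pos >= el$start[i] & s$pos < el$end[i]])
  }, numeric(1))) / sum(s$count_total)
  expect_equal(recon, whole)
  # a fully methylated element reports fraction 1
  hot <- simulate_bisulfite(v$sequence, levels = c(CG = 1, CHG = 1, CHH = 1),
                            depth = 30, non_conversion = 0, seed = 32)
  hot_calls <- call_methylated_sites(hot)
  expect_equal(element_methylation(hot_calls, el, "CG")$fraction_methylated,
               c(1, 1))
  # empty overlap reports missing, not zero
  far <- data.frame(name = "off", start = 5000, end = 6000)
  expect_true(is.na(element_methylation(calls, far, "CHH")$weighted_level))
})

test_that("simulated CHH levels recover the binomial expectation", {
  v <- build_vector(t_strand = 3000, backbone = 0, seed = 33)
  el <- data.frame(name = "all", start = 0, end = 3000)
  p0 <- 0.0035
  bs <- simulate_bisulfite(v$sequence, levels = c(CG = 0.9, CHG = 0.6,
                                                  CHH = 0.3),
                           depth = 50, non_conversion = p0, seed = 34)
  em <- element_methylation(call_methylated_sites(bs, p0 = p0), el, "CHH")
  p_exp <- 0.3 + 0.7 * p0
  n_reads <- em$n_sites * 50
  expect_lt(abs(em$weighted_level - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / n_reads))
})

test_that("exact full-length matches count once in the right cell", {
  v <- fixture_vector()
  el <- v$elements
  read24 <- substr(v$sequence, el$start[2] + 101, el$start[2] + 124)
  tab <- sirna_size_table(c(read24), v)
  expect_equal(unname(tab["nptII", "24"]), 1)
  expect_equal(sum(tab), 1)
  # one mismatch: not counted
  sub <- read24
  substr(sub, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read24, 12, 12))[1]
  expect_equal(sum(sirna_size_table(c(sub), v)), 0)
  # minus-strand reads count at their plus-strand location
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read24)))
  expect_equal(unname(sirna_size_table(c(rc), v)["nptII", "24"]), 1)
  # out-of-range lengths are ignored
  expect_equal(sum(sirna_size_table(substr(v$sequence, 1, 30), v)), 0)
  expect_equal(sum(sirna_size_table(substr(v$sequence, 1, 12), v)), 0)
})

test_that("the size table recovers the generator's class draws exactly", {
  v <- fixture_vector()
  sr <- simulate_small_rna(v, 1200,
                           class_weights = c("15-20" = 0.2, "21" = 0.3,
                                             "22" = 0.1, "23" = 0.1,
                                             "24" = 0.3),
                           seed = 40)
  tab <- sirna_size_table(sr$reads, v)
  truth <- table(factor(sr$truth$element, levels = rownames(tab)),
                 factor(sr$truth$class, levels = colnames(tab)))
  expect_equal(matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab)),
               matrix(as.integer(truth), nrow = nrow(tab),
                      dimnames = dimnames(tab)))
  # each read contributes to exactly one cell
  expect_equal(sum(tab), length(sr$reads))
  expect_equal(attr(tab, "n_counted"), length(sr$reads))
})

test_that("multimapping reads are counted once at the lowest coordinate", {
  # vector with an exact duplicated stretch inside two elements
  set.seed(50)
  base <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
  seq <- paste0(base, base, paste(sample(c("A", "C", "G", "T"), 1000,
                                         replace = TRUE), collapse = ""))
  v <- build_vector(t_strand = 2000, backbone = 0, border_len = 25,
                    sequence = seq,
                    elements = data.frame(name = c("d1", "d2"),
                                          start = c(0, 500),
                                          end = c(500, 1000)))
  read <- substr(seq, 101, 124)
  tab <- sirna_size_table(c(read), v)
  expect_equal(unname(tab["d1", "24"]), 1)
  expect_equal(sum(tab), 1)
  expect_equal(attr(tab, "n_multimapper"), 1)
})
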