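# Synthetic-data generator: concatemers, event implanting, reads,
# molecules, small RNA and bisulfite counts.

test_that("a single unflipped copy yields one truncated T-strand segment", {
  v <- build_vector(seed = 1)
  cc <- simulate_concatemer(v, copies = 1, breakpoint_prob = 0, flip_prob = 0,
                            seed = 2)
  expect_equal(nrow(cc$segments), 1)
  expect_equal(cc$segments$source, "t_strand")
  expect_equal(cc$segments$orientation, "+")
  # full length minus the two border truncations
  expect_equal(concatemer_length(cc),
               t_strand_length(v) - cc$trunc_left - cc$trunc_right)
  expect_true(cc$trunc_left >= 73 && cc$trunc_left <= 113)
})

test_that("border truncations never leave the configured range", {
  v <- build_vector(seed = 1)
  draws <- unlist(lapply(1:500, function(i) {
    cc <- simulate_concatemer(v, copies = 2, flip_prob = 0.5, seed = i)
    c(cc$trunc_left, cc$trunc_right)
  }))
  draws <- draws[!is.na(draws)]
  expect_gt(length(draws), 900)
  expect_true(all(draws >= 73 & draws <= 113))
})

test_that("concatemer simulation is reproducible under a fixed seed", {
  v <- build_vector(seed = 1)
  a <- simulate_concatemer(v, copy_p = 0.4, flip_prob = 0.5,
                           breakpoint_prob = 0.5, linker_prob = 0.5, seed = 99)
  b <- simulate_concatemer(v, copy_p = 0.4, flip_prob = 0.5,
                           breakpoint_prob = 0.5, linker_prob = 0.5, seed = 99)
  expect_identical(a, b)
  expect_error(simulate_concatemer(v, copy_p = 0), "empty copy distribution")
})

test_that("G-rich linkers carry the configured guanine content", {
  v <- build_vector(seed = 5)
  cc <- simulate_concatemer(v, copies = 3, linker_prob = 1, seed = 8)
  expect_true(all(nchar(cc$linkers) == 55))
  gs <- vapply(strsplit(cc$linkers, ""), function(x) sum(x == "G"), integer(1))
  expect_true(all(gs >= 26))
})

test_that("implanting conserves length arithmetic", {
  fx <- fixture_insertion(seed = 21, deletion = 1200)
  L <- concatemer_length(fx$concatemer)
  expect_equal(nchar(fx$derived[["chr1"]]) - nchar(fx$genome[["chr1"]]),
               L - 1200)
  # inversion conserves length and reverse-complements the interval
  g <- fixture_genome(20000, seed = 22)
  res <- implant_events(g, list(inversion_event("chr1", 5000, 9000)))
  expect_equal(nchar(res$genome), nchar(g))
  expect_identical(
    substr(res$genome[["chr1"]], 5001, 9000),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(g[["chr1"]], 5001, 9000)))))
})

test_that("the truth ledger round-trips every event class", {
  g <- fixture_genome(c(60000, 50000), seed = 31)
  v <- build_vector(seed = 32)
  cc <- simulate_concatemer(v, copies = 2, flip_prob = 0.5, seed = 33)
  events <- list(
    insertion_event("chr1", 10000, cc, v, deletion = 500),
    inversion_event("chr1", 30000, 40000),
    excision_event("chr1", 50000, 52000),
    translocation_event("chr2", 5000, 9000, 30000, inverted = TRUE),
    arm_swap_event("chr1", 55000, "chr2", 45000))
  res <- implant_events(g, events, seed = 31)
  expect_true(check_ledger(res$genome, res$ledger))
  # replaying the ledger reproduces the derived genome byte-for-byte
  expect_identical(apply_ledger(g, res$ledger), res$genome)
  # total length bookkeeping
  expect_equal(sum(nchar(res$genome)),
               sum(nchar(g)) + concatemer_length(cc) - 500 - 2000)
})

test_that("overlapping events are rejected with the colliding pair", {
  g <- fixture_genome(20000, seed = 41)
  ev <- list(inversion_event("chr1", 1000, 5000),
             excision_event("chr1", 4000, 6000))
  expect_error(implant_events(g, ev), "overlapping events on chr1")
})

test_that("error-free reads are exact substrings with faithful provenance", {
  g <- fixture_genome(30000, seed = 51)
  rs <- simulate_reads(g, n = 40, mean_length = 3000, seed = 52)
  for (i in seq_len(10)) {
    p <- rs$provenance[i, ]
    src <- substr(g[[p$chrom]], p$start + 1, p$end)
    if (p$strand == "-") {
      src <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(src)))
    }
    expect_identical(rs$reads[[p$read_id]], src)
  }
})

test_that("read sampling attains the expected coverage", {
  g <- fixture_genome(200000, seed = 61)
  n <- 1500; mean_len <- 5000; sd_len <- 1000
  rs <- simulate_reads(g, n = n, mean_length = mean_len, sd_length = sd_len,
                       seed = 62)
  total <- sum(rs$provenance$end - rs$provenance$start)
  # total sequenced bases ~ Normal(n*mean, sqrt(n)*sd)
  expect_lt(abs(total - n * mean_len), 3 * sqrt(n) * sd_len)
  # depth at a fixed position ~ Binomial(n, mean_len / G)
  pos <- 100000
  chr1 <- rs$provenance[rs$provenance$chrom == "chr1", ]
  depth <- sum(chr1$start <= pos & chr1$end > pos)
  p <- mean_len / sum(nchar(g))
  expect_lt(abs(depth - n * p), 3 * sqrt(n * p * (1 - p)) + 3)
})

test_that("reads spanning an implanted junction carry provenance across it", {
  fx <- fixture_insertion(seed = 71, genome_len = 30000)
  op <- fx$ledger$ops[1, ]
  rs <- simulate_reads(fx$derived, n = 200, mean_length = 8000,
                       sd_length = 1000, seed = 72)
  spans <- rs$provenance$start < op$der_start - 100 &
    rs$provenance$end > op$der_end + 100
  expect_gt(sum(spans), 0)
  p <- rs$provenance[which(spans)[1], ]
  # the ledger locates the insert inside the read's derived interval
  expect_true(p$start < op$der_start && p$end > op$der_end)
})

test_that("noiseless molecules reproduce the in-silico digest", {
  g <- fixture_genome(150000, seed = 81)
  mols <- simulate_molecules(g, n = 3, mean_length = 200000, sd_length = 0,
                             seed = 82)
  m <- mols$molecules[[1]]
  p <- mols$provenance[1, ]
  frag <- substr(g[[p$chrom]], p$start + 1, p$end)
  expect_equal(m$labels, digest(frag)$labels)
})

test_that("molecule filters and label dropout behave at the boundaries", {
  g <- fixture_genome(400000, seed = 91)
  nm <- noise_model(min_molecule_len = 100000)
  mols <- simulate_molecules(g, n = 20, mean_length = 110000,
                             sd_length = 30000, noise = nm, seed = 92)
  lens <- vapply(mols$molecules, function(m) m$length, numeric(1))
  expect_true(all(lens >= 100000))
  expect_lt(length(mols$molecules), 20)
  blind <- simulate_molecules(g, n = 5, mean_length = 150000,
                              noise = noise_model(label_fn = 1), seed = 93)
  expect_true(all(vapply(blind$molecules, function(m) length(m$labels),
                         integer(1)) == 0))
})

test_that("small-RNA draws honour class weights and strands", {
  v <- fixture_vector()
  only24 <- simulate_small_rna(v, 200, class_weights = c("15-20" = 0, "21" = 0,
                                                         "22" = 0, "23" = 0,
                                                         "24" = 1), seed = 1)
  expect_true(all(nchar(only24$reads) == 24))
  mix <- simulate_small_rna(v, 4000, class_weights = c("15-20" = 0, "21" = 0.5,
                                                       "22" = 0, "23" = 0,
                                                       "24" = 0.5), seed = 2)
  f21 <- mean(mix$truth$class == "21")
  expect_lt(abs(f21 - 0.5), 3 * sqrt(0.25 / 4000))
  expect_true(all(c("+", "-") %in% mix$truth$strand))
  # reads are exact substrings of the vector on the recorded strand
  i <- which(mix$truth$strand == "-")[1]
  tr <- mix$truth[i, ]
  sub <- substr(v$sequence, tr$start + 1, tr$start + tr$length)
  expect_identical(
    mix$reads[[tr$read_id]],
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub))))
  short <- build_vector(t_strand = 500, backbone = 0, border_len = 20,
                        elements = data.frame(name = "tiny", start = 100,
                                              end = 120), seed = 3)
  expect_error(simulate_small_rna(short, 10), "shorter than the maximum")
})

test_that("bisulfite counts follow the binomial observation model", {
  v <- build_vector(t_strand = 3000, backbone = 0, seed = 4)
  zero <- simulate_bisulfite(v$sequence, levels = c(CG = 0, CHG = 0, CHH = 0),
                             depth = 20, non_conversion = 0, seed = 5)
  expect_true(all(zero$count_meth == 0))
  full <- simulate_bisulfite(v$sequence, levels = c(CG = 1, CHG = 1, CHH = 1),
                             depth = 20, non_conversion = 0.01, seed = 6)
  expect_true(all(full$count_meth == 20))
  p0 <- 0.0035
  bs <- simulate_bisulfite(v$sequence, levels = c(CG = 0.3, CHG = 0.3, CHH = 0.3),
                           depth = 50, non_conversion = p0, seed = 7)
  n_obs <- sum(bs$count_total)
  p_exp <- 0.3 + 0.7 * p0
  frac <- sum(bs$count_meth) / n_obs
  expect_lt(abs(frac - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n_obs))
})
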