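# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data files.

fixture_vector <- function(seed = 101) {
  prok2_like_vector(seed = seed)
}

fixture_genome <- function(lengths = c(60000, 40000), seed = 102) {
  simulate_genome(lengths, seed = seed)
}

# one insertion implanted into a fresh genome; returns everything the
# recovery tests need
fixture_insertion <- function(seed, genome_len = 24000, deletion = 800,
                              copies = 1, flip_prob = 0, breakpoint_prob = 0,
                              point = NULL) {
  g <- simulate_genome(genome_len, seed = seed)
  v <- build_vector(t_strand = 4400, backbone = 4600, seed = seed + 1)
  cc <- simulate_concatemer(v, copies = copies, flip_prob = flip_prob,
                            breakpoint_prob = breakpoint_prob,
                            seed = seed + 2)
  point <- point %||% round(genome_len / 2)
  ev <- insertion_event("chr1", point, cc, v, deletion = deletion)
  res <- implant_events(g, list(ev), seed = seed)
  list(genome = g, vector = v, concatemer = cc, event = ev,
       derived = res$genome, ledger = res$ledger, point = point,
       deletion = deletion)
}

# brute-force two-strand motif scan (independent of digest());
# lookahead so overlapping occurrences are found too
scan_site_positions <- function(sequence, site) {
  hits <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  sort(unique(c(hits(site), hits(rc))))
}

# random label map with positions on a continuous scale
random_label_map <- function(n_labels, length = 100000, id = "m") {
  pos <- sort(stats::runif(n_labels, 0, length - 1))
  while (any(diff(pos) <= 0)) pos <- sort(stats::runif(n_labels, 0, length - 1))
  label_map(id, length, pos)
}
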