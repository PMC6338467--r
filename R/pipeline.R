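# Pipeline orchestration: configuration, staged execution, per-sample
# report assembly and serialization.

PIPELINE_KEYS <- c("sample", "seed", "outdir", "paths", "simulate",
                   "annotate", "sv", "optmap", "epigenome", "log_level")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with optional blocks
#' `paths` (genome/vector/reads/... input files), `simulate`, `annotate`,
#' `sv`, `optmap`, `epigenome` (per-stage parameters), plus `sample`,
#' `seed` and `outdir`. Unknown top-level keys are rejected.
#'
#' @param config Named list, or path to a YAML file.
#' @return The validated configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path", call. = FALSE)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  config$sample <- config$sample %||% "sample"
  config$seed <- config$seed %||% 1L
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order — simulation (or input
#' loading), read/contig annotation, locus clustering and SV calling,
#' optical-map sizing, epigenome profiling — and assembles a
#' `sample_report`. Stages whose inputs are absent are skipped. All
#' randomness derives from the single configured seed via fixed
#' per-stage offsets, so a rerun with the same configuration produces an
#' identical report.
#'
#' @param config A [pipeline_config()] (or list/YAML path coercible to
#'   one).
#' @param quiet Suppress progress messages.
#' @return An object of class `sample_report`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  seed <- as.integer(config$seed)
  say <- function(...) if (!quiet) log_msg("info", ...)
  report <- list(sample = config$sample, seed = seed,
                 schema_version = "1.0", sections = list())

  genome <- NULL; vector <- NULL; reads <- NULL; ledger <- NULL
  src_genome <- NULL

  if (!is.null(config$paths$genome)) genome <- read_fasta(config$paths$genome)
  if (!is.null(config$paths$vector)) {
    vseq <- read_fasta(config$paths$vector)[[1]]
    ts_len <- config$annotate$t_strand %||% round(nchar(vseq) / 2)
    vector <- build_vector(t_strand = ts_len, backbone = nchar(vseq) - ts_len,
                           sequence = vseq)
  }
  if (!is.null(config$paths$reads)) reads <- read_fasta(config$paths$reads)

  sim <- config$simulate
  if (!is.null(sim)) {
    say("simulate: genome + events (seed %d)", seed)
    src_genome <- simulate_genome(
      lengths = unlist(sim$chrom_lengths) %||% c(150000, 120000),
      seed = derive_seed(seed, 1))
    vector <- build_vector(
      t_strand = sim$t_strand %||% 4400,
      backbone = sim$backbone %||% 4600,
      elements = if (isTRUE(sim$prok2_elements %||% TRUE) &&
                       (sim$t_strand %||% 4400) == 4400) {
        prok2_like_vector()$elements
      } else NULL,
      seed = derive_seed(seed, 2))
    n_ins <- sim$n_insertions %||% 2
    events <- list()
    lens <- nchar(src_genome)
    set.seed(derive_seed(seed, 3))
    for (i in seq_len(n_ins)) {
      chrom <- names(src_genome)[((i - 1) %% length(src_genome)) + 1]
      point <- round(lens[[chrom]] * (0.2 + 0.5 * i / n_ins))
      cc <- simulate_concatemer(vector,
                                copies = sim$copies %||% NULL,
                                breakpoint_prob = sim$breakpoint_prob %||% 0.3,
                                flip_prob = sim$flip_prob %||% 0.3,
                                seed = derive_seed(seed, 10 + i))
      events[[length(events) + 1]] <-
        insertion_event(chrom, point, cc, vector,
                        deletion = sim$deletion %||% 1000)
    }
    res <- implant_events(src_genome, events, seed = seed)
    genome <- res$genome
    ledger <- res$ledger
    say("simulate: reads")
    noise <- noise_model(read_sub_rate = sim$read_sub_rate %||% 0,
                         read_indel_rate = sim$read_indel_rate %||% 0)
    rs <- simulate_reads(genome, n = sim$n_reads %||% 60,
                         mean_length = sim$read_length %||% 20000,
                         noise = noise, seed = derive_seed(seed, 4))
    reads <- rs$reads
    report$sections$truth <- list(
      n_events = length(events),
      der_lengths = as.list(nchar(genome)))
  }

  if (!is.null(reads) && !is.null(vector)) {
    say("annotate: %d read(s)", length(reads))
    ref_genome <- src_genome %||% genome
    idx <- build_anchor_index(genome = ref_genome, vector = vector,
                              k = config$annotate$k %||% 14)
    archs <- list()
    for (rid in names(reads)) {
      blocks <- anchor_blocks(reads[[rid]], idx,
                              min_block = config$annotate$min_block %||% 100,
                              min_identity = config$annotate$min_identity %||% 0.8)
      ann <- segment_sequence(blocks, nchar(reads[[rid]]), vector,
                              gap_tol = config$annotate$gap_tol %||% 25,
                              contig_tol = config$annotate$contig_tol %||% 25,
                              query_id = rid)
      ok <- try(summarize_architecture(ann, vector), silent = TRUE)
      if (!inherits(ok, "try-error")) archs[[rid]] <- ok
    }
    spanning <- Filter(function(a) !a$open_ended, archs)
    use <- if (length(spanning)) spanning else archs
    loci <- if (length(use)) {
      cluster_to_loci(architecture_evidence(use),
                      merge_window = config$sv$merge_window %||% 500)
    } else NULL
    sizes <- if (!is.null(loci)) loci$insert_len[!is.na(loci$insert_len)] else numeric(0)
    counts <- count_events(loci, NULL, sizes)
    report$sections$architecture <- list(
      n_queries_with_vector = length(archs),
      loci = loci,
      architectures = lapply(use, unclass_architecture),
      counts = counts)
  }

  if (!is.null(config$epigenome) || !is.null(config$paths$bisulfite) ||
      !is.null(config$paths$small_rna)) {
    epi <- config$epigenome %||% list()
    if (!is.null(vector) && nrow(vector$elements) > 0) {
      say("epigenome: siRNA + methylation")
      srna <- if (!is.null(config$paths$small_rna)) {
        read_fasta(config$paths$small_rna)
      } else if (isTRUE(epi$simulate)) {
        simulate_small_rna(vector, n = epi$n_srna %||% 2000,
                           seed = derive_seed(seed, 5))$reads
      } else NULL
      if (!is.null(srna)) {
        tab <- sirna_size_table(srna, vector)
        report$sections$epigenome$sirna <- as.data.frame(unclass_table(tab))
      }
      bs <- if (!is.null(config$paths$bisulfite)) {
        utils::read.delim(config$paths$bisulfite)
      } else if (isTRUE(epi$simulate)) {
        simulate_bisulfite(vector$sequence, depth = epi$depth %||% 30,
                           non_conversion = epi$non_conversion %||% 0.0035,
                           seed = derive_seed(seed, 6))
      } else NULL
      if (!is.null(bs)) {
        calls <- call_methylated_sites(bs, p0 = epi$non_conversion %||% 0.0035,
                                       fdr = epi$fdr %||% 0.01)
        report$sections$epigenome$methylation <- lapply(
          c("CG", "CHG", "CHH"),
          function(ctx) element_methylation(calls, vector$elements, ctx))
      }
    }
  }

  if (!is.null(config$optmap) && !is.null(genome) && !is.null(src_genome)) {
    say("optmap: molecule simulation + sizing")
    om <- config$optmap
    site <- om$site %||% "GCTCTTC"
    # per-chromosome reference maps from the source genome
    size_calls <- list()
    for (chrom in names(src_genome)) {
      rmap <- digest(src_genome[[chrom]], site, id = chrom)
      qmap <- digest(genome[[chrom]], site, id = paste0(chrom, "_derived"))
      al <- align_label_maps(qmap, rmap)
      sc <- call_insertion_size(al, qmap, rmap,
                                min_size = om$min_size %||% 1500)
      if (nrow(sc)) size_calls[[chrom]] <- cbind(chrom = chrom, sc)
    }
    report$sections$optmap <- list(
      size_calls = if (length(size_calls)) do.call(rbind, size_calls) else NULL)
  }

  if (!is.null(ledger)) report$ledger <- ledger
  structure(report, class = "sample_report")
}

unclass_architecture <- function(a) {
  a <- unclass(a)
  a$segments <- as.data.frame(a$segments)
  a
}

unclass_table <- function(tab) {
  attrs <- attributes(tab)
  attributes(tab) <- attrs[c("dim", "dimnames")]
  tab
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> %s (seed %d)\n", x$sample, x$seed))
  cat("  sections:", paste(names(x$sections), collapse = ", "), "\n")
  cts <- x$sections$architecture$counts
  if (!is.null(cts)) {
    cat(sprintf("  insertions: %d, rearrangements: %d, max insert: %s bp\n",
                cts$n_insertions, cts$n_rearrangements,
                format(cts$max_insertion_size, big.mark = ",")))
  }
  invisible(x)
}

#' Write a sample report as TSV and JSON
#'
#' Emits `report.json` (versioned schema; reparses to an equivalent
#' report) and, when the corresponding sections exist, `loci.tsv`,
#' `size_calls.tsv` and `sirna.tsv` under `dir`.
#'
#' @param report A `sample_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "tsv")`.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, formats = c("json", "tsv")) {
  stopifnot(inherits(report, "sample_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  rep2 <- unclass(report)
  rep2$ledger <- NULL  # ledger is written separately; sequences are large
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(rep2, p, auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    written <- c(written, p)
  }
  if ("tsv" %in% formats) {
    loci <- report$sections$architecture$loci
    if (!is.null(loci)) {
      p <- file.path(dir, "loci.tsv")
      utils::write.table(loci, p, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, p)
    }
    sc <- report$sections$optmap$size_calls
    if (!is.null(sc)) {
      p <- file.path(dir, "size_calls.tsv")
      utils::write.table(sc, p, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, p)
    }
    sir <- report$sections$epigenome$sirna
    if (!is.null(sir)) {
      p <- file.path(dir, "sirna.tsv")
      utils::write.table(cbind(element = rownames(sir), sir), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      written <- c(written, p)
    }
  }
  if (!is.null(report$ledger)) {
    written <- c(written, write_ledger(report$ledger, file.path(dir, "truth_ledger")))
  }
  invisible(written)
}
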