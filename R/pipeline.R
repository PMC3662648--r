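# End-to-end orchestration: simulate (or load) reads, trim, map, build
# pileups, apply contig filters, call SNPs per pool, merge and classify,
# score divergence and Ts/Tv, and select the candidate panel. Every number
# in the summary is recomputable from the per-stage tables the run writes.

#' Assemble a pipeline configuration
#'
#' All thresholds default to the discovery pipeline's standard values:
#' trimming (quality limit 0.05, 5 terminal bases, 100-base minimum),
#' mapping (similarity 0.90, length fraction 0.5), contig filters (length
#' 200, coverage 5x per pool), calling (coverage 8x, variant frequency 10%,
#' 2 reads per allele, base quality 20), panel (divergence 50%, 200-base
#' amplicon).
#'
#' @param reference path to a reference FASTA, or a named DNAStringSet
#' @param reads_high,reads_low FASTQ paths or `read_set`s for the two pools
#' @param out_dir output directory (created); stage tables are written here
#' @param trim a `trim_policy`
#' @param mapping a `mapping_policy`
#' @param calling a `calling_policy`
#' @param contig_min_length,contig_min_cov high-coverage contig filter
#' @param panel_divergence,panel_amplicon candidate-panel selection
#' @param seed integer seed recorded with the run
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(reference, reads_high, reads_low, out_dir,
                            trim = trim_policy(),
                            mapping = mapping_policy(),
                            calling = calling_policy(),
                            contig_min_length = 200L, contig_min_cov = 5,
                            panel_divergence = 0.5, panel_amplicon = 200L,
                            seed = 1L) {
  structure(list(reference = reference, reads_high = reads_high,
                 reads_low = reads_low, out_dir = out_dir, trim = trim,
                 mapping = mapping, calling = calling,
                 contig_min_length = as.integer(contig_min_length),
                 contig_min_cov = contig_min_cov,
                 panel_divergence = panel_divergence,
                 panel_amplicon = as.integer(panel_amplicon),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_reads_input <- function(x, pool, stage) {
  if (inherits(x, "read_set") || is.data.frame(x)) {
    rs <- as.data.table(x)
    rs[, pool := pool]
    return(rs)
  }
  rs <- read_fastq(x, pool = pool)
  if (nrow(rs) == 0) stopf("[%s] empty FASTQ input for pool %s: %s", stage, pool, x)
  rs
}

#' Run the full SNP discovery pipeline
#'
#' Stages: trim, map, pileup, contig filters, per-pool calls,
#' merge/classify, divergence and Ts/Tv, candidate panel. Per-stage tables
#' (TSV), the resolved configuration (JSON) and a summary (JSON) are
#' written under `config$out_dir`.
#'
#' @param config a `pipeline_config`
#' @param verbose log stage progress to stderr
#' @return (invisibly) list with elements reads, placements, pileup,
#'   contig_summary, high_coverage, elevation_unique, calls_high,
#'   calls_low, merged, tstv, panel, summary
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ref <- if (is.character(config$reference) && length(config$reference) == 1 &&
             file.exists(config$reference)) read_reference(config$reference)
         else config$reference
  ref_chr <- ref_as_character(ref)

  # trim ---------------------------------------------------------------
  raw <- list(high = load_reads_input(config$reads_high, "high", "trim"),
              low = load_reads_input(config$reads_low, "low", "trim"))
  trimmed <- lapply(raw, trim_read_set, policy = config$trim)
  summaries <- lapply(trimmed, summarize_read_set)
  for (p in names(trimmed))
    say("trim", "pool %s: %d reads kept (%d discarded), mean length %.1f",
        p, summaries[[p]]$n_reads, attr(trimmed[[p]], "n_discarded"),
        summaries[[p]]$mean_read_length)
  write_read_summary(summaries, file.path(config$out_dir, "read_summary.tsv"))
  reads <- rbindlist(trimmed)

  # map ----------------------------------------------------------------
  idx <- reference_index(ref_chr, config$mapping$seed_length)
  placements <- map_reads(reads, idx, config$mapping)
  say("map", "%d/%d reads placed (%d ambiguous)", nrow(placements),
      nrow(reads), sum(placements$ambiguous))
  fwrite(placements, file.path(config$out_dir, "placements.tsv"), sep = "\t")

  # pileup + contig filters --------------------------------------------
  pileup <- build_pileups(placements, reads, ref_chr)
  csum <- contig_coverage_summary(placements, ref_chr)
  keep <- filter_high_coverage(csum, config$contig_min_length, config$contig_min_cov)
  uniq <- find_elevation_unique(csum, config$contig_min_length, config$contig_min_cov)
  say("contigs", "%d/%d contigs pass the high-coverage filter", length(keep),
      nrow(csum))
  write_contig_summary(csum, file.path(config$out_dir, "contig_summary.tsv"))

  # restrict calling to the high-coverage dataset
  pu <- pileup[contig %in% keep]
  for (a in c("contig_lengths", "pools", "class")) setattr(pu, a, attr(pileup, a))

  # call + merge --------------------------------------------------------
  calls_high <- call_group_snps(pu, "high", config$calling)
  calls_low <- call_group_snps(pu, "low", config$calling)
  merged <- merge_and_classify(calls_high, calls_low, pu, config$calling)
  tstv <- transition_transversion(merged[category != "undetermined"])
  say("classify", "%d merged sites: a=%d b=%d c=%d undetermined=%d",
      nrow(merged), sum(merged$category == "a"), sum(merged$category == "b"),
      sum(merged$category == "c"), sum(merged$category == "undetermined"))
  write_snp_table(merged, file.path(config$out_dir, "snp_table.tsv"))

  # panel ---------------------------------------------------------------
  panel <- select_candidate_panel(merged, nchar(ref_chr),
                                  config$panel_divergence, config$panel_amplicon)
  say("panel", "%d candidate panel SNPs (D >= %.0f%%)", nrow(panel),
      100 * config$panel_divergence)
  fwrite(panel, file.path(config$out_dir, "panel.tsv"), sep = "\t")

  det <- merged[category != "undetermined"]
  summary <- list(
    reads = summaries,
    n_placed = nrow(placements),
    n_contigs = nrow(csum),
    n_high_coverage = length(keep),
    n_elevation_unique = lapply(uniq, length),
    n_snps_total = nrow(merged),
    n_determined = nrow(det),
    categories = list(a = sum(merged$category == "a"),
                      b = sum(merged$category == "b"),
                      c = sum(merged$category == "c"),
                      undetermined = sum(merged$category == "undetermined")),
    tstv = tstv,
    mean_divergence = mean(det$divergence, na.rm = TRUE),
    n_panel = nrow(panel),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(config)
  cfg$reference <- if (is.character(config$reference)) config$reference else "<in-memory>"
  for (nm in c("reads_high", "reads_low"))
    if (!is.character(cfg[[nm]])) cfg[[nm]] <- "<in-memory>"
  cfg[c("trim", "mapping", "calling")] <- lapply(
    cfg[c("trim", "mapping", "calling")], unclass)
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(reads = reads, placements = placements, pileup = pileup,
                 contig_summary = csum, high_coverage = keep,
                 elevation_unique = uniq, calls_high = calls_high,
                 calls_low = calls_low, merged = merged, tstv = tstv,
                 panel = panel, summary = summary))
}

#' Build the default synthetic benchmark dataset
#'
#' The standard study conditions: 200 transcripts of ~1 kb, two pools of
#' three diploid individuals, 30x mean depth per pool, read lengths ~267 /
#' ~246 bases (high / low pool), 0.5% substitution errors with Q30 correct
#' bases and Q10-30 errors.
#'
#' @param seed integer seed driving every stage
#' @param n_transcripts number of reference transcripts
#' @param depth mean depth per pool
#' @return list(reference, truth, reads (list high/low), popmodel, seqmodel)
#' @export
benchmark_dataset <- function(seed = 20919L, n_transcripts = 200L, depth = 30) {
  reference <- generate_reference(n_transcripts, length_mean = 1000,
                                  length_sd = 250, seed = seed)
  popmodel <- population_model(seed = seed)
  truth <- simulate_pool_genotypes(popmodel, reference)
  seqmodel <- sequencing_model(mean_depth_per_pool = depth, seed = seed)
  reads <- simulate_pooled_reads(truth, seqmodel)
  list(reference = reference, truth = truth, reads = reads,
       popmodel = popmodel, seqmodel = seqmodel)
}
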