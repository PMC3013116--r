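#' Default pipeline configuration
#'
#' Flat key-value configuration for [run_full()]. Every tunable of the
#' mapping/calling contract is a named key with its standard default:
#' word size 11, at most 6 alignment errors, minimum alignment length
#' `ceiling(0.8 * modal read length)` unless overridden, strict calling at
#' coverage >= 5 with alt fraction > 0.60, relaxed calling at coverage >= 2
#' with alt fraction > 0.50 inside flagged regions, hyper-mutated flagging at
#' one standard deviation below mean coverage with >= 5 calls per 500 bp
#' window.
#'
#' @param ... overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    reference = NULL, reference_name = NULL,
    wt_reads = NULL, mutant_reads = NULL,
    features = NULL, out_dir = NULL,
    word_size = 11L, max_errors = 6L, min_align_len = NULL,
    both_strands = TRUE,
    min_coverage = 5L, min_alt_fraction = 0.60,
    relaxed_min_coverage = 2L, relaxed_min_alt_fraction = 0.50,
    sd_factor = 1.0, window = 500L, min_cluster = 5L,
    min_uncovered_len = 1L, min_unique_deletion_len = 50L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a flat key-value YAML configuration
#' @param path YAML file with keys as in [default_config()].
#' @return Config list with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

resolve_reference <- function(cfg) {
  ref <- cfg$reference
  if (inherits(ref, "reference_genome")) return(ref)
  if (is.null(ref)) stop("config must name the mediator reference FASTA")
  if (!file.exists(ref)) stop("reference FASTA not found: ", ref)
  genomes <- read_fasta(ref)
  if (!is.null(cfg$reference_name)) {
    if (!cfg$reference_name %in% names(genomes))
      stop("reference_name '", cfg$reference_name, "' not in FASTA")
    genomes[[cfg$reference_name]]
  } else genomes[[1L]]
}

resolve_reads <- function(x, what) {
  if (inherits(x, "read_set")) return(x)
  if (is.null(x)) stop("config must name the ", what, " read file")
  if (!file.exists(x)) stop(what, " read file not found: ", x)
  read_reads(x)
}

# one isolate: align -> pileup -> strict call -> coverage/regions ->
# relaxed call -> merged table
process_isolate <- function(label, reads, ref, index, aln_params,
                            call_params, reg_params) {
  aln <- align_readset(reads, ref, aln_params, index = index)
  pil <- build_pileup(aln, ref)
  strict <- call_differences(pil, call_params, mode = "strict",
                             isolate = label)
  track <- coverage_profile(pil)
  uncovered <- find_uncovered_runs(track, reg_params$min_uncovered_len)
  hyper <- find_hypermutated(track, strict, reg_params)
  relaxed <- if (nrow(hyper))
    call_differences(pil, call_params, mode = "relaxed", regions = hyper,
                     isolate = label)
  else difference_table(NULL, label, ref$name)
  merged <- merge_passes(strict, relaxed, hyper)
  unaligned <- reads[c(aln$unaligned, aln$ambiguous)]
  list(label = label, alignments = aln, pileup = pil, strict = strict,
       relaxed = relaxed, table = merged, track = track,
       uncovered = uncovered, hypermutated = hyper,
       max_insertion = if (track$mean > 0)
         estimate_max_insertion(unaligned, track) else NA_integer_)
}

#' Run the full mediator-based resequencing workflow
#'
#' Executes, for both isolates: alignment to the mediator, pileup, strict
#' variant calling, coverage profiling, uncovered-run and hyper-mutated
#' region detection, relaxed re-calling inside flagged regions, and pass
#' merging; then subtracts the WT table from the mutant's, compares the
#' uncovered regions, bounds the maximal undetected insertion, and (when
#' features are supplied) annotates the mutant-unique variants at codon
#' level. When `out_dir` is set, the difference tables (per isolate, common,
#' unique), region BEDs, annotated table and a run summary are written
#' there.
#'
#' @param config a list from [default_config()], or a path to a YAML file of
#'   the same keys.
#' @return An object of class `medresq_report`.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- do.call(default_config, config[!vapply(config, is.null, TRUE)])
  ref <- resolve_reference(cfg)
  wt_reads <- resolve_reads(cfg$wt_reads, "WT")
  mut_reads <- resolve_reads(cfg$mutant_reads, "mutant")
  features <- if (is.null(cfg$features)) NULL
  else if (inherits(cfg$features, "data.frame")) cfg$features
  else read_features(cfg$features, genome = ref)

  aln_params <- aligner_params(cfg$word_size, cfg$max_errors,
                               cfg$min_align_len, cfg$both_strands)
  call_params <- caller_params(cfg$min_coverage, cfg$min_alt_fraction,
                               cfg$relaxed_min_coverage,
                               cfg$relaxed_min_alt_fraction)
  reg_params <- region_params(cfg$sd_factor, cfg$window, cfg$min_cluster,
                              cfg$min_uncovered_len)

  index <- build_seed_index(ref, cfg$word_size)
  wt <- process_isolate("WT", wt_reads, ref, index, aln_params, call_params,
                        reg_params)
  mut <- process_isolate("mutant", mut_reads, ref, index, aln_params,
                         call_params, reg_params)

  sub <- subtract(mut$table, wt$table)
  mut_only_uncov <- compare_uncovered(mut$uncovered, wt$uncovered,
                                      cfg$min_unique_deletion_len)
  annotations <- if (!is.null(features))
    annotate_variants(sub$unique_to_mutant, features, ref) else NULL

  report <- structure(list(
    reference = ref, config = cfg, wt = wt, mutant = mut,
    subtraction = sub, unique_to_mutant = sub$unique_to_mutant,
    unique_to_wt = sub$unique_to_wt, common = sub$common,
    mutant_only_uncovered = mut_only_uncov,
    annotations = annotations,
    summary = list(
      genome_length = ref$length,
      wt_reads = wt_reads$n_reads, mutant_reads = mut_reads$n_reads,
      wt_aligned = wt$alignments$counts$aligned,
      mutant_aligned = mut$alignments$counts$aligned,
      wt_calls = nrow(wt$table), mutant_calls = nrow(mut$table),
      n_common = sub$n_common,
      n_unique_to_mutant = nrow(sub$unique_to_mutant),
      n_unique_to_wt = nrow(sub$unique_to_wt),
      wt_percent_uncovered = attr(wt$uncovered, "percent_uncovered"),
      mutant_percent_uncovered = attr(mut$uncovered, "percent_uncovered"),
      mutant_max_insertion = mut$max_insertion)),
    class = "medresq_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.medresq_report <- function(x, ...) {
  s <- x$summary
  cat("<medresq_report> mediator-based resequencing\n")
  cat(sprintf("  mediator: %s (%s bp)\n", x$reference$name,
              format(s$genome_length, big.mark = ",")))
  cat(sprintf("  WT:     %s reads, %s aligned, %s calls\n",
              format(s$wt_reads, big.mark = ","),
              format(s$wt_aligned, big.mark = ","),
              format(s$wt_calls, big.mark = ",")))
  cat(sprintf("  mutant: %s reads, %s aligned, %s calls\n",
              format(s$mutant_reads, big.mark = ","),
              format(s$mutant_aligned, big.mark = ","),
              format(s$mutant_calls, big.mark = ",")))
  cat(sprintf("  common: %s | unique to mutant: %d | unique to WT: %d\n",
              format(s$n_common, big.mark = ","), s$n_unique_to_mutant,
              s$n_unique_to_wt))
  cat(sprintf("  mutant max undetected insertion: %s bp\n",
              format(s$mutant_max_insertion, big.mark = ",")))
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' @param report a `medresq_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_difference_table(report$wt$table, p("wt_differences.tsv"))
  write_difference_table(report$mutant$table, p("mutant_differences.tsv"))
  write_difference_table(report$common, p("common.tsv"))
  write_difference_table(report$unique_to_mutant, p("unique_to_mutant.tsv"))
  write_difference_table(report$unique_to_wt, p("unique_to_wt.tsv"))
  nm <- report$reference$name
  write_bed(report$wt$uncovered, p("wt_uncovered.bed"), nm)
  write_bed(report$mutant$uncovered, p("mutant_uncovered.bed"), nm)
  write_bed(report$wt$hypermutated, p("wt_hypermutated.bed"), nm)
  write_bed(report$mutant$hypermutated, p("mutant_hypermutated.bed"), nm)
  write_bed(report$mutant_only_uncovered, p("mutant_only_uncovered.bed"), nm)
  if (!is.null(report$annotations))
    write_annotated_table(report$annotations, p("unique_to_mutant_annotated.tsv"))
  s <- report$summary
  writeLines(sprintf("%s\t%s", names(s), vapply(s, format, "")),
             p("run_summary.tsv"))
  invisible(out_dir)
}
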