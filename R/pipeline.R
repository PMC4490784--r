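#' Analysis configuration with the standard pausing-analysis defaults
#'
#' Central record of every tunable parameter of the pipeline. The defaults
#' are the standard constants of the traveling-ratio procedure: promoter
#' window -30..+300 bp around the TSS, gene body from +300 bp to the
#' transcript end, 650 bp minimum isoform length, TR > 2.0 as the pausing
#' census threshold, 1.5-fold for TR-change classification, twofold for the
#' expression-response grouping, and a 7% flanking margin for single-gene
#' coverage plots.
#'
#' @param coverage,annotation,peaks,chrom_sizes,out Input file paths and
#'   output directory (may be `NULL` when the config is used
#'   programmatically).
#' @param annotation_format `"bed12"` or `"refflat"`.
#' @param total_reads,read_length Library statistics for the background
#'   constant.
#' @param promoter_upstream,promoter_downstream Promoter window extent (bp).
#' @param body_offset Gene-body start relative to the TSS (bp).
#' @param min_length Minimum isoform length (bp).
#' @param tr_threshold Pausing census threshold (strict `>`).
#' @param fold_change TR fold-change classification threshold (inclusive).
#' @param expression_fold Expression-response fold threshold (inclusive).
#' @param margin_frac Metagene flanking margin as a fraction of gene length.
#' @param seed Integer seed for any randomized step.
#' @param treated_coverage,treated_peaks,treated_total_reads,treated_read_length
#'   Optional second condition; when given, [run_full()] also classifies
#'   cross-condition TR changes.
#' @return A `run_config` object (validated list).
#' @export
run_config <- function(coverage = NULL, annotation = NULL, peaks = NULL,
                       chrom_sizes = NULL, out = NULL,
                       annotation_format = "bed12",
                       total_reads = NULL, read_length = NULL,
                       promoter_upstream = 30, promoter_downstream = 300,
                       body_offset = 300, min_length = 650,
                       tr_threshold = 2.0, fold_change = 1.5,
                       expression_fold = 2.0, margin_frac = 0.07,
                       seed = 1,
                       treated_coverage = NULL, treated_peaks = NULL,
                       treated_total_reads = NULL,
                       treated_read_length = NULL) {
  cfg <- list(coverage = coverage, annotation = annotation, peaks = peaks,
              chrom_sizes = chrom_sizes, out = out,
              annotation_format = annotation_format,
              total_reads = total_reads, read_length = read_length,
              promoter_upstream = promoter_upstream,
              promoter_downstream = promoter_downstream,
              body_offset = body_offset, min_length = min_length,
              tr_threshold = tr_threshold, fold_change = fold_change,
              expression_fold = expression_fold, margin_frac = margin_frac,
              seed = as.integer(seed),
              treated_coverage = treated_coverage,
              treated_peaks = treated_peaks,
              treated_total_reads = treated_total_reads,
              treated_read_length = treated_read_length)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  num_pos <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0))
      stop("config parameter out of range: ", nm, " must be a positive number")
  }
  num_pos(cfg$promoter_upstream, "promoter_upstream")
  num_pos(cfg$promoter_downstream, "promoter_downstream")
  num_pos(cfg$body_offset, "body_offset")
  num_pos(cfg$min_length, "min_length")
  num_pos(cfg$tr_threshold, "tr_threshold")
  num_pos(cfg$total_reads, "total_reads")
  num_pos(cfg$read_length, "read_length")
  if (cfg$fold_change <= 1)
    stop("config parameter out of range: fold_change must be > 1")
  if (cfg$expression_fold <= 1)
    stop("config parameter out of range: expression_fold must be > 1")
  if (cfg$margin_frac < 0)
    stop("config parameter out of range: margin_frac must be >= 0")
  if (!cfg$annotation_format %in% c("bed12", "refflat"))
    stop("annotation_format must be 'bed12' or 'refflat'")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [run_config()] arguments; unknown keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file values (flag style).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full per-sample (or two-sample) pausing analysis
#'
#' Reads every input named in the config, runs the per-sample
#' traveling-ratio procedure (and the cross-condition classification when a
#' treated condition is configured), and writes the isoform and gene tables,
#' the comparison table, a summary JSON (class percentages and the fraction
#' of genes above the TR census threshold) and a run manifest into
#' `cfg$out`. Re-running with identical inputs and config reproduces
#' identical tables.
#'
#' @param cfg A `run_config` with input paths set.
#' @return Invisibly, a list of the in-memory results (`control`, optional
#'   `treated` and `comparison`, `summary`, `manifest`).
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  required <- c("coverage", "annotation", "peaks", "chrom_sizes", "out",
                "total_reads", "read_length")
  miss <- required[vapply(cfg[required], is.null, TRUE)]
  if (length(miss))
    stop("missing required config entries: ", paste(miss, collapse = ", "))
  for (f in c("coverage", "annotation", "peaks", "chrom_sizes"))
    if (!file.exists(cfg[[f]])) stop("input not found: ", cfg[[f]])
  two <- !is.null(cfg$treated_coverage)
  if (two && is.null(cfg$treated_peaks))
    stop("treated_coverage given without treated_peaks")

  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  message("reading inputs")
  g <- read_chrom_sizes(cfg$chrom_sizes)
  ann <- read_annotation(cfg$annotation, cfg$annotation_format)
  score_one <- function(cov_path, peak_path, total_reads, read_length, tag) {
    message("scoring sample: ", tag)
    track <- read_bedgraph(cov_path, g)
    peaks <- read_peaks(peak_path)
    stats <- library_stats(total_reads, read_length, g)
    res <- run_sample(ann, track, peaks, stats,
                      min_length = cfg$min_length)
    data.table::fwrite(res$isoforms,
                       file.path(cfg$out, paste0(tag, ".isoforms.tsv")),
                       sep = "\t")
    data.table::fwrite(res$genes,
                       file.path(cfg$out, paste0(tag, ".genes.tsv")),
                       sep = "\t")
    res
  }
  control <- score_one(cfg$coverage, cfg$peaks, cfg$total_reads,
                       cfg$read_length, "control")
  summary <- list(
    control = control$summary,
    control_fraction_tr_above = fraction_above(control$genes,
                                               cfg$tr_threshold))
  results <- list(control = control)
  if (two) {
    treated <- score_one(
      cfg$treated_coverage, cfg$treated_peaks,
      cfg$treated_total_reads %||% cfg$total_reads,
      cfg$treated_read_length %||% cfg$read_length, "treated")
    cmp <- classify_tr_change(control$genes, treated$genes,
                              fold = cfg$fold_change)
    data.table::fwrite(cmp$comparison,
                       file.path(cfg$out, "comparison.tsv"), sep = "\t")
    summary$treated <- treated$summary
    summary$treated_fraction_tr_above <-
      fraction_above(treated$genes, cfg$tr_threshold)
    summary$tr_change <- cmp$summary
    results$treated <- treated
    results$comparison <- cmp
  }
  jsonlite::write_json(summary, file.path(cfg$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- run_manifest(cfg)
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$summary <- summary
  results$manifest <- manifest
  message("done: ", cfg$out)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_manifest <- function(cfg) {
  inputs <- c("coverage", "annotation", "peaks", "chrom_sizes",
              "treated_coverage", "treated_peaks")
  sums <- lapply(cfg[inputs], function(p)
    if (is.null(p)) NULL else unname(tools::md5sum(p)))
  list(
    tool = "polpause",
    version = as.character(utils::packageVersion("polpause")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(cfg),
    input_md5 = sums[!vapply(sums, is.null, TRUE)])
}

#' Read a gene-level TR table written by [run_full()] or [run_sample()]
#'
#' @param path TSV with header columns `gene_id`, `n_isoforms_kept`, `tr`.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("gene_id", "tr") %in% names(dt)))
    stop("gene table needs columns gene_id and tr: ", path)
  data.table::setDF(dt)
  dt
}

#' Read an expression log2 fold-change table
#'
#' @param path TSV with header; a `gene_id` column plus one or more numeric
#'   columns, one per timepoint or contrast.
#' @param column Which fold-change column to use (name or index among the
#'   non-id columns; default the first).
#' @return data.frame with columns `gene_id`, `log2fc`.
#' @export
read_expression <- function(path, column = 1L) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"gene_id" %in% names(dt))
    stop("expression table needs a gene_id column: ", path)
  rest <- setdiff(names(dt), "gene_id")
  if (!length(rest)) stop("expression table has no fold-change column: ", path)
  col <- if (is.character(column)) column else rest[column]
  if (!col %in% rest) stop("no such expression column: ", column)
  data.frame(gene_id = dt$gene_id, log2fc = as.numeric(dt[[col]]),
             stringsAsFactors = FALSE)
}
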