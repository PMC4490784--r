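#' Read peak calls (narrowPeak or BED)
#'
#' narrowPeak (BED6+4) or any BED with at least 3 columns; only chrom, start
#' and end are used downstream (overlap is a yes/no question and peak scores
#' are ignored by the eligibility filter).
#'
#' @param path Path to the peak file.
#' @return A `peak_set`: data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `score` (NA when absent).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(raw)
  if (!any(keep)) return(peak_set(data.frame(
    chrom = character(), start = numeric(), end = numeric())))
  dt <- data.table::fread(text = raw[keep], header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop("peak file must have at least 3 columns: ", path)
  df <- data.frame(chrom = dt[[1]],
                   start = suppressWarnings(as.numeric(dt[[2]])),
                   end = suppressWarnings(as.numeric(dt[[3]])),
                   score = if (ncol(dt) >= 5L)
                     suppressWarnings(as.numeric(dt[[5]])) else NA_real_,
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$start >= df$end)
  if (length(bad))
    stop("invalid peak interval in ", path, " at line ", which(keep)[bad[1]])
  peak_set(df)
}

#' Construct a peak set in code
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `score`. Peaks may overlap; they are stored as
#'   given.
#' @return A `peak_set` object.
#' @export
peak_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start >= df$end)) stop("peak with start >= end")
  if (is.null(df$score)) df$score <- NA_real_
  structure(df, class = c("peak_set", "data.frame"))
}

# >= 1 shared base between each window [start, end) and any peak
overlaps_any_peak <- function(windows, peaks) {
  hit <- logical(nrow(windows))
  if (nrow(peaks) == 0L || nrow(windows) == 0L) return(hit)
  for (chr in intersect(unique(windows$chrom), unique(peaks$chrom))) {
    wi <- which(windows$chrom == chr & windows$end > windows$start)
    pi <- peaks$chrom == chr
    if (!length(wi) || !any(pi)) next
    q <- IRanges::IRanges(start = windows$start[wi] + 1L,
                          end = windows$end[wi])
    s <- IRanges::IRanges(start = peaks$start[pi] + 1L, end = peaks$end[pi])
    hit[wi] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Apply the isoform eligibility filters
#'
#' An isoform enters the traveling-ratio analysis only if (1) it is at least
#' `min_length` bp long (strictly shorter is excluded; exactly `min_length`
#' is kept), and (2) the interval from 30 bp upstream of the TSS to the
#' transcript end overlaps at least one called peak by >= 1 base. Reasons are
#' evaluated in that order and only the first failure is recorded.
#'
#' @param ann Annotation data.frame (see [read_annotation()]).
#' @param peaks A `peak_set` for the same sample.
#' @param g A `genome_table`.
#' @param min_length Minimum isoform length in bp (default 650).
#' @return `ann` with added columns `status` (`"kept"`/`"excluded"`) and
#'   `reason` (`"none"`, `"min_length"`, `"no_peak"`).
#' @export
filter_isoforms <- function(ann, peaks, g, min_length = 650) {
  status <- rep("kept", nrow(ann))
  reason <- rep("none", nrow(ann))
  short <- ann$length < min_length
  elig <- eligibility_window(ann, g)
  no_peak <- !overlaps_any_peak(elig, peaks)
  reason[!short & no_peak] <- "no_peak"
  reason[short] <- "min_length"
  status[short | no_peak] <- "excluded"
  ann$status <- status
  ann$reason <- reason
  ann
}

#' Isoform-level traveling ratio
#'
#' For each isoform the traveling ratio (pausing index) is
#' `TR = (TSS + BC) / (TU + BC)`, where TSS is the mean per-base pileup over
#' the promoter-proximal window (-30..+300 bp around the TSS), TU the mean
#' over the remaining gene body (+300 bp to the transcript end, introns
#' included), and BC the genome-wide background constant from
#' [compute_bc()]. Isoforms whose body window is empty are excluded with
#' reason `"degenerate_window"` instead of receiving a number.
#'
#' @param ann Annotation data.frame; typically the `status == "kept"` rows of
#'   [filter_isoforms()] output, but any annotation is accepted.
#' @param track A `coverage_track`.
#' @param bc Background constant, reads per base (> 0).
#' @param g A `genome_table`.
#' @return data.frame with one row per isoform: `isoform_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `length`, `status`, `reason`,
#'   `tss_mean`, `body_mean`, `bc`, `tr`.
#' @export
isoform_tr <- function(ann, track, bc, g) {
  stopifnot(length(bc) == 1, is.finite(bc))
  if (bc <= 0)
    stop("bc must be > 0 (zero pseudocount makes TR undefined on empty coverage)")
  out <- ann
  if (is.null(out$status)) {
    out$status <- rep("kept", nrow(out))
    out$reason <- rep("none", nrow(out))
  }
  out$tss_mean <- rep(NA_real_, nrow(out))
  out$body_mean <- rep(NA_real_, nrow(out))
  out$bc <- rep(bc, nrow(out))
  out$tr <- rep(NA_real_, nrow(out))
  if (nrow(out) == 0L) return(out)
  prom <- promoter_window(ann, g)
  body <- body_window(ann, g)
  degen <- (body$degenerate | prom$degenerate) & out$status == "kept"
  out$status[degen] <- "excluded"
  out$reason[degen] <- "degenerate_window"
  sel <- out$status == "kept"
  if (any(sel)) {
    out$tss_mean[sel] <- interval_means(track, prom[sel, ])
    out$body_mean[sel] <- interval_means(track, body[sel, ])
    out$tr[sel] <- (out$tss_mean[sel] + bc) / (out$body_mean[sel] + bc)
  }
  out
}

#' Gene-level traveling ratio
#'
#' The TR of a gene is the arithmetic mean of the TRs of its kept isoforms;
#' genes with no kept isoform are absent from the result.
#'
#' @param iso Isoform table from [isoform_tr()] (any mix of genes), or the
#'   kept isoforms of a single gene.
#' @return data.frame with columns `gene_id`, `n_isoforms_kept`, `tr`,
#'   ordered by `gene_id`.
#' @export
gene_tr <- function(iso) {
  kept <- iso[iso$status == "kept" & !is.na(iso$tr), , drop = FALSE]
  if (nrow(kept) == 0L)
    return(data.frame(gene_id = character(), n_isoforms_kept = integer(),
                      tr = numeric(), stringsAsFactors = FALSE))
  dt <- data.table::as.data.table(kept)
  gene_id <- NULL; tr <- NULL  # appease R CMD check
  res <- dt[, list(n_isoforms_kept = .N, tr = mean(tr)), by = gene_id]
  data.table::setorder(res, gene_id)
  data.table::setDF(res)
  res
}

#' Per-sample traveling-ratio analysis
#'
#' Runs the full per-sample procedure: isoform filtering (minimum length,
#' peak overlap), windowed coverage means, isoform TR via
#' `(TSS + BC)/(TU + BC)`, and gene-level averaging. Deterministic for fixed
#' inputs.
#'
#' @param ann Annotation data.frame (see [read_annotation()]).
#' @param track A `coverage_track` of the sample's pileup.
#' @param peaks A `peak_set` called for the same sample.
#' @param stats A `library_stats` for the sample (source of BC).
#' @param min_length Minimum isoform length in bp.
#' @return list with elements `isoforms` (every input isoform, with status,
#'   reason and TR components), `genes` (kept genes only), `bc`, and
#'   `summary` (counts per exclusion reason).
#' @export
run_sample <- function(ann, track, peaks, stats, min_length = 650) {
  bc <- compute_bc(stats)
  if (nrow(ann) == 0L) {
    warning("empty annotation: no isoforms to score")
    iso <- isoform_tr(ann, track, bc, g = track$genome)
    return(list(isoforms = iso, genes = gene_tr(iso), bc = bc,
                summary = summarize_isoforms(iso)))
  }
  flt <- filter_isoforms(ann, peaks, track$genome, min_length = min_length)
  iso <- isoform_tr(flt, track, bc, track$genome)
  genes <- gene_tr(iso)
  list(isoforms = iso, genes = genes, bc = bc,
       summary = summarize_isoforms(iso))
}

summarize_isoforms <- function(iso) {
  list(
    n_isoforms = nrow(iso),
    n_kept = sum(iso$status == "kept"),
    n_excluded_min_length = sum(iso$reason == "min_length"),
    n_excluded_no_peak = sum(iso$reason == "no_peak"),
    n_excluded_degenerate = sum(iso$reason == "degenerate_window"),
    n_genes = length(unique(iso$gene_id[iso$status == "kept"]))
  )
}
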