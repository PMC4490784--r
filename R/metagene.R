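#' Metagene coverage profile of a single gene
#'
#' Per-base pileup over the gene span extended by a flanking margin equal to
#' a fraction of the gene length (7% on either end by default), oriented in
#' transcription direction: position 0 is the 5' edge of the upstream margin
#' for both strands, so the promoter-proximal peak of a paused gene appears
#' near position `m` (the margin length) regardless of strand. Margin bases
#' clamped off the chromosome are filled with 0 and counted in
#' `n_clamped`.
#'
#' @param t One-row annotation data.frame (or a row of one): `chrom`,
#'   `strand`, `start`, `end`; `gene_id`/`isoform_id` used for labeling.
#' @param track A `coverage_track`.
#' @param margin_frac Margin as a fraction of gene length (>= 0), default
#'   0.07; the margin length is rounded to the nearest base.
#' @param bin_count Optional number of equal-width bins; values are averaged
#'   within bins. Must not exceed the extended span length.
#' @param normalization `"raw"` (pileup units), `"max1"` (divide by the
#'   profile maximum), or `"per_million"` (divide by `total_reads/1e6`).
#' @param total_reads Required for `normalization = "per_million"`.
#' @return A `metagene_profile`: list with `gene_id`, `strand`, `margin`,
#'   `positions` (0-based, 5'->3'), `values`, `normalization`, `n_clamped`.
#' @export
metagene_coverage <- function(t, track, margin_frac = 0.07, bin_count = NULL,
                              normalization = c("raw", "max1", "per_million"),
                              total_reads = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(track, "coverage_track"))
  if (is.data.frame(t)) {
    stopifnot(nrow(t) == 1L)
    t <- as.list(t)
  }
  if (margin_frac < 0) stop("margin_frac must be >= 0")
  glen <- t$end - t$start
  m <- round(margin_frac * glen)
  chrlen <- chrom_length(track$genome, t$chrom)
  lo <- t$start - m
  hi <- t$end + m
  clo <- max(lo, 0)
  chi <- min(hi, chrlen)
  r <- track$cov[[t$chrom]]
  vals <- as.numeric(S4Vectors::runValue(r))
  reps <- S4Vectors::runLength(r)
  v <- as.numeric(IRanges::Views(r, start = clo + 1, end = chi)[[1]])
  # re-pad bases clamped off the chromosome with zeros
  v <- c(numeric(clo - lo), v, numeric(hi - chi))
  n_clamped <- (clo - lo) + (hi - chi)
  if (t$strand == "-") v <- rev(v)
  if (!is.null(bin_count)) {
    if (bin_count > length(v))
      stop("bin_count exceeds the extended span length")
    idx <- ((seq_along(v) - 1) * bin_count) %/% length(v)
    v <- as.numeric(tapply(v, idx, mean))
  }
  if (normalization == "max1") {
    mx <- max(v)
    if (mx > 0) v <- v / mx
  } else if (normalization == "per_million") {
    if (is.null(total_reads) || total_reads <= 0)
      stop("per_million normalization needs total_reads > 0")
    v <- v / (total_reads / 1e6)
  }
  structure(list(
    gene_id = if (!is.null(t$gene_id)) t$gene_id else t$isoform_id,
    strand = t$strand, margin = m,
    positions = seq_along(v) - 1, values = v,
    normalization = normalization, n_clamped = n_clamped),
    class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile:", x$gene_id, "(", x$strand, "strand ),",
      length(x$values), "positions, margin", x$margin, "bp,",
      x$normalization, "normalization\n")
  invisible(x)
}

#' Write a metagene profile as a two-column TSV
#'
#' @param profile A `metagene_profile`.
#' @param path Output path (`position<TAB>value`, with header).
#' @return `path`, invisibly.
#' @export
write_metagene <- function(profile, path) {
  data.table::fwrite(
    data.table::data.table(position = profile$positions,
                           value = profile$values),
    path, sep = "\t")
  invisible(path)
}

#' Plot one or more metagene profiles
#'
#' Coverage in transcription direction with the gene span delimited by
#' dashed lines at the margin boundaries.
#'
#' @param profiles A `metagene_profile` or list of them (e.g. the same gene
#'   in two conditions); list names label the tracks.
#' @return A ggplot object.
#' @export
plot_metagene <- function(profiles) {
  if (inherits(profiles, "metagene_profile")) profiles <- list(profiles)
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, function(p) p$gene_id, "")
  df <- do.call(rbind, lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    data.frame(track = nm, position = p$positions, value = p$values)
  }))
  p1 <- profiles[[1]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                   colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(p1$margin,
                                       length(p1$values) - p1$margin),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position (5' → 3', bp)",
                  y = paste0("coverage (", p1$normalization, ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
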