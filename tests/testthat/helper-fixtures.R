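# Shared fixtures and independent oracles. The per-base oracle deliberately
# decodes coverage to a plain numeric vector and loops positions, so it
# shares no code path with the Rle/Views implementation it checks.

tiny_genome <- function(chrA = 10000, chrB = 8000) {
  genome_table(c(chrA = chrA, chrB = chrB))
}

# coverage track from a compact interval spec list: list(c(start, end, value))
make_track <- function(g, chrom = "chrA", spec = list()) {
  if (length(spec) == 0L) {
    df <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), value = numeric())
  } else {
    m <- do.call(rbind, spec)
    df <- data.frame(chrom = chrom, start = m[, 1], end = m[, 2],
                     value = m[, 3])
  }
  coverage_track(df, g)
}

# brute-force per-base mean over [start, end) from raw interval records
per_base_mean <- function(intervals, start, end) {
  pos <- seq.int(start, end - 1)
  v <- numeric(length(pos))
  for (i in seq_len(nrow(intervals))) {
    inside <- pos >= intervals$start[i] & pos < intervals$end[i]
    v[inside] <- v[inside] + intervals$value[i]
  }
  mean(v)
}

# random non-overlapping interval set on [0, len)
random_intervals <- function(len, n_max = 50, vmax = 20) {
  n <- sample.int(n_max, 1)
  cuts <- sort(sample.int(len - 1, min(2 * n, len - 2)))
  s <- cuts[seq(1, length(cuts) - 1, by = 2)]
  e <- cuts[seq(2, length(cuts), by = 2)]
  keep <- e > s
  data.frame(start = s[keep], end = e[keep],
             value = round(stats::runif(sum(keep), 0, vmax), 3))
}

# genome reflection: position x -> L - x on each chromosome; intervals,
# strands and coverage mirrored accordingly
mirror_annotation <- function(ann, g) {
  L <- unclass(g)[ann$chrom]
  data.frame(isoform_id = ann$isoform_id, gene_id = ann$gene_id,
             chrom = ann$chrom,
             strand = ifelse(ann$strand == "+", "-", "+"),
             start = unname(L - ann$end), end = unname(L - ann$start),
             length = ann$length, stringsAsFactors = FALSE)
}

mirror_intervals <- function(df, g) {
  L <- unclass(g)[df$chrom]
  out <- data.frame(chrom = df$chrom, start = unname(L - df$end),
                    end = unname(L - df$start), stringsAsFactors = FALSE)
  if (!is.null(df$value)) out$value <- df$value
  if (!is.null(df$score)) out$score <- df$score
  out[order(out$chrom, out$start), , drop = FALSE]
}

# the constructed five-isoform fixture: two too short, one with no peak
# overlap, two passing
five_isoform_fixture <- function() {
  g <- tiny_genome()
  ann <- annotation_table(
    isoform_id = c("S1.1", "S2.1", "NP.1", "K1.1", "K2.1"),
    gene_id = c("S1", "S2", "NP", "K1", "K2"),
    chrom = "chrA",
    strand = c("+", "-", "+", "+", "-"),
    start = c(100, 900, 2000, 4000, 7000),
    end = c(700, 1540, 3000, 5000, 8000))
  peaks <- peak_set(data.frame(
    chrom = "chrA",
    start = c(80, 880, 3980, 7900),
    end = c(180, 980, 4080, 7990)))
  track <- make_track(g, "chrA", list(
    c(0, 3970, 2), c(3970, 4300, 12), c(4300, 7700, 2),
    c(7700, 8030, 12), c(8030, 10000, 2)))
  list(g = g, ann = ann, peaks = peaks, track = track)
}
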