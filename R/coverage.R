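#' Construct a coverage track from interval data
#'
#' A coverage track stores the per-base pileup value for every position of the
#' genome, run-length encoded per chromosome. Positions not covered by any
#' input interval have value 0. Intervals must be non-overlapping; abutting
#' equal-valued intervals are merged implicitly by the run-length encoding, so
#' split and merged representations of the same pileup are indistinguishable
#' downstream.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `value` (reads per base, non-negative finite).
#' @param g A `genome_table`; intervals must lie within chromosome bounds.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(intervals, g) {
  stopifnot(inherits(g, "genome_table"))
  req <- c("chrom", "start", "end", "value")
  if (!all(req %in% names(intervals)))
    stop("intervals need columns: ", paste(req, collapse = ", "))
  validate_coverage_intervals(intervals, g)
  build_track(intervals, g)
}

validate_coverage_intervals <- function(dt, g, src = "<intervals>") {
  n <- nrow(dt)
  line <- if (is.null(dt$.line)) seq_len(n) else dt$.line
  bad <- which(is.na(dt$start) | is.na(dt$end) | !is.finite(dt$value))
  if (length(bad))
    stop("malformed record in ", src, " at line ", line[bad[1]])
  bad <- which(dt$value < 0)
  if (length(bad))
    stop("negative coverage value in ", src, " at line ", line[bad[1]])
  bad <- which(!(dt$start >= 0 & dt$start < dt$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) in ", src,
         " at line ", line[bad[1]])
  known <- dt$chrom %in% names(unclass(g))
  if (!all(known))
    stop("unknown chromosome '", dt$chrom[which(!known)[1]], "' in ", src,
         " at line ", line[which(!known)[1]])
  len <- chrom_length(g, dt$chrom)
  bad <- which(dt$end > len)
  if (length(bad))
    stop("interval beyond chromosome bounds in ", src,
         " at line ", line[bad[1]])
  # overlap check per chromosome on the start-sorted order
  ord <- order(dt$chrom, dt$start)
  same <- dt$chrom[ord[-1]] == dt$chrom[ord[-length(ord)]]
  olap <- which(same & dt$start[ord[-1]] < dt$end[ord[-length(ord)]])
  if (length(olap))
    stop("overlapping coverage intervals in ", src,
         " at line ", line[ord[olap[1] + 1L]])
  invisible(TRUE)
}

build_track <- function(dt, g) {
  lens <- unclass(g)
  cov <- lapply(names(lens), function(chr) {
    sel <- dt$chrom == chr
    if (!any(sel)) return(S4Vectors::Rle(0, lens[[chr]]))
    IRanges::coverage(
      IRanges::IRanges(start = dt$start[sel] + 1L, end = dt$end[sel]),
      weight = dt$value[sel], width = lens[[chr]])
  })
  names(cov) <- names(lens)
  structure(list(cov = cov, genome = g), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$cov, function(r) sum(as.numeric(S4Vectors::runLength(r)) *
                                             S4Vectors::runValue(r)), 0))
  cat("coverage_track:", length(x$cov), "chromosomes, total pileup mass",
      format(tot, digits = 6), "\n")
  invisible(x)
}

#' Total pileup mass of a coverage track
#'
#' Sum of the per-base value over the whole genome (equals total mapped reads
#' times read length for an extended-read pileup).
#'
#' @param track A `coverage_track`.
#' @return Numeric scalar.
#' @export
track_mass <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  sum(vapply(track$cov, function(r)
    sum(as.numeric(S4Vectors::runLength(r)) * S4Vectors::runValue(r)), 0))
}

#' Read a bedGraph pileup track
#'
#' Four-column bedGraph (`chrom start end value`, 0-based half-open), as
#' produced by peak callers' pileup output or coverage tools. `track` header
#' lines are skipped. Records must be non-overlapping and within chromosome
#' bounds; violations are reported with their line number.
#'
#' @param path Path to a bedGraph file.
#' @param g A `genome_table`.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, g) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(raw)
  if (!any(keep)) return(build_track(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               value = numeric()), g))
  dt <- data.table::fread(text = raw[keep], header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 4L) stop("bedGraph must have 4 columns: ", path)
  df <- data.frame(chrom = dt[[1]],
                   start = suppressWarnings(as.numeric(dt[[2]])),
                   end = suppressWarnings(as.numeric(dt[[3]])),
                   value = suppressWarnings(as.numeric(dt[[4]])),
                   .line = which(keep), stringsAsFactors = FALSE)
  validate_coverage_intervals(df, g, src = path)
  build_track(df, g)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are written as single intervals; zero-valued runs are
#' omitted (bedGraph's uncovered-means-zero convention).
#'
#' @param track A `coverage_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  parts <- lapply(names(track$cov), function(chr) {
    r <- track$cov[[chr]]
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    e <- cumsum(as.numeric(l))
    s <- e - l
    keep <- v != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = chr, start = s[keep], end = e[keep],
                           value = v[keep])
  })
  out <- data.table::rbindlist(parts)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Mean per-base pileup over a window
#'
#' The average read count over `[start, end)`: the sum of the per-base pileup
#' divided by the window width, with uncovered bases contributing zero.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end Window in 0-based half-open coordinates.
#' @return Numeric scalar, reads per base.
#' @export
interval_mean <- function(track, chrom, start, end) {
  interval_means(track, data.frame(chrom = chrom, start = start, end = end))
}

#' Vectorized windowed pileup means
#'
#' @param track A `coverage_track`.
#' @param windows data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open); empty windows are an error.
#' @return Numeric vector of per-window means, in input order.
#' @export
interval_means <- function(track, windows) {
  stopifnot(inherits(track, "coverage_track"))
  n <- nrow(windows)
  if (n == 0L) return(numeric())
  if (any(windows$end <= windows$start))
    stop("empty window: degenerate windows must be excluded before computing means")
  known <- windows$chrom %in% names(track$cov)
  if (!all(known))
    stop("unknown chromosome(s): ",
         paste(unique(windows$chrom[!known]), collapse = ", "))
  len <- chrom_length(track$genome, windows$chrom)
  if (any(windows$start < 0) || any(windows$end > len))
    stop("window outside chromosome bounds")
  out <- numeric(n)
  for (chr in unique(windows$chrom)) {
    sel <- which(windows$chrom == chr)
    v <- IRanges::Views(track$cov[[chr]],
                        start = windows$start[sel] + 1L,
                        end = windows$end[sel])
    out[sel] <- IRanges::viewMeans(v)
  }
  out
}

#' Library statistics for the background pseudocount
#'
#' @param total_reads Total mapped reads in the library (>= 0).
#' @param read_length Read length in bp (> 0); for mixed-length libraries,
#'   the mean read length.
#' @param genome_size Genome size in bp (> 0), or a `genome_table` whose size
#'   is used.
#' @return A `library_stats` object (list).
#' @export
library_stats <- function(total_reads, read_length, genome_size) {
  if (inherits(genome_size, "genome_table"))
    genome_size <- genome_size(genome_size)
  stopifnot(length(total_reads) == 1, length(read_length) == 1,
            length(genome_size) == 1)
  if (is.na(total_reads) || total_reads < 0)
    stop("total_reads must be >= 0")
  if (is.na(read_length) || read_length <= 0)
    stop("read_length must be > 0")
  if (is.na(genome_size) || genome_size <= 0)
    stop("genome_size must be > 0")
  structure(list(total_reads = as.numeric(total_reads),
                 read_length = as.numeric(read_length),
                 genome_size = as.numeric(genome_size)),
            class = "library_stats")
}

#' Background coverage constant (pseudocount)
#'
#' The genome-wide average per-base coverage,
#' `BC = total_reads * read_length / genome_size`, added to both the
#' promoter and body means when forming the traveling ratio so that regions
#' of very low or zero coverage yield stable ratios. Must be positive: with
#' zero mapped reads the ratio is undefined.
#'
#' @param stats A `library_stats` object (or total read count if
#'   `read_length`/`genome_size` are given).
#' @param read_length,genome_size Used when `stats` is a bare read count.
#' @return Numeric scalar, reads per base (> 0).
#' @export
compute_bc <- function(stats, read_length = NULL, genome_size = NULL) {
  if (!inherits(stats, "library_stats"))
    stats <- library_stats(stats, read_length, genome_size)
  if (stats$total_reads == 0)
    stop("total_reads is 0: background constant would be 0 and the traveling ratio undefined")
  stats$total_reads * stats$read_length / stats$genome_size
}
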