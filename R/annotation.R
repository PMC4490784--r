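#' Read a chrom.sizes file
#'
#' Two-column, tab-separated `chrom<TAB>length` table describing the assembly.
#' The genome size (sum of chromosome lengths) is the denominator of the
#' background-coverage pseudocount, so the table should cover the assembly the
#' reads were aligned to.
#'
#' @param path Path to a chrom.sizes file.
#' @return A `genome_table`: named numeric vector of chromosome lengths with a
#'   `genome_size` attribute.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("chrom.sizes must have two columns: ", path)
  genome_table(stats::setNames(as.numeric(dt[[2]]), dt[[1]]))
}

#' Construct a genome table from named chromosome lengths
#'
#' @param lengths Named numeric vector, chromosome name -> length in bp.
#' @return A `genome_table` object.
#' @export
genome_table <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome name in genome table")
  lengths <- stats::setNames(as.numeric(lengths), names(lengths))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive and finite")
  structure(lengths, class = "genome_table")
}

#' @export
print.genome_table <- function(x, ...) {
  cat("genome_table:", length(x), "chromosomes,",
      format(genome_size(x), big.mark = ","), "bp\n")
  invisible(x)
}

#' Total genome size of a genome table
#' @param g A `genome_table`.
#' @return Numeric scalar, sum of chromosome lengths in bp.
#' @export
genome_size <- function(g) {
  stopifnot(inherits(g, "genome_table"))
  sum(unclass(g))
}

chrom_length <- function(g, chrom) {
  stopifnot(inherits(g, "genome_table"))
  len <- unclass(g)[chrom]
  if (anyNA(len)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(len)]), collapse = ", "))
  }
  unname(len)
}

#' Read transcript models from BED12 or refFlat
#'
#' Produces one transcript model per record with 0-based half-open
#' coordinates. BED12 is consumed as-is (columns 1-6; blocks are ignored
#' because gene-body coverage deliberately includes introns); refFlat's
#' txStart/txEnd are already 0-based half-open in the UCSC dump convention
#' and map directly. BED records carry the transcript id in column 4; the
#' gene id defaults to the part of the transcript id before the last
#' underscore-free token -- for BED12 the gene id is taken from an optional
#' 13th column when present, otherwise it equals the transcript id. refFlat
#' column 1 is geneName and column 2 the isoform name.
#'
#' @param path Path to the annotation file.
#' @param format `"bed12"` or `"refflat"`.
#' @return data.frame with columns `isoform_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `length` (bp, `end - start`).
#' @export
read_annotation <- function(path, format = c("bed12", "refflat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = "character")
  if (nrow(dt) == 0L) {
    warning("empty annotation file: ", path)
    return(empty_annotation())
  }
  if (format == "bed12") {
    if (ncol(dt) < 6L) stop("BED12 annotation needs at least 6 columns: ", path)
    ann <- data.frame(
      isoform_id = dt[[4]],
      gene_id    = if (ncol(dt) >= 13L) dt[[13]] else dt[[4]],
      chrom      = dt[[1]],
      strand     = dt[[6]],
      start      = suppressWarnings(as.numeric(dt[[2]])),
      end        = suppressWarnings(as.numeric(dt[[3]])),
      stringsAsFactors = FALSE
    )
  } else {
    if (ncol(dt) < 6L) stop("refFlat annotation needs at least 6 columns: ", path)
    ann <- data.frame(
      isoform_id = dt[[2]],
      gene_id    = dt[[1]],
      chrom      = dt[[3]],
      strand     = dt[[4]],
      start      = suppressWarnings(as.numeric(dt[[5]])),
      end        = suppressWarnings(as.numeric(dt[[6]])),
      stringsAsFactors = FALSE
    )
  }
  validate_annotation(ann, path)
}

empty_annotation <- function() {
  data.frame(isoform_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             start = numeric(), end = numeric(), length = numeric(),
             stringsAsFactors = FALSE)
}

validate_annotation <- function(ann, path = "<annotation>") {
  bad <- which(is.na(ann$start) | is.na(ann$end))
  if (length(bad))
    stop("non-numeric coordinates in ", path, " at line ", bad[1])
  bad <- which(!(ann$start >= 0 & ann$start < ann$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) in ", path,
         " at line ", bad[1])
  bad <- which(!(ann$strand %in% c("+", "-")))
  if (length(bad))
    stop("strand must be '+' or '-' in ", path, " at line ", bad[1])
  dup <- ann$isoform_id[duplicated(ann$isoform_id)]
  if (length(dup))
    stop("duplicate isoform_id in ", path, ": ", dup[1])
  ann$length <- ann$end - ann$start
  ann
}

#' Build a transcript annotation table in code
#'
#' Convenience constructor applying the same invariants as [read_annotation()].
#'
#' @param isoform_id,gene_id,chrom,strand,start,end Vectors, recycled to a
#'   common length; coordinates 0-based half-open.
#' @return Annotation data.frame as from [read_annotation()].
#' @export
annotation_table <- function(isoform_id, gene_id = isoform_id, chrom, strand,
                             start, end) {
  ann <- data.frame(isoform_id = isoform_id, gene_id = gene_id, chrom = chrom,
                    strand = strand, start = as.numeric(start),
                    end = as.numeric(end), stringsAsFactors = FALSE)
  validate_annotation(ann)
}

# Shared strand-aware window arithmetic. All windows are defined in
# transcription direction, materialized genomically, then clamped to
# [0, chrom length]. Offsets in bp relative to TSS (5') and transcript end (3').
make_windows <- function(ann, g, role, from5, to5 = NULL, from3 = NULL, to3 = NULL) {
  len <- chrom_length(g, ann$chrom)
  plus <- ann$strand == "+"
  tss  <- ifelse(plus, ann$start, ann$end)
  tes  <- ifelse(plus, ann$end, ann$start)
  dir  <- ifelse(plus, 1, -1)
  # endpoints in transcription direction: 5' edge e5, 3' edge e3
  e5 <- tss + dir * from5
  e3 <- if (is.null(to5)) tes else tss + dir * to5
  gstart <- ifelse(plus, e5, e3)
  gend   <- ifelse(plus, e3, e5)
  # inverted in transcription direction (e.g. body of a short transcript)
  # means empty, never a swapped positive-width window
  degenerate <- gend <= gstart
  start <- pmax(gstart, 0)
  end   <- pmin(gend, len)
  end   <- pmax(end, start)
  start <- pmin(start, end)
  degenerate <- degenerate | end <= start
  start[degenerate] <- pmin(pmax(gstart[degenerate], 0), len[degenerate])
  end[degenerate] <- start[degenerate]
  data.frame(isoform_id = ann$isoform_id, chrom = ann$chrom,
             start = start, end = end, role = role,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Promoter-proximal window of each transcript
#'
#' The window spans -30 bp to +300 bp around the TSS in transcription
#' direction: `[TSS-30, TSS+300)` on the plus strand and `[TSS-300, TSS+30)`
#' genomically on the minus strand (where the TSS is the transcript's genomic
#' end). Clamped to chromosome bounds.
#'
#' @param ann Annotation data.frame (see [read_annotation()]).
#' @param g A `genome_table`.
#' @param upstream,downstream Window extent in bp around the TSS.
#' @return data.frame of windows (`chrom`, `start`, `end`, 0-based half-open)
#'   with a `degenerate` flag.
#' @export
promoter_window <- function(ann, g, upstream = 30, downstream = 300) {
  make_windows(ann, g, "promoter", from5 = -upstream, to5 = downstream)
}

#' Gene-body window of each transcript
#'
#' From +300 bp past the TSS to the annotated transcript end, introns
#' included. Transcripts of length <= the offset yield an empty window and
#' are flagged `degenerate`; callers must exclude them (the 650 bp minimum
#' length filter always removes them first in the standard pipeline).
#'
#' @inheritParams promoter_window
#' @param offset Distance in bp from the TSS at which the body starts.
#' @return data.frame of windows with a `degenerate` flag.
#' @export
body_window <- function(ann, g, offset = 300) {
  make_windows(ann, g, "body", from5 = offset)
}

#' Peak-eligibility window of each transcript
#'
#' From 30 bp upstream of the TSS to the transcript end (in transcription
#' direction); a transcript is retained for traveling-ratio analysis only if
#' this interval overlaps a called peak by at least one base.
#'
#' @inheritParams promoter_window
#' @param upstream Upstream extension in bp beyond the TSS.
#' @return data.frame of windows.
#' @export
eligibility_window <- function(ann, g, upstream = 30) {
  make_windows(ann, g, "eligibility", from5 = -upstream)
}
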