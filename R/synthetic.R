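#' Configuration for the synthetic Pol II coverage generator
#'
#' The generator emulates the structure the traveling-ratio statistic
#' assumes: a sharp promoter-proximal occupancy component over the
#' -30..+300 bp window (density `a`), a lower uniform gene-body plateau over
#' +300..end (density `b`), and genome-wide background elsewhere. Designed
#' pausing indices follow `p = (a + BC)/(b + BC)`, where BC is the
#' genome-wide mean coverage implied by the library depth, so a zero-noise
#' simulated sample pushed through the pipeline recovers every designed `p`
#' exactly. The intergenic background level is solved so that the
#' genome-wide mean equals BC exactly; a configuration whose designed gene
#' mass exceeds what the intergenic space can absorb is rejected (raise
#' `background`, widen `gap`, or lower densities).
#'
#' @param n_genes Number of regular genes.
#' @param gene_length Length range in bp (`c(lo, hi)`, uniform integer) or a
#'   single fixed length. Must exceed the 300 bp body offset.
#' @param gap Intergenic gap in bp between consecutive gene spans.
#' @param n_chrom Number of chromosomes the genes are split across.
#' @param flank Bp of background before the first and after the last gene of
#'   each chromosome (>= 330 so no analysis window is clamped).
#' @param background Designed genome-wide mean coverage BC in reads/base.
#'   Mutually exclusive with `depth`.
#' @param depth Total mapped reads; BC is then `depth * read_length /
#'   genome_size`.
#' @param read_length Read length in bp.
#' @param paused_frac Fraction of regular genes designed paused (pausing
#'   index drawn from `paused_tr`); the rest draw from `unpaused_tr`.
#' @param paused_tr,unpaused_tr Designed pausing-index ranges (uniform).
#' @param body_density Gene-body density range in reads/base (`c(lo, hi)` or
#'   a single value).
#' @param promoter_density Optional fixed promoter density `a` for every
#'   gene, overriding the pausing-index draws (then `p` is derived from `a`,
#'   `b` and BC).
#' @param noise `"none"` (coverage equals the designed densities exactly) or
#'   `"poisson"` (independent per-base Poisson counts with the designed
#'   densities as means).
#' @param n_short Extra genes of length `short_length` that violate the
#'   650 bp minimum-length filter.
#' @param short_length Length of the deliberately short genes (bp).
#' @param n_unbound Extra genes at background density with no emitted peak
#'   (fail the peak-overlap filter).
#' @param tr_threshold Pausing-index threshold used for the designed class
#'   labels in the truth table.
#' @param seed Integer seed (< 2^31 - 10; the generator derives a few
#'   sub-seeds by small offsets).
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_genes = 100,
                       gene_length = c(1000, 3000),
                       gap = 30000,
                       n_chrom = 2,
                       flank = 1000,
                       background = 5,
                       depth = NULL,
                       read_length = 50,
                       paused_frac = 0.6,
                       paused_tr = c(2.5, 8),
                       unpaused_tr = c(1.05, 1.8),
                       body_density = c(20, 40),
                       promoter_density = NULL,
                       noise = c("none", "poisson"),
                       n_short = 0,
                       short_length = 400,
                       n_unbound = 0,
                       tr_threshold = 2.0,
                       seed = 1) {
  noise <- match.arg(noise)
  if (length(gene_length) == 1L) gene_length <- rep(gene_length, 2)
  if (length(body_density) == 1L) body_density <- rep(body_density, 2)
  if (!is.null(depth)) {
    if (!missing(background) && !is.null(background))
      stop("give either background or depth, not both")
    background <- NULL
  }
  if (is.null(depth) && is.null(background))
    stop("one of background or depth is required")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (gene_length[1] <= 300)
    stop("gene_length must exceed the 300 bp body offset")
  if (gap < 330) stop("gap must be >= 330 bp so windows never collide")
  if (flank < 330) stop("flank must be >= 330 bp so windows are never clamped")
  if (paused_frac < 0 || paused_frac > 1) stop("paused_frac must be in [0,1]")
  if (read_length <= 0) stop("read_length must be > 0")
  if (short_length >= 650)
    stop("short_length must be < 650 to violate the length filter")
  if (short_length <= 300)
    stop("short_length must exceed the 300 bp body offset")
  if (!is.null(depth) && depth <= 0) stop("depth must be > 0")
  if (!is.null(background) && background <= 0) stop("background must be > 0")
  structure(list(
    n_genes = as.integer(n_genes), gene_length = gene_length, gap = gap,
    n_chrom = as.integer(n_chrom), flank = flank, background = background,
    depth = depth, read_length = read_length, paused_frac = paused_frac,
    paused_tr = paused_tr, unpaused_tr = unpaused_tr,
    body_density = body_density, promoter_density = promoter_density,
    noise = noise, n_short = as.integer(n_short),
    short_length = short_length, n_unbound = as.integer(n_unbound),
    tr_threshold = tr_threshold, seed = as.integer(seed)),
    class = "sim_config")
}

# Seeded layout + designed densities; everything downstream of the noise
# model is fixed by the design.
sim_design <- function(cfg) {
  withr::with_seed(cfg$seed, {
    n_reg <- cfg$n_genes
    n_tot <- n_reg + cfg$n_short + cfg$n_unbound
    kind <- c(rep("regular", n_reg), rep("short", cfg$n_short),
              rep("unbound", cfg$n_unbound))
    len <- integer(n_tot)
    len[kind != "short"] <- if (cfg$gene_length[1] == cfg$gene_length[2])
      cfg$gene_length[1] else
        sample(cfg$gene_length[1]:cfg$gene_length[2],
               sum(kind != "short"), replace = TRUE)
    len[kind == "short"] <- cfg$short_length
    strand <- sample(c("+", "-"), n_tot, replace = TRUE)
    # contiguous split across chromosomes
    per <- rep(ceiling(n_tot / cfg$n_chrom), cfg$n_chrom)
    per[cfg$n_chrom] <- n_tot - sum(per[-cfg$n_chrom])
    if (any(per < 1)) stop("more chromosomes than genes")
    chrom_idx <- rep(seq_len(cfg$n_chrom), per)
    chrom <- paste0("chr", chrom_idx)
    start <- numeric(n_tot); end <- numeric(n_tot)
    chrom_len <- numeric(cfg$n_chrom)
    for (ci in seq_len(cfg$n_chrom)) {
      pos <- cfg$flank
      for (i in which(chrom_idx == ci)) {
        start[i] <- pos
        end[i] <- pos + len[i]
        pos <- end[i] + cfg$gap
      }
      # round length up to a multiple of 1000 so common depth/background
      # combinations give an integer read count
      chrom_len[ci] <- 1000 * ceiling((pos - cfg$gap + cfg$flank) / 1000)
    }
    g <- genome_table(stats::setNames(chrom_len, paste0("chr", seq_len(cfg$n_chrom))))
    G <- genome_size(g)
    bc_target <- if (!is.null(cfg$depth))
      cfg$depth * cfg$read_length / G else cfg$background
    total_reads <- round(bc_target * G / cfg$read_length)
    if (total_reads < 1) stop("depth/background too low: < 1 read")
    bc <- total_reads * cfg$read_length / G
    # designed densities
    b <- stats::runif(n_tot, cfg$body_density[1], cfg$body_density[2])
    n_paused <- round(cfg$paused_frac * n_reg)
    paused <- rep(FALSE, n_tot)
    paused[sample(seq_len(n_reg), n_paused)] <- TRUE
    p <- numeric(n_tot)
    p[paused] <- stats::runif(sum(paused), cfg$paused_tr[1], cfg$paused_tr[2])
    p[!paused] <- stats::runif(sum(!paused), cfg$unpaused_tr[1],
                               cfg$unpaused_tr[2])
    if (!is.null(cfg$promoter_density)) {
      a <- rep(cfg$promoter_density, n_tot)
      p <- (a + bc) / (b + bc)
    } else {
      a <- p * (b + bc) - bc
      if (any(a < 0))
        stop("designed pausing index too low for this background: negative promoter density")
    }
    design <- list(
      cfg = cfg, genome = g,
      genes = data.frame(
        gene_id = sprintf("G%05d", seq_len(n_tot)),
        isoform_id = sprintf("G%05d.1", seq_len(n_tot)),
        chrom = chrom, strand = strand, start = start, end = end,
        length = len, kind = kind, a = a, b = b, p = p,
        stringsAsFactors = FALSE),
      bc = bc,
      stats = library_stats(total_reads, cfg$read_length, G))
    finalize_design(design)
  })
}

# Solve the intergenic background so the genome-wide mean is exactly bc,
# then recompute the designed pausing indices for the final densities.
finalize_design <- function(design) {
  genes <- design$genes
  cfg <- design$cfg
  elevated <- genes$kind != "unbound"
  prom_len <- 330
  body_len <- genes$length - 300
  E <- sum(genes$a[elevated] * prom_len + genes$b[elevated] * body_len[elevated])
  B <- sum(prom_len + body_len[elevated])
  G <- genome_size(design$genome)
  bg <- (design$bc * G - E) / (G - B)
  if (bg < 0)
    stop("designed gene coverage exceeds the library depth: raise background/depth, ",
         "widen gap, or lower promoter/body densities")
  genes$a[!elevated] <- bg
  genes$b[!elevated] <- bg
  genes$p <- (genes$a + design$bc) / (genes$b + design$bc)
  genes$designed_paused <- genes$p > cfg$tr_threshold
  genes$designed_filter <- ifelse(genes$kind == "short", "min_length",
                                  ifelse(genes$kind == "unbound", "no_peak",
                                         "kept"))
  design$genes <- genes
  design$bg <- bg
  design
}

# Designed-density windows of one gene set (promoter covers TSS-30..TSS+300,
# body the rest of the span; minus-strand windows mirrored genomically).
design_windows <- function(genes) {
  plus <- genes$strand == "+"
  prom_start <- ifelse(plus, genes$start - 30, genes$end - 300)
  prom_end   <- ifelse(plus, genes$start + 300, genes$end + 30)
  body_start <- ifelse(plus, genes$start + 300, genes$start)
  body_end   <- ifelse(plus, genes$end, genes$end - 300)
  list(prom = data.frame(chrom = genes$chrom, start = prom_start,
                         end = prom_end, value = genes$a),
       body = data.frame(chrom = genes$chrom, start = body_start,
                         end = body_end, value = genes$b))
}

design_track <- function(design, noise, noise_seed) {
  genes <- design$genes
  w <- design_windows(genes)
  lens <- unclass(design$genome)
  cov <- vector("list", length(lens))
  names(cov) <- names(lens)
  win <- rbind(w$prom, w$body)
  for (chr in names(lens)) {
    sel <- win$chrom == chr
    # disjoint windows riding on a uniform background: one coverage pass
    cov[[chr]] <- IRanges::coverage(
      IRanges::IRanges(start = win$start[sel] + 1L, end = win$end[sel]),
      weight = win$value[sel] - design$bg, width = lens[[chr]]) + design$bg
  }
  if (noise == "poisson") {
    cov <- withr::with_seed(noise_seed, lapply(cov, function(r) {
      lam <- as.numeric(r)
      S4Vectors::Rle(stats::rpois(length(lam), lam))
    }))
  }
  structure(list(cov = cov, genome = design$genome),
            class = "coverage_track")
}

design_peaks <- function(design) {
  genes <- design$genes
  sel <- genes$kind != "unbound" & genes$a > design$bg
  w <- design_windows(genes[sel, , drop = FALSE])$prom
  peak_set(data.frame(chrom = w$chrom, start = w$start, end = w$end,
                      score = rep(100, nrow(w)), stringsAsFactors = FALSE))
}

#' Simulate one ChIP-seq-like Pol II sample with known ground truth
#'
#' Generates a coverage track, transcript annotation, peak calls, genome
#' table, library statistics and a truth table from a [sim_config()].
#' With `noise = "none"` the per-base coverage equals the designed promoter
#' and body densities exactly, so [run_sample()] recovers every designed
#' pausing index to machine precision; with `noise = "poisson"` per-base
#' counts are drawn independently with the designed densities as means,
#' reproducibly for a fixed seed. Peaks are emitted over every promoter
#' window whose designed density exceeds the intergenic background, so the
#' eligibility filter keeps exactly the intended genes.
#'
#' @param cfg A `sim_config`.
#' @param dir Optional output directory; when given, writes
#'   `coverage.bedGraph`, `annotation.bed12`, `peaks.narrowPeak`,
#'   `chrom.sizes`, `library_stats.json` and `truth.tsv` (identical bytes
#'   for identical config).
#' @return list with `annotation`, `track`, `peaks`, `genome`, `stats`,
#'   `bc` (designed background constant, equal to `compute_bc(stats)`),
#'   `truth` (per-gene designed densities, pausing index, class and filter
#'   fate), and `config`.
#' @export
simulate_sample <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- sim_design(cfg)
  track <- design_track(design, cfg$noise, noise_seed = cfg$seed + 1L)
  sample_from_design(design, track, cfg, dir)
}

sample_from_design <- function(design, track, cfg, dir = NULL) {
  genes <- design$genes
  ann <- annotation_table(isoform_id = genes$isoform_id,
                          gene_id = genes$gene_id, chrom = genes$chrom,
                          strand = genes$strand, start = genes$start,
                          end = genes$end)
  peaks <- design_peaks(design)
  truth <- genes[, c("gene_id", "isoform_id", "chrom", "strand", "start",
                     "end", "length", "kind", "a", "b", "p",
                     "designed_paused", "designed_filter")]
  out <- list(annotation = ann, track = track, peaks = peaks,
              genome = design$genome, stats = design$stats, bc = design$bc,
              background = design$bg, truth = truth, config = cfg)
  if (!is.null(dir)) write_sim_sample(out, dir)
  out
}

write_sim_sample <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bedgraph(sim$track, file.path(dir, "coverage.bedGraph"))
  write_bed12(sim$annotation, file.path(dir, "annotation.bed12"))
  write_narrowpeak(sim$peaks, file.path(dir, "peaks.narrowPeak"))
  write_chrom_sizes(sim$genome, file.path(dir, "chrom.sizes"))
  jsonlite::write_json(
    list(total_reads = sim$stats$total_reads,
         read_length = sim$stats$read_length,
         genome_size = sim$stats$genome_size,
         bc = sim$bc, background = sim$background),
    file.path(dir, "library_stats.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}

#' Write an annotation table as BED12
#' @param ann Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(ann, path) {
  dt <- data.table::data.table(
    chrom = ann$chrom, start = ann$start, end = ann$end,
    name = ann$isoform_id, score = 0, strand = ann$strand,
    thickStart = ann$start, thickEnd = ann$end, rgb = "0",
    blockCount = 1, blockSizes = paste0(ann$end - ann$start, ","),
    blockStarts = "0,", gene_id = ann$gene_id)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a peak set as narrowPeak
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  dt <- data.table::data.table(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))), score = score,
    strand = ".", signalValue = score, pValue = -1, qValue = -1,
    peak = floor((peaks$end - peaks$start) / 2))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a genome table as chrom.sizes
#' @param g A `genome_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(g, path) {
  data.table::fwrite(
    data.table::data.table(chrom = names(unclass(g)),
                           length = as.numeric(unclass(g))),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Simulate a control/treated sample pair with designed pausing changes
#'
#' Both samples share the same gene layout, body densities and library
#' statistics; the treated sample's designed pausing index is the control's
#' times a per-gene fold multiplier, achieved by rescaling the promoter
#' density (`a_t = p_c * mult * (b + BC) - BC`). The intergenic background
#' is re-solved per sample so the background constant is exact in both.
#'
#' @param cfg A `sim_config` for the shared layout and the control design.
#' @param multipliers Optional numeric vector (> 0), one per gene in layout
#'   order. When `NULL`, `round(increase_frac * n)` randomly chosen regular
#'   genes get a multiplier drawn uniformly from `increase_range`,
#'   `round(decrease_frac * n)` from `1/increase_range`, and the rest exactly
#'   1.
#' @param increase_frac,decrease_frac Fractions of regular genes designed to
#'   increase/decrease.
#' @param increase_range Multiplier range for increased genes (entirely
#'   above the classification fold so designed classes are unambiguous).
#' @param fold Fold threshold used for the designed class labels.
#' @param dir Optional directory; samples are written under `control/` and
#'   `treated/`, the joint truth as `pair_truth.tsv`.
#' @return list with `control`, `treated` (as from [simulate_sample()]),
#'   and `truth` (per gene: control/treated pausing indices, multiplier,
#'   designed class at `fold`).
#' @export
simulate_pair <- function(cfg, multipliers = NULL, increase_frac = 0.6,
                          decrease_frac = 0, increase_range = c(1.6, 2.2),
                          fold = 1.5, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  design_c <- sim_design(cfg)
  n_tot <- nrow(design_c$genes)
  n_reg <- cfg$n_genes
  if (is.null(multipliers)) {
    if (increase_frac + decrease_frac > 1)
      stop("increase_frac + decrease_frac must be <= 1")
    multipliers <- withr::with_seed(cfg$seed + 2L, {
      m <- rep(1, n_tot)
      n_up <- round(increase_frac * n_reg)
      n_dn <- round(decrease_frac * n_reg)
      idx <- sample(seq_len(n_reg), n_up + n_dn)
      m[idx[seq_len(n_up)]] <- stats::runif(n_up, increase_range[1],
                                            increase_range[2])
      if (n_dn > 0)
        m[idx[n_up + seq_len(n_dn)]] <-
          1 / stats::runif(n_dn, increase_range[1], increase_range[2])
      m
    })
  }
  if (length(multipliers) != n_tot)
    stop("need one multiplier per gene (", n_tot, ")")
  if (any(multipliers <= 0)) stop("multipliers must be > 0")

  design_t <- design_c
  gt <- design_t$genes
  reg <- gt$kind != "unbound"
  p_target <- gt$p * multipliers
  a_t <- p_target * (gt$b + design_c$bc) - design_c$bc
  if (any(a_t[reg] < 0))
    stop("a multiplier drives a designed promoter density below zero")
  gt$a[reg] <- a_t[reg]
  design_t$genes <- gt
  design_t <- finalize_design(design_t)

  track_c <- design_track(design_c, cfg$noise, noise_seed = cfg$seed + 3L)
  track_t <- design_track(design_t, cfg$noise, noise_seed = cfg$seed + 4L)
  control <- sample_from_design(design_c, track_c, cfg,
                                if (!is.null(dir)) file.path(dir, "control"))
  treated <- sample_from_design(design_t, track_t, cfg,
                                if (!is.null(dir)) file.path(dir, "treated"))
  ratio <- design_t$genes$p / design_c$genes$p
  truth <- data.frame(
    gene_id = design_c$genes$gene_id,
    kind = design_c$genes$kind,
    p_control = design_c$genes$p,
    p_treated = design_t$genes$p,
    multiplier = multipliers,
    ratio = ratio,
    designed_class = ifelse(ratio >= fold, "increase",
                            ifelse(ratio <= 1 / fold, "decrease",
                                   "no_change")),
    stringsAsFactors = FALSE)
  if (!is.null(dir))
    data.table::fwrite(truth, file.path(dir, "pair_truth.tsv"), sep = "\t")
  list(control = control, treated = treated, truth = truth, fold = fold)
}
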