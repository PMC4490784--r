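#' Classify cross-condition traveling-ratio changes
#'
#' Joins the two gene tables on `gene_id` (only genes passing filters in both
#' samples can be classified -- the ratio is undefined otherwise) and labels
#' each gene by the fold change of its TR: `increase` when
#' `treated/control >= fold`, `decrease` when `treated/control <= 1/fold`
#' ("at least fold-change" is inclusive on both sides), else `no_change`.
#'
#' @param control,treated Gene tables from [gene_tr()] / [run_sample()]
#'   (`gene_id`, `tr`).
#' @param fold Fold-change threshold (> 1), default 1.5.
#' @return list with `comparison` (data.frame: `gene_id`, `tr_control`,
#'   `tr_treated`, `ratio`, `class`), `summary` (per-class counts and
#'   percentages), and `unmatched` (gene ids present in only one table).
#' @export
classify_tr_change <- function(control, treated, fold = 1.5) {
  if (!is.numeric(fold) || length(fold) != 1 || is.na(fold) || fold <= 1)
    stop("fold threshold must be a single number > 1")
  common <- intersect(control$gene_id, treated$gene_id)
  cc <- control[match(common, control$gene_id), ]
  tt <- treated[match(common, treated$gene_id), ]
  ratio <- tt$tr / cc$tr
  cls <- ifelse(ratio >= fold, "increase",
                ifelse(ratio <= 1 / fold, "decrease", "no_change"))
  cmp <- data.frame(gene_id = common, tr_control = cc$tr, tr_treated = tt$tr,
                    ratio = ratio, class = cls, stringsAsFactors = FALSE)
  counts <- vapply(c("increase", "decrease", "no_change"),
                   function(k) sum(cls == k), integer(1))
  summary <- data.frame(
    class = names(counts),
    n = as.integer(counts),
    percent = if (length(common)) 100 * counts / length(common) else
      rep(NA_real_, 3),
    row.names = NULL, stringsAsFactors = FALSE)
  list(comparison = cmp, summary = summary,
       unmatched = list(
         control_only = setdiff(control$gene_id, common),
         treated_only = setdiff(treated$gene_id, common)))
}

#' Fraction of genes above a traveling-ratio threshold
#'
#' Census of pausing: the fraction of genes whose TR is strictly greater than
#' the threshold (TR > 2 is the conventional mark of a paused gene).
#'
#' @param genes Gene table (`gene_id`, `tr`), non-empty.
#' @param threshold TR threshold, default 2.0; strict `>` comparison.
#' @return list with `n_above`, `n_total`, `fraction`.
#' @export
fraction_above <- function(genes, threshold = 2.0) {
  if (nrow(genes) == 0L) stop("empty gene table")
  n_above <- sum(genes$tr > threshold)
  list(n_above = n_above, n_total = nrow(genes),
       fraction = n_above / nrow(genes))
}

#' Traveling-ratio distributions for gene groups
#'
#' For each named group, the TR values of its member genes found in the
#' table, plus a complement group over the genes in none of the groups.
#' Group ids absent from the table are reported, not fatal; a group with no
#' matched gene at all is an error.
#'
#' @param genes Gene table (`gene_id`, `tr`).
#' @param groups Named list of character vectors of gene ids, or a single
#'   `gene_group` from [gene_group()].
#' @param complement_label Label for the complement group.
#' @return list with `distributions` (named list of sorted TR vectors,
#'   including the complement) and `missing` (named list of unmatched ids).
#' @export
group_distributions <- function(genes, groups,
                                complement_label = "remaining") {
  if (inherits(groups, "gene_group"))
    groups <- stats::setNames(list(groups$gene_ids), groups$label)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  dist <- list(); missing <- list()
  for (lab in names(groups)) {
    ids <- unique(groups[[lab]])
    hit <- ids %in% genes$gene_id
    if (!any(hit)) stop("group '", lab, "' matches no gene in the table")
    missing[[lab]] <- ids[!hit]
    dist[[lab]] <- sort(genes$tr[genes$gene_id %in% ids])
  }
  in_any <- genes$gene_id %in% unique(unlist(groups))
  dist[[complement_label]] <- sort(genes$tr[!in_any])
  list(distributions = dist, missing = missing)
}

#' Construct a gene group
#'
#' @param label Group label.
#' @param gene_ids Character vector of gene ids (de-duplicated, non-empty).
#' @return A `gene_group` object.
#' @export
gene_group <- function(label, gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  if (!length(gene_ids)) stop("gene group '", label, "' is empty")
  structure(list(label = label, gene_ids = gene_ids), class = "gene_group")
}

#' Read a gene group from a one-id-per-line text file
#'
#' @param path File with one gene id per line (blank lines and `#` comments
#'   skipped).
#' @param label Group label; defaults to the file name without extension.
#' @return A `gene_group`.
#' @export
read_gene_group <- function(path, label = NULL) {
  if (!file.exists(path)) stop("gene group file not found: ", path)
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !grepl("^#", ids)]
  if (is.null(label))
    label <- tools::file_path_sans_ext(basename(path))
  gene_group(label, ids)
}

#' Seeded random gene set
#'
#' Uniform sample of `n` genes without replacement from the universe;
#' identical seed and universe ordering give an identical set. Used to draw
#' size-matched random control groups for distribution comparisons.
#'
#' @param universe Character vector of gene ids to sample from.
#' @param n Number of genes to draw (default 23).
#' @param seed Integer seed.
#' @param label Group label.
#' @return A `gene_group`; the seed and universe size are attached as
#'   attributes `seed` and `universe_size`.
#' @export
random_gene_set <- function(universe, n = 23, seed, label = "random") {
  universe <- as.character(universe)
  if (n > length(universe))
    stop("cannot sample ", n, " genes from a universe of ", length(universe))
  picked <- withr::with_seed(seed,
                             sample(universe, size = n, replace = FALSE))
  grp <- gene_group(label, picked)
  attr(grp, "seed") <- seed
  attr(grp, "universe_size") <- length(universe)
  grp
}

#' Group genes by expression response
#'
#' Splits genes into an `"Up"` group -- at least `fold`-fold induced, i.e.
#' `log2FC >= log2(fold)` (inclusive) -- and an `"Other"` group (unaffected
#' or affected less than `fold`-fold).
#'
#' @param expr data.frame with columns `gene_id` and `log2fc` (finite).
#' @param fold Linear fold-change threshold, default 2.
#' @return list of two `gene_group`s named `Up` and `Other`.
#' @export
classify_expression_response <- function(expr, fold = 2.0) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(expr)))
  bad <- !is.finite(expr$log2fc)
  if (any(bad))
    stop("non-finite log2 fold change for gene(s): ",
         paste(utils::head(expr$gene_id[bad], 5), collapse = ", "))
  up <- expr$log2fc >= log2(fold)
  res <- list()
  if (any(up)) res$Up <- gene_group("Up", expr$gene_id[up])
  if (any(!up)) res$Other <- gene_group("Other", expr$gene_id[!up])
  res
}

#' Binned density of log-scaled traveling ratios
#'
#' Histogram of `log10(TR)` in equal-width bins over the observed (or given)
#' range, as plotted for pausing-distribution comparisons.
#'
#' @param tr Numeric vector of TR values (> 0).
#' @param bins Number of equal bins over log10(TR), default 50.
#' @param range Optional `c(lo, hi)` range on the log10 scale.
#' @return data.frame with `log10_tr_mid`, `count`, `density` (fraction of
#'   genes per bin).
#' @export
tr_density <- function(tr, bins = 50, range = NULL) {
  stopifnot(all(tr > 0))
  x <- log10(tr)
  if (is.null(range)) range <- base::range(x)
  if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  x <- pmin(pmax(x, range[1]), range[2])
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(log10_tr_mid = h$mids, count = h$counts,
             density = h$counts / length(x))
}
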