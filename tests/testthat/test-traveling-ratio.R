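g <- tiny_genome()

test_that("length filter excludes strictly below 650 bp and keeps 650 exactly", {
  peaks <- peak_set(data.frame(chrom = "chrA", start = 5000, end = 5100))
  ann <- annotation_table(c("A", "B"), chrom = "chrA", strand = "+",
                          start = 1000, end = c(1600, 1650))
  flt <- filter_isoforms(ann, peaks, g)
  expect_equal(flt$status, c("excluded", "excluded"))  # B: no peak nearby
  expect_equal(flt$reason, c("min_length", "no_peak"))
  # 650 bp with an overlapping peak is kept
  near <- peak_set(data.frame(chrom = "chrA", start = 1500, end = 1550))
  expect_equal(filter_isoforms(ann, near, g)$status, c("excluded", "kept"))
})

test_that("peak eligibility needs >= 1 shared base with 30bp-upstream..end", {
  ann <- annotation_table("A", chrom = "chrA", strand = "+",
                          start = 1000, end = 6000)
  # eligibility window is [970, 6000)
  hit <- peak_set(data.frame(chrom = "chrA", start = 5999, end = 6100))
  miss <- peak_set(data.frame(chrom = "chrA", start = 6000, end = 6200))
  far <- peak_set(data.frame(chrom = "chrA", start = 6100, end = 6200))
  edge <- peak_set(data.frame(chrom = "chrA", start = 900, end = 971))
  expect_equal(filter_isoforms(ann, hit, g)$status, "kept")
  expect_equal(filter_isoforms(ann, miss, g)$reason, "no_peak")
  expect_equal(filter_isoforms(ann, far, g)$reason, "no_peak")
  expect_equal(filter_isoforms(ann, edge, g)$status, "kept")
})

test_that("min_length is recorded before no_peak when both apply", {
  ann <- annotation_table("A", chrom = "chrA", strand = "+",
                          start = 1000, end = 1500)
  none <- peak_set(data.frame(chrom = "chrA", start = 9000, end = 9100))
  expect_equal(filter_isoforms(ann, none, g)$reason, "min_length")
})

test_that("isoform TR follows (TSS + BC)/(TU + BC)", {
  ann <- annotation_table("A", chrom = "chrA", strand = "+",
                          start = 1000, end = 6000)
  # promoter [970,1300) at 10, body [1300,6000) at 2
  trk <- make_track(g, "chrA", list(c(970, 1300, 10), c(1300, 6000, 2)))
  res <- isoform_tr(ann, trk, bc = 0.5, g)
  expect_equal(res$tss_mean, 10)
  expect_equal(res$body_mean, 2)
  expect_equal(res$tr, 10.5 / 2.5)  # = 4.2
  # uniform coverage gives TR exactly 1 for any bc
  uni <- make_track(g, "chrA", list(c(0, 10000, 7)))
  expect_equal(isoform_tr(ann, uni, bc = 0.3, g)$tr, 1.0)
  # zero coverage everywhere: BC/BC = 1
  zero <- make_track(g, "chrA", list())
  expect_equal(isoform_tr(ann, zero, bc = 0.01, g)$tr, 1.0)
  expect_error(isoform_tr(ann, trk, bc = 0, g), "bc must be > 0")
})

test_that("degenerate body windows are excluded, not scored", {
  ann <- annotation_table("A", chrom = "chrA", strand = "+",
                          start = 1000, end = 1250)
  trk <- make_track(g, "chrA", list(c(0, 10000, 3)))
  res <- isoform_tr(ann, trk, bc = 0.5, g)
  expect_equal(res$status, "excluded")
  expect_equal(res$reason, "degenerate_window")
  expect_true(is.na(res$tr))
})

test_that("gene TR averages kept isoforms and drops empty genes", {
  iso <- data.frame(
    isoform_id = c("a1", "a2", "b1", "c1"),
    gene_id = c("A", "A", "B", "C"),
    status = c("kept", "kept", "kept", "excluded"),
    tr = c(2.0, 4.0, 4.2, NA))
  gt <- gene_tr(iso)
  expect_equal(gt$gene_id, c("A", "B"))
  expect_equal(gt$tr, c(3.0, 4.2))
  expect_equal(gt$n_isoforms_kept, c(2L, 1L))
  # bounded by min/max of the gene's isoform TRs
  expect_true(gt$tr[1] >= 2.0 && gt$tr[1] <= 4.0)
  expect_equal(nrow(gene_tr(iso[iso$status == "excluded", ])), 0L)
})

test_that("run_sample classifies the five-isoform fixture as designed", {
  fx <- five_isoform_fixture()
  stats <- library_stats(total_reads = 1000, read_length = 50, fx$g)
  res <- run_sample(fx$ann, fx$track, fx$peaks, stats)
  expect_equal(nrow(res$isoforms), 5L)
  expect_equal(sum(res$isoforms$status == "kept"), 2L)
  got <- setNames(res$isoforms$reason, res$isoforms$isoform_id)
  expect_equal(got[c("S1.1", "S2.1", "NP.1", "K1.1", "K2.1")],
               c(S1.1 = "min_length", S2.1 = "min_length", NP.1 = "no_peak",
                 K1.1 = "none", K2.1 = "none"))
  expect_equal(res$summary$n_excluded_min_length, 2L)
  expect_equal(res$summary$n_excluded_no_peak, 1L)
  expect_equal(sort(res$genes$gene_id), c("K1", "K2"))
})

test_that("an empty annotation yields empty tables and a warning", {
  fx <- five_isoform_fixture()
  stats <- library_stats(1000, 50, fx$g)
  expect_warning(res <- run_sample(fx$ann[0, ], fx$track, fx$peaks, stats),
                 "empty annotation")
  expect_equal(nrow(res$isoforms), 0L)
  expect_equal(nrow(res$genes), 0L)
})

test_that("TR is monotone in the window means and tends to 1 as bc grows", {
  trf <- function(tss, tu, bc) (tss + bc) / (tu + bc)
  ann <- annotation_table("A", chrom = "chrA", strand = "+",
                          start = 1000, end = 6000)
  mk <- function(a, b) make_track(g, "chrA",
                                  list(c(970, 1300, a), c(1300, 6000, b)))
  t1 <- isoform_tr(ann, mk(5, 2), 0.5, g)$tr
  t2 <- isoform_tr(ann, mk(9, 2), 0.5, g)$tr
  t3 <- isoform_tr(ann, mk(9, 4), 0.5, g)$tr
  expect_true(t2 > t1)   # increasing in tss_mean
  expect_true(t3 < t2)   # decreasing in body_mean
  expect_true(all(c(t1, t2, t3) > 0))
  # pseudocount limit: bc >> coverage drives TR to 1
  big_bc <- 1e6 * 9
  expect_equal(isoform_tr(ann, mk(9, 2), big_bc, g)$tr, 1.0,
               tolerance = 1e-3)
  expect_equal(trf(9, 2, big_bc), isoform_tr(ann, mk(9, 2), big_bc, g)$tr)
})

test_that("every TR is invariant under reflection of the whole genome", {
  fx <- five_isoform_fixture()
  stats <- library_stats(1000, 50, fx$g)
  fwd <- run_sample(fx$ann, fx$track, fx$peaks, stats)

  mann <- mirror_annotation(fx$ann, fx$g)
  iv <- data.frame(chrom = "chrA",
                   start = c(0, 3970, 4300, 7700, 8030),
                   end = c(3970, 4300, 7700, 8030, 10000),
                   value = c(2, 12, 2, 12, 2))
  mtrack <- coverage_track(mirror_intervals(iv, fx$g), fx$g)
  mpeaks <- peak_set(mirror_intervals(as.data.frame(fx$peaks), fx$g))
  rev <- run_sample(mann, mtrack, mpeaks, stats)

  m <- match(fwd$isoforms$isoform_id, rev$isoforms$isoform_id)
  expect_equal(fwd$isoforms$status, rev$isoforms$status[m])
  expect_equal(fwd$isoforms$tr, rev$isoforms$tr[m], tolerance = 1e-12)
  expect_equal(fwd$genes$tr,
               rev$genes$tr[match(fwd$genes$gene_id, rev$genes$gene_id)],
               tolerance = 1e-12)
})
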