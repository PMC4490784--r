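test_that("zero-noise simulation round-trips every designed pausing index", {
  cfg <- sim_config(n_genes = 30, noise = "none", seed = 2)
  sim <- simulate_sample(cfg)
  res <- run_sample(sim$annotation, sim$track, sim$peaks, sim$stats)
  expect_equal(res$bc, sim$bc)
  m <- match(res$genes$gene_id, sim$truth$gene_id)
  expect_equal(nrow(res$genes), 30L)
  expect_true(all(abs(res$genes$tr / sim$truth$p[m] - 1) <= 1e-9))
})

test_that("designed filter violations are recovered by the pipeline", {
  cfg <- sim_config(n_genes = 10, n_short = 2, n_unbound = 2,
                    noise = "none", seed = 4)
  sim <- simulate_sample(cfg)
  res <- run_sample(sim$annotation, sim$track, sim$peaks, sim$stats)
  m <- match(sim$truth$isoform_id, res$isoforms$isoform_id)
  expect_equal(res$isoforms$reason[m],
               ifelse(sim$truth$designed_filter == "kept", "none",
                      sim$truth$designed_filter))
  expect_equal(res$summary$n_kept, 10L)
  expect_equal(res$summary$n_excluded_min_length, 2L)
  expect_equal(res$summary$n_excluded_no_peak, 2L)
})

test_that("total pileup mass matches the library depth exactly at zero noise", {
  cfg <- sim_config(n_genes = 25, noise = "none", seed = 6)
  sim <- simulate_sample(cfg)
  expect_equal(track_mass(sim$track),
               sim$stats$total_reads * sim$stats$read_length,
               tolerance = 1e-9)
  expect_equal(compute_bc(sim$stats), sim$bc, tolerance = 1e-12)
  expect_true(sim$background >= 0 && sim$background <= sim$bc)
})

test_that("identical seeds give byte-identical simulated outputs", {
  cfg <- sim_config(n_genes = 8, noise = "poisson", seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_sample(cfg, dir = d1)
  simulate_sample(cfg, dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 6)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # and a different seed changes the coverage
  d3 <- withr::local_tempdir()
  simulate_sample(sim_config(n_genes = 8, noise = "poisson", seed = 10), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "coverage.bedGraph"))),
    unname(tools::md5sum(file.path(d3, "coverage.bedGraph")))))
})

test_that("written samples re-read through the file readers unchanged", {
  cfg <- sim_config(n_genes = 12, noise = "none", seed = 8)
  d <- withr::local_tempdir()
  sim <- simulate_sample(cfg, dir = d)
  g <- read_chrom_sizes(file.path(d, "chrom.sizes"))
  expect_equal(unclass(g), unclass(sim$genome), ignore_attr = TRUE)
  ann <- read_annotation(file.path(d, "annotation.bed12"), "bed12")
  track <- read_bedgraph(file.path(d, "coverage.bedGraph"), g)
  peaks <- read_peaks(file.path(d, "peaks.narrowPeak"))
  st <- jsonlite::read_json(file.path(d, "library_stats.json"))
  stats <- library_stats(st$total_reads, st$read_length, st$genome_size)
  res_file <- run_sample(ann, track, peaks, stats)
  res_mem <- run_sample(sim$annotation, sim$track, sim$peaks, sim$stats)
  expect_equal(res_file$genes, res_mem$genes, tolerance = 1e-12)
})

test_that("an overfull design is rejected rather than silently clipped", {
  cfg <- sim_config(n_genes = 10, background = 0.05, body_density = 50,
                    gap = 400, noise = "none", seed = 1)
  expect_error(simulate_sample(cfg), "exceeds the library depth")
  expect_error(sim_config(n_genes = 10, gap = 100), "gap")
  expect_error(sim_config(n_genes = 10, background = 2, depth = 1000),
               "not both")
})

test_that("an identity contrast classifies every gene as no_change", {
  cfg <- sim_config(n_genes = 15, noise = "none", seed = 12)
  pr <- simulate_pair(cfg, multipliers = rep(1, 15))
  rc <- run_sample(pr$control$annotation, pr$control$track,
                   pr$control$peaks, pr$control$stats)
  rt <- run_sample(pr$treated$annotation, pr$treated$track,
                   pr$treated$peaks, pr$treated$stats)
  cmp <- classify_tr_change(rc$genes, rt$genes)
  expect_equal(unique(cmp$comparison$class), "no_change")
  expect_equal(cmp$summary$percent[cmp$summary$class == "no_change"], 100)
})

test_that("designed fold increases are recovered exactly at zero noise", {
  cfg <- sim_config(n_genes = 20, paused_frac = 0.3, noise = "none",
                    seed = 13)
  pr <- simulate_pair(cfg, increase_frac = 0.6, fold = 1.5)
  expect_equal(sum(pr$truth$designed_class == "increase"), 12L)
  rc <- run_sample(pr$control$annotation, pr$control$track,
                   pr$control$peaks, pr$control$stats)
  rt <- run_sample(pr$treated$annotation, pr$treated$track,
                   pr$treated$peaks, pr$treated$stats)
  cmp <- classify_tr_change(rc$genes, rt$genes, fold = 1.5)
  got <- setNames(cmp$comparison$class, cmp$comparison$gene_id)
  want <- setNames(pr$truth$designed_class, pr$truth$gene_id)
  expect_equal(got[names(want)], want)
  expect_equal(cmp$summary$percent[cmp$summary$class == "increase"], 60)
  # treated designed indices equal control times the multiplier
  expect_equal(pr$truth$p_treated, pr$truth$p_control * pr$truth$multiplier,
               tolerance = 1e-12)
})

test_that("poisson noise perturbs but reproducibly tracks the design", {
  cfg <- sim_config(n_genes = 40, noise = "poisson", seed = 21)
  s1 <- simulate_sample(cfg)
  s2 <- simulate_sample(cfg)
  expect_identical(s1$track$cov, s2$track$cov)
  res <- run_sample(s1$annotation, s1$track, s1$peaks, s1$stats)
  m <- match(res$genes$gene_id, s1$truth$gene_id)
  rel <- abs(res$genes$tr / s1$truth$p[m] - 1)
  expect_true(all(rel < 0.25))     # noisy, but near the design
  expect_gt(max(rel), 0)           # and actually noisy
})
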