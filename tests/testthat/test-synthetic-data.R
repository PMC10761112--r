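test_that("noise-free sections hit their closed-form region means", {
  p1 <- quiet_params(rho = 1)
  s1 <- generate_section(p1, seed = 1)
  expect_equal(mean(s1$cb1[s1$rois$sdh]), mean(s1$cb1[s1$rois$ddh]))

  p2 <- quiet_params(rho = 2)
  s2 <- generate_section(p2, seed = 1)
  expect_equal(mean(s2$cb1[s2$rois$sdh]) / mean(s2$cb1[s2$rois$ddh]), 2.0)
  expect_equal(mean(s2$cb1[s2$rois$sdh]), p2$base_intensity * 2)
  expect_equal(mean(s2$cb1[s2$rois$ddh]), p2$base_intensity)
  expect_equal(mean(s2$cb1[s2$rois$background]),
               p2$base_intensity * p2$background_frac)
  # subject effect scales everything multiplicatively
  s3 <- generate_section(p2, subject_effect = 1.3, seed = 1)
  expect_equal(mean(s3$cb1[s3$rois$sdh]), 1.3 * p2$base_intensity * 2)
})

test_that("phantom invariants hold: shapes, nonnegativity, disjoint masks", {
  for (seed in 1:5) {
    s <- generate_section(phantom_params(), seed = seed)
    expect_identical(dim(s$cb1), dim(s$cgrp))
    expect_true(all(s$cb1 >= 0) && all(s$cgrp >= 0))
    r <- s$rois
    expect_false(any(r$sdh & r$ddh))
    expect_false(any(r$sdh & r$background))
    expect_false(any(r$ddh & r$background))
    # SDH band strictly inside the dorsal horn
    expect_true(all(s$horn_mask[r$sdh]))
    expect_true(any(s$horn_mask & !r$sdh))
  }
})

test_that("marker channel is bright only inside the SDH band", {
  s <- generate_section(quiet_params(), seed = 3)
  expect_true(all(s$cgrp[s$rois$sdh] > 0))
  expect_true(all(s$cgrp[!s$rois$sdh] == 0))
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_params(band_px = 200), "strictly inside")
  expect_error(phantom_params(rho = 0), "rho")
  expect_error(phantom_params(background_frac = 1), "background_frac")
})

test_that("measured ratio calibrates to rho under default noise", {
  # Monte-Carlo over seeds at the rat-scale anchor contrast
  p <- phantom_params(rho = 1.78)
  ratios <- vapply(1:20, function(seed) {
    s <- generate_section(p, seed = seed)
    mean(s$cb1[s$rois$sdh]) / mean(s$cb1[s$rois$ddh])
  }, 1)
  expect_lt(abs(mean(ratios) - 1.78) / 1.78, 0.05)
})

test_that("cohorts have the declared size and subject-effect structure", {
  spec <- cohort_spec(n_per_cell = 6, replicates = 3, sexes = "female",
                      species = "rat", master_seed = 11)
  co <- generate_cohort(spec)
  expect_length(co$sections, 18)
  expect_equal(nrow(co$metadata), 18)
  expect_length(unique(co$metadata$subject), 6)
  expect_length(unique(co$metadata$subject_effect), 6)
  # effects shared across a subject's replicates
  by_subj <- tapply(co$metadata$subject_effect, co$metadata$subject,
                    function(x) length(unique(x)))
  expect_true(all(by_subj == 1))
})

test_that("cohort generation is reproducible from the master seed", {
  spec <- cohort_spec(n_per_cell = 2, replicates = 2, master_seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$metadata, b$metadata)
  for (i in seq_along(a$sections)) {
    expect_identical(a$sections[[i]]$cb1, b$sections[[i]]$cb1)
    expect_identical(a$sections[[i]]$cgrp, b$sections[[i]]$cgrp)
  }
  c2 <- generate_cohort(cohort_spec(n_per_cell = 2, replicates = 2, master_seed = 6))
  expect_false(identical(a$sections[[1]]$cb1, c2$sections[[1]]$cb1))
})

test_that("with all variance sources off every subject ratio equals rho", {
  spec <- cohort_spec(n_per_cell = 3, replicates = 2, sexes = "female",
                      params = quiet_params(rho = 1.5), master_seed = 2)
  co <- generate_cohort(spec)
  m <- measure_cohort(co, roi_source = "truth")
  expect_equal(m$cohort$ratio, rep(1.5, 3), tolerance = 1e-12)
})

test_that("count matrices honour their negative-binomial specification", {
  spec <- counts_spec(genes = c("g1", "g2"), clusters = c("c1", "c2"),
                      cells_per_cluster = 30,
                      means = matrix(c(0, 0, 0, 0), 2, 2),
                      laminae = c("lamina I", "lamina V"), seed = 3)
  d <- generate_counts(spec)
  expect_true(all(d$counts == 0))
  groups <- pool_groups(d$annotation, grouping_scheme())
  for (g in names(groups)) {
    expect_equal(percent_expressed(d$counts, groups[[g]], "g1"), 0)
  }
})

test_that("SDH-enriched target gene shows higher pooled average CPM", {
  wins <- vapply(1:10, function(seed) {
    d <- generate_counts(default_counts_spec(cells_per_cluster = 60, seed = seed))
    tab <- dot_plot_table(d$counts, d$annotation, grouping_scheme(), "Cnr1")
    tab$avg_cpm[tab$group == "SDH"] > tab$avg_cpm[tab$group == "DDH"]
  }, TRUE)
  expect_true(all(wins))
})

test_that("counts are reproducible and dispersion -> Inf approaches Poisson", {
  spec <- counts_spec(genes = "g", clusters = "c", cells_per_cluster = 1e4,
                      means = matrix(5), dispersion = Inf,
                      laminae = "lamina I", seed = 9)
  d <- generate_counts(spec)
  x <- as.numeric(d$counts)
  expect_lt(abs(var(x) / mean(x) - 1), 0.1)
  d2 <- generate_counts(spec)
  expect_identical(d$counts, d2$counts)
  # finite dispersion is overdispersed: var/mean ~ 1 + mu/size
  spec2 <- counts_spec(genes = "g", clusters = "c", cells_per_cluster = 1e4,
                       means = matrix(5), dispersion = 2,
                       laminae = "lamina I", seed = 9)
  x2 <- as.numeric(generate_counts(spec2)$counts)
  expect_gt(var(x2) / mean(x2), 2)
})

test_that("counts_spec validates its inputs", {
  expect_error(counts_spec("g", "c", 10, matrix(-1), laminae = "lamina I"),
               ">= 0")
  expect_error(counts_spec("g", "c", 10, matrix(1), dispersion = 0,
                           laminae = "lamina I"), "> 0")
  expect_error(counts_spec("g", "c", 10, matrix(1), laminae = ""),
               "nonempty")
  expect_error(counts_spec("g", "c", 10, matrix(1), laminae = "lamina I",
                           target_genes = "absent"), "absent")
})
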