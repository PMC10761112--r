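test_that("CPM normalization follows the formula and conserves 1e6 per cell", {
  cpm <- cpm_normalize(matrix(c(1, 0, 3), 3, 1,
                              dimnames = list(c("a", "b", "c"), "cell")))
  expect_equal(as.numeric(cpm), c(250000, 0, 750000))
  expect_equal(sum(cpm), 1e6)

  set.seed(4)
  m <- matrix(rpois(300, 2), 20, 15,
              dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:15)))
  m[, 1] <- pmax(m[, 1], 1) # keep every cell nonzero for this check
  cpm <- cpm_normalize(m)
  expect_equal(unname(colSums(cpm)), rep(1e6, ncol(cpm)))
  # doubling a cell's counts leaves its CPM unchanged
  m2 <- m; m2[, 3] <- m2[, 3] * 2
  expect_equal(cpm_normalize(m2)[, 3], cpm[, 3])
})

test_that("zero-total cells are dropped with a warning, all-zero errors", {
  m <- matrix(c(1, 2, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_warning(cpm <- cpm_normalize(m), "zero total")
  expect_equal(colnames(cpm), "c1")
  expect_error(cpm_normalize(matrix(0, 2, 2)), "every cell")
})

test_that("laminar annotations parse into tokens with range expansion", {
  expect_equal(parse_laminae("laminae I-II"), c("I", "II"))
  expect_equal(parse_laminae("lamina IIo"), "IIo")
  expect_equal(parse_laminae("laminae III-VI"), c("III", "IV", "V", "VI"))
  expect_setequal(parse_laminae("laminae II, IIi"), c("II", "IIi"))
  expect_error(parse_laminae("lamina VII"), "unresolvable")
  expect_error(parse_laminae("laminae IIo-III"), "unresolvable")
})

test_that("pooling follows the laminar scheme with dual membership", {
  fx <- worked_fixture()
  ann2 <- cluster_annotation(
    cells = data.frame(cell = paste0("c", 1:8),
                       cluster = rep(c("C1", "C2"), each = 4)),
    clusters = data.frame(cluster = c("C1", "C2"),
                          laminae = c("laminae I-II", "lamina V"))
  )
  groups <- pool_groups(ann2, grouping_scheme())
  # lamina II sits in both pools, so C1 joins SDH and DDH
  expect_setequal(groups$SDH, paste0("c", 1:4))
  expect_setequal(groups$DDH, paste0("c", 1:8))
  expect_setequal(groups$DH, paste0("c", 1:8))

  # a lamina V cluster is DDH-only
  groups1 <- pool_groups(fx$ann, grouping_scheme())
  expect_setequal(groups1$SDH, paste0("c", 1:4))
  expect_setequal(groups1$DDH, paste0("c", 5:8))

  # empty scheme: every cell only in the overall group
  g0 <- pool_groups(fx$ann, grouping_scheme(list()))
  expect_equal(names(g0), "DH")
  expect_length(g0$DH, 8)
})

test_that("average CPM and percent expressed match their definitions", {
  fx <- worked_fixture()
  cpm <- cpm_normalize(fx$counts)
  expect_equal(average_cpm(cpm, c("c1", "c2"), "g1"), (500000 + 0) / 2)
  expect_equal(average_cpm(cpm, paste0("c", 5:8), "g1"), 0)
  expect_equal(percent_expressed(fx$counts, paste0("c", 1:4), "g1"), 75)
  expect_equal(percent_expressed(fx$counts, paste0("c", 5:8), "g1"), 0)
  expect_equal(percent_expressed(fx$counts, paste0("c", 1:4), "g2"), 100)
  expect_error(average_cpm(cpm, character(0), "g1"), "empty")
  expect_error(percent_expressed(fx$counts, "c1", "nope"), "not in matrix")
})

test_that("color z-scores use population standardization with the
           zero-variance convention", {
  expect_equal(color_zscore(c(10, 10, 10)), c(0, 0, 0))
  expect_equal(color_zscore(c(0, 999999)), c(-1, 1))
  expect_equal(color_zscore(123456), 0)
  set.seed(8)
  for (i in 1:5) {
    z <- color_zscore(runif(4, 0, 1e5))
    expect_equal(mean(z), 0)
    expect_equal(sqrt(mean(z^2)), 1)
  }
})

test_that("the dot-plot table reproduces the hand-computed oracle exactly", {
  fx <- worked_fixture()
  tab <- dot_plot_table(fx$counts, fx$ann, grouping_scheme(), c("g1", "g2", "g3"))
  expect_equal(tab$group, rep(c("SDH", "DDH", "DH"), 3))
  # every cell totals 10 counts, so CPM = count * 1e5; oracle values are
  # plain arithmetic on the printed matrix
  expect_equal(tab$avg_cpm[tab$gene == "g1"], c(200000, 0, 100000))
  expect_equal(tab$avg_cpm[tab$gene == "g2"], c(450000, 100000, 275000))
  expect_equal(tab$avg_cpm[tab$gene == "g3"], c(350000, 900000, 625000))
  expect_equal(tab$pct_expressed[tab$gene == "g1"], c(75, 0, 37.5))
  expect_equal(tab$pct_expressed[tab$gene == "g2"], c(100, 75, 87.5))
  expect_equal(tab$pct_expressed[tab$gene == "g3"], c(75, 100, 87.5))
  expect_equal(tab$n_cells, rep(c(4, 4, 8), 3))
  for (g in c("g1", "g2", "g3")) {
    x <- log10(tab$avg_cpm[tab$gene == g] + 1)
    expect_equal(tab$z[tab$gene == g],
                 (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
    expect_equal(mean(tab$z[tab$gene == g]), 0)
  }
})

test_that("permuting cell order leaves the dot-plot table unchanged", {
  fx <- worked_fixture()
  tab1 <- dot_plot_table(fx$counts, fx$ann, grouping_scheme(), c("g1", "g2"))
  perm <- c(5, 2, 8, 1, 4, 7, 3, 6)
  counts2 <- fx$counts[, perm]
  ann2 <- cluster_annotation(cells = fx$ann$cells[perm, ],
                             clusters = fx$ann$clusters)
  tab2 <- dot_plot_table(counts2, ann2, grouping_scheme(), c("g1", "g2"))
  expect_equal(tab1, tab2)
})

test_that("missing target genes error or warn, never vanish silently", {
  fx <- worked_fixture()
  expect_error(dot_plot_table(fx$counts, fx$ann, genes = c("x", "y")),
               "none of the target genes")
  expect_warning(tab <- dot_plot_table(fx$counts, fx$ann,
                                       genes = c("g1", "missing")),
                 "missing")
  expect_setequal(unique(tab$gene), "g1")
})

test_that("a zero-count cell can only dilute a group", {
  fx <- worked_fixture()
  counts <- cbind(fx$counts, c9 = c(0, 0, 1)) # zero for g1/g2
  ann <- cluster_annotation(
    cells = rbind(fx$ann$cells, data.frame(cell = "c9", cluster = "C1")),
    clusters = fx$ann$clusters
  )
  before <- dot_plot_table(fx$counts, fx$ann, grouping_scheme(), "g1")
  after <- dot_plot_table(counts, ann, grouping_scheme(), "g1")
  expect_lte(after$avg_cpm[after$group == "SDH"],
             before$avg_cpm[before$group == "SDH"])
  expect_lte(after$pct_expressed[after$group == "SDH"],
             before$pct_expressed[before$group == "SDH"])
})

test_that("dot plots render deterministically and reject empty tables", {
  fx <- worked_fixture()
  tab <- dot_plot_table(fx$counts, fx$ann, grouping_scheme(), c("g1", "g2"))
  f <- withr::local_tempfile(fileext = ".png")
  render_dot_plot(tab, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_error(render_dot_plot(tab[0, ], withr::local_tempfile(fileext = ".png")),
               "empty")
})

test_that("MTX round trip preserves counts and annotations", {
  d <- generate_counts(default_counts_spec(n_background = 5,
                                           cells_per_cluster = 10, seed = 2))
  dir <- withr::local_tempdir()
  write_counts_mtx(d$counts, d$annotation, dir)
  rt <- read_counts_mtx(dir)
  expect_equal(rt$counts, d$counts)
  expect_equal(rt$annotation$clusters, d$annotation$clusters)
})
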