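test_that("signed-rank normal approximation reproduces the small-n anchors", {
  # uniformly positive differences with distinct magnitudes
  a6 <- c(2.1, 3.2, 4.3, 5.4, 6.5, 7.6); b6 <- c(1.0, 1.5, 2.0, 2.5, 3.0, 3.5)
  t6 <- wilcoxon_signed_rank(a6, b6)
  expect_equal(unname(t6$statistic["W"]), 21)
  expect_equal(round(t6$p, 3), 0.028)
  expect_equal(t6$p, 2 * pnorm(-(21 - 10.5) / sqrt(6 * 7 * 13 / 24)))

  a7 <- 2:8 + 0.1 * (1:7); b7 <- rep(1, 7)
  t7 <- wilcoxon_signed_rank(a7, b7)
  expect_equal(unname(t7$statistic["W"]), 28)
  expect_equal(round(t7$p, 3), 0.018)
})

test_that("signed-rank exact mode enumerates the sign distribution", {
  d <- c(3, 5, 8, 2, 9, 4) # all positive, distinct
  t <- wilcoxon_signed_rank(d, mode = "exact")
  expect_equal(t$p, 2 / 64)
  # against the independent enumeration oracle on random differences
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:9, 1)
    d <- round(rnorm(n), 2)
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d, mode = "exact")$p,
                 oracle_signed_rank_p(d))
  }
})

test_that("zero differences are discarded with a note, all-zero errors", {
  t <- wilcoxon_signed_rank(c(0, 1, 2, 3, 0, 4, 5, 6))
  expect_equal(unname(t$n["n"]), 6)
  expect_match(paste(t$notes, collapse = " "), "zero difference")
  expect_equal(round(t$p, 3), 0.028) # reduces to the n = 6 anchor
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "all differences")
})

test_that("rank-test invariances hold: monotone for Mann-Whitney, affine
           for signed-rank", {
  set.seed(7)
  a <- rlnorm(8); b <- rlnorm(8)
  # Mann-Whitney only sees pooled ranks, so any strictly increasing
  # transform leaves it untouched
  f <- function(x) x^3 + 2 * log1p(x)
  expect_equal(mann_whitney_u(a, b, mode = "exact")$p,
               mann_whitney_u(f(a), f(b), mode = "exact")$p)
  expect_equal(mann_whitney_u(a, b)$p, mann_whitney_u(f(a), f(b))$p)
  # the signed-rank test ranks difference magnitudes, so its invariance is
  # to increasing affine maps (shared shift and positive rescale)
  g <- function(x) 2.5 * x + 3
  expect_equal(wilcoxon_signed_rank(a, b)$p,
               wilcoxon_signed_rank(g(a), g(b))$p)
  expect_equal(wilcoxon_signed_rank(a, b, mode = "exact")$p,
               wilcoxon_signed_rank(g(a), g(b), mode = "exact")$p)
  # W within combinatorial bounds
  W <- wilcoxon_signed_rank(a, b)$statistic[["W"]]
  expect_gte(W, 0); expect_lte(W, 8 * 9 / 2)
})

test_that("Mann-Whitney handles symmetry, separation and tie degeneracy", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  t <- mann_whitney_u(x, x)
  expect_equal(unname(t$statistic["U"]), 8) # n1 n2 / 2
  expect_equal(t$p, 1.0)
  sep <- mann_whitney_u(c(1, 2, 3), c(10, 20, 30), mode = "exact")
  expect_equal(sep$p, 2 / 20)
  allsame <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(allsame$p, 1)
})

test_that("Mann-Whitney exact matches the enumeration oracle", {
  set.seed(11)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- round(rnorm(n1), 1); b <- round(rnorm(n2), 1) # rounding makes ties
    expect_equal(mann_whitney_u(a, b, mode = "exact")$p, oracle_mwu_p(a, b))
  }
})

test_that("exact and asymptotic Mann-Whitney agree for moderate n", {
  # above the enumeration cap the exact request resolves to the asymptotic
  # mode (with a note), so the two agree exactly at n1 = n2 = 20
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(20, 0.5)
    pe <- mann_whitney_u(a, b, mode = "exact")$p
    pa <- mann_whitney_u(a, b, mode = "asymptotic")$p
    expect_lt(abs(pe - pa), 0.02)
  }
  # at the cap boundary the normal approximation is already close: compare
  # to the reference exact distribution (no ties, so it is available)
  for (i in 1:5) {
    a <- rnorm(7); b <- rnorm(7, 0.5)
    pe <- mann_whitney_u(a, b, mode = "exact")$p
    pref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)$p.value
    expect_equal(pe, pref)
  }
})

test_that("enumeration caps fall back to the asymptotic mode with a note", {
  set.seed(5)
  t <- wilcoxon_signed_rank(rnorm(30), rnorm(30), mode = "exact")
  expect_equal(t$mode, "asymptotic")
  expect_match(paste(t$notes, collapse = " "), "cap")
  t2 <- mann_whitney_u(rnorm(10), rnorm(10), mode = "exact")
  expect_equal(t2$mode, "asymptotic")
})

test_that("one-way ANOVA matches the textbook fixture and t^2 identity", {
  t <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(unname(t$statistic["F"]), 3.0)
  expect_equal(unname(t$df), c(2, 6))

  set.seed(2)
  g1 <- rnorm(8); g2 <- rnorm(8, 1)
  F <- one_way_anova(list(g1, g2))$statistic[["F"]]
  tt <- t.test(g1, g2, var.equal = TRUE)$statistic
  expect_equal(F, unname(tt)^2)
  expect_error(one_way_anova(list(rep(1, 3), rep(1, 3))), "degenerate")
})

test_that("assumption gate passes clean normal data and fails outliers", {
  verdicts <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- rnorm(50)
    assumption_checks(list(x, x))$verdict
  }, TRUE)
  expect_gte(mean(verdicts), 0.9)

  set.seed(1)
  clean <- rnorm(10)
  spiked <- c(rnorm(9), 40) # extreme outlier drives variance and non-normality
  rep <- assumption_checks(list(clean, spiked))
  expect_false(rep$verdict)
  expect_error(assumption_checks(list(clean, c(1, 2))), "too small")
})

test_that("the gate selects the prescribed test", {
  met <- structure(list(levene = c(statistic = 0, p = 1),
                        shapiro = data.frame(group = 1, W = 1, p = 1),
                        alpha = 0.05, verdict = TRUE),
                   class = "assumption_report")
  violated <- met; violated$verdict <- FALSE
  expect_equal(select_test("independent", met)$test, "one_way_anova")
  expect_equal(select_test("independent", violated)$test, "mann_whitney_u")
  expect_equal(select_test("paired", violated)$test, "wilcoxon_signed_rank")
  paired_met <- select_test("paired", met)
  expect_equal(paired_met$test, "wilcoxon_signed_rank")
  expect_match(paired_met$note, "assumptions met")
})

test_that("alignment matches a hand-computed balanced 2x2 oracle", {
  # cells (A1,B1)=(1,3), (A1,B2)=(5,7), (A2,B1)=(2,4), (A2,B2)=(10,14)
  y <- c(1, 3, 5, 7, 2, 4, 10, 14)
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(rep(c("b1", "b2"), each = 2), 2)
  # cell means: 2, 6, 3, 12; row means: 4, 7.5; col means: 2.5, 9; grand 5.75
  # residuals: -1,1,-1,1,-1,1,-2,2
  expect_equal(art_align(y, A, B, "A"),
               c(-1, 1, -1, 1, -1, 1, -2, 2) +
                 rep(c(4 - 5.75, 7.5 - 5.75), each = 4))
  expect_equal(art_align(y, A, B, "B"),
               c(-1, 1, -1, 1, -1, 1, -2, 2) +
                 rep(rep(c(2.5 - 5.75, 9 - 5.75), each = 2), 2))
  # interaction estimates: cell - row - col + grand, in cell order
  # (a1,b1), (a1,b2), (a2,b1), (a2,b2)
  inter <- c(2 - 4 - 2.5 + 5.75, 6 - 4 - 9 + 5.75,
             3 - 7.5 - 2.5 + 5.75, 12 - 7.5 - 9 + 5.75)
  expect_equal(art_align(y, A, B, "A:B"),
               c(-1, 1, -1, 1, -1, 1, -2, 2) + rep(inter, each = 2))
})

test_that("aligned responses sum to zero and pure effects align away", {
  set.seed(21)
  cells <- expand.grid(A = c("x", "y"), B = c("u", "v"))
  for (i in 1:10) {
    # balanced complete layout, rows in random order
    ord <- sample(24)
    A <- rep(cells$A, each = 6)[ord]
    B <- rep(cells$B, each = 6)[ord]
    y <- rnorm(24)
    for (eff in c("A", "B", "A:B")) {
      al <- art_align(y, A, B, eff)
      expect_lt(abs(sum(al)), 1e-8 * max(1, max(abs(y))))
    }
  }
  # a pure A main effect leaves nothing for B after alignment
  A <- rep(c("x", "y"), each = 8)
  B <- rep(rep(c("u", "v"), each = 4), 2)
  y <- ifelse(A == "x", 0, 10) + rnorm(16, sd = 0.1)
  aligned_b <- art_align(y, A, B, "B")
  fit <- anova(aov(aligned_b ~ factor(A) * factor(B)))
  expect_lt(fit["factor(A)", "F value"], 1e-6)
})

test_that("ART ANOVA detects a strong main effect and reports clean
           diagnostics", {
  set.seed(33)
  A <- rep(c("f", "m"), each = 14)
  B <- rep(rep(c("rat", "human"), each = 7), 2)
  hits <- 0
  for (i in 1:500) {
    y <- rnorm(28) + ifelse(A == "f", 2, 0) # 2 SD shift on A
    res <- art_anova(y, A, B)
    hits <- hits + (res$effects$p[res$effects$effect == "A"] < 0.05)
  }
  expect_gte(hits / 500, 0.9)

  y <- rnorm(28)
  res <- art_anova(y, A, B)
  expect_lt(max(abs(res$diagnostics$aligned_sum)), 1e-8)
  expect_lt(max(unlist(res$diagnostics$cross_F)), 1e-6)
  # ranks are a permutation: the rank transform must conserve the rank sum
  al <- art_align(y, A, B, "A")
  expect_equal(sum(rank(al)), 28 * 29 / 2)
})

test_that("ART ANOVA rejects incomplete or under-replicated layouts", {
  y <- rnorm(6)
  A <- c("a", "a", "a", "a", "b", "b")
  B <- c("u", "u", "v", "v", "u", "u") # cell (b, v) empty
  expect_error(art_anova(y, A, B), "two observations per cell|empty cell")
  expect_error(art_align(rnorm(4), c("a", "a", "b", "b"), c("u", "v", "u", "u")),
               "empty cell")
})

test_that("ART ANOVA handles mildly unbalanced layouts", {
  set.seed(9)
  A <- c(rep("f", 12), rep("m", 14))
  B <- c(rep(c("rat", "human"), each = 6), rep(c("rat", "human"), each = 7))
  y <- rnorm(26) + ifelse(A == "f", 1.5, 0)
  res <- art_anova(y, A, B)
  expect_equal(nrow(res$effects), 3)
  expect_true(all(res$effects$p >= 0 & res$effects$p <= 1))
  expect_lt(res$effects$p[res$effects$effect == "A"], 0.05)
})
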