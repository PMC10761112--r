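#' Test-result container
#'
#' @param method method name.
#' @param statistic named statistic value.
#' @param p two-sided p-value.
#' @param n sample size(s), named where applicable.
#' @param mode `"exact"` or `"asymptotic"`.
#' @param notes character vector of notes (zero differences discarded, tie
#'   handling, cap fallbacks).
#' @return An object of class `dh_test`.
#' @export
dh_test <- function(method, statistic, p, n, mode = "asymptotic", notes = character()) {
  check_that(is.finite(p) && p >= 0 && p <= 1, "p-value must be in [0, 1]")
  structure(list(method = method, statistic = statistic, p = p, n = n,
                 mode = mode, notes = notes), class = "dh_test")
}

#' @export
print.dh_test <- function(x, ...) {
  cat(sprintf("%s (%s): %s = %.4g, p = %.4g, n = %s\n",
              x$method, x$mode, names(x$statistic)[1], x$statistic[1], x$p,
              paste(x$n, collapse = "/")))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are discarded before ranking and no continuity
#' correction is applied in the asymptotic mode — the variant that
#' reproduces SPSS output for small paired designs (two-sided p = .028 at
#' n = 6 and .018 at n = 7 when every difference has the same sign).
#' Absolute differences are ranked with average ranks on ties; W is the sum
#' of ranks of the positive differences.
#'
#' Exact mode enumerates all `2^n` sign assignments of the observed ranks
#' (capped at n = 25; beyond the cap the test falls back to asymptotic mode
#' with a note) and doubles the smaller tail, capping at 1. Asymptotic mode
#' uses `Z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)` with
#' a tie correction in the variance.
#'
#' @param a,b paired numeric vectors, or `b = NULL` to treat `a` as
#'   differences.
#' @param mode `"exact"` or `"asymptotic"`.
#' @return A [dh_test()] with statistic `W`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, mode = c("asymptotic", "exact")) {
  mode <- match.arg(mode)
  d <- if (is.null(b)) a else {
    check_that(length(a) == length(b), "paired samples must have equal length")
    a - b
  }
  check_that(all(is.finite(d)), "differences must be finite")
  notes <- character()
  nzero <- sum(d == 0)
  if (nzero > 0) {
    notes <- c(notes, sprintf("%d zero difference(s) discarded", nzero))
    d <- d[d != 0]
  }
  if (length(d) == 0) stop("all differences are zero; signed-rank test undefined", call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- table(r)
  if (any(ties > 1)) notes <- c(notes, "average ranks used for tied absolute differences")

  if (mode == "exact" && n > 25) {
    notes <- c(notes, "n above exact-enumeration cap (25); asymptotic mode used")
    mode <- "asymptotic"
  }
  if (mode == "exact") {
    # distribution of W over all 2^n sign assignments, by iterative doubling
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    total <- length(sums)
    p <- min(1, 2 * min(sum(sums >= W), sum(sums <= W)) / total)
    return(dh_test("Wilcoxon signed-rank", c(W = W), p, c(n = n), "exact", notes))
  }
  mu <- n * (n + 1) / 4
  tie_counts <- as.vector(table(abs(d)[duplicated(abs(d)) | duplicated(abs(d), fromLast = TRUE)]))
  tie_term <- if (length(tie_counts)) sum(tie_counts^3 - tie_counts) / 48 else 0
  v <- n * (n + 1) * (2 * n + 1) / 24 - tie_term
  if (v <= 0) {
    return(dh_test("Wilcoxon signed-rank", c(W = W), 1, c(n = n), "asymptotic",
                   c(notes, "degenerate variance")))
  }
  Z <- (W - mu) / sqrt(v)
  p <- 2 * pnorm(-abs(Z))
  out <- dh_test("Wilcoxon signed-rank", c(W = W), min(p, 1), c(n = n), "asymptotic", notes)
  out$Z <- Z
  out
}

#' Mann-Whitney U test for independent samples
#'
#' U is computed from the rank sum of the first sample in the pooled
#' ranking (average ranks on ties): `U = R1 - n1(n1+1)/2`. Exact mode
#' enumerates all `choose(n1+n2, n1)` group labelings of the pooled ranks
#' (capped at n1+n2 = 14, falling back to asymptotic beyond it) and doubles
#' the smaller tail. Asymptotic mode uses the normal approximation with
#' tie-corrected variance and no continuity correction.
#'
#' @param a,b numeric samples.
#' @param mode `"exact"` or `"asymptotic"`.
#' @return A [dh_test()] with statistic `U` (for sample `a`).
#' @export
mann_whitney_u <- function(a, b, mode = c("asymptotic", "exact")) {
  mode <- match.arg(mode)
  check_that(length(a) >= 1 && length(b) >= 1, "both samples must be nonempty")
  check_that(all(is.finite(c(a, b))), "samples must be finite")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  notes <- character()
  if (anyDuplicated(c(a, b))) notes <- c(notes, "average ranks used for ties")

  if (mode == "exact" && N > 14) {
    notes <- c(notes, "n1+n2 above exact-enumeration cap (14); asymptotic mode used")
    mode <- "asymptotic"
  }
  if (mode == "exact") {
    labelings <- combn(N, n1)
    Us <- colSums(matrix(r[labelings], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(sum(Us >= U), sum(Us <= U)) / ncol(labelings))
    return(dh_test("Mann-Whitney U", c(U = U), p, c(n1 = n1, n2 = n2), "exact", notes))
  }
  mu <- n1 * n2 / 2
  tie_counts <- as.vector(table(c(a, b)))
  tie_counts <- tie_counts[tie_counts > 1]
  tie_term <- if (length(tie_counts)) sum(tie_counts^3 - tie_counts) / (N * (N - 1)) else 0
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    return(dh_test("Mann-Whitney U", c(U = U), 1, c(n1 = n1, n2 = n2), "asymptotic",
                   c(notes, "degenerate variance (all values tied)")))
  }
  Z <- (U - mu) / sqrt(v)
  out <- dh_test("Mann-Whitney U", c(U = U), min(2 * pnorm(-abs(Z)), 1),
                 c(n1 = n1, n2 = n2), "asymptotic", notes)
  out$Z <- Z
  out
}

#' One-way analysis of variance
#'
#' Standard between/within F test on two or more independent groups,
#' delegated to the base ANOVA fit.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return A [dh_test()] with statistic `F` and `df` field.
#' @export
one_way_anova <- function(groups) {
  check_that(is.list(groups) && length(groups) >= 2, "need at least two groups")
  check_that(all(vapply(groups, length, 1L) >= 2), "every group needs n >= 2")
  y <- unlist(groups)
  if (diff(range(y)) == 0) {
    stop("degenerate ANOVA: no variance between or within groups", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  tab <- suppressWarnings(anova(aov(y ~ g))) # perfect separation warns
  F <- tab$`F value`[1]
  out <- dh_test("one-way ANOVA", c(F = F), tab$`Pr(>F)`[1],
                 c(n = length(y)), "asymptotic")
  out$df <- c(df1 = tab$Df[1], df2 = tab$Df[2])
  out
}

#' Parametric-assumption checks
#'
#' Levene's test (mean-centered variant) for homogeneity of variance
#' across groups, and a Shapiro-Wilk normality test per group. The verdict
#' is `TRUE` iff the Levene p and every Shapiro-Wilk p exceed `alpha`;
#' a constant group fails normality by convention.
#'
#' @param groups list of numeric vectors, each of length >= 3.
#' @param alpha significance level for the gate.
#' @return An object of class `assumption_report`: `levene` (statistic, p),
#'   `shapiro` (per-group data frame), `alpha`, `verdict`.
#' @export
assumption_checks <- function(groups, alpha = 0.05) {
  check_that(is.list(groups) && length(groups) >= 1, "`groups` must be a nonempty list")
  ns <- vapply(groups, length, 1L)
  small <- which(ns < 3)
  if (length(small)) {
    stop("group(s) too small for assumption checks (n >= 3 needed): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), ns))
  lev <- if (length(groups) >= 2) {
    tab <- car::leveneTest(y ~ g, center = mean)
    Fv <- tab$`F value`[1]; pv <- tab$`Pr(>F)`[1]
    if (!is.finite(Fv)) { Fv <- 0; pv <- 1 } # identical spreads in every group
    c(statistic = Fv, p = pv)
  } else {
    c(statistic = NA_real_, p = 1)
  }
  sw <- do.call(rbind, lapply(seq_along(groups), function(i) {
    x <- groups[[i]]
    if (diff(range(x)) == 0) {
      data.frame(group = i, W = NA_real_, p = 0) # constant: not normal
    } else {
      s <- shapiro.test(x)
      data.frame(group = i, W = unname(s$statistic), p = s$p.value)
    }
  }))
  verdict <- lev[["p"]] > alpha && all(sw$p > alpha)
  structure(list(levene = lev, shapiro = sw, alpha = alpha, verdict = verdict),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("Levene (mean-centered): F = %.4g, p = %.4g\n",
              x$levene[["statistic"]], x$levene[["p"]]))
  cat("Shapiro-Wilk per group:\n")
  print(x$shapiro, row.names = FALSE)
  cat(sprintf("parametric assumptions %s at alpha = %g\n",
              if (x$verdict) "met" else "violated", x$alpha))
  invisible(x)
}

#' Select the test prescribed by the assumption gate
#'
#' Independent samples get a one-way ANOVA when parametric assumptions are
#' met and a Mann-Whitney U test otherwise. Paired samples get the Wilcoxon
#' signed-rank test; the paired comparison is run as Wilcoxon even when
#' assumptions are met (with a note), since the battery defines no paired
#' parametric branch.
#'
#' @param design `"paired"` or `"independent"`.
#' @param report an [assumption_checks()] report.
#' @return A list with `test` (one of `"one_way_anova"`, `"mann_whitney_u"`,
#'   `"wilcoxon_signed_rank"`) and `note`.
#' @export
select_test <- function(design = c("paired", "independent"), report) {
  design <- match.arg(design)
  check_that(inherits(report, "assumption_report"), "`report` must be an assumption_report")
  if (design == "independent") {
    if (report$verdict) {
      list(test = "one_way_anova", note = "parametric assumptions met")
    } else {
      list(test = "mann_whitney_u", note = "parametric assumptions violated")
    }
  } else {
    note <- if (report$verdict) {
      "assumptions met, but paired comparisons are run as Wilcoxon signed-rank"
    } else {
      "parametric assumptions violated"
    }
    list(test = "wilcoxon_signed_rank", note = note)
  }
}
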