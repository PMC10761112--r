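#' Align responses for one effect of a two-factor layout
#'
#' The alignment step of the aligned rank transform: strip every effect
#' except the one of interest by subtracting cell means, then add back the
#' estimated effect of interest, computed from unweighted marginal means of
#' the cell means:
#'
#' * `A`: `y' = (y - cell) + (rowmean_A - grand)`
#' * `B`: `y' = (y - cell) + (colmean_B - grand)`
#' * `A:B`: `y' = (y - cell) + (cell - rowmean_A - colmean_B + grand)`
#'
#' Aligned responses sum to zero (exactly, up to floating point, for a
#' complete layout), and a factorial ANOVA on the *unranked* aligned
#' responses gives F = 0 for every effect other than the target — the
#' standard diagnostic that the alignment is correct.
#'
#' @param y numeric response vector.
#' @param A,B factors (coerced) of the same length as `y`; every A x B cell
#'   must be occupied.
#' @param effect `"A"`, `"B"`, or `"A:B"`.
#' @return Numeric vector of aligned responses.
#' @export
art_align <- function(y, A, B, effect = c("A", "B", "A:B")) {
  effect <- match.arg(effect)
  A <- factor(A); B <- factor(B)
  check_that(length(y) == length(A) && length(y) == length(B),
             "response and factors must have equal length")
  check_that(all(is.finite(y)), "responses must be finite")
  counts <- table(A, B)
  if (any(counts == 0)) {
    stop("empty cell(s) in the two-factor layout: ",
         paste(outer(rownames(counts), colnames(counts), paste, sep = ":")[counts == 0],
               collapse = ", "), call. = FALSE)
  }
  cell_means <- tapply(y, list(A, B), mean)
  row_means <- rowMeans(cell_means) # unweighted marginal means
  col_means <- colMeans(cell_means)
  grand <- mean(cell_means)
  ai <- as.integer(A); bi <- as.integer(B)
  cell <- cell_means[cbind(ai, bi)]
  est <- switch(effect,
    "A" = row_means[ai] - grand,
    "B" = col_means[bi] - grand,
    "A:B" = cell - row_means[ai] - col_means[bi] + grand
  )
  unname((y - cell) + est)
}

# Full two-way factorial ANOVA. Balanced complete layouts use the
# closed-form sums of squares; unbalanced layouts fall back to a Type III
# fit with sum-to-zero contrasts.
two_way_anova_table <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  counts <- table(A, B)
  a <- nrow(counts); b <- ncol(counts); N <- length(y)
  dfs <- c(A = a - 1, B = b - 1, `A:B` = (a - 1) * (b - 1))
  df_err <- N - a * b
  check_that(df_err >= 1, "need more than one observation per cell for the F tests")
  if (length(unique(as.vector(counts))) == 1L) {
    n <- counts[1, 1]
    cell_means <- tapply(y, list(A, B), mean)
    row_means <- rowMeans(cell_means); col_means <- colMeans(cell_means)
    grand <- mean(cell_means)
    inter <- sweep(sweep(cell_means, 1, row_means), 2, col_means) + grand
    ss <- c(
      A = n * b * sum((row_means - grand)^2),
      B = n * a * sum((col_means - grand)^2),
      `A:B` = n * sum(inter^2)
    )
    ss_err <- sum((y - cell_means[cbind(as.integer(A), as.integer(B))])^2)
  } else {
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old))
    fit <- stats::lm(y ~ A * B)
    tab <- car::Anova(fit, type = 3)
    ss <- c(A = tab["A", "Sum Sq"], B = tab["B", "Sum Sq"],
            `A:B` = tab["A:B", "Sum Sq"])
    ss_err <- tab["Residuals", "Sum Sq"]
  }
  ms_err <- ss_err / df_err
  F <- (ss / dfs) / ms_err
  p <- stats::pf(F, dfs, df_err, lower.tail = FALSE)
  data.frame(effect = names(dfs), ss = unname(ss), df1 = unname(dfs),
             df2 = df_err, F = unname(F), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Two-way aligned rank transform ANOVA
#'
#' Nonparametric factorial test: for each effect (both mains and the
#' interaction), align the responses for that effect ([art_align()]), rank
#' the aligned responses (average ranks on ties), run a full two-way ANOVA
#' on the ranks, and report that effect's F and p. Diagnostics record the
#' aligned-response column sums (which must vanish) and the F values of the
#' non-target effects in an ANOVA on the aligned but *unranked* responses
#' (which must be ~0 when the alignment is correct).
#'
#' @param y numeric response vector.
#' @param A,B factors of the same length; complete layout with at least two
#'   observations per cell.
#' @param alpha significance level recorded alongside the table.
#' @return An object of class `art_effect_table`: data frame `effects`
#'   (effect, F, df1, df2, p, significant), list `diagnostics` with
#'   `aligned_sum` and `cross_F` per effect, and `alpha`.
#' @export
art_anova <- function(y, A, B, alpha = 0.05) {
  A <- factor(A); B <- factor(B)
  counts <- table(A, B)
  check_that(all(counts >= 2), "ART ANOVA needs at least two observations per cell")
  effects <- c("A", "B", "A:B")
  rows <- list()
  aligned_sum <- numeric(0)
  cross_F <- list()
  for (eff in effects) {
    aligned <- art_align(y, A, B, eff)
    aligned_sum[eff] <- sum(aligned)
    ranks <- rank(aligned)
    tab <- two_way_anova_table(ranks, A, B)
    rows[[eff]] <- tab[tab$effect == eff, c("F", "df1", "df2", "p")]
    diag_tab <- two_way_anova_table(aligned, A, B)
    cross_F[[eff]] <- setNames(diag_tab$F[diag_tab$effect != eff],
                               diag_tab$effect[diag_tab$effect != eff])
  }
  eff_tab <- cbind(data.frame(effect = effects, stringsAsFactors = FALSE),
                   do.call(rbind, rows))
  rownames(eff_tab) <- NULL
  eff_tab$significant <- eff_tab$p < alpha
  structure(list(effects = eff_tab,
                 diagnostics = list(aligned_sum = aligned_sum, cross_F = cross_F),
                 alpha = alpha),
            class = "art_effect_table")
}

#' @export
print.art_effect_table <- function(x, ...) {
  cat("Aligned rank transform two-way ANOVA\n")
  print(x$effects, row.names = FALSE)
  cat(sprintf("max |aligned sum| = %.3g; max cross-effect F on aligned data = %.3g\n",
              max(abs(x$diagnostics$aligned_sum)),
              max(unlist(x$diagnostics$cross_F))))
  invisible(x)
}
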