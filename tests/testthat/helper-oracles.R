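# Independent brute-force oracles for the exact rank tests. These
# deliberately use a different enumeration mechanism (expand.grid over
# binary vectors) than the package implementations.

# Distribution of the signed-rank statistic W over all sign assignments of
# the given differences, and the doubled-tail two-sided p for the observed W.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(W_all >= W_obs), mean(W_all <= W_obs)))
}

# Doubled-tail two-sided p for the Mann-Whitney U of sample `a`, by
# enumerating group labelings as binary vectors.
oracle_mwu_p <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  lab <- as.matrix(expand.grid(rep(list(c(0, 1)), N)))
  lab <- lab[rowSums(lab) == n1, , drop = FALSE]
  U_all <- as.vector(lab %*% r) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(U_all >= U_obs), mean(U_all <= U_obs)))
}

# Fast low-noise phantom parameters shared by several tests; overrides win.
quiet_params <- function(...) {
  args <- list(poisson_gain = 0, read_noise_sd = 0,
               subject_sd = 0, replicate_sd = 0)
  args[names(list(...))] <- list(...)
  do.call(phantom_params, args)
}

# Shared worked fixture: 3 genes x 8 cells, every cell totalling 10 counts,
# cluster C1 (cells 1-4, lamina I -> SDH) and C2 (cells 5-8, lamina V -> DDH).
worked_fixture <- function() {
  counts <- matrix(c(
    5, 0, 1, 2, 0, 0, 0, 0,   # g1
    5, 8, 3, 2, 1, 1, 2, 0,   # g2
    0, 2, 6, 6, 9, 9, 8, 10   # g3
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:8)))
  ann <- cluster_annotation(
    cells = data.frame(cell = paste0("c", 1:8),
                       cluster = rep(c("C1", "C2"), each = 4)),
    clusters = data.frame(cluster = c("C1", "C2"),
                          laminae = c("lamina I", "lamina V"))
  )
  list(counts = counts, ann = ann)
}

# Grow a mask by one pixel in every direction (for boundary-ring checks).
dilate1 <- function(mask) {
  as.matrix(EBImage::imageData(EBImage::dilate(
    EBImage::as.Image(mask * 1), EBImage::makeBrush(3, "box")
  ))) > 0
}
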