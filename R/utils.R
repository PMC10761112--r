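#' @importFrom stats rnorm rpois rnbinom rlnorm pnorm shapiro.test aov anova
#'   setNames complete.cases sd
#' @importFrom utils read.csv write.csv combn head
NULL

# Internal parameter validation helper: stops with the offending name.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a child seed from a master seed
#'
#' All randomness in the synthetic-data generators flows from one master
#' seed. Child streams (one per subject, one per section, one per count
#' matrix) are split off deterministically with a multiplicative
#' congruential mix, so that any individual phantom can be regenerated
#' without replaying the whole cohort.
#'
#' @param master integer master seed.
#' @param index nonnegative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(master, index) {
  check_that(is_scalar_num(master), "`master` must be a single finite number")
  check_that(is_scalar_num(index) && index >= 0, "`index` must be a single nonnegative number")
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (abs(master) %% m)
  s <- (s * 48271) %% m
  s <- (s + (index %% m) * 16807) %% m
  as.integer(s %% (m - 1L) + 1)
}

# Run an expression with a local RNG state so generators do not disturb the
# caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Population (divide-by-n) standard deviation; used for display z-scoring.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Summed-area table lookup: sum of `x` over rows r0..r1, cols c0..c1 given
# the cumulative table `S` (padded with a leading zero row/col).
box_sum <- function(S, r0, r1, c0, c1) {
  S[r1 + 1, c1 + 1] - S[r0, c1 + 1] - S[r1 + 1, c0] + S[r0, c0]
}

padded_cumsum2d <- function(x) {
  S <- apply(apply(x, 2, cumsum), 1, cumsum)
  S <- t(S)
  rbind(0, cbind(0, S))
}
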