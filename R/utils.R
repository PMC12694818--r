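# Internal numerical and bookkeeping helpers.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All stochastic stages in the package draw their randomness from a single
#' user-supplied master seed. Independent streams (one per simulated mother,
#' per replicate, per pipeline stage) are derived with a fixed linear scheme
#' so that results are reproducible and do not depend on evaluation order.
#' Derived seeds stay below 2^31 - 1.
#'
#' @param seed master seed (non-negative integer).
#' @param offset stream index (non-negative integer).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, offset) {
  # exact in double arithmetic: values stay far below 2^53
  as.integer((abs(seed) %% 2147483647 * 48271 + offset * 7919) %% 2147483647)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Gauss-Legendre nodes/weights on [0, 1] by Golub-Welsch (symmetric
# tridiagonal Jacobi matrix). Exact for polynomials of degree <= 2n - 1,
# which is what makes the Kimura moment checks exact for a truncated series.
gauss_legendre01 <- function(n) {
  stopifnot(n >= 2)
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(nodes = (e$values + 1) / 2, weights = e$vectors[1, ]^2)
}

# Two-sample Kolmogorov-Smirnov distance without the hypothesis-test
# machinery. For continuous data the supremum is attained at a jump of the
# smaller sample's ECDF, so it is evaluated there in O(n log m):
# D = max_i max(i/n - Fy(x_(i)), Fy(x_(i)) - (i-1)/n).
ks_distance <- function(x, y, y_sorted = FALSE) {
  if (length(x) > length(y)) {
    tmp <- x; x <- y; y <- tmp
    y_sorted <- FALSE
  }
  x <- sort(x)
  if (!y_sorted) y <- sort(y)
  Fy <- findInterval(x, y) / length(y)
  i <- seq_along(x)
  max(i / length(x) - Fy, Fy - (i - 1) / length(x))
}

# Shapiro-Wilk gate used throughout the testing policy. shapiro.test() is
# limited to 5000 observations; longer vectors are thinned deterministically
# (every k-th value in input order) so the gate stays reproducible.
shapiro_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0) {
    return(list(normal = FALSE, p_value = NA_real_))
  }
  if (length(x) > 5000) {
    x <- x[seq(1, length(x), length.out = 5000)]
  }
  p <- stats::shapiro.test(x)$p.value
  list(normal = p > alpha, p_value = p)
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

collect_warnings <- function(expr) {
  warnings <- character(0)
  value <- withCallingHandlers(
    expr,
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  list(value = value, warnings = warnings)
}
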