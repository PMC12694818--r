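# The Kimura (1955) distribution of allele frequency under pure random drift,
# in the heteroplasmy parameterisation used in mtDNA transmission genetics:
# initial mutant fraction p and drift parameter b in [0, 1), with
#
#   E[X] = p,   Var[X] = p(1-p)(1-b),
#
# so b = (1 - 1/N)^t for a haploid Wright-Fisher population of N segregating
# mtDNA copies after t generations (b -> 1 means no drift). The distribution
# is a mixture of point masses at 0 (loss) and 1 (fixation) and a continuous
# density on (0, 1).
#
# Series evaluation. With F_i(x) = 2F1(1-i, i+2; 2; x), a degree-(i-1)
# polynomial, the classical eigenfunction expansion is
#
#   f(x)  = p q * sum_{i>=1} i(i+1)(2i+1) F_i(p) F_i(x) b^{i(i+1)/2}
#   P1(b) = p + sum_{i>=1} (2i+1) p q (-1)^i F_i(p) b^{i(i+1)/2}
#   P0(b) = q - sum_{i>=1} (2i+1) p q        F_i(p) b^{i(i+1)/2},  q = 1 - p.
#
# F_i links to Jacobi polynomials: F_i(x) = P_{i-1}^{(1,1)}(1 - 2x) / i, and
# P_n^{(1,1)} obeys the stable three-term recurrence
#   n(n+2) P_n(z) = (n+1)(2n+1) z P_{n-1}(z) - n(n+1) P_{n-2}(z),
# which is how all series terms are generated. |F_i| <= 1 on [0, 1] (Jacobi
# polynomials with unit weights peak at the endpoints), so the i-th density
# term is bounded by i(i+1)(2i+1) p q |F_i(p)| b^{i(i+1)/2}, the truncation
# criterion. Since the truncated density is a polynomial, moments are
# computed EXACTLY with Gauss-Legendre quadrature of sufficient order.

# Jacobi P_n^(1,1) values for n = 0..(nmax-1) at points z; returns a
# length(z) x nmax matrix.
jacobi11_matrix <- function(z, nmax) {
  out <- matrix(0, length(z), nmax)
  out[, 1] <- 1
  if (nmax >= 2) out[, 2] <- 2 * z
  if (nmax >= 3) {
    for (n in 2:(nmax - 1)) {
      out[, n + 1] <- ((n + 1) * (2 * n + 1) * z * out[, n] -
                         n * (n + 1) * out[, n - 1]) / (n * (n + 2))
    }
  }
  out
}

# F_i(x) = 2F1(1-i, i+2; 2; x) for i = 1..imax; length(x) x imax matrix.
kimura_F <- function(x, imax) {
  P <- jacobi11_matrix(1 - 2 * x, imax)
  sweep(P, 2, seq_len(imax), "/")
}

#' The Kimura pure-drift distribution of heteroplasmy
#'
#' Constructs the end-state distribution of heteroplasmy after neutral random
#' drift from initial fraction `p` with drift parameter `b`
#' (`Var = p(1-p)(1-b)`): loss mass `P0`, fixation mass `P1`, and the
#' continuous density on (0, 1), evaluated by an adaptively truncated
#' eigenfunction series. Mass conservation, `E[X] = p` and the variance
#' identity are verified at construction and the achieved residuals stored.
#'
#' @param p initial mutant fraction, strictly in (0, 1).
#' @param b drift parameter in `[0, 1)`; `b` within `1e-12` of 1 is accepted
#'   as the degenerate no-drift limit (point mass at `p`).
#' @param tolerance series tolerance in (0, 1e-3]; terms are added until the
#'   next term's bound falls below `tolerance * 1e-3` (hard cap 500 terms),
#'   and the mass-conservation residual must be below `tolerance`.
#' @param grid_points size of the uniform density grid on (0, 1) used for
#'   CDF construction and inverse-CDF sampling.
#' @return an object of class `kimura_distribution`: list with `p`, `b`,
#'   `loss_mass`, `fixation_mass`, `density` (vectorised function on (0,1)),
#'   `truncation_order`, `mean`, `variance`, `residual_mass`, `degenerate`,
#'   plus the sampling grid and interior CDF.
#' @examples
#' kd <- kimura_distribution(0.5, 0.5)
#' kd$loss_mass + kd$fixation_mass + integrate(kd$density, 0, 1)$value
#' @export
kimura_distribution <- function(p, b, tolerance = 1e-6, grid_points = 2001) {
  stopifnot(length(p) == 1, length(b) == 1)
  if (!(p > 0 && p < 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (!(b >= 0 && b <= 1)) stop("b must lie in [0, 1]", call. = FALSE)
  if (!(tolerance > 0 && tolerance <= 1e-3)) {
    stop("tolerance must lie in (0, 1e-3]", call. = FALSE)
  }
  q <- 1 - p

  if (b >= 1 - 1e-12) {
    # no-drift limit: degenerate at p
    obj <- list(
      p = p, b = b, loss_mass = 0, fixation_mass = 0,
      density = function(x) rep(0, length(x)),
      truncation_order = 0L, mean = p, variance = 0,
      residual_mass = 0, degenerate = TRUE,
      grid = numeric(0), interior_cdf = numeric(0)
    )
    class(obj) <- "kimura_distribution"
    return(obj)
  }

  max_terms <- 500L
  i <- seq_len(max_terms)
  log_w <- i * (i + 1) / 2 * log(b)          # log b^{i(i+1)/2}
  w <- ifelse(log_w < -690, 0, exp(log_w))   # drop terms that underflow
  Fp <- as.vector(kimura_F(p, max_terms))
  term_bound <- i * (i + 1) * (2 * i + 1) * p * q * abs(Fp) * w
  cut <- tolerance * 1e-3
  below <- term_bound < cut
  # keep terms up to the last one at or above the cut
  n_terms <- if (all(below)) 1L else max(which(!below))
  n_terms <- min(n_terms + 1L, max_terms)

  ii <- seq_len(n_terms)
  wi <- w[ii]
  Fpi <- Fp[ii]
  dens_coef <- ii * (ii + 1) * (2 * ii + 1) * p * q * Fpi * wi
  P1 <- p + sum((2 * ii + 1) * p * q * (-1)^ii * Fpi * wi)
  P0 <- q - sum((2 * ii + 1) * p * q * Fpi * wi)
  # boundary masses are probabilities; clip microscopic negative residue
  P0 <- min(max(P0, 0), 1)
  P1 <- min(max(P1, 0), 1)

  density <- function(x) {
    x <- as.numeric(x)
    out <- numeric(length(x))
    ok <- x > 0 & x < 1
    if (any(ok)) out[ok] <- pmax(as.vector(kimura_F(x[ok], n_terms) %*% dens_coef), 0)
    out
  }

  # exact moments of the truncated polynomial density
  gl <- gauss_legendre01(max(64L, ceiling((n_terms + 3) / 2)))
  fv <- density(gl$nodes)
  m0 <- sum(gl$weights * fv)
  m1 <- sum(gl$weights * gl$nodes * fv)
  m2 <- sum(gl$weights * gl$nodes^2 * fv)
  mass <- P0 + P1 + m0
  mean_x <- P1 + m1
  var_x <- P1 + m2 - mean_x^2
  residual <- abs(mass - 1)
  if (residual > tolerance) {
    stop(sprintf(paste0("Kimura series failed to conserve mass at %d terms: ",
                        "residual %.3g > tolerance %.3g"),
                 n_terms, residual, tolerance), call. = FALSE)
  }

  grid <- seq_len(grid_points) / (grid_points + 1)
  fg <- density(grid)
  # trapezoid CDF of the interior density along the grid, rescaled so the
  # interior integrates exactly to its quadrature mass
  step <- 1 / (grid_points + 1)
  cdf <- cumsum(c(0, (fg[-1] + fg[-grid_points]) / 2 * step))
  # add the two boundary slivers implicitly: rescale to m0
  if (cdf[grid_points] > 0) cdf <- cdf * (m0 / cdf[grid_points])

  obj <- list(
    p = p, b = b, loss_mass = P0, fixation_mass = P1,
    density = density, truncation_order = n_terms,
    mean = mean_x, variance = var_x, residual_mass = residual,
    degenerate = FALSE, grid = grid, interior_cdf = cdf
  )
  class(obj) <- "kimura_distribution"
  obj
}

#' @export
print.kimura_distribution <- function(x, ...) {
  cat(sprintf("Kimura drift distribution: p = %.4g, b = %.4g\n", x$p, x$b))
  cat(sprintf("  P(loss) = %.4g, P(fixation) = %.4g, %d series terms\n",
              x$loss_mass, x$fixation_mass, x$truncation_order))
  cat(sprintf("  mean = %.6g, variance = %.6g (residual mass %.2g)\n",
              x$mean, x$variance, x$residual_mass))
  invisible(x)
}

#' Sample heteroplasmy values from a Kimura distribution
#'
#' Draws i.i.d. values from the mixture: loss/fixation atoms first, then
#' inverse-CDF sampling of the interior density on the construction grid
#' (linear interpolation between grid points).
#'
#' @param dist a [kimura_distribution()] object.
#' @param n number of draws.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return numeric vector of heteroplasmy fractions in `[0, 1]`.
#' @export
kimura_sample <- function(dist, n, seed) {
  stopifnot(inherits(dist, "kimura_distribution"), n >= 1)
  if (dist$degenerate) {
    warning("degenerate Kimura distribution (b ~ 1): all samples equal p",
            call. = FALSE)
    return(with_seed(seed, rep(dist$p, n)))
  }
  with_seed(seed, {
    u <- stats::runif(n)
    out <- numeric(n)
    out[u < dist$loss_mass] <- 0
    out[u > 1 - dist$fixation_mass] <- 1
    mid <- u >= dist$loss_mass & u <= 1 - dist$fixation_mass
    if (any(mid)) {
      target <- u[mid] - dist$loss_mass
      cdf <- dist$interior_cdf
      grid <- dist$grid
      j <- findInterval(target, cdf, all.inside = TRUE)
      dj <- cdf[j + 1] - cdf[j]
      frac <- ifelse(dj > 0, (target - cdf[j]) / dj, 0.5)
      out[mid] <- grid[j] + frac * (grid[j + 1] - grid[j])
    }
    out
  })
}

#' Moment estimator of the drift parameter b
#'
#' Under the Kimura model the offspring variance around the mother value is
#' `h0(1-h0)(1-b)`, giving the variance-matching estimator
#' `b_hat = 1 - sum((h - h0)^2) / sum(h0(1-h0))`, clamped to `[0, 1)`.
#'
#' @param h0 mother heteroplasmy fractions, strictly interior.
#' @param h offspring/oocyte heteroplasmy fractions.
#' @return list with `b_hat`, `n`, and flags `no_drift` (zero dispersion:
#'   `b_hat` returned as the 1-limit) and `clamped` (raw estimate below 0).
#' @export
estimate_b <- function(h0, h) {
  ok <- is.finite(h0) & is.finite(h)
  h0 <- h0[ok]
  h <- h[ok]
  if (length(h0) < 2) stop("need at least 2 (h0, h) pairs", call. = FALSE)
  if (any(h0 <= 0 | h0 >= 1)) {
    stop("all h0 must lie strictly in (0, 1)", call. = FALSE)
  }
  raw <- 1 - sum((h - h0)^2) / sum(h0 * (1 - h0))
  no_drift <- FALSE
  clamped <- FALSE
  if (raw >= 1) {
    no_drift <- TRUE
    raw <- 1 - 1e-9
  } else if (raw < 0) {
    clamped <- TRUE
    warning("negative raw drift estimate clamped to 0 (dispersion exceeds the binomial-style bound)",
            call. = FALSE)
    raw <- 0
  }
  list(b_hat = raw, n = length(h0), no_drift = no_drift, clamped = clamped)
}

#' Simulation-based neutral-drift null test for selection on heteroplasmy
#'
#' Compares observed mother-to-offspring log heteroplasmy shifts against a
#' neutral null built by simulation: the drift parameter `b` is estimated
#' from the observed pairs by variance matching (so the test is sensitive to
#' the location/shape signature of selection, not to dispersion), then for
#' each mother `multiplier` draws are taken from Kimura(`h0`, `b_hat`) and
#' transformed to log shifts. The test statistic is the two-sample
#' Kolmogorov-Smirnov distance between observed and pooled simulated shifts;
#' its p-value comes from `n_null` parametric re-simulations (one draw per
#' pair each) against the same pool.
#'
#' @param pairs data frame with columns `mother_h` and `pup_h` (fractions);
#'   a `mother_id` column is used for per-mother stream seeding when present.
#' @param multiplier simulated draws per observed pair (default 1000).
#' @param seed master seed; per-mother and per-replicate streams are derived
#'   from it (see [derive_seed()]), so results do not depend on row order.
#' @param n_null number of re-simulated null replicates for the p-value.
#' @param boundary policy for log-transforming boundary draws/observations,
#'   see [boundary_policy()].
#' @param assay_copies clamp width parameter when `boundary = "clamp"`.
#' @param tolerance passed to [kimura_distribution()].
#' @return object of class `neutral_null`: `b_hat`, `ks_statistic`,
#'   `p_value`, `mean_difference` (observed minus simulated mean log shift;
#'   negative under purifying selection), `n_observed`, `n_simulated`,
#'   `boundary_exclusions` (counts for observed and simulated sets),
#'   `observed_shifts`, `simulated_shifts`, and `density_curves` (a data
#'   frame of x, observed_density, simulated_density for plotting parity).
#' @export
neutral_null_test <- function(pairs, multiplier = 1000, seed = 1,
                              n_null = 199,
                              boundary = c("exclude", "clamp"),
                              assay_copies = 5000, tolerance = 1e-6) {
  boundary <- match.arg(boundary)
  ok <- is.finite(pairs$mother_h) & is.finite(pairs$pup_h) &
    pairs$mother_h > 0 & pairs$mother_h < 1
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 10) {
    stop("insufficient data: need at least 10 pairs with interior mother heteroplasmy",
         call. = FALSE)
  }

  # observed log shifts under the boundary policy
  bp <- suppressWarnings(boundary_policy(pairs$pup_h, boundary, assay_copies))
  obs_keep <- !is.na(bp$h)
  observed <- log_shift(bp$h[obs_keep], pairs$mother_h[obs_keep])
  n_obs_excluded <- bp$n_boundary * (boundary == "exclude")
  if (sum(obs_keep) < 10) {
    stop("insufficient data after boundary exclusions", call. = FALSE)
  }

  fit <- estimate_b(pairs$mother_h, pairs$pup_h)
  b_hat <- fit$b_hat

  # one distribution per distinct mother heteroplasmy; mothers are ordered
  # by h0 so stream assignment is row-order invariant
  h0_levels <- sort(unique(pairs$mother_h))
  n_per_h0 <- as.integer(table(factor(pairs$mother_h, levels = h0_levels)))
  dists <- lapply(h0_levels, function(p) {
    kimura_distribution(p, b_hat, tolerance = tolerance)
  })

  draw_logshift <- function(idx, n_draws, stream) {
    x <- kimura_sample(dists[[idx]], n_draws,
                       derive_seed(seed, stream))
    bpd <- suppressWarnings(boundary_policy(x, boundary, assay_copies))
    keep <- !is.na(bpd$h)
    list(ls = log_shift(bpd$h[keep], rep(h0_levels[idx], sum(keep))),
         n_boundary = bpd$n_boundary * (boundary == "exclude"))
  }

  sim <- vector("list", length(h0_levels))
  n_sim_excluded <- 0L
  for (k in seq_along(h0_levels)) {
    d <- draw_logshift(k, multiplier * n_per_h0[k], stream = k)
    sim[[k]] <- d$ls
    n_sim_excluded <- n_sim_excluded + d$n_boundary
  }
  simulated <- unlist(sim)
  sim_sorted <- sort(simulated)

  ks_obs <- ks_distance(observed, sim_sorted, y_sorted = TRUE)

  # parametric re-simulation: null replicates of the observed sample size.
  # All draws for one mother are taken in a single batch (streams stay
  # deterministic and order-invariant), then resliced per replicate.
  per_rep <- vector("list", n_null)
  for (k in seq_along(h0_levels)) {
    x <- kimura_sample(dists[[k]], n_null * n_per_h0[k],
                       derive_seed(seed, 100000 + k))
    bpd <- suppressWarnings(boundary_policy(x, boundary, assay_copies))
    xm <- matrix(bpd$h, nrow = n_per_h0[k], ncol = n_null)
    for (r in seq_len(n_null)) {
      v <- xm[, r]
      v <- v[!is.na(v)]
      if (length(v)) {
        per_rep[[r]] <- c(per_rep[[r]],
                          log_shift(v, rep(h0_levels[k], length(v))))
      }
    }
  }
  ks_null <- vapply(per_rep, function(v) {
    ks_distance(v, sim_sorted, y_sorted = TRUE)
  }, numeric(1))
  p_value <- (1 + sum(ks_null >= ks_obs)) / (n_null + 1)

  xs <- seq(min(c(observed, simulated)), max(c(observed, simulated)),
            length.out = 256)
  dob <- stats::density(observed, from = xs[1], to = xs[256], n = 256)
  dsi <- stats::density(simulated, from = xs[1], to = xs[256], n = 256)

  out <- list(
    b_hat = b_hat,
    multiplier = multiplier,
    ks_statistic = ks_obs,
    p_value = p_value,
    mean_difference = mean(observed) - mean(simulated),
    n_observed = length(observed),
    n_simulated = length(simulated),
    boundary_exclusions = c(observed = n_obs_excluded,
                            simulated = n_sim_excluded),
    observed_shifts = observed,
    simulated_shifts = simulated,
    density_curves = data.frame(x = dob$x,
                                observed_density = dob$y,
                                simulated_density = dsi$y),
    boundary = boundary,
    seed = seed
  )
  class(out) <- "neutral_null"
  out
}

#' @export
print.neutral_null <- function(x, ...) {
  cat("Neutral-drift null test (Kimura simulation)\n")
  cat(sprintf("  n observed = %d, n simulated = %d (multiplier %d), b_hat = %.4f\n",
              x$n_observed, x$n_simulated, x$multiplier, x$b_hat))
  cat(sprintf("  KS = %.4f, p = %.4g, mean log-shift difference = %.4f\n",
              x$ks_statistic, x$p_value, x$mean_difference))
  if (sum(x$boundary_exclusions) > 0) {
    cat(sprintf("  boundary exclusions: %d observed, %d simulated\n",
                x$boundary_exclusions[["observed"]],
                x$boundary_exclusions[["simulated"]]))
  }
  invisible(x)
}
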