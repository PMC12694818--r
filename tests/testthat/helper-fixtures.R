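# Shared fixture builders. Everything is generated in code; no binary data.

make_pairs <- function(mother_h, pup_h, mother_id = NULL) {
  n <- length(pup_h)
  if (is.null(mother_id)) mother_id <- rep("M1", n)
  data.frame(
    mother_id = mother_id,
    pup_id = sprintf("P%03d", seq_len(n)),
    generation = "F2",
    mother_h = rep_len(mother_h, n),
    pup_h = pup_h,
    stringsAsFactors = FALSE
  )
}

# discrete Wright-Fisher end-state frequencies: the independent oracle for
# the Kimura distribution (t binomial resampling generations at N copies)
wf_oracle <- function(p, N, t, n_rep, seed) {
  set.seed(seed)
  x <- rep(p, n_rep)
  for (g in seq_len(t)) x <- rbinom(n_rep, N, x) / N
  x
}

# lattice-binned total-variation distance between WF end states and a
# kimura_distribution: N+1 bins centred at k/N, boundary atoms merged into
# the end bins (fine equal-width bins are empty on the WF lattice and
# would measure binning, not fit)
lattice_tv <- function(kd, wf_x, N) {
  wf_mass <- tabulate(round(wf_x * N) + 1, N + 1) / length(wf_x)
  gl <- mitodrift:::gauss_legendre01(64)
  edges <- ((0:(N + 1)) - 0.5) / N
  edges[1] <- 0
  edges[N + 2] <- 1
  km <- vapply(seq_len(N + 1), function(j) {
    a <- edges[j]
    b <- edges[j + 1]
    sum(gl$weights * kd$density(a + (b - a) * gl$nodes)) * (b - a)
  }, numeric(1))
  km[1] <- km[1] + kd$loss_mass
  km[N + 1] <- km[N + 1] + kd$fixation_mass
  0.5 * sum(abs(wf_mass - km))
}

# exact moments of a kimura_distribution by high-order quadrature
kimura_moments <- function(kd) {
  gl <- mitodrift:::gauss_legendre01(max(64, kd$truncation_order))
  fv <- kd$density(gl$nodes)
  list(mass = kd$loss_mass + kd$fixation_mass + sum(gl$weights * fv),
       mean = kd$fixation_mass + sum(gl$weights * gl$nodes * fv),
       var = kd$fixation_mass + sum(gl$weights * gl$nodes^2 * fv) -
         (kd$fixation_mass + sum(gl$weights * gl$nodes * fv))^2)
}
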