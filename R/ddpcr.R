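# Droplet digital PCR quantification.
#
# A reaction is partitioned into ~20,000 droplets; each allele is read in its
# own fluorescence channel (FAM = wild-type, HEX = mutant). Under Poisson
# occupancy the mean number of molecules per droplet is
#   lambda = -ln(1 - k/N)
# for k positive droplets out of N, and copies per reaction = lambda * N.
# Heteroplasmy is the lambda ratio lambda_hex / (lambda_hex + lambda_fam),
# which is correct even when droplets hold several molecules (a raw
# positive-droplet ratio is biased at high occupancy).

#' Quantify wild-type and mutant copies from ddPCR droplet counts
#'
#' @param wells data frame with columns `sample_id`, `droplets_total`,
#'   `fam_positive` (wild-type channel), `hex_positive` (mutant channel), and
#'   optionally `droplet_volume_nl` (default 0.85 nL, QX200 convention; used
#'   only for the optional copies-per-microlitre column).
#' @return data frame with one row per well: `sample_id`, `wt_copies`,
#'   `mut_copies`, `total_copies` (expected molecules per reaction),
#'   `heteroplasmy` (`NA` with `empty = TRUE` when both channels are blank),
#'   and `copies_per_ul`.
#' @examples
#' ddpcr_quantify(data.frame(sample_id = "a", droplets_total = 10000,
#'                           fam_positive = 6321, hex_positive = 3935))
#' @export
ddpcr_quantify <- function(wells) {
  req <- c("sample_id", "droplets_total", "fam_positive", "hex_positive")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols)) {
    stop("ddpcr wells missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  N <- as.numeric(wells$droplets_total)
  kf <- as.numeric(wells$fam_positive)
  kh <- as.numeric(wells$hex_positive)
  if (any(N <= 0)) stop("droplets_total must be positive", call. = FALSE)
  if (any(kf < 0 | kh < 0 | kf > N | kh > N)) {
    stop("positive-droplet counts must lie in [0, droplets_total]", call. = FALSE)
  }
  if (any(kf == N | kh == N)) {
    stop("saturation: a channel with every droplet positive cannot be quantified",
         call. = FALSE)
  }
  vol_nl <- if ("droplet_volume_nl" %in% names(wells)) {
    as.numeric(wells$droplet_volume_nl)
  } else {
    rep(0.85, length(N))
  }
  lam_f <- -log1p(-kf / N)
  lam_h <- -log1p(-kh / N)
  wt <- lam_f * N
  mut <- lam_h * N
  total <- wt + mut
  het <- ifelse(total > 0, mut / total, NA_real_)
  data.frame(
    sample_id = wells$sample_id,
    wt_copies = wt,
    mut_copies = mut,
    total_copies = total,
    heteroplasmy = het,
    empty = total == 0,
    copies_per_ul = ifelse(total > 0, total / (N * vol_nl * 1e-3), NA_real_),
    stringsAsFactors = FALSE
  )
}
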