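# Heteroplasmy values and the shift transforms.
#
# Heteroplasmy h is the fraction of mtDNA copies carrying a variant, stored
# internally on the [0, 1] fraction scale, always. Percent-scale input is
# converted exactly once at the I/O boundary (see `validate_table()` and the
# `percent` arguments); no heuristic rescaling ever happens downstream.

#' Validate heteroplasmy values (fraction scale)
#'
#' @param x numeric vector of heteroplasmy values.
#' @param percent if `TRUE`, `x` is on the 0-100 percent scale and is divided
#'   by 100 (the one and only place this conversion happens).
#' @param what label used in error messages.
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' as_heteroplasmy(c(6.72, 25.2), percent = TRUE)
#' @export
as_heteroplasmy <- function(x, percent = FALSE, what = "heteroplasmy") {
  x <- as.numeric(x)
  if (percent) x <- x / 100
  bad <- is.finite(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop(sprintf("%s out of [0,1] (after any percent conversion): %s",
                 what, paste(utils::head(x[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Heteroplasmy shift ratio R = h(1-h0) / (h0(1-h))
#'
#' The odds ratio of carrying the mutant allele in the offspring (or oocyte)
#' relative to its mother. R = 1 is unbiased transmission; R < 1 indicates a
#' reduction of the mutant fraction in the offspring.
#'
#' @param h offspring/oocyte heteroplasmy, fraction in `[0, 1)`.
#' @param h0 mother (reference) heteroplasmy, fraction in `(0, 1)`.
#' @return numeric vector of shift ratios.
#' @seealso [log_shift()] for the natural-log (logit-difference) scale.
#' @examples
#' shift_ratio(0.2, 0.4)   # 0.375
#' @export
shift_ratio <- function(h, h0) {
  h <- as_heteroplasmy(h, what = "h")
  h0 <- as_heteroplasmy(h0, what = "h0")
  if (any(h0 <= 0 | h0 >= 1, na.rm = TRUE)) {
    stop("undefined reference: mother heteroplasmy h0 must lie strictly in (0,1)",
         call. = FALSE)
  }
  if (any(h >= 1, na.rm = TRUE)) {
    stop("saturation: h = 1 (mutation fixed) has an infinite shift ratio",
         call. = FALSE)
  }
  h * (1 - h0) / (h0 * (1 - h))
}

#' Log heteroplasmy shift L = ln(h(1-h0) / (h0(1-h))) = logit(h) - logit(h0)
#'
#' Antisymmetric in (h, h0) and additive across chained transmissions:
#' `log_shift(h2, h0) = log_shift(h2, h1) + log_shift(h1, h0)`.
#'
#' Both arguments must be strictly interior. Records at the boundary (variant
#' lost or fixed) are handled by the analysis functions through
#' [boundary_policy()], not here.
#'
#' @inheritParams shift_ratio
#' @return numeric vector of log shifts.
#' @examples
#' log_shift(0.5, 0.25)  # log(3)
#' @export
log_shift <- function(h, h0) {
  h <- as_heteroplasmy(h, what = "h")
  h0 <- as_heteroplasmy(h0, what = "h0")
  if (any(h <= 0 | h >= 1 | h0 <= 0 | h0 >= 1, na.rm = TRUE)) {
    stop(paste0("boundary heteroplasmy (0 or 1) has no finite log shift; ",
                "apply boundary_policy() first"),
         call. = FALSE)
  }
  stats::qlogis(h) - stats::qlogis(h0)
}

#' Resolve boundary heteroplasmy values before log-scale analysis
#'
#' Heteroplasmy 0 (variant lost) or 1 (fixed) has an infinite logit. The
#' default policy excludes such records (returned as `NA`, counted, and
#' reported with a warning); the alternative clamps them to
#' `[eps, 1 - eps]` with `eps = 1 / (2 * assay_copies)`, half a copy at the
#' resolution of the measuring assay.
#'
#' @param h numeric vector of heteroplasmy fractions.
#' @param policy `"exclude"` (default) or `"clamp"`.
#' @param assay_copies effective template copies of the assay; sets the clamp
#'   width. Default 5000 (amplicon-sequencing scale).
#' @return list with `h` (boundary values `NA`d or clamped) and `n_boundary`,
#'   the number of affected records.
#' @export
boundary_policy <- function(h, policy = c("exclude", "clamp"),
                            assay_copies = 5000) {
  policy <- match.arg(policy)
  at_boundary <- is.finite(h) & (h <= 0 | h >= 1)
  n <- sum(at_boundary)
  if (n > 0) {
    if (policy == "exclude") {
      h[at_boundary] <- NA_real_
      warning(sprintf("%d boundary heteroplasmy value(s) excluded from log-shift analysis", n),
              call. = FALSE)
    } else {
      eps <- 1 / (2 * assay_copies)
      h <- pmin(pmax(h, eps), 1 - eps)
    }
  }
  list(h = h, n_boundary = n)
}
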