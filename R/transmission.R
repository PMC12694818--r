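# Selection inference on mother-offspring and mother-oocyte heteroplasmy.
#
# Testing policy used throughout (matching common practice in this
# literature): normality is gated by a Shapiro-Wilk test at alpha = 0.05;
# normal data get a t-test, otherwise the Mann-Whitney U / Wilcoxon
# signed-rank test is used. The test actually applied is always recorded.

FOLLICLE_STAGES <- c("primordial", "primary", "early_secondary",
                     "late_secondary", "antral", "MII", "offspring")

#' Mother-offspring transmission regression
#'
#' Ordinary least squares of offspring heteroplasmy on mother heteroplasmy.
#' The unbiased-transmission line has slope 1 (and intercept 0); a slope
#' below 1 indicates a systematic reduction of the mutant fraction in
#' offspring. Both a with-intercept and a through-origin fit are available
#' because published "fitted curves" rarely state which was used.
#'
#' @param pairs data frame with columns `mother_h`, `pup_h` (fractions).
#' @param through_origin fit `pup_h ~ 0 + mother_h` instead of
#'   `pup_h ~ mother_h`.
#' @return list of class `transmission_fit`: `slope`, `intercept` (`NA` for
#'   through-origin), `slope_ci95`, `p_value` (slope), `r_squared`, `n`,
#'   `through_origin`.
#' @export
fit_transmission_regression <- function(pairs, through_origin = FALSE) {
  ok <- is.finite(pairs$mother_h) & is.finite(pairs$pup_h)
  d <- pairs[ok, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(d$mother_h) == 0) {
    stop("singular design: all mother heteroplasmies identical", call. = FALSE)
  }
  fml <- if (through_origin) pup_h ~ 0 + mother_h else pup_h ~ mother_h
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  slope_row <- "mother_h"
  ci <- stats::confint(fit)[slope_row, ]
  out <- list(
    slope = unname(co[slope_row, "Estimate"]),
    intercept = if (through_origin) NA_real_ else unname(co["(Intercept)", "Estimate"]),
    slope_ci95 = unname(ci),
    p_value = unname(co[slope_row, "Pr(>|t|)"]),
    r_squared = sm$r.squared,
    n = nrow(d),
    through_origin = through_origin
  )
  class(out) <- "transmission_fit"
  out
}

#' @export
print.transmission_fit <- function(x, ...) {
  cat(sprintf("Transmission regression (%s), n = %d\n",
              if (x$through_origin) "through origin" else "with intercept", x$n))
  cat(sprintf("  slope = %.4f [%.4f, %.4f], p = %.3g, r^2 = %.3f\n",
              x$slope, x$slope_ci95[1], x$slope_ci95[2], x$p_value,
              x$r_squared))
  if (!x$through_origin) cat(sprintf("  intercept = %.4f\n", x$intercept))
  invisible(x)
}

#' Mean log heteroplasmy shift test against zero
#'
#' Computes per-pair log shifts, then tests their mean against 0 (unbiased
#' transmission) with the normality-gated policy: Shapiro-Wilk at
#' alpha = 0.05 chooses between a one-sample t-test and a Wilcoxon
#' signed-rank test.
#'
#' @inheritParams fit_transmission_regression
#' @param boundary,assay_copies boundary handling, see [boundary_policy()].
#' @return list: `mean_log_shift`, `ci95` (normal-theory CI of the mean),
#'   `p_value`, `test_used`, `shapiro_p`, `n`, `n_boundary_excluded`.
#' @export
mean_shift_test <- function(pairs, boundary = c("exclude", "clamp"),
                            assay_copies = 5000) {
  boundary <- match.arg(boundary)
  ok <- is.finite(pairs$mother_h) & is.finite(pairs$pup_h) &
    pairs$mother_h > 0 & pairs$mother_h < 1
  d <- pairs[ok, , drop = FALSE]
  bp <- suppressWarnings(boundary_policy(d$pup_h, boundary, assay_copies))
  keep <- !is.na(bp$h)
  if (sum(keep) < 3) {
    stop("insufficient data: need at least 3 usable (interior) pairs",
         call. = FALSE)
  }
  L <- log_shift(bp$h[keep], d$mother_h[keep])
  n <- length(L)
  m <- mean(L)
  if (stats::sd(L) == 0) {
    return(list(mean_log_shift = m, ci95 = c(m, m), p_value = NA_real_,
                test_used = "none (zero variance)", shapiro_p = NA_real_,
                n = n, n_boundary_excluded = bp$n_boundary))
  }
  gate <- shapiro_gate(L)
  if (gate$normal) {
    tt <- stats::t.test(L, mu = 0)
    p <- tt$p.value
    used <- "one-sample t-test"
  } else {
    wt <- stats::wilcox.test(L, mu = 0, exact = FALSE)
    p <- wt$p.value
    used <- "Wilcoxon signed-rank"
  }
  ci <- m + c(-1, 1) * stats::qt(0.975, n - 1) * sem(L)
  list(mean_log_shift = m, ci95 = ci, p_value = p, test_used = used,
       shapiro_p = gate$p_value, n = n, n_boundary_excluded = bp$n_boundary)
}

#' Per-stage heteroplasmy shift summary across folliculogenesis
#'
#' Summarises the shift of oocyte (or offspring) heteroplasmy relative to the
#' mother at each follicle stage: arithmetic mean of the shift ratio R (the
#' scale this literature reports per stage), median, a seeded bootstrap 95%
#' CI, and Mann-Whitney U tests between consecutive stages (raw and
#' Holm-adjusted).
#'
#' @param records data frame with columns `mother_h`, `h`, and `stage` (one
#'   of primordial, primary, early_secondary, late_secondary, antral, MII,
#'   offspring).
#' @param scale `"ratio"` (default; the per-stage reporting convention) or
#'   `"log"`.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed seed for the bootstrap.
#' @return list with `summary` (stage, n, mean_shift, median_shift,
#'   ci95_lower, ci95_upper) and `pairwise` (stage_a, stage_b, p_value,
#'   p_holm) data frames. Stages with no records are omitted with a warning.
#' @export
stage_shift_summary <- function(records, scale = c("ratio", "log"),
                                n_boot = 1000, seed = 1) {
  scale <- match.arg(scale)
  stage <- as.character(records$stage)
  bad <- !stage %in% FOLLICLE_STAGES
  if (any(bad)) {
    stop("unknown stage label(s): ", paste(unique(stage[bad]), collapse = ", "),
         call. = FALSE)
  }
  shift <- if (scale == "ratio") {
    shift_ratio(records$h, records$mother_h)
  } else {
    bp <- suppressWarnings(boundary_policy(records$h))
    ifelse(is.na(bp$h), NA_real_, suppressWarnings(
      stats::qlogis(bp$h) - stats::qlogis(records$mother_h)))
  }
  usable <- !is.na(shift)
  present <- FOLLICLE_STAGES[FOLLICLE_STAGES %in% stage[usable]]
  empty <- setdiff(unique(stage), present)
  if (length(empty) > 0) {
    warning("stage(s) with no usable records omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  if (length(present) == 0) stop("no usable records", call. = FALSE)
  rows <- lapply(seq_along(present), function(k) {
    x <- shift[stage == present[k] & !is.na(shift)]
    bm <- with_seed(derive_seed(seed, k), {
      vapply(seq_len(n_boot),
             function(j) mean(sample(x, length(x), replace = TRUE)),
             numeric(1))
    })
    data.frame(stage = present[k], n = length(x), mean_shift = mean(x),
               median_shift = stats::median(x),
               ci95_lower = unname(stats::quantile(bm, 0.025)),
               ci95_upper = unname(stats::quantile(bm, 0.975)),
               stringsAsFactors = FALSE)
  })
  summary_df <- do.call(rbind, rows)

  pairwise <- NULL
  if (length(present) >= 2) {
    pw <- lapply(seq_len(length(present) - 1), function(k) {
      a <- shift[stage == present[k] & !is.na(shift)]
      b <- shift[stage == present[k + 1] & !is.na(shift)]
      p <- if (stats::sd(c(a, b)) == 0) 1 else
        suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      data.frame(stage_a = present[k], stage_b = present[k + 1],
                 p_value = p, stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, pw)
    pairwise$p_holm <- stats::p.adjust(pairwise$p_value, method = "holm")
  }
  list(summary = summary_df, pairwise = pairwise, scale = scale)
}

#' Maternal-age effect on the heteroplasmy shift
#'
#' Aggregates the shift ratio per delivery (mean over the pups of one
#' litter), then correlates delivery means with maternal age at delivery
#' (Pearson, with Spearman alongside). A pup-level analysis is available
#' behind `level = "pup"`.
#'
#' @param pairs data frame with `mother_h`, `pup_h`, `maternal_age_months`,
#'   `litter_id`.
#' @param scale shift scale, `"ratio"` (default) or `"log"`.
#' @param level `"delivery"` (default) or `"pup"`.
#' @return list: `per_delivery` table (litter_id, maternal_age_months,
#'   mean_shift, n_pups), `pearson_r`, `p_value`, `spearman_rho`,
#'   `spearman_p`, `n`.
#' @export
age_effect <- function(pairs, scale = c("ratio", "log"),
                       level = c("delivery", "pup")) {
  scale <- match.arg(scale)
  level <- match.arg(level)
  req <- c("mother_h", "pup_h", "maternal_age_months", "litter_id")
  if (!all(req %in% names(pairs))) {
    stop("pairs must carry maternal_age_months and litter_id", call. = FALSE)
  }
  d <- pairs[is.finite(pairs$mother_h) & is.finite(pairs$pup_h) &
               is.finite(pairs$maternal_age_months) &
               !is.na(pairs$litter_id), , drop = FALSE]
  shift <- if (scale == "ratio") shift_ratio(d$pup_h, d$mother_h) else {
    bp <- suppressWarnings(boundary_policy(d$pup_h))
    suppressWarnings(stats::qlogis(bp$h) - stats::qlogis(d$mother_h))
  }
  d$shift <- shift
  d <- d[is.finite(d$shift), , drop = FALSE]
  agg <- do.call(rbind, lapply(split(d, d$litter_id), function(g) {
    data.frame(litter_id = g$litter_id[1],
               maternal_age_months = mean(g$maternal_age_months),
               mean_shift = mean(g$shift), n_pups = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  x <- if (level == "delivery") agg$maternal_age_months else d$maternal_age_months
  y <- if (level == "delivery") agg$mean_shift else d$shift
  if (length(unique(x)) < 2) {
    stop("undefined correlation: a single distinct maternal age", call. = FALSE)
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(per_delivery = agg, pearson_r = unname(pe$estimate),
       p_value = pe$p.value, spearman_rho = unname(sp$estimate),
       spearman_p = sp$p.value, n = length(x), level = level)
}

#' Association between litter size and mother heteroplasmy
#'
#' One record per delivery (mother heteroplasmy, litter size); Pearson
#' correlation. A null result argues against embryonic lethality of
#' high-heteroplasmy litters. With `first_litter_only = TRUE` only each
#' mother's first delivery (earliest maternal age) is used, removing the
#' maternal-age confounder on litter size.
#'
#' @param pairs data frame with `mother_id`, `mother_h`, `litter_id`,
#'   `litter_size` (and `maternal_age_months` for the first-litter filter).
#' @param first_litter_only restrict to each mother's first delivery.
#' @return list: `correlation`, `p_value`, `n_deliveries`, `deliveries`.
#' @export
litter_size_association <- function(pairs, first_litter_only = FALSE) {
  req <- c("mother_h", "litter_id", "litter_size")
  if (!all(req %in% names(pairs))) {
    stop("pairs must carry litter_id and litter_size", call. = FALSE)
  }
  d <- pairs[!is.na(pairs$litter_id) & is.finite(pairs$litter_size), ,
             drop = FALSE]
  del <- do.call(rbind, lapply(split(d, d$litter_id), function(g) {
    data.frame(litter_id = g$litter_id[1],
               mother_id = if ("mother_id" %in% names(g)) g$mother_id[1] else NA,
               mother_h = g$mother_h[1],
               litter_size = g$litter_size[1],
               maternal_age_months = if ("maternal_age_months" %in% names(g))
                 g$maternal_age_months[1] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(del) <- NULL
  if (first_litter_only) {
    del <- do.call(rbind, lapply(split(del, del$mother_id), function(g) {
      g[order(g$maternal_age_months, g$litter_id), , drop = FALSE][1, , drop = FALSE]
    }))
  }
  if (nrow(del) < 3) stop("need at least 3 deliveries", call. = FALSE)
  if (stats::sd(del$litter_size) == 0) {
    stop("undefined correlation: constant litter size", call. = FALSE)
  }
  ct <- stats::cor.test(del$mother_h, del$litter_size, method = "pearson")
  list(correlation = unname(ct$estimate), p_value = ct$p.value,
       n_deliveries = nrow(del), deliveries = del)
}

#' Cross-tissue heteroplasmy stability (coefficient of variation)
#'
#' Per mouse, the coefficient of variation (sample SD / mean, in percent) of
#' heteroplasmy across tissues; stability of the grand mean CV justifies
#' using a single sentinel tissue (e.g. tail) as a whole-body proxy.
#'
#' @param measurements data frame with columns `mouse_id`, `tissue`, `h`.
#' @return list of class `tissue_stability`: `per_mouse_cv` (data frame
#'   mouse_id, n_tissues, cv_percent) and `grand_mean_cv` (arithmetic mean
#'   over mice, percent). Mice with fewer than 2 tissues or zero mean are
#'   excluded with a warning.
#' @export
tissue_cv <- function(measurements) {
  req <- c("mouse_id", "tissue", "h")
  if (!all(req %in% names(measurements))) {
    stop("measurements must have mouse_id, tissue, h", call. = FALSE)
  }
  d <- measurements[is.finite(measurements$h), , drop = FALSE]
  rows <- lapply(split(d, d$mouse_id), function(g) {
    if (nrow(g) < 2) {
      warning(sprintf("mouse %s has < 2 tissues; excluded", g$mouse_id[1]),
              call. = FALSE)
      return(NULL)
    }
    if (mean(g$h) == 0) {
      warning(sprintf("mouse %s has zero mean heteroplasmy; CV undefined, excluded",
                      g$mouse_id[1]), call. = FALSE)
      return(NULL)
    }
    data.frame(mouse_id = g$mouse_id[1], n_tissues = nrow(g),
               cv_percent = 100 * stats::sd(g$h) / mean(g$h),
               stringsAsFactors = FALSE)
  })
  per_mouse <- do.call(rbind, rows)
  if (is.null(per_mouse) || nrow(per_mouse) == 0) {
    stop("no mouse with >= 2 tissues and nonzero mean", call. = FALSE)
  }
  rownames(per_mouse) <- NULL
  out <- list(per_mouse_cv = per_mouse,
              grand_mean_cv = mean(per_mouse$cv_percent))
  class(out) <- "tissue_stability"
  out
}

#' @export
print.tissue_stability <- function(x, ...) {
  cat(sprintf("Tissue heteroplasmy stability: %d mice, grand mean CV = %.2f%%\n",
              nrow(x$per_mouse_cv), x$grand_mean_cv))
  invisible(x)
}

#' Per-day copy-number and heteroplasmy dynamics in cultured oocytes
#'
#' Summarises wild-type, mutant and total mtDNA copies (mean +/- SEM) and
#' heteroplasmy (mean, median, min, max — the min-to-max presentation used
#' for culture time courses) per culture day and group, and compares day-7
#' total copies between edited and unedited oocytes with the
#' normality-gated policy (two-sample t-test vs Mann-Whitney U).
#'
#' @param records data frame with columns `day`, `group` (edited/unedited),
#'   `h`, `wt_copies`, `mut_copies`.
#' @param comparison_day day for the between-group total-copies comparison.
#' @return list: `per_day` summary data frame and `comparison` (list with
#'   `day`, `test_used`, `p_value`, group means), or `NULL` comparison (with
#'   a warning) if a group is missing on that day.
#' @export
copy_dynamics_summary <- function(records, comparison_day = 7) {
  req <- c("day", "group", "h", "wt_copies", "mut_copies")
  if (!all(req %in% names(records))) {
    stop("records must have day, group, h, wt_copies, mut_copies",
         call. = FALSE)
  }
  d <- records[is.finite(records$day), , drop = FALSE]
  if (length(unique(d$day)) < 2) stop("need at least 2 distinct days", call. = FALSE)
  d$total_copies <- d$wt_copies + d$mut_copies
  key <- interaction(d$day, d$group, drop = TRUE)
  per_day <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(
      day = g$day[1], group = g$group[1], n = nrow(g),
      wt_mean = mean(g$wt_copies), wt_sem = sem(g$wt_copies),
      mut_mean = mean(g$mut_copies), mut_sem = sem(g$mut_copies),
      total_mean = mean(g$total_copies), total_sem = sem(g$total_copies),
      h_mean = mean(g$h), h_median = stats::median(g$h),
      h_min = min(g$h), h_max = max(g$h),
      stringsAsFactors = FALSE
    )
  }))
  per_day <- per_day[order(per_day$group, per_day$day), , drop = FALSE]
  rownames(per_day) <- NULL

  cmp <- NULL
  d7 <- d[d$day == comparison_day, , drop = FALSE]
  groups <- unique(d7$group)
  if (length(groups) < 2) {
    warning(sprintf("day-%s comparison skipped: need both groups present",
                    comparison_day), call. = FALSE)
  } else {
    a <- d7$total_copies[d7$group == groups[1]]
    b <- d7$total_copies[d7$group == groups[2]]
    normal <- shapiro_gate(a)$normal && shapiro_gate(b)$normal
    if (normal) {
      p <- stats::t.test(a, b)$p.value
      used <- "two-sample t-test"
    } else {
      p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      used <- "Mann-Whitney U"
    }
    means <- stats::setNames(c(mean(a), mean(b)), as.character(groups))
    cmp <- list(day = comparison_day, test_used = used, p_value = p,
                group_means = means)
  }
  list(per_day = per_day, comparison = cmp)
}
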