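# Seeded generators emulating the experimental data-generating processes:
# a bottlenecked mouse pedigree with optional per-replication selection, the
# follicle-culture copy-number time course (mutant elimination plus
# compensatory wild-type replication), ddPCR droplet partitioning, and
# per-site base-count pileups for the off-target caller. Every generator is
# bitwise reproducible from (config, seed) and leaves the caller's RNG
# untouched.

# One Wright-Fisher transmission: t generations of binomial resampling at N
# copies, with haploid selection s acting on the mutant replication
# probability each generation: p' = p(1+s) / (1 + p s). Vectorised over h.
wf_transmit <- function(h, bottleneck_n, generations, s = 0) {
  for (g in seq_len(generations)) {
    hp <- h * (1 + s) / (1 + h * s)
    h <- stats::rbinom(length(h), bottleneck_n, hp) / bottleneck_n
  }
  h
}

# binomial measurement noise at the assay's effective copy number
measure_h <- function(h, copies) {
  stats::rbinom(length(h), copies, h) / copies
}

#' Simulate a bottlenecked mtDNA transmission pedigree
#'
#' Emulates a mouse colony founded by one heteroplasmic female: each
#' transmission passes the mother's heteroplasmy through `t` Wright-Fisher
#' generations at `N` segregating copies (drift parameter
#' `b = (1 - 1/N)^t`), with optional per-replication selection `s`
#' (`s = 0` neutral, `s < 0` purifying), followed by binomial measurement
#' noise. Mothers beyond the first generation inherit from a random mother
#' of the previous generation, so the colony spans generations F1-F5 like a
#' real breeding scheme. Litter sizes, delivery structure and maternal ages
#' are generated independently of heteroplasmy by default; `age_slope`
#' injects a per-month multiplicative selection trend for power studies.
#'
#' @param founder_h founder heteroplasmy fraction (default 0.067, a typical
#'   DdCBE-founder value).
#' @param n_mothers number of mothers (default 44).
#' @param pups_per_mother pups per mother (default 18, giving ~793 pairs at
#'   the default mother count).
#' @param bottleneck_n effective mtDNA copy number through the bottleneck
#'   (default 200).
#' @param generations_per_transmission Wright-Fisher generations per
#'   mother-to-pup transmission (default 15).
#' @param selection_s per-replication relative fitness deviation of mutant
#'   copies; must exceed -1.
#' @param measurement_copies assay copies for binomial measurement noise
#'   (default 5000).
#' @param mean_litter_size Poisson mean for litter sizes (default 7,
#'   truncated at 1).
#' @param age_slope extra selection per month of maternal age (0 = ages
#'   carry no signal).
#' @param seed master seed.
#' @return data frame in the `pairs` schema: `mother_id`, `pup_id`,
#'   `generation`, `mother_h`, `pup_h`, `maternal_age_months`, `litter_id`,
#'   `litter_size`.
#' @export
simulate_pedigree <- function(founder_h = 0.067, n_mothers = 44,
                              pups_per_mother = 18, bottleneck_n = 200,
                              generations_per_transmission = 15,
                              selection_s = 0, measurement_copies = 5000,
                              mean_litter_size = 7, age_slope = 0,
                              seed = 1) {
  stopifnot(bottleneck_n >= 2, generations_per_transmission >= 1,
            selection_s > -1, n_mothers >= 1, pups_per_mother >= 1)
  with_seed(derive_seed(seed, 101), {
    n_gen <- 5L
    gen_of <- rep(seq_len(n_gen), length.out = n_mothers)
    # true mother heteroplasmies: F1 mothers drift from the founder, later
    # generations from a random mother of the previous one
    true_h <- numeric(n_mothers)
    for (g in seq_len(n_gen)) {
      idx <- which(gen_of == g)
      if (!length(idx)) next
      src <- if (g == 1) rep(founder_h, length(idx)) else {
        prev <- which(gen_of == g - 1)
        true_h[sample(prev, length(idx), replace = TRUE)]
      }
      true_h[idx] <- wf_transmit(src, bottleneck_n,
                                 generations_per_transmission, selection_s)
    }
    # keep mothers usable as references: re-draw fixed/lost lineages from
    # the founder (a real colony would not breed homoplasmic-WT females)
    redo <- which(true_h <= 0 | true_h >= 1)
    guard <- 0
    while (length(redo) && guard < 50) {
      true_h[redo] <- wf_transmit(rep(founder_h, length(redo)), bottleneck_n,
                                  generations_per_transmission, selection_s)
      redo <- which(true_h <= 0 | true_h >= 1)
      guard <- guard + 1
    }
    true_h[true_h <= 0 | true_h >= 1] <- founder_h

    rows <- vector("list", n_mothers)
    for (m in seq_len(n_mothers)) {
      n_pups <- pups_per_mother
      # delivery structure: litters of ~Poisson(mean_litter_size) pups
      sizes <- integer(0)
      while (sum(sizes) < n_pups) {
        sizes <- c(sizes, max(1L, stats::rpois(1, mean_litter_size)))
      }
      excess <- sum(sizes) - n_pups
      sizes[length(sizes)] <- sizes[length(sizes)] - excess
      sizes <- sizes[sizes > 0]
      litter_of <- rep(seq_along(sizes), sizes)
      age_at <- 2 + 1.5 * (seq_along(sizes) - 1) +
        round(stats::runif(length(sizes), 0, 1), 1)

      s_eff <- selection_s + age_slope * (age_at[litter_of] - mean(age_at))
      pup_true <- vapply(seq_len(n_pups), function(j) {
        wf_transmit(true_h[m], bottleneck_n, generations_per_transmission,
                    s_eff[j])
      }, numeric(1))
      mother_obs <- measure_h(rep(true_h[m], 1), measurement_copies)
      rows[[m]] <- data.frame(
        mother_id = sprintf("M%03d", m),
        pup_id = sprintf("M%03d_P%03d", m, seq_len(n_pups)),
        generation = paste0("F", gen_of[m]),
        mother_h = mother_obs,
        pup_h = measure_h(pup_true, measurement_copies),
        maternal_age_months = age_at[litter_of],
        litter_id = sprintf("M%03d_L%02d", m, litter_of),
        litter_size = sizes[litter_of],
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
}

#' Simulate follicle-culture mtDNA copy-number time courses
#'
#' Daily stochastic update per oocyte over a 7-day culture: mutant copies
#' are removed with per-copy probability `elimination_rate_delta` per day
#' (degradation/mitophagy), and replication fills a fraction
#' `replication_rate` of the remaining deficit toward `target_copies` each
#' day (binomial draws). By default only wild-type copies replicate
#' (compensatory replication); `mutant_replication_fraction` re-admits
#' mutant copies to replication at a reduced rate for sensitivity analysis.
#' With the default rate the total reaches ~90% of the 100,000-copy target
#' by day 3, the expansion tempo seen in cultured secondary follicles.
#'
#' @param n_oocytes number of oocytes.
#' @param initial_total_copies starting copies per oocyte (default 25000,
#'   secondary-follicle scale).
#' @param initial_h starting heteroplasmy (default 0.3, the typical
#'   day-1 editing load; 0 for unedited).
#' @param target_copies replication target T (default 1e5, the mature-oocyte
#'   plateau).
#' @param replication_rate per-day fraction of the deficit toward T that is
#'   filled (default 0.55).
#' @param elimination_rate_delta per-day per-copy removal probability for
#'   mutant copies (default 0.3 for edited, use 0 for unedited).
#' @param days days to record (subset of 0:7).
#' @param group `"edited"` or `"unedited"` label written to the records.
#' @param mutant_replication_fraction fraction of the wild-type replication
#'   rate granted to mutant copies (default 0 = strict compensatory model).
#' @param seed master seed.
#' @return data frame in the `oocytes` schema (culture form): `mouse_id`
#'   (oocyte id), `mother_h` (initial h), `day`, `group`, `h`, `wt_copies`,
#'   `mut_copies`.
#' @export
simulate_follicle_timecourse <- function(n_oocytes = 30,
                                         initial_total_copies = 25000,
                                         initial_h = 0.3,
                                         target_copies = 1e5,
                                         replication_rate = 0.55,
                                         elimination_rate_delta = 0.3,
                                         days = 0:7,
                                         group = "edited",
                                         mutant_replication_fraction = 0,
                                         seed = 1) {
  stopifnot(target_copies > initial_total_copies,
            elimination_rate_delta >= 0, elimination_rate_delta <= 1,
            all(days >= 0 & days <= 7))
  days <- sort(unique(as.integer(days)))
  with_seed(derive_seed(seed, 202), {
    mut <- stats::rbinom(n_oocytes, initial_total_copies, initial_h)
    wt <- initial_total_copies - mut
    out <- vector("list", max(days) + 1)
    record <- function(day) {
      data.frame(
        mouse_id = sprintf("OO%03d", seq_len(n_oocytes)),
        mother_h = initial_h, day = day, group = group,
        h = ifelse(wt + mut > 0, mut / (wt + mut), 0),
        wt_copies = wt, mut_copies = mut,
        stringsAsFactors = FALSE
      )
    }
    if (0 %in% days) out[[1]] <- record(0)
    for (day in seq_len(max(days))) {
      mut <- stats::rbinom(n_oocytes, mut, 1 - elimination_rate_delta)
      deficit <- pmax(target_copies - (wt + mut), 0)
      new_copies <- stats::rbinom(n_oocytes, deficit, replication_rate)
      if (mutant_replication_fraction > 0) {
        frac_mut <- mutant_replication_fraction * mut /
          pmax(mut + wt, 1)
        new_mut <- stats::rbinom(n_oocytes, new_copies, frac_mut)
        mut <- mut + new_mut
        wt <- wt + new_copies - new_mut
      } else {
        wt <- wt + new_copies
      }
      if (day %in% days) out[[day + 1]] <- record(day)
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })
}

#' Simulate a ddPCR well by Poisson droplet occupancy
#'
#' Distributes `copies_wt` and `copies_mut` molecules over `droplets`
#' partitions as independent Poisson occupancy per channel; a droplet is
#' positive in a channel iff it received at least one molecule of that
#' allele, so positives are Binomial(droplets, 1 - exp(-copies/droplets)).
#'
#' @param copies_wt,copies_mut true template molecules per reaction.
#' @param droplets droplet count (default 20000).
#' @param seed seed.
#' @param sample_id well label.
#' @return one-row data frame in the `ddpcr` schema: `sample_id`,
#'   `droplets_total`, `fam_positive` (wild-type), `hex_positive` (mutant).
#' @export
simulate_ddpcr <- function(copies_wt, copies_mut, droplets = 20000,
                           seed = 1, sample_id = "well1") {
  stopifnot(droplets >= 1, copies_wt >= 0, copies_mut >= 0)
  with_seed(derive_seed(seed, 303), {
    data.frame(
      sample_id = sample_id,
      droplets_total = droplets,
      fam_positive = stats::rbinom(1, droplets, 1 - exp(-copies_wt / droplets)),
      hex_positive = stats::rbinom(1, droplets, 1 - exp(-copies_mut / droplets)),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate per-site base-count pileups for off-target screening
#'
#' Reference bases follow a fixed deterministic cycle (position mod 4:
#' 1 = C, 2 = G, 3 = A, 0 = T) so fixtures are stable across seeds; listed
#' edit positions must fall on a C or G. At an edited site, reads convert
#' (C->T or G->A) at the site's edit rate; every site additionally receives
#' uniform sequencing error spread over the three non-reference bases.
#'
#' @param n_sites number of sites (positions 1..n_sites).
#' @param depth reads per site.
#' @param edit_positions named numeric vector: names are positions, values
#'   are conversion rates in `[0, 1]`.
#' @param sequencing_error per-read error rate in `[0, 0.01]`.
#' @param seed seed.
#' @return data frame in the `sites` schema: `pos`, `ref`, `a_count`,
#'   `c_count`, `g_count`, `t_count`.
#' @export
simulate_site_counts <- function(n_sites = 100, depth = 10000,
                                 edit_positions = numeric(0),
                                 sequencing_error = 0.001, seed = 1) {
  stopifnot(sequencing_error >= 0, sequencing_error <= 0.01,
            all(edit_positions >= 0 & edit_positions <= 1))
  refs <- c("T", "C", "G", "A")[(seq_len(n_sites) %% 4) + 1]
  pos_edit <- as.integer(names(edit_positions))
  if (length(edit_positions) && any(!refs[pos_edit] %in% c("C", "G"))) {
    stop("config error: edit position(s) on a non-C/G reference base: ",
         paste(pos_edit[!refs[pos_edit] %in% c("C", "G")], collapse = ", "),
         call. = FALSE)
  }
  rate <- numeric(n_sites)
  rate[pos_edit] <- as.numeric(edit_positions)
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(seed, 404), {
    counts <- matrix(0L, n_sites, 4, dimnames = list(NULL, bases))
    for (j in seq_len(n_sites)) {
      ref <- refs[j]
      conv <- switch(ref, C = "T", G = "A", NA_character_)
      pr <- stats::setNames(rep(sequencing_error / 3, 4), bases)
      pr[ref] <- 1 - sequencing_error
      if (!is.na(conv) && rate[j] > 0) {
        pr[conv] <- pr[conv] + rate[j] * pr[ref]
        pr[ref] <- pr[ref] * (1 - rate[j])
      }
      counts[j, ] <- as.integer(stats::rmultinom(1, depth, pr))
    }
    data.frame(pos = seq_len(n_sites), ref = refs,
               a_count = counts[, "A"], c_count = counts[, "C"],
               g_count = counts[, "G"], t_count = counts[, "T"],
               stringsAsFactors = FALSE)
  })
}
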