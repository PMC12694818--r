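# Conversion-rate off-target calling for cytosine base editing.
#
# A DdCBE installs C.G -> T.A edits; unintended edits are screened by whole
# mtDNA sequencing. At every reference C the conversion rate is the fraction
# of reads showing T (at reference G, the fraction showing A; the same event
# seen on the opposite strand). Sites at or above the threshold (default 1%,
# inclusive) and not in the known on-target set are flagged. Reference A/T
# sites are never evaluated. Counts are pooled across strands.

#' Call off-target edits from per-site base counts
#'
#' @param sites data frame with columns `pos` (1-based position on the
#'   mitochondrial reference), `ref` (one of A/C/G/T) and the read counts
#'   `a_count`, `c_count`, `g_count`, `t_count`.
#' @param threshold flag sites with conversion rate `>= threshold`
#'   (inclusive); must lie in (0, 1). Default 0.01.
#' @param exclude integer vector of on-target positions to leave unflagged
#'   (they still appear in the output with their rates).
#' @return data frame with one row per evaluable C/G site: `pos`,
#'   `edit_class` (`"C>T"` or `"G>A"`), `conversion_rate`, `flagged`.
#'   Zero-depth sites are skipped with a warning; A/T sites are dropped
#'   silently.
#' @examples
#' s <- data.frame(pos = 1:2, ref = c("C", "A"),
#'                 a_count = c(0, 100), c_count = c(990, 0),
#'                 g_count = c(0, 0), t_count = c(10, 0))
#' call_offtargets(s)
#' @export
call_offtargets <- function(sites, threshold = 0.01, exclude = integer(0)) {
  req <- c("pos", "ref", "a_count", "c_count", "g_count", "t_count")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols)) {
    stop("site table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  ref <- toupper(as.character(sites$ref))
  if (any(!ref %in% c("A", "C", "G", "T"))) {
    stop("unknown ref base(s): ",
         paste(unique(ref[!ref %in% c("A", "C", "G", "T")]), collapse = ", "),
         call. = FALSE)
  }
  counts <- as.matrix(sites[, c("a_count", "c_count", "g_count", "t_count")])
  if (any(counts < 0)) stop("negative base counts", call. = FALSE)
  depth <- rowSums(counts)

  keep <- ref %in% c("C", "G")
  zero <- keep & depth == 0
  if (any(zero)) {
    warning(sprintf("%d C/G site(s) with zero depth skipped", sum(zero)),
            call. = FALSE)
  }
  keep <- keep & depth > 0
  if (!any(keep)) {
    return(data.frame(pos = integer(0), edit_class = character(0),
                      conversion_rate = numeric(0), flagged = logical(0)))
  }
  ref_k <- ref[keep]
  rate <- ifelse(ref_k == "C",
                 counts[keep, "t_count"] / depth[keep],
                 counts[keep, "a_count"] / depth[keep])
  out <- data.frame(
    pos = as.integer(sites$pos[keep]),
    edit_class = ifelse(ref_k == "C", "C>T", "G>A"),
    conversion_rate = rate,
    flagged = rate >= threshold & !(as.integer(sites$pos[keep]) %in% exclude),
    stringsAsFactors = FALSE
  )
  out[order(out$pos), , drop = FALSE]
}
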