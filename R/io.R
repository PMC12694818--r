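# TSV schemas, validation at the I/O boundary, and atomic writers.
#
# All tables are plain tab-separated files with a header. Heteroplasmy
# columns may be on the percent scale in files; conversion to fractions
# happens exactly once here, and only when the caller passes
# `percent = TRUE` (never by heuristic detection).

TABLE_SCHEMAS <- list(
  pairs = list(
    required = c("mother_id", "pup_id", "generation", "mother_h", "pup_h"),
    optional = c("maternal_age_months", "litter_id", "litter_size"),
    numeric = c("mother_h", "pup_h", "maternal_age_months", "litter_size"),
    heteroplasmy = c("mother_h", "pup_h")
  ),
  oocytes = list(
    required = c("mouse_id", "mother_h", "stage_or_day", "group", "h"),
    optional = c("wt_copies", "mut_copies"),
    numeric = c("mother_h", "h", "wt_copies", "mut_copies"),
    heteroplasmy = c("mother_h", "h")
  ),
  tissues = list(
    required = c("mouse_id", "tissue", "h"),
    optional = character(0),
    numeric = "h",
    heteroplasmy = "h"
  ),
  ddpcr = list(
    required = c("sample_id", "droplets_total", "fam_positive", "hex_positive"),
    optional = "droplet_volume_nl",
    numeric = c("droplets_total", "fam_positive", "hex_positive",
                "droplet_volume_nl"),
    heteroplasmy = character(0)
  ),
  sites = list(
    required = c("pos", "ref", "a_count", "c_count", "g_count", "t_count"),
    optional = character(0),
    numeric = c("pos", "a_count", "c_count", "g_count", "t_count"),
    heteroplasmy = character(0)
  )
)

#' Read and validate a study table against its schema
#'
#' @param path TSV file (header required; lines starting with `#` are
#'   treated as comments). Blank fields are missing values.
#' @param schema_name one of `"pairs"`, `"oocytes"`, `"tissues"`,
#'   `"ddpcr"`, `"sites"`.
#' @param percent if `TRUE`, heteroplasmy columns are on the 0-100 scale
#'   and are divided by 100 (exactly once, here).
#' @return validated data frame with typed columns; an error aggregating
#'   every violation (file, row, column) otherwise.
#' @export
validate_table <- function(path, schema_name, percent = FALSE) {
  if (!schema_name %in% names(TABLE_SCHEMAS)) {
    stop("unknown schema: ", schema_name, call. = FALSE)
  }
  schema <- TABLE_SCHEMAS[[schema_name]]
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("", "NA"))
  errors <- character(0)
  missing_cols <- setdiff(schema$required, names(df))
  if (length(missing_cols)) {
    errors <- c(errors, sprintf("%s: missing required column(s): %s",
                                path, paste(missing_cols, collapse = ", ")))
  }
  if (!length(errors)) {
    for (col in intersect(schema$numeric, names(df))) {
      v <- df[[col]]
      if (!is.numeric(v)) {
        parsed <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(v) & is.na(parsed))
        if (length(bad)) {
          errors <- c(errors, sprintf(
            "%s: column '%s': unparseable numeric at data row(s) %s",
            path, col, paste(utils::head(bad, 5), collapse = ", ")))
        } else {
          df[[col]] <- parsed
        }
      }
    }
    for (col in intersect(schema$heteroplasmy, names(df))) {
      if (!is.numeric(df[[col]])) next
      v <- if (percent) df[[col]] / 100 else df[[col]]
      bad <- which(is.finite(v) & (v < 0 | v > 1))
      if (length(bad)) {
        errors <- c(errors, sprintf(
          "%s: column '%s': heteroplasmy out of range at data row(s) %s",
          path, col, paste(utils::head(bad, 5), collapse = ", ")))
      } else {
        df[[col]] <- v
      }
    }
  }
  if (length(errors)) {
    stop("validation failed:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  df
}

# write a TSV atomically (temp file in the same directory, then rename)
write_tsv_atomic <- function(df, path, header_comments = character(0)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, "w")
  if (length(header_comments)) {
    writeLines(paste0("# ", header_comments), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

# row count + md5 fingerprint for reports
fingerprint_input <- function(path) {
  list(path = path,
       rows = length(readLines(path, warn = FALSE)) - 1L,
       md5 = unname(tools::md5sum(path)))
}

#' Locate mapped study-datasheet tables, if installed
#'
#' The published numerical datasheet (an XLSX workbook) is not
#' redistributable with the package. To reproduce the published numbers,
#' export its sheets to the package TSV schemas (`pairs.tsv`,
#' `oocytes.tsv`, `tissues.tsv`, fraction or percent scale noted in a
#' `percent` marker file) and drop them into
#' `inst/extdata/s1_datasheet/` before installation (or point `dir` at
#' them). Returns `NULL` when absent.
#'
#' @param dir directory containing the mapped TSVs; defaults to the
#'   installed `extdata/s1_datasheet`.
#' @return list of validated tables (`pairs`, `oocytes`, `tissues`; missing
#'   files are `NULL`), or `NULL` when the directory does not exist.
#' @export
load_study_datasheet <- function(dir = system.file("extdata", "s1_datasheet",
                                                   package = "mitodrift")) {
  if (is.null(dir) || !nzchar(dir) || !dir.exists(dir)) return(NULL)
  percent <- file.exists(file.path(dir, "percent"))
  grab <- function(name, schema) {
    f <- file.path(dir, paste0(name, ".tsv"))
    if (file.exists(f)) validate_table(f, schema, percent = percent) else NULL
  }
  list(pairs = grab("pairs", "pairs"),
       oocytes = grab("oocytes", "oocytes"),
       tissues = grab("tissues", "tissues"))
}
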