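#' Filtering and screening thresholds
#'
#' Bundles every threshold used across the pipeline. Defaults reproduce the
#' standard analysis settings: Class I site confidence (localization
#' probability >= 0.75, or A-score strictly greater than 13), differential
#' calling (fold change >= 1.3 up / <= 0.76 down with p < 0.05), and the four
#' high-confidence co-regulation filters (frequency ratio >= 10%, Fisher test
#' p < 0.05, support from >= 3 distinct publications and >= 3 distinct
#' experimental-condition codes).
#'
#' @param loc_prob_min Minimum localization probability for a Class I site
#'   (inclusive).
#' @param ascore_min A-score cutoff for a Class I site; the comparison is
#'   strict (`ascore > ascore_min`).
#' @param up_threshold Minimum fold change (treatment/control) for an
#'   upregulated call (inclusive).
#' @param down_threshold Maximum fold change for a downregulated call
#'   (inclusive).
#' @param p_threshold p-value cutoff for a differential call (strict `<`).
#' @param min_pmids Minimum number of distinct publications (PMIDs) required,
#'   both for predominance and for the co-regulation PMID-confidence filter.
#' @param min_codes Minimum number of distinct experimental-condition codes
#'   supporting a co-regulation.
#' @param freq_ratio_min Minimum co-regulation frequency as a fraction of the
#'   predominant site's total differential frequency.
#' @param fet_alpha Significance level for the one-sided Fisher exact test.
#' @return A list of class `"filter_config"`.
#' @examples
#' filter_config()
#' @export
filter_config <- function(loc_prob_min = 0.75,
                          ascore_min = 13,
                          up_threshold = 1.3,
                          down_threshold = 0.76,
                          p_threshold = 0.05,
                          min_pmids = 3L,
                          min_codes = 3L,
                          freq_ratio_min = 0.10,
                          fet_alpha = 0.05) {
  cfg <- list(
    loc_prob_min = as.numeric(loc_prob_min),
    ascore_min = as.numeric(ascore_min),
    up_threshold = as.numeric(up_threshold),
    down_threshold = as.numeric(down_threshold),
    p_threshold = as.numeric(p_threshold),
    min_pmids = as.integer(min_pmids),
    min_codes = as.integer(min_codes),
    freq_ratio_min = as.numeric(freq_ratio_min),
    fet_alpha = as.numeric(fet_alpha)
  )
  num <- unlist(cfg[c("loc_prob_min", "ascore_min", "up_threshold",
                      "down_threshold", "p_threshold", "freq_ratio_min",
                      "fet_alpha")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all thresholds must be positive and finite", call. = FALSE)
  }
  if (!(cfg$up_threshold > 1 && cfg$down_threshold < 1)) {
    stop("up_threshold must exceed 1 and down_threshold must be below 1",
         call. = FALSE)
  }
  if (cfg$min_pmids < 1L || cfg$min_codes < 1L) {
    stop("min_pmids and min_codes must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (k in names(x)) cat(sprintf("  %-15s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a key = value configuration file
#'
#' Parses a plain-text configuration file with one `key = value` pair per
#' line (`#` starts a comment). Keys matching [filter_config()] arguments are
#' collected into a `filter_config`; all other keys are returned verbatim as
#' strings.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `filters` (a `filter_config`) and `options`
#'   (named list of the remaining keys).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) {
    stop("configuration line is not 'key = value': ", lines[bad][1L],
         call. = FALSE)
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  names(vals) <- keys
  filter_keys <- names(formals(filter_config))
  fk <- intersect(keys, filter_keys)
  filters <- do.call(filter_config, as.list(as.numeric(vals[fk])) |>
                       stats::setNames(fk))
  list(filters = filters, options = as.list(vals[setdiff(keys, filter_keys)]))
}
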