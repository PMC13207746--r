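#' Tally joint regulation patterns for a site pair
#'
#' Over every differential dataset in which BOTH sites carry a regulation
#' call (`U` or `D`), counts the four joint patterns: `nUU`, `nDD`
#' (concordant) and `nUD`, `nDU` (discordant), the first letter referring to
#' `site1`. Datasets where either site is undetected or uncalled do not enter
#' the tally (they matter only in the condition-level contingency table of
#' [build_contingency()]).
#'
#' @param corpus A harmonized [phos_corpus()].
#' @param site1,site2 Canonical site tokens (e.g. `"CAV1_Y14"`); must differ.
#' @return One-row tibble: `site1`, `site2`, `nUU`, `nDD`, `nUD`, `nDU`,
#'   `n_both`.
#' @export
count_patterns <- function(corpus, site1, site2) {
  stopifnot(inherits(corpus, "phos_corpus"))
  if (identical(site1, site2)) {
    stop("site1 and site2 must be distinct sites", call. = FALSE)
  }
  calls <- called_records(corpus)
  c1 <- calls[calls$token == site1, c("dataset_id", "call")]
  c2 <- calls[calls$token == site2, c("dataset_id", "call")]
  joint <- dplyr::inner_join(c1, c2, by = "dataset_id",
                             suffix = c("1", "2"))
  pattern_row(site1, site2, joint$call1, joint$call2)
}

# differential records carrying a usable call (conflicts excluded)
called_records <- function(corpus) {
  corpus$differential[corpus$differential$call %in% c("U", "D"), , drop = FALSE]
}

pattern_row <- function(site1, site2, calls1, calls2) {
  code <- paste0(calls1, calls2)
  tibble::tibble(
    site1 = site1, site2 = site2,
    nUU = sum(code == "UU"), nDD = sum(code == "DD"),
    nUD = sum(code == "UD"), nDU = sum(code == "DU"),
    n_both = length(code)
  )
}

#' Positive and negative co-regulation ratios
#'
#' The positive co-regulation ratio of a site pair is the number of
#' concordantly regulated conditions over the number of discordantly
#' regulated ones, `(nUU + nDD) / (nUD + nDU)`; the negative ratio is its
#' reciprocal. Higher values indicate stronger coordinated (respectively
#' opposed) regulation. A zero denominator under a nonzero numerator yields
#' `Inf` (infinite concordance/discordance); a pair with no co-called
#' conditions at all yields `NA` for both ("no data").
#'
#' @param counts One-row tibble from [count_patterns()] (or any list with
#'   fields `nUU`, `nDD`, `nUD`, `nDU`).
#' @return One-row tibble with `positive_ratio` and `negative_ratio`.
#' @export
coregulation_ratios <- function(counts) {
  conc <- counts$nUU + counts$nDD
  disc <- counts$nUD + counts$nDU
  ratio <- function(num, den) {
    dplyr::case_when(
      num == 0 & den == 0 ~ NA_real_,
      den == 0 ~ Inf,
      TRUE ~ num / den
    )
  }
  tibble::tibble(positive_ratio = ratio(conc, disc),
                 negative_ratio = ratio(disc, conc))
}

#' Intra-protein co-occurrence matrix
#'
#' Computes pattern counts and co-regulation ratios for every unordered pair
#' of Class I sites of one protein, in long format ready for dual-layer
#' heat-map rendering (positive and negative ratios as separate columns).
#'
#' @param corpus A harmonized [phos_corpus()].
#' @param protein Gene symbol of the target protein.
#' @param cfg A [filter_config()].
#' @return Tibble with columns `site1`, `site2`, `nUU`, `nDD`, `nUD`, `nDU`,
#'   `n_both`, `positive_ratio`, `negative_ratio`; one row per unordered
#'   pair, sites ordered by position.
#' @export
cooccurrence_matrix <- function(corpus, protein, cfg = filter_config()) {
  stopifnot(inherits(corpus, "phos_corpus"))
  freqs <- suppressWarnings(site_frequencies(corpus, protein, cfg))
  tokens <- freqs$token[order(freqs$position)]
  if (length(tokens) < 2L) {
    warning("fewer than 2 Class I sites for ", protein,
            "; no pairs to evaluate")
    return(tibble::tibble(site1 = character(), site2 = character(),
                          nUU = integer(), nDD = integer(), nUD = integer(),
                          nDU = integer(), n_both = integer(),
                          positive_ratio = numeric(),
                          negative_ratio = numeric()))
  }
  calls <- called_records(corpus)
  calls <- calls[calls$token %in% tokens, c("dataset_id", "token", "call")]
  pairs <- utils::combn(tokens, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    s1 <- pairs[1L, k]; s2 <- pairs[2L, k]
    joint <- dplyr::inner_join(
      calls[calls$token == s1, c("dataset_id", "call")],
      calls[calls$token == s2, c("dataset_id", "call")],
      by = "dataset_id", suffix = c("1", "2"))
    pattern_row(s1, s2, joint$call1, joint$call2)
  })
  counts <- dplyr::bind_rows(rows)
  dplyr::bind_cols(counts, coregulation_ratios(counts))
}
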