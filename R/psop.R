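#' Screen phosphosites of other proteins for co-differential regulation
#'
#' For one predominant site of the target protein, every phosphosite of every
#' other protein with at least one co-called condition is evaluated in two
#' categories: `UUDD` (positive co-regulation, concordant conditions `d` as
#' the co-regulation frequency, one-sided Fisher test toward concordance) and
#' `UDDU` (negative co-regulation, discordant conditions `c`, one-sided test
#' toward discordance). Four high-confidence filters are evaluated per row
#' and combined into `passes`:
#' frequency ratio (category frequency over the predominant site's total
#' differential frequency) at least `freq_ratio_min`; Fisher p below
#' `fet_alpha`; support from at least `min_pmids` distinct publications and
#' `min_codes` distinct experimental-condition codes, both counted over the
#' conditions contributing to the row's own category. Rows failing filters
#' are retained with `passes = FALSE`; a Benjamini-Hochberg column `fet_bh`
#' is reported for reference but does not enter `passes`.
#'
#' @param corpus A harmonized [phos_corpus()].
#' @param predominant_site Canonical token of the predominant site.
#' @param cfg A [filter_config()].
#' @return Tibble with one row per (site, category) with positive category
#'   frequency; columns `site`, `gene`, `category`, pattern counts,
#'   contingency cells `a`-`d`, `fet_p`, `fet_bh`, `coreg_freq`,
#'   `freq_ratio`, `pmid_count`, `code_count`, `passes`.
#' @export
psop_screen <- function(corpus, predominant_site, cfg = filter_config()) {
  stopifnot(inherits(corpus, "phos_corpus"))
  pred_gene <- parse_site_token(predominant_site)$gene

  empty <- tibble::tibble(
    site = character(), gene = character(), category = character(),
    nUU = integer(), nDD = integer(), nUD = integer(), nDU = integer(),
    a = integer(), b = integer(), c = integer(), d = integer(),
    fet_p = numeric(), fet_bh = numeric(), coreg_freq = integer(),
    freq_ratio = numeric(), pmid_count = integer(), code_count = integer(),
    passes = logical())

  calls <- called_records(corpus)
  pred_calls <- calls[calls$token == predominant_site,
                      c("dataset_id", "call")]
  pred_diff_count <- nrow(pred_calls)
  if (pred_diff_count == 0L) {
    warning("predominant site ", predominant_site,
            " has no differential calls in the corpus")
    return(empty)
  }
  n_total <- sum(corpus$metas$dataset_type == "differential")
  meta <- corpus$metas[, c("dataset_id", "pmid", "condition_code")]

  others <- calls[calls$gene != pred_gene,
                  c("dataset_id", "token", "gene", "call")]
  if (nrow(others) == 0L) return(empty)
  other_n <- dplyr::count(others, .data$token, name = "other_called_n")

  joint <- others %>%
    dplyr::inner_join(pred_calls, by = "dataset_id",
                      suffix = c("_other", "_pred")) %>%
    dplyr::mutate(
      code = classify_pattern(.data$call_pred, .data$call_other),
      category = ifelse(.data$code %in% c("UU", "DD"), "UUDD", "UDDU")) %>%
    dplyr::left_join(meta, by = "dataset_id")
  if (nrow(joint) == 0L) return(empty)

  counts <- joint %>%
    dplyr::group_by(.data$token, .data$gene) %>%
    dplyr::summarise(
      nUU = sum(.data$code == "UU"), nDD = sum(.data$code == "DD"),
      nUD = sum(.data$code == "UD"), nDU = sum(.data$code == "DU"),
      .groups = "drop") %>%
    dplyr::mutate(n_both = .data$nUU + .data$nDD + .data$nUD + .data$nDU) %>%
    dplyr::left_join(other_n, by = "token") %>%
    dplyr::mutate(
      d = .data$nUU + .data$nDD,
      c = .data$nUD + .data$nDU,
      b = (pred_diff_count - .data$n_both) +
        (.data$other_called_n - .data$n_both),
      a = n_total - .data$b - .data$c - .data$d)

  support <- joint %>%
    dplyr::group_by(.data$token, .data$category) %>%
    dplyr::summarise(
      pmid_count = dplyr::n_distinct(.data$pmid),
      code_count = dplyr::n_distinct(.data$condition_code),
      .groups = "drop")

  per_cat <- dplyr::bind_rows(
    dplyr::mutate(counts, category = "UUDD", coreg_freq = .data$d),
    dplyr::mutate(counts, category = "UDDU", coreg_freq = .data$c)) %>%
    dplyr::filter(.data$coreg_freq > 0L) %>%
    dplyr::inner_join(support, by = c("token", "category"))

  if (nrow(per_cat) == 0L) return(empty)

  per_cat$fet_p <- NA_real_
  pos <- per_cat$category == "UUDD"
  if (any(pos)) {
    per_cat$fet_p[pos] <- fisher_one_sided(per_cat[pos, c("a", "b", "c", "d")],
                                           direction = "positive")
  }
  if (any(!pos)) {
    per_cat$fet_p[!pos] <- fisher_one_sided(
      per_cat[!pos, c("a", "b", "c", "d")], direction = "negative")
  }

  per_cat %>%
    dplyr::mutate(
      fet_bh = stats::p.adjust(.data$fet_p, method = "BH"),
      freq_ratio = .data$coreg_freq / pred_diff_count,
      passes = .data$fet_p < cfg$fet_alpha &
        .data$freq_ratio >= cfg$freq_ratio_min &
        .data$pmid_count >= cfg$min_pmids &
        .data$code_count >= cfg$min_codes) %>%
    dplyr::transmute(
      site = .data$token, gene = .data$gene, category = .data$category,
      nUU = .data$nUU, nDD = .data$nDD, nUD = .data$nUD, nDU = .data$nDU,
      a = .data$a, b = .data$b, c = .data$c, d = .data$d,
      fet_p = .data$fet_p, fet_bh = .data$fet_bh,
      coreg_freq = as.integer(.data$coreg_freq),
      freq_ratio = .data$freq_ratio,
      pmid_count = as.integer(.data$pmid_count),
      code_count = as.integer(.data$code_count),
      passes = .data$passes) %>%
    dplyr::arrange(.data$category, .data$fet_p, .data$gene, .data$site)
}
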