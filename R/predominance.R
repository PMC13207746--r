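#' Per-site detection frequencies for a protein
#'
#' Counts, for every Class I phosphosite of a protein, the number of
#' profiling datasets in which it was identified, the number of differential
#' datasets in which it was called up- or down-regulated, and the number of
#' distinct studies (PMIDs) supporting either kind of detection. Frequency is
#' dataset-level: a dataset contributes at most 1 to each count regardless of
#' how many peptides reported the site.
#'
#' @param corpus A harmonized [phos_corpus()].
#' @param protein Gene symbol of the target protein.
#' @param cfg A [filter_config()] (Class I thresholds for profiling rows).
#' @return Tibble with one row per site: `gene`, `residue`, `position`,
#'   `token`, `profiling_count`, `differential_count`, `up_count`,
#'   `down_count`, `study_count`.
#' @export
site_frequencies <- function(corpus, protein, cfg = filter_config()) {
  stopifnot(inherits(corpus, "phos_corpus"))
  protein <- toupper(protein)

  prof <- corpus$profiling[corpus$profiling$gene == protein, , drop = FALSE]
  if (nrow(prof)) {
    prof <- prof[is_class1(prof$loc_prob, prof$ascore, cfg), , drop = FALSE]
  }
  diff <- corpus$differential[corpus$differential$gene == protein &
                                corpus$differential$call %in% c("U", "D"), ,
                              drop = FALSE]
  if (nrow(prof) == 0L && nrow(diff) == 0L) {
    warning("protein ", protein, " has no Class I sites in the corpus")
    return(tibble::tibble(gene = character(), residue = character(),
                          position = integer(), token = character(),
                          profiling_count = integer(),
                          differential_count = integer(),
                          up_count = integer(), down_count = integer(),
                          study_count = integer()))
  }
  meta_pmid <- stats::setNames(corpus$metas$pmid, corpus$metas$dataset_id)

  prof_counts <- prof %>%
    dplyr::distinct(.data$token, .data$dataset_id) %>%
    dplyr::count(.data$token, name = "profiling_count")
  diff_counts <- diff %>%
    dplyr::distinct(.data$token, .data$dataset_id, .data$call) %>%
    dplyr::group_by(.data$token) %>%
    dplyr::summarise(
      differential_count = dplyr::n(),
      up_count = sum(.data$call == "U"),
      down_count = sum(.data$call == "D"),
      .groups = "drop")

  detections <- dplyr::bind_rows(
    prof[, c("token", "dataset_id")], diff[, c("token", "dataset_id")])
  study_counts <- detections %>%
    dplyr::mutate(pmid = meta_pmid[.data$dataset_id]) %>%
    dplyr::distinct(.data$token, .data$pmid) %>%
    dplyr::count(.data$token, name = "study_count")

  ids <- dplyr::bind_rows(
    prof[, c("gene", "residue", "position", "token")],
    diff[, c("gene", "residue", "position", "token")]) %>%
    dplyr::distinct(.data$token, .keep_all = TRUE)

  out <- ids %>%
    dplyr::left_join(prof_counts, by = "token") %>%
    dplyr::left_join(diff_counts, by = "token") %>%
    dplyr::left_join(study_counts, by = "token") %>%
    dplyr::mutate(dplyr::across(
      dplyr::all_of(c("profiling_count", "differential_count", "up_count",
                      "down_count", "study_count")),
      ~ as.integer(dplyr::coalesce(.x, 0L)))) %>%
    dplyr::arrange(.data$position)
  out
}

#' Rank sites and designate the predominant phosphosites
#'
#' Sites are ordered by combined detection frequency (profiling plus
#' differential) descending, ties broken by differential frequency then by
#' position ascending. A site is designated predominant when it is detected
#' in both dataset types and supported by at least `min_pmids` distinct
#' studies.
#'
#' @param freqs Output of [site_frequencies()].
#' @param cfg A [filter_config()].
#' @return `freqs` reordered, with columns `total_count`, `rank` and logical
#'   `predominant` appended.
#' @export
rank_predominant <- function(freqs, cfg = filter_config()) {
  if (nrow(freqs) == 0L) {
    stop("cannot rank an empty frequency table", call. = FALSE)
  }
  out <- freqs %>%
    dplyr::mutate(total_count = .data$profiling_count +
                    .data$differential_count) %>%
    dplyr::arrange(dplyr::desc(.data$total_count),
                   dplyr::desc(.data$differential_count),
                   .data$position) %>%
    dplyr::mutate(
      rank = dplyr::row_number(),
      predominant = .data$profiling_count > 0L &
        .data$differential_count > 0L &
        .data$study_count >= cfg$min_pmids)
  out
}

#' Plot-ready lollipop table of site frequencies
#'
#' Exports per-site rows suitable for lollipop-style rendering of a
#' protein's phosphorylation landscape: profiling height, upregulation height
#' and downregulation height (emitted as a negative value so the down
#' lollipops hang below the axis), with optional protein-domain overlap
#' labels.
#'
#' @param freqs Output of [site_frequencies()] (or [rank_predominant()]).
#' @param domains Optional tibble with columns `domain`, `start`, `end`
#'   (1-based inclusive protein coordinates).
#' @return Tibble with columns `token`, `position`, `profiling_height`,
#'   `up_height`, `down_height`, `domain`.
#' @export
export_lollipop_table <- function(freqs, domains = NULL) {
  out <- tibble::tibble(
    token = freqs$token,
    position = freqs$position,
    profiling_height = freqs$profiling_count,
    up_height = freqs$up_count,
    down_height = -freqs$down_count,
    domain = NA_character_
  )
  if (!is.null(domains) && nrow(domains)) {
    if (any(domains$start > domains$end)) {
      stop("domain intervals must have start <= end", call. = FALSE)
    }
    for (i in seq_len(nrow(domains))) {
      inside <- out$position >= domains$start[i] &
        out$position <= domains$end[i]
      out$domain[inside] <- domains$domain[i]
    }
  }
  out
}
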