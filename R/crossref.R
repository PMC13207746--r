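#' Cross-reference upstream kinases with the co-regulation screen
#'
#' A candidate upstream kinase of the target site is reported when (i) it
#' annotates the target site in the curated kinase-substrate table and (ii)
#' at least one of the kinase's OWN phosphosites appears among the passing
#' co-regulated sites of the screen — i.e. the kinase itself is
#' co-differentially regulated with the site it is annotated to
#' phosphorylate. Evidence status (`validated`/`predicted`) is carried
#' through from the curation.
#'
#' @param psop_results Output of [psop_screen()].
#' @param kinase_table Tibble with columns `kinase`, `substrate_gene`,
#'   `residue`, `position`, `evidence`, `source`.
#' @param target_site Canonical token of the screened predominant site.
#' @return Tibble with one row per reported kinase: `kinase`, `evidence`,
#'   `categories` (co-regulation directions observed among its passing
#'   sites), `best_fet_p`, `n_coregulated_sites`, `sources`; ordered by
#'   kinase symbol.
#' @export
crossref_kinases <- function(psop_results, kinase_table, target_site) {
  empty <- tibble::tibble(kinase = character(), evidence = character(),
                          categories = character(), best_fet_p = numeric(),
                          n_coregulated_sites = integer(),
                          sources = character())
  if (is.null(kinase_table) || nrow(kinase_table) == 0L) {
    warning("kinase table is empty; no kinases to cross-reference")
    return(empty)
  }
  needed <- c("kinase", "substrate_gene", "residue", "position", "evidence",
              "source")
  miss <- setdiff(needed, names(kinase_table))
  if (length(miss)) {
    stop("kinase table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!kinase_table$evidence %in% c("validated", "predicted"))) {
    stop("kinase evidence must be 'validated' or 'predicted'", call. = FALSE)
  }
  kt <- kinase_table
  kt$substrate_token <- format_site_token(toupper(kt$substrate_gene),
                                          kt$residue, kt$position)
  annot <- kt[kt$substrate_token == target_site, , drop = FALSE]
  if (nrow(annot) == 0L) return(empty)

  hits <- psop_results[psop_results$passes, , drop = FALSE]
  annot %>%
    dplyr::group_by(kinase = toupper(.data$kinase)) %>%
    dplyr::summarise(
      evidence = if (any(.data$evidence == "validated")) "validated"
                 else "predicted",
      sources = paste(sort(unique(.data$source)), collapse = ";"),
      .groups = "drop") %>%
    dplyr::rowwise() %>%
    dplyr::mutate(
      n_coregulated_sites = sum(hits$gene == .data$kinase),
      categories = paste(sort(unique(hits$category[hits$gene ==
                                                     .data$kinase])),
                         collapse = ";"),
      best_fet_p = if (.data$n_coregulated_sites > 0L) {
        min(hits$fet_p[hits$gene == .data$kinase])
      } else NA_real_) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$n_coregulated_sites > 0L) %>%
    dplyr::select(dplyr::all_of(c("kinase", "evidence", "categories",
                                  "best_fet_p", "n_coregulated_sites",
                                  "sources"))) %>%
    dplyr::arrange(.data$kinase)
}

#' Cross-reference high-confidence interaction partners
#'
#' Interaction partners of the target protein are retained when supported by
#' at least `min_db_support` distinct source databases; for each retained
#' partner, its phosphosites among the passing co-regulated sites of the
#' screen are listed with their co-regulation categories.
#'
#' @param psop_results Output of [psop_screen()].
#' @param ppi Tibble with columns `partner`, `source_db` (one row per
#'   partner-database support assertion).
#' @param min_db_support Minimum number of distinct supporting databases
#'   (default 2: cross-database corroboration).
#' @param all_partners If `TRUE`, partners with no co-regulated phosphosite
#'   are kept with an empty site list; dropped otherwise.
#' @return Tibble with columns `partner`, `n_sources`, `sources`,
#'   `coregulated_sites` (semicolon-joined tokens), `categories`; ordered by
#'   partner symbol.
#' @export
crossref_interactors <- function(psop_results, ppi, min_db_support = 2L,
                                 all_partners = FALSE) {
  if (min_db_support < 1L) {
    stop("min_db_support must be >= 1", call. = FALSE)
  }
  if (!all(c("partner", "source_db") %in% names(ppi))) {
    stop("ppi table needs columns partner, source_db", call. = FALSE)
  }
  hits <- psop_results[psop_results$passes, , drop = FALSE]
  out <- ppi %>%
    dplyr::group_by(partner = toupper(.data$partner)) %>%
    dplyr::summarise(
      n_sources = dplyr::n_distinct(.data$source_db),
      sources = paste(sort(unique(.data$source_db)), collapse = ";"),
      .groups = "drop") %>%
    dplyr::filter(.data$n_sources >= min_db_support) %>%
    dplyr::rowwise() %>%
    dplyr::mutate(
      coregulated_sites = paste(sort(unique(
        hits$site[hits$gene == .data$partner])), collapse = ";"),
      categories = paste(sort(unique(
        hits$category[hits$gene == .data$partner])), collapse = ";")) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$partner)
  if (!all_partners) {
    out <- out[nzchar(out$coregulated_sites), , drop = FALSE]
  }
  out
}

#' Group passing co-regulated sites by biological process
#'
#' Descriptive, annotation-based grouping (no statistical enrichment): each
#' passing site of the screen is joined to its curated biological-process
#' labels, in long format suitable for network-style export. Sites without
#' any annotation are routed to an `"unannotated"` bucket. The sign column
#' translates the category: `UUDD` is positive co-regulation, `UDDU`
#' negative.
#'
#' @param psop_results Output of [psop_screen()].
#' @param process_table Tibble with columns `gene`, `residue`, `position`,
#'   `process`.
#' @return Tibble with columns `process`, `site`, `sign`, ordered by
#'   (process, site).
#' @export
group_by_process <- function(psop_results, process_table) {
  if (!all(c("gene", "residue", "position", "process") %in%
           names(process_table))) {
    stop("process table needs columns gene, residue, position, process",
         call. = FALSE)
  }
  hits <- psop_results[psop_results$passes, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble::tibble(process = character(), site = character(),
                          sign = character()))
  }
  pt <- process_table
  pt$site <- format_site_token(toupper(pt$gene), pt$residue, pt$position)
  hits %>%
    dplyr::transmute(
      site = .data$site,
      sign = ifelse(.data$category == "UUDD", "positive", "negative")) %>%
    dplyr::left_join(pt[, c("site", "process")], by = "site",
                     relationship = "many-to-many") %>%
    dplyr::mutate(process = dplyr::coalesce(.data$process, "unannotated")) %>%
    dplyr::distinct() %>%
    dplyr::select(dplyr::all_of(c("process", "site", "sign"))) %>%
    dplyr::arrange(.data$process, .data$site)
}

#' Read curated annotation tables
#'
#' Convenience readers for the three curation TSVs consumed by the
#' cross-referencing stage.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the validated columns.
#' @name read_annotation_tables
NULL

#' @rdname read_annotation_tables
#' @export
read_kinase_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(position = "i",
                                                      .default = "c"),
                        progress = FALSE)
  needed <- c("kinase", "substrate_gene", "residue", "position", "evidence",
              "source")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_annotation_tables
#' @export
read_ppi_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  miss <- setdiff(c("partner", "source_db"), names(df))
  if (length(miss)) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_annotation_tables
#' @export
read_process_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(position = "i",
                                                      .default = "c"),
                        progress = FALSE)
  miss <- setdiff(c("gene", "residue", "position", "process"), names(df))
  if (length(miss)) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}
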