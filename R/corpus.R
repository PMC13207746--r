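#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

DATASET_COLS <- c("dataset_id", "pmid", "condition_code", "dataset_type",
                  "enrichment")
PROFILING_COLS <- c("dataset_id", "pmid", "condition_code", "gene",
                    "accession", "residue", "position", "loc_prob", "ascore")
DIFFERENTIAL_COLS <- c("dataset_id", "pmid", "condition_code", "gene",
                       "accession", "residue", "position", "fold_change",
                       "p_value")

#' Construct a phosphoproteomic corpus
#'
#' A corpus bundles dataset-level metadata with site-level profiling
#' (qualitative identification) and differential (quantitative
#' test-vs-control) records. Profiling datasets are condition-level lists of
#' identified phosphosites with localization confidence; differential
#' datasets carry per-site fold changes and p-values from which regulation
#' calls (`U`/`D`/`none`) are derived.
#'
#' @param metas Tibble with columns `dataset_id`, `pmid`, `condition_code`,
#'   `dataset_type` (`"profiling"` or `"differential"`), `enrichment`
#'   (`"STY"`, `"ST"` or `"Y"`).
#' @param profiling Tibble with columns `dataset_id`, `gene`, `accession`,
#'   `residue`, `position`, `loc_prob`, `ascore` (either score may be `NA`,
#'   not both).
#' @param differential Tibble with columns `dataset_id`, `gene`, `accession`,
#'   `residue`, `position`, `fold_change`, `p_value` and (optionally,
#'   recomputed otherwise) `call`.
#' @param cfg A [filter_config()] used to derive calls and collapse
#'   duplicate rows.
#' @return An object of class `phos_corpus`.
#' @export
phos_corpus <- function(metas, profiling, differential,
                        cfg = filter_config()) {
  metas <- tibble::as_tibble(metas)
  profiling <- tibble::as_tibble(profiling)
  differential <- tibble::as_tibble(differential)

  if (anyDuplicated(metas$dataset_id)) {
    stop("dataset_id values must be unique within a corpus", call. = FALSE)
  }
  if (any(!metas$dataset_type %in% c("profiling", "differential"))) {
    stop("dataset_type must be 'profiling' or 'differential'", call. = FALSE)
  }
  if (any(!metas$enrichment %in% c("STY", "ST", "Y"))) {
    stop("enrichment must be one of STY, ST, Y", call. = FALSE)
  }
  check_sites <- function(df, what) {
    if (nrow(df) == 0L) return(invisible())
    if (any(!df$residue %in% c("S", "T", "Y"))) {
      stop(what, ": residue must be one of S, T, Y", call. = FALSE)
    }
    if (any(df$position < 1L)) {
      stop(what, ": positions must be >= 1", call. = FALSE)
    }
    miss <- setdiff(unique(df$dataset_id), metas$dataset_id)
    if (length(miss)) {
      stop(what, ": records reference unknown dataset_id(s): ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    }
  }
  check_sites(profiling, "profiling")
  check_sites(differential, "differential")
  if (nrow(profiling)) {
    # triggers validation of score ranges and both-absent records
    is_class1(profiling$loc_prob, profiling$ascore, cfg)
  }

  profiling <- collapse_profiling(add_site_token(profiling))
  differential <- finalize_differential(add_site_token(differential), cfg)

  structure(
    list(metas = metas, profiling = profiling, differential = differential),
    class = "phos_corpus", cfg = cfg
  )
}

#' @export
print.phos_corpus <- function(x, ...) {
  cat(sprintf(
    "<phos_corpus> %d datasets (%d profiling, %d differential), %d studies\n",
    nrow(x$metas), sum(x$metas$dataset_type == "profiling"),
    sum(x$metas$dataset_type == "differential"),
    dplyr::n_distinct(x$metas$pmid)))
  cat(sprintf("  profiling records:    %d (%d sites)\n", nrow(x$profiling),
              dplyr::n_distinct(x$profiling$token)))
  cat(sprintf("  differential records: %d (%d sites, %d called U/D)\n",
              nrow(x$differential), dplyr::n_distinct(x$differential$token),
              sum(x$differential$call %in% c("U", "D"))))
  invisible(x)
}

# Duplicate profiling rows for the same site in the same dataset (multiple
# peptides) are collapsed to the best-localized evidence.
collapse_profiling <- function(profiling) {
  if (nrow(profiling) == 0L) return(profiling)
  safe_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  profiling %>%
    dplyr::group_by(.data$dataset_id, .data$token) %>%
    dplyr::summarise(
      gene = dplyr::first(.data$gene),
      accession = dplyr::first(.data$accession),
      residue = dplyr::first(.data$residue),
      position = dplyr::first(.data$position),
      loc_prob = safe_max(.data$loc_prob),
      ascore = safe_max(.data$ascore),
      .groups = "drop"
    ) %>%
    dplyr::select(dplyr::all_of(c("dataset_id", "gene", "accession",
                                  "residue", "position", "loc_prob",
                                  "ascore", "token")))
}

# Derive calls and resolve duplicate differential rows per (dataset, site):
# agreeing duplicates keep the most extreme fold change; a site reported both
# U and D in one dataset resolves to the smaller p-value, and an exact p tie
# is flagged "conflict" (excluded from all co-regulation counting).
finalize_differential <- function(differential, cfg) {
  if (nrow(differential) == 0L) {
    differential$call <- character()
    return(differential)
  }
  if (any(differential$fold_change <= 0)) {
    stop("differential: fold changes must be positive", call. = FALSE)
  }
  differential$call <- call_regulation(differential$fold_change,
                                       differential$p_value, cfg)
  differential %>%
    dplyr::group_by(.data$dataset_id, .data$token) %>%
    dplyr::group_modify(~ resolve_duplicate_calls(.x)) %>%
    dplyr::ungroup() %>%
    dplyr::select(dplyr::all_of(c("dataset_id", "gene", "accession",
                                  "residue", "position", "fold_change",
                                  "p_value", "call", "token")))
}

resolve_duplicate_calls <- function(rows) {
  if (nrow(rows) == 1L) return(rows)
  has_u <- any(rows$call == "U")
  has_d <- any(rows$call == "D")
  if (has_u && has_d) {
    contenders <- rows[rows$call %in% c("U", "D"), ]
    best <- contenders[contenders$p_value == min(contenders$p_value), ]
    if (length(unique(best$call)) > 1L) {
      out <- best[1L, ]
      out$call <- "conflict"
      return(out)
    }
    return(best[1L, ])
  }
  ord <- order(-abs(log(rows$fold_change)), rows$p_value)
  rows[ord[1L], ]
}

#' Read a corpus from TSV files
#'
#' Loads the three corpus tables (`datasets.tsv`, `profiling.tsv`,
#' `differential.tsv`) from a directory, validates their schemas, derives
#' regulation calls, and collapses duplicate per-dataset site rows.
#'
#' @param dir Directory containing the three TSV files.
#' @param cfg A [filter_config()].
#' @return A [phos_corpus()].
#' @export
read_corpus <- function(dir, cfg = filter_config()) {
  read_table <- function(file, required, col_types) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      stop("missing corpus file: ", path, call. = FALSE)
    }
    df <- readr::read_tsv(path, col_types = col_types,
                          na = c("", "NA"), progress = FALSE)
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      stop(file, " is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    df
  }
  metas <- read_table("datasets.tsv", DATASET_COLS, readr::cols(
    dataset_id = "c", pmid = "c", condition_code = "c",
    dataset_type = "c", enrichment = "c"))
  profiling <- read_table("profiling.tsv", PROFILING_COLS, readr::cols(
    dataset_id = "c", pmid = "c", condition_code = "c", gene = "c",
    accession = "c", residue = "c", position = "i",
    loc_prob = "d", ascore = "d"))
  differential <- read_table("differential.tsv", DIFFERENTIAL_COLS,
                             readr::cols(
    dataset_id = "c", pmid = "c", condition_code = "c", gene = "c",
    accession = "c", residue = "c", position = "i",
    fold_change = "d", p_value = "d"))
  check_meta_consistency(profiling, metas, "profiling.tsv")
  check_meta_consistency(differential, metas, "differential.tsv")
  phos_corpus(metas,
              dplyr::select(profiling, -dplyr::all_of(c("pmid",
                                                        "condition_code"))),
              dplyr::select(differential, -dplyr::all_of(c("pmid",
                                                           "condition_code"))),
              cfg)
}

check_meta_consistency <- function(records, metas, file) {
  if (nrow(records) == 0L) return(invisible())
  joined <- dplyr::inner_join(
    dplyr::distinct(records, .data$dataset_id, .data$pmid,
                    .data$condition_code),
    metas, by = "dataset_id", suffix = c("", ".meta"))
  bad <- joined$pmid != joined$pmid.meta |
    joined$condition_code != joined$condition_code.meta
  if (any(bad)) {
    stop(file, ": pmid/condition_code disagree with datasets.tsv for ",
         paste(utils::head(joined$dataset_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
}

#' Write a corpus to TSV files
#'
#' Inverse of [read_corpus()]: emits `datasets.tsv`, `profiling.tsv` and
#' `differential.tsv` with stable column order (record files carry the
#' dataset's `pmid` and `condition_code` for self-containedness).
#'
#' @param corpus A [phos_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "phos_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_key <- dplyr::select(corpus$metas,
                            dplyr::all_of(c("dataset_id", "pmid",
                                            "condition_code")))
  write_results(corpus$metas[DATASET_COLS], file.path(dir, "datasets.tsv"))
  prof <- dplyr::inner_join(corpus$profiling, meta_key, by = "dataset_id")
  write_results(prof[PROFILING_COLS], file.path(dir, "profiling.tsv"))
  diff <- dplyr::inner_join(corpus$differential, meta_key, by = "dataset_id")
  write_results(diff[DIFFERENTIAL_COLS], file.path(dir, "differential.tsv"))
  invisible(dir)
}

#' Write a result table as TSV
#'
#' Thin writer used by every stage: tab-separated, no quoting surprises,
#' column order exactly as in the input table.
#'
#' @param table A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Harmonize corpus identifiers
#'
#' Re-keys every record to canonical HGNC-style gene symbols (via an
#' alias-to-symbol map) and UniProt-style accessions (via a symbol-to-accession
#' map). Records whose gene alias or resulting symbol is absent from the maps
#' are dropped and counted in the harmonization report attached to the result
#' (see [harmonization_report()]). Duplicate rows created by alias merging are
#' re-collapsed with the same rules as at read time.
#'
#' @param corpus A [phos_corpus()].
#' @param gene_map Tibble with columns `alias`, `symbol`.
#' @param accession_map Tibble with columns `symbol`, `accession`.
#' @return A harmonized [phos_corpus()] with a `harmonization` attribute.
#' @export
harmonize <- function(corpus, gene_map, accession_map) {
  stopifnot(inherits(corpus, "phos_corpus"))
  gene_map <- tibble::as_tibble(gene_map)
  accession_map <- tibble::as_tibble(accession_map)
  if (nrow(gene_map) == 0L || nrow(accession_map) == 0L) {
    stop("gene_map and accession_map must be nonempty", call. = FALSE)
  }
  if (!all(c("alias", "symbol") %in% names(gene_map))) {
    stop("gene_map needs columns alias, symbol", call. = FALSE)
  }
  if (!all(c("symbol", "accession") %in% names(accession_map))) {
    stop("accession_map needs columns symbol, accession", call. = FALSE)
  }
  gene_map$alias <- toupper(gene_map$alias)
  gene_map$symbol <- toupper(gene_map$symbol)
  accession_map$symbol <- toupper(accession_map$symbol)

  rekey <- function(df, what) {
    n_in <- nrow(df)
    sym <- gene_map$symbol[match(toupper(df$gene), gene_map$alias)]
    n_gene_drop <- sum(is.na(sym))
    df$gene <- sym
    df <- df[!is.na(sym), , drop = FALSE]
    acc <- accession_map$accession[match(df$gene, accession_map$symbol)]
    n_acc_drop <- sum(is.na(acc))
    df$accession <- acc
    df <- df[!is.na(acc), , drop = FALSE]
    df$token <- paste0(df$gene, "_", df$residue, df$position)
    list(df = df,
         report = tibble::tibble(table = what, n_in = n_in,
                                 dropped_unmapped_gene = n_gene_drop,
                                 dropped_unmapped_accession = n_acc_drop,
                                 n_out = nrow(df)))
  }
  prof <- rekey(corpus$profiling, "profiling")
  diff <- rekey(corpus$differential, "differential")

  out <- corpus
  out$profiling <- collapse_profiling(prof$df)
  # calls are already derived; alias merging may have created duplicates
  out$differential <- diff$df %>%
    dplyr::group_by(.data$dataset_id, .data$token) %>%
    dplyr::group_modify(~ resolve_duplicate_calls(.x)) %>%
    dplyr::ungroup() %>%
    dplyr::select(dplyr::all_of(names(diff$df)))
  attr(out, "harmonization") <- dplyr::bind_rows(prof$report, diff$report)
  out
}

#' Harmonization drop-count report
#'
#' @param corpus A corpus returned by [harmonize()].
#' @return Tibble with per-table input, dropped and output row counts.
#' @export
harmonization_report <- function(corpus) {
  rep <- attr(corpus, "harmonization")
  if (is.null(rep)) {
    stop("corpus has not been harmonized", call. = FALSE)
  }
  rep
}

#' Subset profiling records to Class I identifications
#'
#' @param corpus A [phos_corpus()].
#' @param cfg A [filter_config()].
#' @return The corpus with non-Class-I profiling rows removed.
#' @export
filter_class1 <- function(corpus, cfg = filter_config()) {
  stopifnot(inherits(corpus, "phos_corpus"))
  if (nrow(corpus$profiling)) {
    keep <- is_class1(corpus$profiling$loc_prob, corpus$profiling$ascore, cfg)
    corpus$profiling <- corpus$profiling[keep, , drop = FALSE]
  }
  corpus
}
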