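#' Run the full co-regulation pipeline
#'
#' Orchestrates every stage over one corpus: (optional) synthetic corpus
#' generation or reading + harmonization, predominant-site ranking,
#' intra-protein co-occurrence, the co-differential-regulation screen for
#' each predominant site, and (when curation tables are supplied)
#' kinase/interactor/process cross-referencing. All stage outputs are written
#' as TSV under `out_dir` together with a JSON run summary; outputs are
#' byte-identical across runs with the same configuration and seed.
#'
#' The configuration file uses `key = value` lines:
#' \describe{
#'   \item{protein}{target gene symbol (required).}
#'   \item{out_dir}{output directory (required).}
#'   \item{corpus_dir}{directory with the three corpus TSVs; alternatively}
#'   \item{simulate, seed}{`simulate = demo` generates the packaged demo
#'     synthetic corpus with the given seed.}
#'   \item{gene_map, accession_map}{optional mapping TSVs; when both are
#'     given the corpus is harmonized before analysis.}
#'   \item{kinase_table, ppi_table, process_table}{optional curation TSVs.}
#'   \item{any [filter_config()] field}{threshold overrides.}
#' }
#'
#' @param config_path Path to the configuration file.
#' @return The run summary (list), invisibly. As a side effect writes
#'   `site_frequencies.tsv`, `cooccurrence.tsv`, `psop_<site>.tsv`,
#'   cross-reference tables and `run_summary.json` under `out_dir`.
#' @export
run_pipeline <- function(config_path) {
  conf <- read_config(config_path)
  cfg <- conf$filters
  opt <- conf$options
  if (is.null(opt$protein) || !nzchar(opt$protein)) {
    stop("configuration must name a target protein (key 'protein')",
         call. = FALSE)
  }
  if (is.null(opt$out_dir)) {
    stop("configuration must name an output directory (key 'out_dir')",
         call. = FALSE)
  }
  protein <- toupper(opt$protein)
  out_dir <- opt$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  summary <- list(filters = unclass(cfg))
  if (!is.null(opt$corpus_dir)) {
    corpus <- read_corpus(opt$corpus_dir, cfg)
    files <- file.path(opt$corpus_dir,
                       c("datasets.tsv", "profiling.tsv", "differential.tsv"))
    summary$input_digests <- as.list(tools::md5sum(files))
    if (!is.null(opt$gene_map) && !is.null(opt$accession_map)) {
      corpus <- harmonize(
        corpus,
        readr::read_tsv(opt$gene_map, col_types = "cc", progress = FALSE),
        readr::read_tsv(opt$accession_map, col_types = "cc",
                        progress = FALSE))
      summary$harmonization <- harmonization_report(corpus)
    }
  } else if (identical(opt$simulate, "demo")) {
    seed <- if (is.null(opt$seed)) 42L else as.integer(opt$seed)
    sim <- generate_corpus(demo_synthetic_config(seed = seed), cfg)
    corpus <- sim$corpus
    summary$seed <- seed
  } else {
    stop("configuration must provide 'corpus_dir' or 'simulate = demo'",
         call. = FALSE)
  }

  corpus <- filter_class1(corpus, cfg)
  summary$n_datasets <- nrow(corpus$metas)
  summary$n_profiling_records <- nrow(corpus$profiling)
  summary$n_differential_records <- nrow(corpus$differential)

  freqs <- rank_predominant(site_frequencies(corpus, protein, cfg), cfg)
  write_results(freqs, file.path(out_dir, "site_frequencies.tsv"))
  summary$n_sites <- nrow(freqs)
  predominant <- freqs$token[freqs$predominant]
  summary$predominant_sites <- as.list(predominant)

  cooc <- cooccurrence_matrix(corpus, protein, cfg)
  write_results(cooc, file.path(out_dir, "cooccurrence.tsv"))
  summary$n_site_pairs <- nrow(cooc)

  kinases <- if (!is.null(opt$kinase_table)) {
    read_kinase_table(opt$kinase_table)
  }
  ppi <- if (!is.null(opt$ppi_table)) read_ppi_table(opt$ppi_table)
  processes <- if (!is.null(opt$process_table)) {
    read_process_table(opt$process_table)
  }

  summary$psop <- list()
  for (site in predominant) {
    res <- psop_screen(corpus, site, cfg)
    write_results(res, file.path(out_dir, paste0("psop_", site, ".tsv")))
    summary$psop[[site]] <- list(
      n_screened = nrow(res),
      n_passing_UUDD = sum(res$passes & res$category == "UUDD"),
      n_passing_UDDU = sum(res$passes & res$category == "UDDU"))
    if (!is.null(kinases)) {
      kx <- crossref_kinases(res, kinases, site)
      write_results(kx, file.path(out_dir, paste0("kinases_", site, ".tsv")))
      summary$psop[[site]]$n_kinases <- nrow(kx)
    }
    if (!is.null(ppi)) {
      ix <- crossref_interactors(res, ppi)
      write_results(ix,
                    file.path(out_dir, paste0("interactors_", site, ".tsv")))
      summary$psop[[site]]$n_interactors <- nrow(ix)
    }
    if (!is.null(processes)) {
      px <- group_by_process(res, processes)
      write_results(px,
                    file.path(out_dir, paste0("processes_", site, ".tsv")))
      summary$psop[[site]]$n_process_links <- nrow(px)
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Demo synthetic configuration
#'
#' A corpus emulating the structure of the real meta-analysis at
#' demonstration scale: 5 studies contributing 12 experimental conditions
#' each, a CAV1-like target protein with two highly detected sites (Y14,
#' S37) plus lower-frequency sites (S9, Y25), an intra-protein coordinated
#' module (S37-S9), and planted partner sites on kinase/interactor genes so
#' the cross-referencing stage has true positives to find.
#'
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
demo_synthetic_config <- function(seed = 42L) {
  synthetic_config(
    n_studies = 5L,
    conditions_per_study = c(12L, 12L),
    n_proteins = 40L,
    sites_per_protein = c(1L, 3L),
    base_detect_prob = 0.15,
    predominant_sites = tibble::tibble(
      token = c("CAV1_Y14", "CAV1_S37", "CAV1_S9", "CAV1_Y25", "CAV1_Y6",
                "SRC_S17", "ERBB2_Y877", "ERBB3_Y1328", "LYN_Y32",
                "TEC_Y519", "ABL2_Y515", "MET_Y1234", "EPHA2_Y772",
                "CAVIN1_Y308", "VCL_S272", "SNAP23_S110", "CSNK1E_S389",
                "GRK5_S484"),
      detect_prob = c(0.6, 0.6, 0.25, 0.15, 0.1,
                      rep(0.15, 13))),
    planted_pairs = tibble::tibble(
      site_a = c("CAV1_S37", "CAV1_Y14",
                 "CAV1_Y14", "CAV1_Y14", "CAV1_Y14", "CAV1_Y14",
                 "CAV1_Y14", "CAV1_Y14", "CAV1_Y14", "CAV1_Y14",
                 "CAV1_Y14", "CAV1_S37", "CAV1_S37"),
      site_b = c("CAV1_S9", "CAV1_Y25",
                 "SRC_S17", "ERBB2_Y877", "ERBB3_Y1328", "LYN_Y32",
                 "TEC_Y519", "ABL2_Y515", "MET_Y1234", "EPHA2_Y772",
                 "CAVIN1_Y308", "CSNK1E_S389", "GRK5_S484"),
      rho = c(0.9, 0.75, rep(0.95, 9), 0.95, 0.95),
      co_detect_prob = c(0.3, 0.3, rep(0.6, 9), 0.6, 0.6)),
    seed = seed
  )
}
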