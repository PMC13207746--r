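# Shared fixture builders. All corpora are constructed in code.

extdata_path <- function(...) {
  system.file("extdata", ..., package = "phoscoreg", mustWork = TRUE)
}

demo_corpus_harmonized <- function(cfg = filter_config()) {
  co <- read_corpus(extdata_path("demo_corpus"), cfg)
  harmonize(
    co,
    readr::read_tsv(extdata_path("demo_gene_map.tsv"), col_types = "cc",
                    progress = FALSE),
    readr::read_tsv(extdata_path("demo_accession_map.tsv"), col_types = "cc",
                    progress = FALSE))
}

# minimal hand-built corpus: calls are set directly through fold changes and
# p-values chosen on the right side of the thresholds
tiny_corpus <- function(calls1, calls2, gene1 = "AAA", gene2 = "BBB",
                        extra_datasets = 0L) {
  n <- max(length(calls1), length(calls2)) + extra_datasets
  metas <- tibble::tibble(
    dataset_id = sprintf("D%02d", seq_len(n)),
    pmid = sprintf("PM%02d", seq_len(n)),
    condition_code = sprintf("C%02d", seq_len(n)),
    dataset_type = "differential",
    enrichment = "STY")
  mk <- function(calls, gene, residue, position) {
    keep <- which(calls %in% c("U", "D"))
    tibble::tibble(
      dataset_id = sprintf("D%02d", keep),
      gene = gene, accession = paste0("ACC_", gene),
      residue = residue, position = position,
      fold_change = ifelse(calls[keep] == "U", 2.0, 0.5),
      p_value = 0.01)
  }
  differential <- dplyr::bind_rows(mk(calls1, gene1, "S", 10L),
                                   mk(calls2, gene2, "Y", 20L))
  profiling <- tibble::tibble(
    dataset_id = character(), gene = character(), accession = character(),
    residue = character(), position = integer(), loc_prob = numeric(),
    ascore = numeric())
  phos_corpus(metas, profiling, differential)
}

# the frozen planted-recovery study design: 5 studies x 12 conditions,
# a predominant anchor site and 20 planted positive partners
recovery_config <- function(seed, rho = 0.95, co_detect = 0.6,
                            n_partners = 20L) {
  partners <- sprintf("KIN%02d_S%d", seq_len(n_partners),
                      10L * seq_len(n_partners))
  synthetic_config(
    n_studies = 5L, conditions_per_study = c(12L, 12L),
    n_proteins = 220L, sites_per_protein = c(2L, 2L),
    base_detect_prob = 0.15,
    predominant_sites = tibble::tibble(
      token = c("TARG_Y14", partners),
      detect_prob = c(0.7, rep(0.15, n_partners))),
    planted_pairs = tibble::tibble(
      site_a = "TARG_Y14", site_b = partners,
      rho = rho, co_detect_prob = co_detect),
    seed = seed)
}
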