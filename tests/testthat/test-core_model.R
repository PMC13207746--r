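test_that("site tokens parse and round-trip through the canonical form", {
  parsed <- parse_site_token(c("CAV1_Y14", "CAV1_S37", "cav1_t6", "A_B1_S5"))
  expect_equal(parsed$gene, c("CAV1", "CAV1", "CAV1", "A_B1"))
  expect_equal(parsed$residue, c("Y", "S", "T", "S"))
  expect_equal(parsed$position, c(14L, 37L, 6L, 5L))
  tokens <- c("CAV1_Y14", "CAV1_S37", "MAPK1_T185")
  expect_identical(format_site_token(parse_site_token(tokens)), tokens)
})

test_that("malformed site tokens are rejected with the offending token named", {
  expect_error(parse_site_token("CAV1_X9"), "CAV1_X9")
  expect_error(parse_site_token("CAV1Y14"), "malformed")
  expect_error(parse_site_token("CAV1_Y"), "malformed")
  expect_error(parse_site_token(""), "nonempty")
  expect_error(format_site_token("CAV1", "B", 14), "S, T, Y")
  expect_error(format_site_token("CAV1", "Y", 0), ">= 1")
})

test_that("Class I rule honours both score routes and their boundaries", {
  expect_true(is_class1(0.80, NA))
  expect_true(is_class1(NA, 14))
  expect_false(is_class1(0.50, 10))
  # boundaries: localization probability inclusive, A-score strict
  expect_true(is_class1(0.75, NA))
  expect_false(is_class1(NA, 13))
  expect_false(is_class1(0.7499, 13))
  expect_true(is_class1(0.74, 13.001))
  expect_error(is_class1(NA, NA), "localization probability or an A-score")
  expect_error(is_class1(1.2, NA), "\\[0, 1\\]")
})

test_that("differential calling partitions the input space", {
  expect_equal(call_regulation(1.3, 0.01), "U")
  expect_equal(call_regulation(0.76, 0.04), "D")
  expect_equal(call_regulation(1.0, 0.001), "none")
  expect_equal(call_regulation(2.0, 0.20), "none")
  # p boundary is strict
  expect_equal(call_regulation(2.0, 0.05), "none")
  expect_error(call_regulation(-1, 0.01), "positive")
  # property: exactly one label for any valid input
  set.seed(11)
  fc <- exp(stats::runif(500, -2, 2))
  p <- stats::runif(500)
  calls <- call_regulation(fc, p)
  expect_true(all(calls %in% c("U", "D", "none")))
  cfg <- filter_config()
  manual <- ifelse(p < cfg$p_threshold & fc >= cfg$up_threshold, "U",
            ifelse(p < cfg$p_threshold & fc <= cfg$down_threshold, "D",
                   "none"))
  expect_identical(calls, manual)
})

test_that("filter_config validates its thresholds", {
  expect_error(filter_config(up_threshold = 0.9), "up_threshold")
  expect_error(filter_config(p_threshold = -0.1), "positive")
  cfg <- filter_config(min_pmids = 2)
  expect_identical(cfg$min_pmids, 2L)
})

test_that("corpus reading validates schemas and collapses duplicates", {
  co <- read_corpus(extdata_path("demo_corpus"))
  expect_s3_class(co, "phos_corpus")
  expect_equal(nrow(co$metas), 8L)
  # duplicate differential rows in one dataset are unique per (dataset, site)
  expect_false(any(duplicated(
    co$differential[, c("dataset_id", "token")])))
  expect_false(any(duplicated(
    co$profiling[, c("dataset_id", "token")])))
  # missing column is a named schema error
  tmp <- withr::local_tempdir()
  file.copy(list.files(extdata_path("demo_corpus"), full.names = TRUE), tmp)
  ds <- readr::read_tsv(file.path(tmp, "datasets.tsv"), col_types = readr::cols())
  readr::write_tsv(ds[, -2], file.path(tmp, "datasets.tsv"))
  expect_error(suppressWarnings(read_corpus(tmp)), "datasets.tsv.*pmid")
})

test_that("a corpus round-trips through write_corpus/read_corpus", {
  co <- demo_corpus_harmonized()
  tmp <- withr::local_tempdir()
  write_corpus(co, tmp)
  back <- read_corpus(tmp)
  sort_by_key <- function(df) df[order(df$dataset_id, df$token), ]
  expect_equal(sort_by_key(back$profiling), sort_by_key(co$profiling),
               ignore_attr = TRUE)
  expect_equal(sort_by_key(back$differential), sort_by_key(co$differential),
               ignore_attr = TRUE)
  expect_equal(back$metas[order(back$metas$dataset_id), ],
               co$metas[order(co$metas$dataset_id), ], ignore_attr = TRUE)
})

test_that("harmonization re-keys aliases and counts dropped records", {
  co <- read_corpus(extdata_path("demo_corpus"))
  # before: VIP21 is a distinct gene
  expect_true("VIP21" %in% co$profiling$gene)
  h <- demo_corpus_harmonized()
  expect_false("VIP21" %in% h$profiling$gene)
  expect_false("VIP21" %in% h$differential$gene)
  rep <- harmonization_report(h)
  # one differential record (gene UNKNOWNX) is unmappable
  expect_equal(rep$dropped_unmapped_gene[rep$table == "differential"], 1L)
  expect_equal(rep$dropped_unmapped_gene[rep$table == "profiling"], 0L)
  # every surviving record carries a canonical accession
  expect_false(anyNA(h$differential$accession))
  expect_error(harmonize(co, tibble::tibble(alias = character(),
                                            symbol = character()),
                         tibble::tibble(symbol = "A", accession = "B")),
               "nonempty")
})

test_that("identity harmonization leaves a canonical corpus unchanged", {
  h <- demo_corpus_harmonized()
  genes <- unique(c(h$profiling$gene, h$differential$gene))
  id_map <- tibble::tibble(alias = genes, symbol = genes)
  acc <- dplyr::distinct(dplyr::bind_rows(
    h$profiling[, c("gene", "accession")],
    h$differential[, c("gene", "accession")]))
  names(acc) <- c("symbol", "accession")
  h2 <- harmonize(h, id_map, acc)
  expect_equal(h2$differential, h$differential, ignore_attr = TRUE)
  expect_equal(h2$profiling, h$profiling, ignore_attr = TRUE)
})

test_that("conflicting duplicate calls resolve by smaller p, ties flagged", {
  metas <- tibble::tibble(dataset_id = "D1", pmid = "P", condition_code = "C",
                          dataset_type = "differential", enrichment = "STY")
  prof <- tibble::tibble(dataset_id = character(), gene = character(),
                         accession = character(), residue = character(),
                         position = integer(), loc_prob = numeric(),
                         ascore = numeric())
  mkdiff <- function(fc, p) tibble::tibble(
    dataset_id = "D1", gene = "G", accession = "A", residue = "S",
    position = 5L, fold_change = fc, p_value = p)
  # U (p 0.01) beats D (p 0.03)
  co <- phos_corpus(metas, prof, mkdiff(c(2.0, 0.5), c(0.01, 0.03)))
  expect_equal(co$differential$call, "U")
  expect_equal(co$differential$fold_change, 2.0)
  # exact tie -> conflict, excluded from co-regulation counting
  co2 <- phos_corpus(metas, prof, mkdiff(c(2.0, 0.5), c(0.01, 0.01)))
  expect_equal(co2$differential$call, "conflict")
  # agreeing duplicates keep the extreme fold change
  co3 <- phos_corpus(metas, prof, mkdiff(c(1.5, 3.0), c(0.01, 0.02)))
  expect_equal(co3$differential$fold_change, 3.0)
})

test_that("key = value configuration files parse into a filter_config", {
  tmp <- withr::local_tempfile(lines = c(
    "# thresholds", "up_threshold = 1.5", "p_threshold = 0.01",
    "protein = CAV1"))
  conf <- read_config(tmp)
  expect_equal(conf$filters$up_threshold, 1.5)
  expect_equal(conf$filters$p_threshold, 0.01)
  expect_equal(conf$filters$down_threshold, 0.76)  # default retained
  expect_equal(conf$options$protein, "CAV1")
})
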