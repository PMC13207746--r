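test_that("demo-corpus site frequencies match hand-derived counts", {
  h <- demo_corpus_harmonized()
  f <- site_frequencies(h, "CAV1")
  y14 <- f[f$token == "CAV1_Y14", ]
  s37 <- f[f$token == "CAV1_S37", ]
  # Y14: profiling in P01-P04 (P04 loc_prob 0.75 is Class I);
  # differential called in D01 (U), D02 (D), D04 (U); D03 is sub-threshold
  expect_equal(y14$profiling_count, 4L)
  expect_equal(y14$differential_count, 3L)
  expect_equal(y14$up_count, 2L)
  expect_equal(y14$down_count, 1L)
  expect_equal(y14$study_count, 3L)
  # S37: P01 (alias row merges with A-score row), P02; P04 fails Class I
  # (loc 0.74, A-score exactly 13); differential D03 (U), D04 (D)
  expect_equal(s37$profiling_count, 2L)
  expect_equal(s37$differential_count, 2L)
  expect_equal(s37$study_count, 3L)
  expect_equal(f$up_count + f$down_count, f$differential_count)
})

test_that("frequencies are invariant to record row order", {
  h <- demo_corpus_harmonized()
  shuffled <- h
  set.seed(4)
  shuffled$profiling <- shuffled$profiling[sample(nrow(shuffled$profiling)), ]
  shuffled$differential <-
    shuffled$differential[sample(nrow(shuffled$differential)), ]
  expect_equal(site_frequencies(shuffled, "CAV1"),
               site_frequencies(h, "CAV1"))
})

test_that("profiling count conservation holds on a synthetic corpus", {
  sim <- generate_corpus(recovery_config(seed = 8L, n_partners = 2L))
  co <- sim$corpus
  genes <- unique(co$profiling$gene)
  total <- sum(vapply(genes, function(g) {
    sum(site_frequencies(co, g)$profiling_count)
  }, numeric(1)))
  pairs <- dplyr::distinct(co$profiling, .data$token, .data$dataset_id)
  expect_equal(total, nrow(pairs))
})

test_that("ranking orders by combined frequency and flags predominance", {
  h <- demo_corpus_harmonized()
  ranked <- rank_predominant(site_frequencies(h, "CAV1"))
  expect_equal(ranked$token[1], "CAV1_Y14")  # 4 + 3 beats 2 + 2
  expect_true(all(diff(ranked$total_count) <= 0))
  # both demo sites are seen in both dataset types across >= 3 studies
  expect_setequal(ranked$token[ranked$predominant],
                  c("CAV1_Y14", "CAV1_S37"))
  # a site absent from one dataset type is never predominant
  f <- site_frequencies(h, "SRC")
  r <- rank_predominant(f)
  expect_false(r$predominant[r$token == "SRC_Y419"])  # profiling only
  expect_error(rank_predominant(f[0, ]), "empty")
})

test_that("total-count ties break by differential frequency then position", {
  freqs <- tibble::tibble(
    gene = "G", residue = c("S", "S", "S"), position = c(30L, 10L, 20L),
    token = c("G_S30", "G_S10", "G_S20"),
    profiling_count = c(5L, 3L, 4L), differential_count = c(1L, 3L, 2L),
    up_count = c(1L, 3L, 2L), down_count = 0L, study_count = 3L)
  ranked <- rank_predominant(freqs)
  expect_equal(ranked$token, c("G_S10", "G_S20", "G_S30"))
})

test_that("a higher-detection site outranks a lower one on synthetic data", {
  cfg <- synthetic_config(
    n_studies = 5L, conditions_per_study = 100L, n_proteins = 0L,
    base_detect_prob = 0,
    predominant_sites = tibble::tibble(token = c("TT_S5", "TT_S9"),
                                       detect_prob = c(0.9, 0.1)),
    seed = 13L)
  sim <- generate_corpus(cfg)
  ranked <- rank_predominant(site_frequencies(sim$corpus, "TT"))
  expect_equal(ranked$token[1], "TT_S5")
  expect_true(ranked$predominant[1])
})

test_that("unknown protein yields an empty table with a warning", {
  h <- demo_corpus_harmonized()
  expect_warning(f <- site_frequencies(h, "NOPE"), "NOPE")
  expect_equal(nrow(f), 0L)
})

test_that("lollipop export emits negative down heights and domain labels", {
  h <- demo_corpus_harmonized()
  f <- site_frequencies(h, "CAV1")
  domains <- tibble::tibble(domain = c("scaffolding", "transmembrane"),
                            start = c(82L, 102L), end = c(101L, 134L))
  tab <- export_lollipop_table(f, domains)
  expect_equal(tab$down_height, -f$down_count)
  expect_true(all(is.na(tab$domain)))  # Y14/S37 lie outside both domains
  tab2 <- export_lollipop_table(
    tibble::tibble(token = "X_S90", position = 90L, profiling_count = 1L,
                   up_count = 0L, down_count = 0L), domains)
  expect_equal(tab2$domain, "scaffolding")
  expect_error(export_lollipop_table(f, tibble::tibble(
    domain = "bad", start = 10L, end = 5L)), "start <= end")
})
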