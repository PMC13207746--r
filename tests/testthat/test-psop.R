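test_that("pattern codes put the predominant site's status first", {
  expect_equal(classify_pattern("U", "U"), "UU")
  expect_equal(classify_pattern("D", "U"), "DU")
  expect_equal(classify_pattern("U", "D"), "UD")
  expect_equal(classify_pattern("D", "D"), "DD")
  # reversing the pair order letter-swaps the code
  x <- c("U", "D", "U"); y <- c("D", "D", "U")
  swapped <- classify_pattern(y, x)
  expect_identical(substr(swapped, 1, 1), substr(classify_pattern(x, y), 2, 2))
  expect_error(classify_pattern("none", "U"), "U and D")
})

test_that("contingency cells follow the condition-level definitions", {
  # 10 differential datasets: 4 neither, 3 exactly-one, 1 discordant,
  # 2 concordant
  co <- tiny_corpus(
    calls1 = c("U",    "U", "D", "U",    "U",    "none", "none", rep("none", 3)),
    calls2 = c("none", "U", "D", "D",    "none", "D",    "none", rep("none", 3)))
  tab <- build_contingency(co, "AAA_S10", "BBB_Y20")
  expect_equal(unlist(tab[c("a", "b", "c", "d")], use.names = FALSE),
               c(4L, 3L, 1L, 2L))
  expect_equal(tab$n, 10L)
  expect_error(build_contingency(co, "AAA_S10", "AAA_S10"),
               "different proteins")
})

test_that("a never-co-detected pair has an empty co-called block", {
  co <- tiny_corpus(calls1 = c("U", "U", "none", "none"),
                    calls2 = c("none", "none", "D", "none"))
  tab <- build_contingency(co, "AAA_S10", "BBB_Y20")
  expect_equal(tab$c + tab$d, 0L)
  expect_equal(tab$a + tab$b, tab$n)
})

test_that("the one-sided exact test matches the enumeration oracle", {
  # oracle-first frozen cases (values computed by fet_oracle)
  expect_equal(fisher_one_sided(8, 2, 2, 8, direction = "positive"),
               fet_oracle(8, 2, 2, 8, "positive"), tolerance = 1e-14)
  # hand enumeration: margins (10,10)x(10,10), tail k=8..10 gives
  # (45*45 + 10*10 + 1)/C(20,10) = 2126/184756
  expect_equal(fisher_one_sided(8, 2, 2, 8, direction = "positive"),
               2126 / 184756, tolerance = 1e-12)
  # degenerate family: no co-called conditions -> p = 1
  expect_equal(fisher_one_sided(5, 3, 0, 0, direction = "positive"), 1)
  expect_equal(fisher_one_sided(5, 3, 0, 0, direction = "negative"), 1)
  # random spot checks in both directions
  set.seed(99)
  for (i in 1:200) {
    cells <- stats::rpois(4, 4)
    for (dir in c("positive", "negative")) {
      expect_equal(
        fisher_one_sided(cells[1], cells[2], cells[3], cells[4], dir),
        fet_oracle(cells[1], cells[2], cells[3], cells[4], dir),
        tolerance = 1e-12)
    }
  }
  expect_error(fisher_one_sided(-1, 1, 1, 1), "nonnegative")
})

test_that("the exact test agrees with the standard conditional test", {
  # stats::fisher.test on [[a,b],[c,d]] with alternative 'greater' is the
  # same conditional family with extremeness toward large a (equivalently d)
  set.seed(7)
  for (i in 1:50) {
    cells <- stats::rpois(4, 5)
    m <- matrix(cells, 2, byrow = TRUE)
    expect_equal(
      fisher_one_sided(cells[1], cells[2], cells[3], cells[4], "positive"),
      stats::fisher.test(m, alternative = "greater")$p.value,
      tolerance = 1e-9)
    expect_equal(
      fisher_one_sided(cells[1], cells[2], cells[3], cells[4], "negative"),
      stats::fisher.test(m, alternative = "less")$p.value,
      tolerance = 1e-9)
  }
})

test_that("p is non-increasing in d for fixed a, b and fixed c + d", {
  for (a in c(2, 5)) for (b in c(3, 8)) for (tot in c(6, 11)) {
    p <- fisher_one_sided(rep(a, tot + 1), b, tot:0, 0:tot,
                          direction = "positive")
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("screen results respect conservation and the filter contract", {
  sim <- generate_corpus(recovery_config(seed = 23L, n_partners = 5L))
  res <- psop_screen(sim$corpus, "TARG_Y14")
  expect_true(all(res$coreg_freq > 0))
  # c + d equals the co-called tally for every screened pair
  for (k in sample(nrow(res), 10)) {
    pc <- count_patterns(sim$corpus, "TARG_Y14", res$site[k])
    expect_equal(res$c[k] + res$d[k], pc$n_both)
    expect_equal(res$nUU[k], pc$nUU)
  }
  # contingency rows always total the corpus differential dataset count
  expect_true(all(res$a + res$b + res$c + res$d ==
                    sum(sim$corpus$metas$dataset_type == "differential")))
  cfg <- filter_config()
  expect_identical(res$passes,
                   res$fet_p < cfg$fet_alpha &
                     res$freq_ratio >= cfg$freq_ratio_min &
                     res$pmid_count >= cfg$min_pmids &
                     res$code_count >= cfg$min_codes)
  # category frequency picks the matching cell
  expect_true(all(res$coreg_freq[res$category == "UUDD"] ==
                    res$d[res$category == "UUDD"]))
  expect_true(all(res$coreg_freq[res$category == "UDDU"] ==
                    res$c[res$category == "UDDU"]))
})

test_that("support filters veto otherwise significant pairs", {
  # strong concordance concentrated in a single study/condition pair
  metas <- tibble::tibble(
    dataset_id = sprintf("D%02d", 1:20),
    pmid = c(rep("PM1", 10), rep("PM2", 10)),
    condition_code = c(rep("C1", 10), rep("C2", 10)),
    dataset_type = "differential", enrichment = "STY")
  prof <- tibble::tibble(dataset_id = character(), gene = character(),
                         accession = character(), residue = character(),
                         position = integer(), loc_prob = numeric(),
                         ascore = numeric())
  mk <- function(gene, pos, sets) tibble::tibble(
    dataset_id = sprintf("D%02d", sets), gene = gene,
    accession = paste0("A_", gene), residue = "S", position = pos,
    fold_change = 2, p_value = 0.01)
  diff <- dplyr::bind_rows(mk("AAA", 10L, 1:10), mk("BBB", 20L, 1:10))
  co <- phos_corpus(metas, prof, diff)
  res <- psop_screen(co, "AAA_S10")
  row <- res[res$site == "BBB_S20" & res$category == "UUDD", ]
  expect_lt(row$fet_p, 0.05)
  expect_gte(row$freq_ratio, 0.10)
  expect_equal(row$pmid_count, 1L)   # only one study supports it
  expect_false(row$passes)
})

test_that("screening an uncalled site warns and returns nothing", {
  co <- tiny_corpus(calls1 = c("U", "D"), calls2 = c("U", "U"))
  expect_warning(res <- psop_screen(co, "ZZZ_S1"), "no differential calls")
  expect_equal(nrow(res), 0L)
})
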