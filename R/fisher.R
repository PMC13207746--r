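#' Condition-level contingency table for a site pair
#'
#' Builds the 2x2 contingency table over all differential datasets
#' (experimental conditions) in the corpus for one predominant site of the
#' target protein and one phosphosite of another protein:
#' \describe{
#'   \item{a}{conditions where neither site was called differentially
#'     regulated,}
#'   \item{b}{conditions where exactly one of the two was called, whichever
#'     direction,}
#'   \item{c}{conditions with discordant calls (one up, one down) —
#'     negative co-regulation,}
#'   \item{d}{conditions with concordant calls (both up or both down) —
#'     positive co-regulation.}
#' }
#' `a + b + c + d` equals the total number of differential datasets. Only
#' `U`/`D` calls count as detection here; sub-threshold (`none`) and
#' conflicting records do not.
#'
#' @param corpus A harmonized [phos_corpus()].
#' @param predominant_site,other_site Canonical site tokens on different
#'   proteins.
#' @return One-row tibble with columns `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(corpus, predominant_site, other_site) {
  stopifnot(inherits(corpus, "phos_corpus"))
  g1 <- parse_site_token(predominant_site)$gene
  g2 <- parse_site_token(other_site)$gene
  if (identical(g1, g2)) {
    stop("contingency tables are defined for sites on different proteins; ",
         "use count_patterns()/cooccurrence_matrix() within a protein",
         call. = FALSE)
  }
  n_total <- sum(corpus$metas$dataset_type == "differential")
  calls <- called_records(corpus)
  ds1 <- calls$dataset_id[calls$token == predominant_site]
  c2 <- calls[calls$token == other_site, c("dataset_id", "call")]
  c1 <- calls[calls$token == predominant_site, c("dataset_id", "call")]
  joint <- dplyr::inner_join(c1, c2, by = "dataset_id", suffix = c("1", "2"))
  d <- sum(joint$call1 == joint$call2)
  cc <- nrow(joint) - d
  b <- (length(ds1) - nrow(joint)) + (nrow(c2) - nrow(joint))
  a <- n_total - b - cc - d
  tibble::tibble(a = a, b = b, c = cc, d = d, n = n_total)
}

#' One-sided Fisher's exact test on the co-regulation contingency
#'
#' Exact one-sided p-value for association in the 2x2 table
#' `[[a, b], [c, d]]` of [build_contingency()], conditioning on both margins
#' (`a + b`, `c + d`; `a + c`, `b + d`). Under the null the free cell follows
#' the hypergeometric distribution; `direction = "positive"` sums the
#' probabilities of all tables at least as extreme toward large `d`
#' (concordance), `direction = "negative"` toward large `c` (discordance).
#' The observed table is always included, so the p-value lies in (0, 1].
#'
#' Vectorized over tables.
#'
#' @param a,b,c,d Nonnegative integer cell counts (vectors recycled to a
#'   common length), or `a` may be a data frame carrying columns
#'   `a`, `b`, `c`, `d`.
#' @param direction `"positive"` (extreme = large `d`) or `"negative"`
#'   (extreme = large `c`).
#' @return Numeric vector of exact one-sided p-values.
#' @examples
#' fisher_one_sided(8, 2, 2, 8, direction = "positive")
#' @export
fisher_one_sided <- function(a, b = NULL, c = NULL, d = NULL,
                             direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (is.data.frame(a) || is.list(a)) {
    tab <- a
    a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  cells <- cbind(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency cells must be nonnegative integers", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    fet_tail(a[i], b[i], c[i], d[i], direction)
  }, numeric(1))
}

# Exact tail sum over the conditional hypergeometric family. With both
# margins fixed the table has one free cell; parameterize by k = a-cell.
# Then d' = (c+d) - (a+c) + k increases with k, c' decreases with k, so the
# "positive" tail is k >= a and the "negative" tail is k <= a.
fet_tail <- function(a, b, c, d, direction) {
  r1 <- a + b; r2 <- c + d
  c1 <- a + c
  nn <- r1 + r2
  kmin <- max(0, c1 - r2)
  kmax <- min(r1, c1)
  k <- if (direction == "positive") a:kmax else kmin:a
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(nn, c1)
  min(1, sum(exp(logp)))
}
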