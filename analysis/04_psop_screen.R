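#!/usr/bin/env Rscript
# Stage 4: screen phosphosites of other proteins (PsOPs) for significant
# co-differential regulation with each predominant CAV1 site. Every pair is
# evaluated on the condition-level contingency (neither / one / discordant /
# concordant) with a one-sided exact test, then filtered on frequency ratio
# >= 10%, p < 0.05, >= 3 PMIDs and >= 3 condition codes.

suppressMessages(library(phoscoreg))

corpus <- read_corpus("results/corpus")
freqs <- rank_predominant(site_frequencies(corpus, "CAV1"))
top_sites <- freqs$token[freqs$rank <= 2]

for (site in top_sites) {
  res <- psop_screen(corpus, site)
  write_results(res, sprintf("results/psop_%s.tsv", site))
  cat(sprintf("%s: screened %d (site, category) pairs; %d pass UUDD, %d pass UDDU\n",
              site, nrow(res),
              sum(res$passes & res$category == "UUDD"),
              sum(res$passes & res$category == "UDDU")))
  hits <- res[res$passes & res$category == "UUDD", ]
  if (nrow(hits)) {
    cat("  top positively co-regulated sites:\n")
    print(as.data.frame(utils::head(
      hits[, c("site", "d", "c", "fet_p", "freq_ratio", "pmid_count")], 8)))
  }
}
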