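#!/usr/bin/env Rscript
# Stage 2: rank CAV1 phosphosites by detection frequency and designate the
# predominant sites. Also exports the lollipop plot table with the CAV1
# scaffolding (82-101) and transmembrane (102-134) domain annotations.

suppressMessages(library(phoscoreg))

corpus <- read_corpus("results/corpus")
freqs <- rank_predominant(site_frequencies(corpus, "CAV1"))
write_results(freqs, "results/site_frequencies.tsv")

domains <- tibble::tibble(domain = c("scaffolding", "transmembrane"),
                          start = c(82L, 102L), end = c(101L, 134L))
write_results(export_lollipop_table(freqs, domains),
              "results/lollipop_table.tsv")

cat("CAV1 site ranking (profiling + differential detections):\n")
print(as.data.frame(freqs[, c("token", "profiling_count",
                              "differential_count", "study_count",
                              "rank", "predominant")]))
cat(sprintf("\ntop-ranked sites: %s\n",
            paste(freqs$token[freqs$rank <= 2], collapse = ", ")))
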