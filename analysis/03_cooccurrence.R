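#!/usr/bin/env Rscript
# Stage 3: intra-protein co-occurrence of CAV1 phosphosite pairs. For every
# pair of Class I sites, tallies the four joint regulation patterns over the
# conditions where both sites are called, and reports the positive and
# negative co-regulation ratios (concordant/discordant and its reciprocal).

suppressMessages(library(phoscoreg))

corpus <- read_corpus("results/corpus")
m <- cooccurrence_matrix(corpus, "CAV1")
write_results(m, "results/cooccurrence.tsv")

cat("CAV1 phosphosite pair co-occurrence:\n")
print(as.data.frame(m))
strongest <- m[which.max(ifelse(is.finite(m$positive_ratio),
                                m$positive_ratio, -Inf)), ]
cat(sprintf("\nstrongest positive co-regulation: %s - %s (ratio %.2f over %d co-called conditions)\n",
            strongest$site1, strongest$site2, strongest$positive_ratio,
            strongest$n_both))
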