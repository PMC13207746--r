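#!/usr/bin/env Rscript
# Stage 5: cross-reference the screen hits against the demo curation tables:
# upstream kinases (validated/predicted), high-confidence interaction
# partners (>= 2 source databases), and biological-process grouping.

suppressMessages(library(phoscoreg))

extdata <- function(...) system.file("extdata", ..., package = "phoscoreg",
                                     mustWork = TRUE)
kinases <- read_kinase_table(extdata("demo_kinases.tsv"))
ppi <- read_ppi_table(extdata("demo_ppi.tsv"))
processes <- read_process_table(extdata("demo_processes.tsv"))

for (site in c("CAV1_Y14", "CAV1_S37")) {
  res <- readr::read_tsv(sprintf("results/psop_%s.tsv", site),
                         col_types = readr::cols(), progress = FALSE)
  kx <- crossref_kinases(res, kinases, site)
  ix <- crossref_interactors(res, ppi)
  px <- group_by_process(res, processes)
  write_results(kx, sprintf("results/kinases_%s.tsv", site))
  write_results(ix, sprintf("results/interactors_%s.tsv", site))
  write_results(px, sprintf("results/processes_%s.tsv", site))
  cat(sprintf("%s: %d co-regulated upstream kinases [%s]; %d high-confidence interactors [%s]\n",
              site, nrow(kx), paste(kx$kinase, collapse = ", "),
              nrow(ix), paste(ix$partner, collapse = ", ")))
}
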