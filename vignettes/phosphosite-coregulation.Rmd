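---
title: "Site-centric phosphosite co-regulation meta-analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-centric phosphosite co-regulation meta-analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscoreg)
```

## The problem

Individual phosphoproteomic studies rarely interrogate a specific
phosphosite deeply: mass-spectrometry detection is stochastic, enrichment
chemistries (IMAC, TiO2, antibody-based pY capture) bias which residues are
seen, and any one study covers a narrow slice of experimental conditions.
For a heavily modified scaffolding protein such as caveolin-1 (CAV1), the
functional meaning of each site (e.g. Y14 versus S37) is therefore best
read out of *many* studies at once. `phoscoreg` implements a site-centric
meta-analysis over curated result tables from such studies: it asks which
sites of a target protein are most consistently detected, which site pairs
within the protein are coordinately regulated, and which phosphosites of
*other* proteins (PsOPs) are co-differentially regulated with the target's
predominant sites — a correlational signal that nominates upstream kinases
and functionally coupled interaction partners without requiring site-directed
experiments.

The unit of analysis throughout is the *condition-level dataset*: one
biological or experimental condition reported in a study. A study (one
PMID) typically contributes several datasets. Profiling datasets are
qualitative lists of identified sites; differential datasets compare a
condition to its control and report per-site fold changes and p-values.

## Filtering and calling model

Two gates standardize the heterogeneous inputs:

* **Class I site confidence.** A site identification is retained when its
  localization probability is at least 0.75 (inclusive) or its A-score is
  strictly greater than 13. The strict A-score comparison follows the
  primary definition of the criterion; both cutoffs are fields of
  `filter_config()` and can be changed.
* **Differential calling.** A site in a differential dataset is called
  upregulated (`U`) when fold change $\ge$ 1.3 and $p < 0.05$,
  downregulated (`D`) when fold change $\le$ 0.76 and $p < 0.05$, and
  `none` otherwise. The fold-change boundaries are inclusive, the p-value
  boundary strict, and the three labels partition the input space.

Duplicate rows for the same site in the same dataset (distinct
phosphopeptides) are collapsed before analysis: profiling duplicates keep
the best localization evidence; differential duplicates that agree in
direction keep the most extreme fold change. A site reported both `U` and
`D` within one dataset resolves to the call with the smaller p-value; an
exact p-value tie is flagged as a conflict and the record is excluded from
all co-regulation counting. Frequency counts are per dataset, never per
peptide, which is why collapsing must precede counting.

Identifier harmonization maps gene aliases to canonical HGNC-style symbols
and symbols to UniProt-style accessions through user-supplied tables;
unmappable records are dropped and counted in a per-table report rather
than silently discarded. Positions are 1-based coordinates on the mapped
canonical accession; no isoform remapping is attempted.

## Predominant sites

For the target protein, each Class I site accumulates a profiling count
(datasets identifying it), a differential count (datasets calling it `U` or
`D`), and a study count (distinct PMIDs behind either). Sites are ranked by
profiling + differential count, with ties broken by differential count and
then position. A site is designated *predominant* when it is seen in both
dataset types and supported by at least three independent studies (the
`min_pmids` threshold). The combined rank key reflects the requirement that
predominant sites be consistently detected in both qualitative and
quantitative data; the three-study floor guards against single-laboratory
artifacts.

## Intra-protein co-occurrence

For two sites of the same protein, over the conditions where **both** carry
a call, the four joint patterns are tallied: $n_{UU}, n_{DD}$ (concordant)
and $n_{UD}, n_{DU}$ (discordant). The positive co-regulation ratio is

$$R^{+} = \frac{n_{UU} + n_{DD}}{n_{UD} + n_{DU}},$$

and the negative ratio is its reciprocal. When both are finite and nonzero
their product is exactly 1 — an identity the test suite asserts on
randomized corpora. A zero denominator under a nonzero numerator is
reported as `Inf` (infinite concordance or discordance), and a pair with no
co-called conditions as `NA`; the distinction matters because downstream
consumers must not confuse "never discordant" with "never observed".
Conditions where only one site is detected are deliberately ignored here —
they carry no information about the *joint* direction — but they do enter
the contingency table of the inter-protein screen below.

If the partner site's call copies the anchor's with probability $\rho$
whenever both are observed, then $n_{UU}+n_{DD} \sim
\mathrm{Bin}(n_{both}, \rho)$ and $R^{+}$ estimates $\rho/(1-\rho)$. The
test suite checks this calibration at $\rho \in \{0.5, 0.7, 0.9\}$ with
$n_{both} \ge 500$, using the delta-method standard error
$\sqrt{\rho(1-\rho)/n}\,/(1-\rho)^2$ and a 3-sigma band.

## The PsOP screen

For a predominant site and a phosphosite of a different protein, every
differential dataset falls in exactly one cell of a condition-level
contingency table:

| cell | conditions |
|------|------------|
| $a$  | neither site called |
| $b$  | exactly one of the two called, either direction |
| $c$  | discordant calls (negative co-regulation) |
| $d$  | concordant calls (positive co-regulation) |

with $a+b+c+d = n$, the total number of differential datasets. Only `U`/`D`
calls count as "detected" here: a sub-threshold record carries no
directional evidence, and treating it as detection would make cell $b$
depend on reporting practices that vary across studies.

Significance is assessed by a one-sided Fisher's exact test on
$[[a,b],[c,d]]$, conditioning on both margins, with extremeness measured on
the $d$ cell for the positive (UUDD) screen and on the $c$ cell for the
negative (UDDU) screen. With margins fixed the table has one free cell, so
the null distribution is hypergeometric; the implementation sums the exact
tail via `lchoose` and is validated against an exhaustive enumeration
oracle (plain factorial products over every table with the same margins)
for *all* tables with $n \le 50$ at $10^{-12}$ tolerance, and against
`stats::fisher.test` (whose `"greater"`/`"less"` alternatives coincide with
this family) on random tables. The margin-conditioning choice is the only
reading under which "one-sided" distinguishes the UUDD and UDDU screens;
it is a design decision, since the cell arrangement is not forced by the
contingency definitions themselves.

A screened pair becomes a high-confidence hit (`passes`) only if all four
filters hold:

1. frequency ratio: category frequency ($d$ or $c$) $\ge$ 10% of the
   predominant site's total differential count;
2. Fisher $p < 0.05$ (raw — no multiple-testing correction enters the
   decision, matching the screen's design; a Benjamini–Hochberg column is
   emitted for reference);
3. support from $\ge$ 3 distinct publications (PMID confidence), counted
   over the conditions contributing to the row's own category;
4. support from $\ge$ 3 distinct experimental-condition codes, counted the
   same way.

Both passing and failing rows are retained in the output so that filter
behavior is auditable.

## Cross-referencing

Curated kinase–substrate, protein–protein-interaction and
biological-process tables are consumed as plain TSVs (no live database
queries). A kinase is reported for a target site only when it annotates
that site *and* at least one of the kinase's own phosphosites passes the
screen — i.e. the kinase itself shows co-differential regulation with its
putative substrate site. Interaction partners require support from at least
two distinct source databases by default (`min_db_support = 2`), a reading
of "corroborated by cross-database support" that is configurable because
the evidence rule could also be read as one-database-plus-any-corroboration.
Process grouping is descriptive annotation joining, deliberately not an
over-representation or gene-set-enrichment analysis; unannotated passing
sites are kept in an explicit `unannotated` bucket rather than dropped.

## The synthetic corpus generator

Because the method's inputs are curated tables assembled from hundreds of
publications, verification needs corpora whose ground truth is known by
construction. `generate_corpus()` simulates:

* a configurable number of studies, each contributing a fixed cycle of
  experimental conditions; each condition yields one differential dataset
  and one mirrored profiling dataset (localization probabilities drawn
  above the Class I cutoff);
* per-site stochastic detection: every site is detected independently per
  condition with its detection probability; a detected differential record
  is assigned `U` or `D` with equal probability, a fold change drawn
  log-normally around the configured effect size and truncated at the
  calling threshold, and a p-value uniform below the calling cutoff — so
  every emitted record survives `call_regulation()` by construction
  (detection probability is thus the probability of appearing as a
  *called* record, which is the quantity all downstream counting sees);
* planted pairs: in each condition where the anchor site is detected, the
  partner is co-detected with probability `co_detect_prob` and its call
  copies the anchor's with probability $\rho$ (flips otherwise). The
  anchor's marginal detection is untouched, so one predominant site can
  anchor many pairs without its detection frequency being inflated — the
  property that makes the screen's null calibration meaningful when many
  partners share an anchor.

Everything is a deterministic function of the configuration and one seed;
generation is single-threaded and consumes one seeded stream sequentially.
`planted_truth()` restates the configuration as an evaluable truth table
with no randomness.

### What the generator does and does not emulate

It emulates multi-study structure, dataset-level detection stochasticity,
threshold-surviving effect sizes, and planted concordant/discordant
co-regulation. It does **not** emulate peptide-level effects (missed
cleavages, multiply phosphorylated peptides), enrichment-chemistry bias
between STY/ST/Y platforms, protein-abundance confounding, or
non-uniform p-value behavior of real differential tests. Passing the
planted-recovery tests therefore demonstrates that the pipeline's counting
and statistics are correct, not that the biological screen is robust to
every real-data artifact.

### Chosen study conditions

The validation corpus uses 5 studies x 12 conditions (60 differential
datasets), an anchor site detected at probability 0.7, twenty planted
positive partners at $\rho = 0.95$ with co-detection 0.6, and a background
detection probability of 0.15. The corpus shape and planted-pair settings
follow the validation design; the two detection rates are this package's
own choices: 0.7 corresponds to a strongly predominant site (in real
corpora even the most frequently perturbed sites of a well-studied protein
appear in roughly 30–60% of differential datasets, and an anchor near the
top of that range gives the screen a fair chance at 60 conditions), while
0.15 reflects that an ordinary phosphosite is seen in a small minority of
datasets — background rates far above that would describe a corpus in
which every site is predominant. Simulation sizes elsewhere (600
co-detected conditions for ratio calibration, 1000 conditions for binomial
detection checks) were chosen so that 3-sigma bands are tight enough to be
informative.

## Numerical and degenerate-input choices

* The exact-test tail is accumulated in log space (`lchoose`) and clamped
  to 1; the observed table is always included, so $p \in (0, 1]$, and a
  pair with no co-called conditions ($c = d = 0$) gives exactly $p = 1$.
* Ratio sentinels: `Inf` for zero denominators with signal, `NA` for
  no-data pairs, never an exception.
* Ranking ties break deterministically (differential count, then
  position), and every exported table has a stable row order, so repeated
  runs are byte-identical under a fixed seed.
* Empty inputs (unknown protein, empty kinase table, fewer than two sites)
  return empty typed tables with warnings rather than errors, because in a
  screening loop over many proteins a vacuous case is expected, not
  exceptional.

## Known limitations

* The contingency design mixes detection and direction: cell $b$ counts
  detection asymmetry while $c$ and $d$ count directional agreement. When
  the two sites have very different detection frequencies, the
  discordant-direction (UDDU) test can reject more often than its nominal
  level even for independent sites — visible in the demo corpus, where a
  highly detected anchor accrues a tail of spurious UDDU hits that survive
  the frequency filters. The package reports both categories faithfully;
  consumers should weight UDDU hits against this asymmetry (the
  reproducibility filters mitigate but do not remove it).
* Co-regulation is correlational. Nothing in the screen establishes
  causality, directionality, or physical interaction; the kinase and
  interactor cross-references intersect the screen with curated knowledge
  precisely because the statistic alone cannot.
* Protein-abundance confounding (coordinated changes in parent protein
  levels masquerading as site co-regulation) is not corrected; the
  required protein-level quantification is rarely available in curated
  result tables.
* No multiple-testing correction enters the pass/fail decision; the screen
  leans on the frequency, PMID and condition-code filters for error
  control, and the emitted `fet_bh` column lets users apply a stricter
  criterion.
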