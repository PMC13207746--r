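#' Configuration for the synthetic corpus generator
#'
#' Describes a multi-study phosphoproteomic corpus with known planted
#' structure. Each study contributes a number of experimental conditions; each
#' condition yields one differential dataset and one mirrored profiling
#' dataset. Every site is detected independently per condition with its
#' detection probability (`base_detect_prob`, overridable per site via
#' `predominant_sites`); a detected site is reported as up- or down-regulated
#' with equal probability, with fold change and p-value drawn so the call
#' survives the differential-calling thresholds. Planted pairs add
#' co-regulation: in every condition where the anchor site (`site_a`) is
#' detected, the partner (`site_b`) is co-detected with probability
#' `co_detect_prob`, and its call then copies the anchor's with probability
#' `rho` (concordant) or flips it with probability `1 - rho` (discordant).
#' The anchor's own detection is untouched, so one predominant site can
#' anchor many planted pairs without its detection frequency being inflated;
#' the partner may additionally be detected independently (with an
#' independent call) in conditions where the pair mechanism does not fire.
#'
#' The generic site universe is deterministic given the configuration (see
#' [synthetic_sites()]), so planted pairs can reference sites by token.
#'
#' @param n_studies Number of studies (distinct PMIDs).
#' @param conditions_per_study Length-2 integer range; study *i* contributes a
#'   number of conditions cycling through the range deterministically.
#' @param n_proteins Number of background proteins.
#' @param sites_per_protein Length-2 integer range of sites per protein
#'   (cycled deterministically).
#' @param base_detect_prob Per-condition detection probability of a background
#'   site.
#' @param predominant_sites Tibble with columns `token`, `detect_prob`:
#'   sites with elevated (or otherwise overridden) detection probability.
#'   Tokens absent from the generic universe are added as extra sites.
#' @param planted_pairs Tibble with columns `site_a` (anchor token), `site_b`
#'   (partner token), `rho` (concordance probability in \[0, 1\]) and
#'   `co_detect_prob` (partner co-detection probability given the anchor is
#'   detected).
#' @param effect_fc_up,effect_fc_down Location of the fold-change distribution
#'   for up/down calls; must lie beyond the calling thresholds.
#' @param fc_sdlog Log-scale spread of fold changes (truncated at the calling
#'   threshold so every emitted record survives calling).
#' @param seed Integer seed; the whole corpus is a deterministic function of
#'   the configuration and this seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_studies = 5L,
                             conditions_per_study = c(12L, 12L),
                             n_proteins = 50L,
                             sites_per_protein = c(1L, 3L),
                             base_detect_prob = 0.3,
                             predominant_sites = NULL,
                             planted_pairs = NULL,
                             effect_fc_up = 1.8,
                             effect_fc_down = 0.55,
                             fc_sdlog = 0.15,
                             seed = 42L) {
  if (length(conditions_per_study) == 1L) {
    conditions_per_study <- rep(conditions_per_study, 2L)
  }
  if (length(sites_per_protein) == 1L) {
    sites_per_protein <- rep(sites_per_protein, 2L)
  }
  cfg <- list(
    n_studies = as.integer(n_studies),
    conditions_per_study = as.integer(conditions_per_study),
    n_proteins = as.integer(n_proteins),
    sites_per_protein = as.integer(sites_per_protein),
    base_detect_prob = as.numeric(base_detect_prob),
    predominant_sites = if (is.null(predominant_sites)) {
      tibble::tibble(token = character(), detect_prob = numeric())
    } else tibble::as_tibble(predominant_sites),
    planted_pairs = if (is.null(planted_pairs)) {
      tibble::tibble(site_a = character(), site_b = character(),
                     rho = numeric(), co_detect_prob = numeric())
    } else tibble::as_tibble(planted_pairs),
    effect_fc_up = as.numeric(effect_fc_up),
    effect_fc_down = as.numeric(effect_fc_down),
    fc_sdlog = as.numeric(fc_sdlog),
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_studies >= 1L, cfg$n_proteins >= 0L,
            cfg$conditions_per_study[1] >= 1L,
            cfg$conditions_per_study[2] >= cfg$conditions_per_study[1])
  probs <- c(cfg$base_detect_prob, cfg$predominant_sites$detect_prob,
             cfg$planted_pairs$rho, cfg$planted_pairs$co_detect_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Deterministic site universe of a synthetic configuration
#'
#' Background protein *i* is named `PRO<i>` with accession `ACC<i>`; its sites
#' cycle residues S, T, Y at spaced positions. Sites declared in
#' `predominant_sites` or `planted_pairs` but absent from the background
#' universe are appended. The universe is a pure function of the
#' configuration (no randomness), so callers can reference sites by token.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble with columns `gene`, `accession`, `residue`, `position`,
#'   `token`, `detect_prob`.
#' @export
synthetic_sites <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lo <- cfg$sites_per_protein[1]; hi <- cfg$sites_per_protein[2]
  n_sites <- if (cfg$n_proteins > 0L) {
    lo + (seq_len(cfg$n_proteins) - 1L) %% (hi - lo + 1L)
  } else integer()
  gene <- rep(sprintf("PRO%03d", seq_len(cfg$n_proteins)), n_sites)
  accession <- rep(sprintf("ACC%05d", seq_len(cfg$n_proteins)), n_sites)
  j <- unlist(lapply(n_sites, seq_len), use.names = FALSE)
  sites <- tibble::tibble(
    gene = gene, accession = accession,
    residue = c("S", "T", "Y")[(j - 1L) %% 3L + 1L],
    position = 7L * j
  )
  sites <- add_site_token(sites)
  declared <- unique(c(cfg$predominant_sites$token,
                       cfg$planted_pairs$site_a, cfg$planted_pairs$site_b))
  extra <- setdiff(declared, sites$token)
  # planted-pair members must be declared somewhere; only predominant_sites
  # tokens may introduce brand-new sites
  unknown <- setdiff(c(cfg$planted_pairs$site_a, cfg$planted_pairs$site_b),
                     c(sites$token, cfg$predominant_sites$token))
  if (length(unknown)) {
    stop("planted pair references unknown site(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (length(extra)) {
    parsed <- parse_site_token(extra)
    parsed$accession <- paste0("ACC_", parsed$gene)
    parsed$token <- extra
    sites <- dplyr::bind_rows(
      sites, parsed[, c("gene", "accession", "residue", "position", "token")])
  }
  sites$detect_prob <- cfg$base_detect_prob
  idx <- match(cfg$predominant_sites$token, sites$token)
  sites$detect_prob[idx] <- cfg$predominant_sites$detect_prob
  sites
}

#' Ground truth of the planted structure
#'
#' Pure restatement of the configuration as an evaluable truth table: per
#' planted pair the expected co-regulation sign and expected positive
#' co-regulation ratio `rho / (1 - rho)`; per site the configured detection
#' probability. No randomness is involved.
#'
#' @param cfg A [synthetic_config()].
#' @return List with tibbles `pairs` (`site_a`, `site_b`, `rho`,
#'   `co_detect_prob`, `expected_sign`, `expected_positive_ratio`) and
#'   `sites` (`token`, `detect_prob`).
#' @export
planted_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  sites <- synthetic_sites(cfg)
  pairs <- cfg$planted_pairs
  pairs$expected_sign <- ifelse(pairs$rho > 0.5, "positive",
                                ifelse(pairs$rho < 0.5, "negative", "null"))
  pairs$expected_positive_ratio <- ifelse(pairs$rho < 1,
                                          pairs$rho / (1 - pairs$rho), Inf)
  list(pairs = pairs,
       sites = sites[, c("token", "detect_prob")])
}

#' Generate a synthetic corpus with planted co-regulation
#'
#' Simulates the full corpus described by a [synthetic_config()]: one
#' differential and one mirrored profiling dataset per experimental condition,
#' stochastic per-site detection, guaranteed-to-survive fold-change/p-value
#' pairs, and planted concordant/discordant site pairs. Deterministic given
#' the configuration seed.
#'
#' @param cfg A [synthetic_config()].
#' @param filters A [filter_config()] supplying the calling thresholds that
#'   generated records must survive.
#' @return List with elements `corpus` (a [phos_corpus()]) and `truth`
#'   (see [planted_truth()]).
#' @export
generate_corpus <- function(cfg, filters = filter_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$effect_fc_up < filters$up_threshold ||
      cfg$effect_fc_down > filters$down_threshold) {
    stop("effect fold changes must lie beyond the calling thresholds",
         call. = FALSE)
  }
  sites <- synthetic_sites(cfg)
  n_sites <- nrow(sites)

  lo <- cfg$conditions_per_study[1]; hi <- cfg$conditions_per_study[2]
  conds_per_study <- lo + (seq_len(cfg$n_studies) - 1L) %% (hi - lo + 1L)
  study <- rep(seq_len(cfg$n_studies), conds_per_study)
  n_cond <- length(study)
  cond_code <- sprintf("S%02dC%02d", study,
                       unlist(lapply(conds_per_study, seq_len)))
  pmid <- sprintf("PMID%04d", 1000L + study)

  metas <- tibble::tibble(
    dataset_id = c(sprintf("DS%04d_diff", seq_len(n_cond)),
                   sprintf("DS%04d_prof", seq_len(n_cond))),
    pmid = rep(pmid, 2L),
    condition_code = rep(cond_code, 2L),
    dataset_type = rep(c("differential", "profiling"), each = n_cond),
    enrichment = "STY"
  )

  withr::with_seed(cfg$seed, {
    # site x condition detection and (latent) call matrices
    det <- matrix(stats::runif(n_sites * n_cond) < sites$detect_prob,
                  nrow = n_sites)
    call <- matrix(ifelse(stats::runif(n_sites * n_cond) < 0.5, "U", "D"),
                   nrow = n_sites)
    # planted pairs: conditional on the anchor being detected, the partner is
    # co-detected with probability co_detect_prob and its call copies the
    # anchor's with probability rho (flips otherwise). The anchor's marginal
    # detection probability is untouched, so one site can anchor many pairs
    # without its detection frequency being inflated.
    if (nrow(cfg$planted_pairs)) {
      flip <- c(U = "D", D = "U")
      for (i in seq_len(nrow(cfg$planted_pairs))) {
        p <- cfg$planted_pairs[i, ]
        ia <- match(p$site_a, sites$token)
        ib <- match(p$site_b, sites$token)
        co <- (stats::runif(n_cond) < p$co_detect_prob) & det[ia, ]
        concord <- stats::runif(n_cond) < p$rho
        det[ib, co] <- TRUE
        call[ib, co] <- ifelse(concord[co], call[ia, co],
                               flip[call[ia, co]])
      }
    }
    hit <- which(det, arr.ind = TRUE)
    site_idx <- hit[, 1L]; cond_idx <- hit[, 2L]
    calls <- call[det]
    n_rec <- length(calls)

    # fold changes log-normal around the effect size, truncated at the
    # calling threshold; p-values uniform below the calling cutoff
    fc <- ifelse(
      calls == "U",
      pmax(cfg$effect_fc_up * exp(stats::rnorm(n_rec, 0, cfg$fc_sdlog)),
           filters$up_threshold),
      pmin(cfg$effect_fc_down * exp(stats::rnorm(n_rec, 0, cfg$fc_sdlog)),
           filters$down_threshold))
    pv <- stats::runif(n_rec, 0, filters$p_threshold)
    loc_prob <- stats::runif(n_rec, filters$loc_prob_min, 1)

    differential <- tibble::tibble(
      dataset_id = sprintf("DS%04d_diff", cond_idx),
      gene = sites$gene[site_idx],
      accession = sites$accession[site_idx],
      residue = sites$residue[site_idx],
      position = sites$position[site_idx],
      fold_change = fc,
      p_value = pv
    )
    profiling <- tibble::tibble(
      dataset_id = sprintf("DS%04d_prof", cond_idx),
      gene = sites$gene[site_idx],
      accession = sites$accession[site_idx],
      residue = sites$residue[site_idx],
      position = sites$position[site_idx],
      loc_prob = loc_prob,
      ascore = NA_real_
    )
    list(corpus = phos_corpus(metas, profiling, differential, filters),
         truth = planted_truth(cfg))
  })
}
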