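#' Class I site confidence filter
#'
#' A phosphosite identification is Class I when its phosphate placement on a
#' specific residue is confident: localization probability at least
#' `loc_prob_min` (default 0.75, inclusive) or A-score strictly greater than
#' `ascore_min` (default 13). Either score may be absent (`NA`); a record with
#' both absent is invalid.
#'
#' @param loc_prob Numeric vector of localization probabilities in \[0, 1\],
#'   `NA` when not reported.
#' @param ascore Numeric vector of A-scores (>= 0), `NA` when not reported.
#' @param cfg A [filter_config()].
#' @return Logical vector: `TRUE` where the identification is Class I.
#' @examples
#' is_class1(c(0.80, NA, 0.50), c(NA, 14, 10))
#' @export
is_class1 <- function(loc_prob, ascore, cfg = filter_config()) {
  n <- max(length(loc_prob), length(ascore))
  loc_prob <- rep_len(as.numeric(loc_prob), n)
  ascore <- rep_len(as.numeric(ascore), n)
  if (any(is.na(loc_prob) & is.na(ascore))) {
    stop("each record needs a localization probability or an A-score",
         call. = FALSE)
  }
  if (any(loc_prob < 0 | loc_prob > 1, na.rm = TRUE)) {
    stop("localization probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(ascore < 0, na.rm = TRUE)) {
    stop("A-scores must be nonnegative", call. = FALSE)
  }
  (!is.na(loc_prob) & loc_prob >= cfg$loc_prob_min) |
    (!is.na(ascore) & ascore > cfg$ascore_min)
}

#' Call differential regulation of a phosphosite
#'
#' Applies the fold-change / p-value rule used to define differential
#' regulation: a site is upregulated (`"U"`) when its fold change
#' (treatment/control) is at least `up_threshold` with p-value below
#' `p_threshold`, downregulated (`"D"`) when the fold change is at most
#' `down_threshold` with p-value below `p_threshold`, and `"none"` otherwise.
#' Exactly one of the three labels applies to any valid input.
#'
#' @param fold_change Positive numeric vector of treatment/control ratios.
#' @param p_value Numeric vector of p-values in \[0, 1\].
#' @param cfg A [filter_config()].
#' @return Character vector with values `"U"`, `"D"` or `"none"`.
#' @examples
#' call_regulation(c(1.3, 0.76, 1.0, 2.0), c(0.01, 0.04, 0.001, 0.20))
#' @export
call_regulation <- function(fold_change, p_value, cfg = filter_config()) {
  fold_change <- as.numeric(fold_change)
  p_value <- as.numeric(p_value)
  if (anyNA(fold_change) || any(fold_change <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  if (anyNA(p_value) || any(p_value < 0 | p_value > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  sig <- p_value < cfg$p_threshold
  out <- rep("none", length(fold_change))
  out[sig & fold_change >= cfg$up_threshold] <- "U"
  out[sig & fold_change <= cfg$down_threshold] <- "D"
  out
}

#' Classify the joint regulation pattern of a site pair
#'
#' Encodes the joint state of a target-protein phosphosite and a phosphosite
#' of another protein as a two-letter pattern code. The first letter is the
#' target (predominant) site's call, the second the other site's call:
#' `UU`/`DD` are the positive (concordant) patterns, `UD`/`DU` the negative
#' (discordant) ones.
#'
#' @param call_predominant,call_other Character vectors of calls, each `"U"`
#'   or `"D"`.
#' @return Character vector of pattern codes in `c("UU","DD","UD","DU")`.
#' @examples
#' classify_pattern(c("U", "D"), c("U", "U"))
#' @export
classify_pattern <- function(call_predominant, call_other) {
  if (any(!call_predominant %in% c("U", "D")) ||
      any(!call_other %in% c("U", "D"))) {
    stop("pattern codes are defined only for calls U and D", call. = FALSE)
  }
  paste0(call_predominant, call_other)
}
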