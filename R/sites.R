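#' Parse a phosphosite token
#'
#' Phosphosites are identified throughout the package by a canonical token of
#' the form `"<GENE>_<residue><position>"`, e.g. `"CAV1_Y14"`: the HGNC gene
#' symbol, an underscore, the phosphoacceptor residue (S, T or Y) and the
#' 1-based position in the protein sequence. `parse_site_token()` splits a
#' token into its components; [format_site_token()] is its inverse, so
#' `format_site_token(parse_site_token(x))` returns `x` in canonical
#' (uppercase) form.
#'
#' @param token Character vector of site tokens.
#' @return A tibble with columns `gene` (uppercase symbol), `residue`
#'   (one of `"S"`, `"T"`, `"Y"`) and `position` (integer, >= 1).
#' @examples
#' parse_site_token(c("CAV1_Y14", "CAV1_S37"))
#' @export
parse_site_token <- function(token) {
  if (length(token) == 0L) {
    return(tibble::tibble(gene = character(), residue = character(),
                          position = integer()))
  }
  token <- as.character(token)
  if (anyNA(token) || any(!nzchar(token))) {
    stop("site tokens must be nonempty strings", call. = FALSE)
  }
  # gene may itself contain underscores/hyphens; the residue+position block is
  # everything after the LAST underscore
  m <- regmatches(token, regexpr("_[STYsty][0-9]+$", token))
  bad <- lengths(regmatches(token, gregexpr("_[STYsty][0-9]+$", token))) == 0L
  if (any(bad)) {
    stop("malformed site token(s): ",
         paste(utils::head(token[bad], 5L), collapse = ", "),
         " (expected \"<GENE>_<S|T|Y><position>\")", call. = FALSE)
  }
  gene <- toupper(substr(token, 1L, nchar(token) - nchar(m)))
  residue <- toupper(substr(m, 2L, 2L))
  position <- as.integer(substring(m, 3L))
  if (any(!nzchar(gene))) {
    stop("malformed site token(s): missing gene symbol in ",
         paste(utils::head(token[!nzchar(gene)], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(position < 1L)) {
    stop("site positions must be >= 1", call. = FALSE)
  }
  tibble::tibble(gene = gene, residue = residue, position = position)
}

#' Format phosphosite components as canonical tokens
#'
#' @param x A data frame with columns `gene`, `residue`, `position`
#'   (as returned by [parse_site_token()]), or a gene vector when `residue`
#'   and `position` are supplied separately.
#' @param residue,position Optional vectors used when `x` is a gene vector.
#' @return Character vector of canonical tokens, e.g. `"CAV1_Y14"`.
#' @examples
#' format_site_token("CAV1", "Y", 14)
#' @export
format_site_token <- function(x, residue = NULL, position = NULL) {
  if (is.data.frame(x)) {
    gene <- x$gene
    residue <- x$residue
    position <- x$position
  } else {
    gene <- x
  }
  stopifnot(!is.null(residue), !is.null(position))
  residue <- toupper(as.character(residue))
  if (any(!residue %in% c("S", "T", "Y"))) {
    stop("residue must be one of S, T, Y", call. = FALSE)
  }
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L)) {
    stop("position must be an integer >= 1", call. = FALSE)
  }
  paste0(toupper(gene), "_", residue, position)
}

# internal: add a `token` column to a record table carrying gene/residue/position
add_site_token <- function(df) {
  df$token <- paste0(df$gene, "_", df$residue, df$position)
  df
}
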