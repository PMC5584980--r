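#' Parse HLA-I allele names
#'
#' Accepts the three common dialects -- `"HLA-A02:01"`, `"A02:01"` and the
#' compact `"A0201"` -- and returns the canonical compact form used
#' internally (locus letter + 2-digit group + 2-digit protein, e.g.
#' `"A0201"`). Parsing is lossless: [format_allele()] renders the colon
#' form back.
#'
#' @param x Character vector of allele names in any accepted dialect.
#' @return Character vector of compact allele names.
#' @export
#' @examples
#' parse_allele(c("HLA-A02:01", "B07:02", "C0702"))
parse_allele <- function(x) {
  y <- toupper(trimws(x))
  y <- sub("^HLA-", "", y)
  y <- gsub(":", "", y, fixed = TRUE)
  bad <- !grepl("^[ABC][0-9]{4}$", y)
  if (any(bad)) {
    stop("unparseable HLA-I allele name(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  y
}

#' Render a compact allele name as "HLA-A02:01"
#'
#' @param x Character vector of compact allele names (see [parse_allele()]).
#' @return Character vector in the `HLA-<locus><group>:<protein>` form.
#' @export
format_allele <- function(x) {
  x <- parse_allele(x)
  paste0("HLA-", substr(x, 1, 3), ":", substr(x, 4, 5))
}

#' Locus of an allele
#'
#' @param x Character vector of allele names.
#' @return Character vector with values `"A"`, `"B"` or `"C"`.
#' @export
allele_locus <- function(x) {
  substr(parse_allele(x), 1, 1)
}

#' Validate a genotype (set of alleles for one sample)
#'
#' Checks the HLA-I constraints: 1--6 distinct alleles, at most two per
#' locus.
#'
#' @param alleles Character vector of allele names.
#' @param sample_id Optional sample identifier used in error messages.
#' @return The parsed, deduplicated genotype (invisibly sorted).
#' @export
validate_genotype <- function(alleles, sample_id = NULL) {
  g <- unique(parse_allele(alleles))
  who <- if (is.null(sample_id)) "" else paste0(" in sample '", sample_id, "'")
  if (length(g) < 1L || length(g) > 6L) {
    stop("genotype", who, " must contain 1-6 distinct alleles, got ", length(g))
  }
  per_locus <- table(allele_locus(g))
  if (any(per_locus > 2L)) {
    bad <- names(per_locus)[per_locus > 2L]
    stop("more than 2 HLA-", paste(bad, collapse = "/"),
         " alleles", who, ": ", paste(g, collapse = ", "))
  }
  sort(g)
}
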