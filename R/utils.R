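#' Normalize text for matching and counting
#'
#' Applies the package-wide normalization used before any string comparison:
#' Unicode NFC composition, unification of the apostrophe variants common in
#' Ukrainian typing practice (`'`, `’`, `ʼ`) to U+02BC, and case
#' folding. Counting and duplicate detection both go through this function so
#' that `Війна` and `війна`
#' are one lemma.
#'
#' @param x Character vector.
#' @param fold_case Lowercase after composition? Default `TRUE`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_lemma(c("Війна", "сім'я"))
normalize_lemma <- function(x, fold_case = TRUE) {
  x <- stringi::stri_trans_nfc(x)
  # apostrophe variants: ASCII ', RIGHT SINGLE QUOTATION MARK, MODIFIER LETTER
  # APOSTROPHE -> U+02BC (the form used in Ukrainian orthography references)
  x <- stringi::stri_replace_all_regex(x, "['’ʼ]", "ʼ")
  if (fold_case) x <- stringi::stri_trans_tolower(x)
  x
}

# whitespace collapse + normalization; the duplicate-detection key
normalize_narrative <- function(x) {
  x <- normalize_lemma(x, fold_case = TRUE)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

# Derive a child RNG seed from a master seed and an index; stays inside the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample SD with the single-observation convention: n = 1 reports 0
sd_or_zero <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1L) 0 else stats::sd(x)
}
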