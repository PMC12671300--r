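#' Normalize words for lookup and comparison
#'
#' Applies the package-wide normalization policy: Unicode NFC composition,
#' whitespace trimming, and lower-casing. Umlauts and other non-ASCII
#' letters are preserved, so German forms such as `"Löwe"` normalize to
#' `"löwe"` and remain distinct from `"lowe"`. The normalized form is the
#' key used for repetition detection, lexicon lookup, and embedding lookup.
#'
#' @param x Character vector of surface forms.
#' @return Character vector of the same length with normalized forms.
#' @examples
#' vf_normalize(c("  Hund ", "LÖWE", "cat"))
#' @export
vf_normalize <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringi::stri_trim_both(x)
  stringi::stri_trans_tolower(x)
}

# first-letter capitalized variant, used as embedding-vocabulary fallback
# (German nouns are capitalized in natural training corpora)
capitalize_first <- function(x) {
  out <- x
  has <- !is.na(x) & nchar(x) > 0L
  out[has] <- paste0(
    stringi::stri_trans_toupper(stringi::stri_sub(x[has], 1L, 1L)),
    stringi::stri_sub(x[has], 2L)
  )
  out
}
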