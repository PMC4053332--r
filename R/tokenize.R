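#' Tokenize raw turn text
#'
#' Splits a turn transcription into tokens and derives a comparison form
#' (`norm`) for each. The default policy splits on whitespace, lowercases to
#' obtain the norm, removes tokens made purely of punctuation, and keeps
#' clitic contractions attached as written (`"she's"` is one token). Word
#' matching throughout the package is over norms, so matching is
#' case-insensitive.
#'
#' @param raw a single character string (one turn's transcription).
#' @param policy a tokenization policy from [tokenization_policy()].
#' @return a data.frame with columns `surface` and `norm`, one row per token.
#' @examples
#' tokenize("It does very handy")
#' @export
tokenize <- function(raw, policy = tokenization_policy()) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw) || !nzchar(trimws(raw))) {
    return(data.frame(surface = character(0), norm = character(0),
                      stringsAsFactors = FALSE))
  }
  surface <- strsplit(trimws(raw), "[ \t\r\n]+")[[1]]
  if (policy$strip_punct_tokens) {
    pure_punct <- !grepl("[[:alnum:]]", surface)
    surface <- surface[!pure_punct]
  }
  norm <- if (policy$lowercase) tolower(surface) else surface
  data.frame(surface = surface, norm = norm, stringsAsFactors = FALSE)
}

#' Tokenization policy
#'
#' @param lowercase lowercase surfaces to produce the comparison form.
#' @param strip_punct_tokens drop tokens containing no alphanumeric
#'   character (pure punctuation).
#' @return a list of class `"turnsim_tok_policy"`.
#' @export
tokenization_policy <- function(lowercase = TRUE, strip_punct_tokens = TRUE) {
  structure(list(lowercase = lowercase,
                 strip_punct_tokens = strip_punct_tokens),
            class = "turnsim_tok_policy")
}
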