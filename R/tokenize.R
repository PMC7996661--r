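#' Tokenize clinical text
#'
#' Splits text into word and punctuation tokens with exact character offsets.
#' Tokens are maximal runs of letters/digits (with internal apostrophes) or
#' single punctuation characters; whitespace is never part of a token.
#' Offsets are 0-based half-open over characters, so
#' `substr(text, start + 1, end)` recovers each surface form and concatenating
#' token surfaces with the original gaps reproduces the text exactly.
#'
#' @param text A single character string (may be empty).
#' @return A tibble with columns `start`, `end` (integer offsets), `surface`,
#'   and shape columns `lower`, `is_cap` (initial capital), `has_digit`,
#'   `is_punct`.
#' @examples
#' tokenize("Worked as a builder.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(
      start = integer(), end = integer(), surface = character(),
      lower = character(), is_cap = logical(), has_digit = logical(),
      is_punct = logical()
    ))
  }
  m <- gregexpr("[[:alnum:]]+(?:'[[:alnum:]]+)*|[^[:alnum:][:space:]]",
    text,
    perl = TRUE
  )[[1]]
  if (m[1] == -1L) {
    return(tokenize(""))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  surface <- slice_text(text, start, end)
  tibble(
    start = start, end = end, surface = surface,
    lower = tolower(surface),
    is_cap = grepl("^[[:upper:]]", surface),
    has_digit = grepl("[[:digit:]]", surface),
    is_punct = grepl("^[^[:alnum:]]$", surface)
  )
}

# Sentence index per token: sentences end at ., ?, ! or newline boundaries.
token_sentence_index <- function(tokens, text) {
  if (nrow(tokens) == 0L) {
    return(integer())
  }
  enders <- tokens$surface %in% c(".", "?", "!")
  # a newline in the gap before a token also starts a new sentence
  gap_start <- c(0L, tokens$end[-nrow(tokens)])
  gaps <- slice_text(text, gap_start, tokens$start)
  new_line <- grepl("\n", gaps, fixed = TRUE)
  sent <- integer(nrow(tokens))
  cur <- 1L
  for (i in seq_len(nrow(tokens))) {
    if (i > 1L && (enders[i - 1L] || new_line[i])) cur <- cur + 1L
    sent[i] <- cur
  }
  sent
}
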