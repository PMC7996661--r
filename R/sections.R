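#' Default section header patterns
#'
#' Personal-history headers (`default_ph_headers()`) locate the narrative
#' region where a patient's background — occupation, education, family — is
#' described.  Stop headers (`default_stop_headers()`) are other recognised
#' clinical headers that terminate a section.
#' @return A character vector of lowercase header phrases.
#' @export
default_ph_headers <- function() {
  c("personal history", "background history", "social history",
    "family and personal history")
}

#' @rdname default_ph_headers
#' @export
default_stop_headers <- function() {
  c("medication", "mental state", "mental state examination", "risk",
    "plan", "diagnosis", "history of presenting complaint", "impression")
}

# match a header at the start of a line: optional leading whitespace, the
# phrase, optional ":" and trailing whitespace, then end-of-line content.
header_regex <- function(patterns) {
  alt <- paste0(vapply(patterns, function(p) {
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p)
  }, character(1)), collapse = "|")
  sprintf("(?im)^[ \t]*(%s)[ \t]*(:[ \t]*|$)", alt)
}

#' Extract personal-history sections
#'
#' Finds personal-history sections by line-anchored, case-insensitive header
#' matching (trailing colons and whitespace are tolerated).  A section runs
#' from the first non-whitespace character after its header to the start of
#' the next recognised header line (personal-history or stop header) or the
#' end of the document.  Sections never overlap.  When no header matches the
#' result is empty and downstream stages treat the whole document as
#' out-of-section text.
#'
#' @param text A single document text.
#' @param ph_headers Personal-history header phrases.
#' @param stop_headers Other clinical header phrases that end a section.
#' @return A tibble with columns `start`, `end` (0-based half-open) and
#'   `header_matched`.
#' @examples
#' extract_personal_history("Personal History: Worked as a builder.\nPlan: review.")
#' @export
extract_personal_history <- function(text,
                                     ph_headers = default_ph_headers(),
                                     stop_headers = default_stop_headers()) {
  stopifnot(length(ph_headers) > 0)
  empty <- tibble(start = integer(), end = integer(),
                  header_matched = character())
  if (is.na(text) || !nzchar(text)) {
    return(empty)
  }
  locate_all <- function(patterns) {
    m <- gregexpr(header_regex(patterns), text, perl = TRUE)[[1]]
    if (m[1] == -1L) {
      return(tibble(h_start = integer(), h_end = integer()))
    }
    tibble(h_start = as.integer(m) - 1L,
           h_end = as.integer(m) - 1L + attr(m, "match.length"))
  }
  ph <- locate_all(ph_headers)
  if (nrow(ph) == 0L) {
    return(empty)
  }
  all_h <- bind_rows(ph, locate_all(stop_headers)) |> arrange(.data$h_start)
  out <- purrr::map(seq_len(nrow(ph)), function(i) {
    s <- ph$h_end[i]
    nxt <- all_h$h_start[all_h$h_start > ph$h_start[i]]
    e <- if (length(nxt)) min(nxt) else nchar(text)
    # skip whitespace (incl. the newline after a bare header line)
    while (s < e && grepl("^[[:space:]]$", substr(text, s + 1, s + 1))) {
      s <- s + 1L
    }
    if (s >= e) {
      return(NULL)
    }
    tibble(
      start = s, end = as.integer(e),
      header_matched = trimws(sub(":?[ \t]*$", "",
                                  slice_text(text, ph$h_start[i], ph$h_end[i])))
    )
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) empty else arrange(out, .data$start)
}

#' Extract sections for every document in a table
#'
#' @param docs A documents tibble.
#' @inheritParams extract_personal_history
#' @return A tibble with `doc_id`, `start`, `end`, `header_matched`.
#' @export
extract_sections <- function(docs,
                             ph_headers = default_ph_headers(),
                             stop_headers = default_stop_headers()) {
  purrr::map2(docs$doc_id, docs$text, function(id, txt) {
    s <- extract_personal_history(txt, ph_headers, stop_headers)
    if (nrow(s)) s$doc_id <- id
    s
  }) |>
    bind_rows() |>
    (\(x) if (nrow(x)) select(x, "doc_id", "start", "end", "header_matched")
          else tibble(doc_id = character(), start = integer(),
                      end = integer(), header_matched = character()))()
}

# TRUE per row of `spans` if the span midpoint lies inside any section of doc
in_any_section <- function(start, end, sections) {
  if (is.null(sections) || nrow(sections) == 0L) {
    return(rep(FALSE, length(start)))
  }
  vapply(seq_along(start), function(i) {
    any(sections$start <= start[i] & end[i] <= sections$end)
  }, logical(1))
}
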