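#' Read standoff occupation annotations
#'
#' Parses a BRAT-style `.ann` file against its document.  Span lines look
#' like `T1<TAB>Occupation 12 19<TAB>builder`; each span is followed by
#' attribute lines `A<n><TAB>Relation T1 patient`,
#' `A<n><TAB>Kind T1 title` and `A<n><TAB>Label T1 builder`.  Offsets are
#' 0-based half-open over characters.  The stored surface must equal the
#' document's text slice — a mismatch is an error, not a warning, because it
#' means the annotation and the text have drifted apart.  Identical duplicate
#' annotations are collapsed silently; conflicting annotations on the same
#' span (e.g. different relations) are kept for the evaluator to arbitrate.
#'
#' @param path Path to a `.ann` file.
#' @param doc A one-row documents tibble (or a list with `doc_id` and `text`).
#' @return An annotations tibble with columns `doc_id`, `start`, `end`,
#'   `surface`, `mention_kind`, `label`, `relation`.
#' @export
read_standoff <- function(path, doc) {
  stopifnot(!is.null(doc$doc_id), !is.null(doc$text))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(empty_annotations())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  spans <- list()
  attrs <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    id <- p[[1]]
    if (startsWith(id, "T")) {
      if (length(p) != 3L) {
        abort(sprintf("malformed span line %d in %s", i, path))
      }
      f <- strsplit(p[[2]], " ", fixed = TRUE)[[1]]
      if (length(f) != 3L || f[[1]] != "Occupation" ||
          is.na(suppressWarnings(as.integer(f[[2]])))) {
        abort(sprintf("malformed span line %d in %s", i, path))
      }
      spans[[id]] <- list(
        start = as.integer(f[[2]]), end = as.integer(f[[3]]),
        surface = p[[3]]
      )
    } else if (startsWith(id, "A")) {
      if (length(p) != 2L) {
        abort(sprintf("malformed attribute line %d in %s", i, path))
      }
      f <- strsplit(p[[2]], " ", fixed = TRUE)[[1]]
      if (length(f) < 3L) {
        abort(sprintf("malformed attribute line %d in %s", i, path))
      }
      attrs[[length(attrs) + 1L]] <- list(
        name = f[[1]], target = f[[2]],
        value = paste(f[-(1:2)], collapse = " ")
      )
    } else {
      abort(sprintf("malformed line %d in %s", i, path))
    }
  }
  text <- doc$text[[1]]
  ann <- purrr::imap(spans, function(s, id) {
    if (s$start < 0L || s$end <= s$start || s$end > nchar(text)) {
      abort(sprintf("span %s out of range in %s", id, path))
    }
    got <- slice_text(text, s$start, s$end)
    if (!identical(got, s$surface)) {
      abort(sprintf(
        "surface mismatch for %s in %s: file has %s, text has %s",
        id, path, dQuote(s$surface), dQuote(got)
      ))
    }
    a <- purrr::keep(attrs, ~ .x$target == id)
    get1 <- function(nm, default = NA_character_) {
      hit <- purrr::keep(a, ~ .x$name == nm)
      if (length(hit)) hit[[1]]$value else default
    }
    tibble(
      doc_id = doc$doc_id[[1]], start = s$start, end = s$end,
      surface = s$surface,
      mention_kind = get1("Kind", "title"),
      label = get1("Label", "other"),
      relation = get1("Relation")
    )
  })
  out <- bind_rows(ann)
  out <- distinct(out)
  arrange(out, .data$start, .data$end, .data$relation)
}

#' Write standoff occupation annotations
#'
#' Inverse of [read_standoff()].  Output ordering is deterministic: by
#' `start`, then `end`, then `relation`.  An empty annotation set yields an
#' empty file.
#'
#' @param annotations An annotations tibble for a single document.
#' @param path Output `.ann` path.
#' @return `path`, invisibly.
#' @export
write_standoff <- function(annotations, path) {
  if (nrow(annotations) == 0L) {
    readr::write_file("", path)
    return(invisible(path))
  }
  assert_annotation_cols(annotations)
  annotations <- arrange(annotations, .data$start, .data$end, .data$relation)
  lines <- character(0)
  a_id <- 0L
  for (i in seq_len(nrow(annotations))) {
    x <- annotations[i, ]
    tid <- paste0("T", i)
    lines <- c(lines, sprintf(
      "%s\tOccupation %d %d\t%s", tid, x$start, x$end, x$surface
    ))
    for (attr in list(
      c("Relation", x$relation),
      c("Kind", x$mention_kind %||% "title"),
      c("Label", x$label)
    )) {
      if (!is.na(attr[[2]])) {
        a_id <- a_id + 1L
        lines <- c(lines, sprintf("A%d\t%s %s %s", a_id, attr[[1]], tid,
                                  attr[[2]]))
      }
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read or write a whole annotation directory
#'
#' One `<doc_id>.ann` per document, next to the `.txt` files.
#' @param docs A documents tibble.
#' @param path Directory of `.ann` files.
#' @param annotations Annotations tibble with a `doc_id` column.
#' @return `read_standoff_dir()` a combined annotations tibble;
#'   `write_standoff_dir()` the path, invisibly.
#' @export
read_standoff_dir <- function(path, docs) {
  out <- purrr::map(seq_len(nrow(docs)), function(i) {
    f <- file.path(path, paste0(docs$doc_id[i], ".ann"))
    if (!file.exists(f)) {
      return(empty_annotations())
    }
    read_standoff(f, docs[i, ])
  })
  bind_rows(out)
}

#' @rdname read_standoff_dir
#' @export
write_standoff_dir <- function(annotations, docs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(docs))) {
    id <- docs$doc_id[i]
    write_standoff(
      filter(annotations, .data$doc_id == id),
      file.path(path, paste0(id, ".ann"))
    )
  }
  invisible(path)
}
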