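#' Construct a table of clinical documents
#'
#' Validates and normalises a tibble of free-text clinical documents.  A
#' document has an opaque `doc_id` (unique), a `patient_id`, a `doc_type`
#' (attachment, event, discharge_summary, risk_assessment or other), its
#' `text`, and `age` — the patient's age in whole years at the document date.
#' Documents from patients under 16 are never admitted to a corpus: callers
#' must gate them out first (see [read_documents()], which does so and
#' reports the count).
#'
#' @param docs A data frame with columns `doc_id`, `patient_id`, `doc_type`,
#'   `text`, `age`.
#' @return A validated tibble with the same columns.
#' @export
clinical_documents <- function(docs) {
  docs <- as_tibble(docs)
  needed <- c("doc_id", "patient_id", "doc_type", "text", "age")
  missing_cols <- setdiff(needed, names(docs))
  if (length(missing_cols)) {
    abort(paste0("documents are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(docs$doc_id)) {
    abort("doc_id must be unique within a corpus")
  }
  bad_type <- setdiff(unique(docs$doc_type), doc_types())
  if (length(bad_type)) {
    abort(paste0("unknown doc_type: ", paste(bad_type, collapse = ", ")))
  }
  docs$age <- as.integer(docs$age)
  if (any(is.na(docs$age)) || any(docs$age < 16L)) {
    abort("documents from patients aged under 16 cannot enter a corpus")
  }
  docs$text[is.na(docs$text)] <- ""
  docs[needed]
}

#' Read a document directory
#'
#' Reads one UTF-8 `.txt` file per document plus a sidecar metadata TSV with
#' header `doc_id`, `patient_id`, `doc_type`, `age`.  Documents where the
#' patient was under 16 at the document date are excluded (the count is
#' reported); a text file without a metadata row, or a metadata row whose
#' text file is missing, is a hard error.
#'
#' @param path Directory containing `<doc_id>.txt` files.
#' @param metadata_path Path to the metadata TSV (default
#'   `file.path(path, "metadata.tsv")`).
#' @return A tibble of documents as from [clinical_documents()].
#' @export
read_documents <- function(path, metadata_path = file.path(path, "metadata.tsv")) {
  if (!dir.exists(path)) abort(paste0("no such directory: ", path))
  meta <- readr::read_tsv(metadata_path, col_types = readr::cols(
    doc_id = readr::col_character(), patient_id = readr::col_character(),
    doc_type = readr::col_character(), age = readr::col_integer()
  ))
  files <- list.files(path, pattern = "\\.txt$")
  ids <- sub("\\.txt$", "", files)
  orphan <- setdiff(ids, meta$doc_id)
  if (length(orphan)) {
    abort(paste0("no metadata row for document(s): ",
                 paste(head(orphan, 5), collapse = ", ")))
  }
  missing_file <- setdiff(meta$doc_id, ids)
  if (length(missing_file)) {
    abort(paste0("missing or unreadable text file for: ",
                 paste(head(missing_file, 5), collapse = ", ")))
  }
  n_gated <- sum(meta$age < 16L)
  if (n_gated > 0L) {
    inform(sprintf("age gate: excluded %d document(s) with patient age < 16",
                   n_gated))
    meta <- filter(meta, .data$age >= 16L)
  }
  meta$text <- if (nrow(meta) == 0L) {
    character(0)
  } else {
    vapply(
      file.path(path, paste0(meta$doc_id, ".txt")),
      function(f) readr::read_file(f), character(1), USE.NAMES = FALSE
    )
  }
  clinical_documents(meta)
}

#' Write a document directory
#'
#' Inverse of [read_documents()]: one `<doc_id>.txt` per document plus
#' `metadata.tsv`.  Writing then reading yields byte-identical texts.
#'
#' @param docs A documents tibble.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path) {
  docs <- clinical_documents(docs)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  purrr::walk2(
    docs$text, file.path(path, paste0(docs$doc_id, ".txt")),
    readr::write_file
  )
  readr::write_tsv(
    docs[c("doc_id", "patient_id", "doc_type", "age")],
    file.path(path, "metadata.tsv")
  )
  invisible(path)
}
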