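# Shared internal helpers: span arithmetic, seeds, validation.

# 0-based half-open character offsets are used everywhere.  `start` is the
# index of the first character, `end` one past the last.
slice_text <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

spans_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

# Deterministic fan-out of one user seed to per-stage seeds.  Offsets are
# fixed so any stage can be re-run in isolation; kept well below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    corpus = 101L, split = 211L, mention = 307L, relation = 401L,
    extract = 503L, profile = 601L, eval = 701L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

assert_annotation_cols <- function(ann, arg = "annotations") {
  needed <- c("start", "end", "surface", "label", "relation")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols)) {
    abort(sprintf(
      "`%s` is missing column(s): %s", arg,
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(ann)
}

empty_annotations <- function() {
  tibble(
    doc_id = character(), start = integer(), end = integer(),
    surface = character(), mention_kind = character(),
    label = character(), relation = character()
  )
}

relation_levels <- function() c("patient", "family", "clinician", "other_person")

doc_types <- function() {
  c("attachment", "event", "discharge_summary", "risk_assessment", "other")
}
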