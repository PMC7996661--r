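# Relation assignment: whose occupation is it?  An SVM over contextual cue
# features, wrapped by deterministic cue rules (rules win), then the
# healthcare-occupation filter.

#' Contextual features for relation classification
#'
#' For each mention: the nearest preceding pronoun (he/she/they, including
#' possessives, vs none), whether a kinship cue ("mother", "wife", ...)
#' occurs within five tokens to the left, whether a clinician cue ("Dr",
#' "consultant", "seen", ...) occurs within five tokens to the left, whether
#' a non-kin person cue ("friend", "neighbour", ...) occurs within five
#' tokens to the left, whether the mention lies inside a personal-history
#' section, and the token distance from sentence start.  Deterministic.
#'
#' @param mentions An annotations tibble for one document.
#' @param doc A one-row documents tibble (or list with `text`).
#' @param sections Optional precomputed sections for the document.
#' @return A tibble of features, one row per mention, in input order.
#' @export
featurize_relation <- function(mentions, doc, sections = NULL) {
  text <- doc$text[[1]]
  toks <- tokenize(text)
  sections <- sections %||% extract_personal_history(text)
  sent <- token_sentence_index(toks, text)
  pronouns <- c("he", "she", "they", "his", "her", "their")
  kin <- kinship_cues()
  clin <- clinician_cues()
  oth <- other_person_cues()
  purrr::map(seq_len(nrow(mentions)), function(r) {
    first_tok <- which(toks$start >= mentions$start[r])[1]
    if (is.na(first_tok)) first_tok <- nrow(toks)
    left5 <- toks$lower[max(1L, first_tok - 5L):max(1L, first_tok - 1L)]
    if (first_tok == 1L) left5 <- character(0)
    left_all <- toks$lower[seq_len(first_tok - 1L)]
    pron_idx <- which(left_all %in% pronouns)
    tibble(
      pronoun = if (length(pron_idx)) {
        p <- left_all[max(pron_idx)]
        unname(c(he = "he", she = "she", they = "they",
                 his = "he", her = "she", their = "they")[[p]])
      } else "none",
      kin_cue = any(left5 %in% kin),
      clin_cue = any(left5 %in% clin),
      other_cue = any(left5 %in% oth),
      in_section = in_any_section(mentions$start[r], mentions$end[r],
                                  sections),
      sent_pos = {
        s <- sent[first_tok]
        first_tok - min(which(sent == s))
      }
    )
  }) |> bind_rows()
}

relation_design <- function(features) {
  cbind(
    pron_he = as.numeric(features$pronoun == "he"),
    pron_she = as.numeric(features$pronoun == "she"),
    pron_they = as.numeric(features$pronoun == "they"),
    kin_cue = as.numeric(features$kin_cue),
    clin_cue = as.numeric(features$clin_cue),
    other_cue = as.numeric(features$other_cue),
    in_section = as.numeric(features$in_section),
    sent_pos = features$sent_pos
  )
}

#' Train the occupation-relation classifier
#'
#' Fits a linear-kernel support-vector machine (C = 1) with probability
#' estimates over the relation labels \{patient, family, clinician,
#' other_person\}, using the gold mentions of the corpus's training split.
#' Training is reproducible given the seed (the probability calibration uses
#' R's RNG).
#'
#' @param corpus An `occ_corpus`.
#' @param split Split to train on (default `"train"`; `NULL` for all).
#' @param seed Integer seed.
#' @return An object of class `occ_relation_model`.
#' @export
train_relation_model <- function(corpus, split = "train", seed = 1L) {
  stopifnot(inherits(corpus, "occ_corpus"))
  ids <- if (is.null(split)) corpus$documents$doc_id else
    corpus$split$doc_id[corpus$split$split %in% split]
  ann <- filter(corpus$annotations, .data$doc_id %in% ids)
  if (nrow(ann) == 0L) {
    abort("no training mentions in the requested split")
  }
  labs <- unique(ann$relation)
  if (length(labs) < 2L) {
    abort("training split contains only one relation label; cannot fit a classifier")
  }
  docs <- filter(corpus$documents, .data$doc_id %in% unique(ann$doc_id))
  feats <- purrr::map(seq_len(nrow(docs)), function(i) {
    m <- filter(ann, .data$doc_id == docs$doc_id[i])
    f <- featurize_relation(m, docs[i, ])
    f$relation <- m$relation
    f
  }) |> bind_rows()
  X <- relation_design(feats)
  y <- factor(feats$relation, levels = relation_levels())
  y <- droplevels(y)
  fit <- withr::with_seed(stage_seed(seed, "relation"), {
    e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE,
               probability = TRUE)
  })
  structure(list(
    fit = fit, levels = levels(y), all_levels = relation_levels(),
    tokenizer = tokenizer_version(), seed = as.integer(seed),
    n_mentions = nrow(feats),
    corpus_hash = rlang::hash(list(ann, docs$doc_id))
  ), class = "occ_relation_model")
}

#' @export
print.occ_relation_model <- function(x, ...) {
  cat(sprintf(
    "<occ_relation_model> linear SVM over %s; trained on %d mentions\n",
    paste(x$levels, collapse = "/"), x$n_mentions
  ))
  invisible(x)
}

#' @export
glance.occ_relation_model <- function(x, ...) {
  tibble(
    n_mentions = x$n_mentions, n_support = x$fit$tot.nSV,
    labels = paste(x$levels, collapse = ";")
  )
}

#' Read or write a serialized relation model
#' @param model An `occ_relation_model`.
#' @param path File path.
#' @return `read_relation_model()` the model; `write_relation_model()` the
#'   path, invisibly.
#' @export
write_relation_model <- function(model, path) {
  stopifnot(inherits(model, "occ_relation_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_relation_model
#' @export
read_relation_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "occ_relation_model")) {
    abort("not a relation model artifact")
  }
  model
}

# probability-like scores per mention over the full label set (missing
# training labels get probability 0)
relation_scores <- function(model, features) {
  X <- relation_design(features)
  pr <- attr(
    predict(model$fit, X, probability = TRUE), "probabilities"
  )
  out <- matrix(0, nrow(X), length(model$all_levels),
                dimnames = list(NULL, model$all_levels))
  out[, colnames(pr)] <- pr
  out
}

#' Assign relations to detected mentions
#'
#' Combines the SVM prediction with deterministic cue rules.  Precedence,
#' highest first: a clinician cue within five tokens left forces
#' `clinician`; a kinship cue forces `family`; otherwise the model label
#' stands when its probability is at least 0.4; below that confidence the
#' fallback is `patient` inside a personal-history section and
#' `other_person` outside.  With `rules_enabled = FALSE` the cue overrides
#' are skipped.  With a `NULL` model the rules plus the location fallback
#' alone decide (the rule-based-only configuration).
#'
#' @param mentions An annotations tibble for one document (relation ignored).
#' @param doc A one-row documents tibble.
#' @param model An `occ_relation_model` or `NULL`.
#' @param rules_enabled Apply cue-rule overrides?
#' @param sections Optional precomputed sections.
#' @param conf_threshold Minimum model probability for the model label to
#'   stand.
#' @return The mentions tibble with `relation` filled in.
#' @export
classify_relation <- function(mentions, doc, model = NULL,
                              rules_enabled = TRUE, sections = NULL,
                              conf_threshold = 0.4) {
  if (nrow(mentions) == 0L) {
    return(mentions)
  }
  features <- featurize_relation(mentions, doc, sections)
  n <- nrow(mentions)
  label <- rep(NA_character_, n)
  conf_ok <- rep(FALSE, n)
  if (!is.null(model)) {
    sc <- relation_scores(model, features)
    best <- max.col(sc, ties.method = "first")
    label <- colnames(sc)[best]
    conf_ok <- sc[cbind(seq_len(n), best)] >= conf_threshold
  }
  fallback <- if_else(features$in_section, "patient", "other_person")
  out <- if_else(conf_ok, label, fallback)
  if (rules_enabled) {
    out[features$kin_cue] <- "family"
    out[features$clin_cue] <- "clinician"
  }
  mentions$relation <- out
  mentions
}

#' Healthcare occupation filter
#'
#' Re-assigns `relation = "clinician"` to any annotation whose normalised
#' label is in the healthcare filter list and whose relation is
#' `"patient"`.  Nothing is deleted, so clinician-occupation extractions
#' stay available for audit, but after filtering no patient-attributed
#' annotation can carry a health or social care occupation.  The operation
#' is idempotent.
#'
#' @param annotations An annotations tibble with relations assigned.
#' @param filter Character vector of normalised labels
#'   ([default_healthcare_filter()]).  An empty filter is permitted (no-op,
#'   with a warning).
#' @return The annotations tibble, relabelled where required.
#' @export
apply_healthcare_filter <- function(annotations,
                                    filter = default_healthcare_filter()) {
  if (length(filter) == 0L) {
    warn("empty healthcare filter: no annotations re-labelled")
    return(annotations)
  }
  if (nrow(annotations) == 0L) {
    return(annotations)
  }
  hit <- annotations$label %in% filter & annotations$relation == "patient"
  annotations$relation[hit] <- "clinician"
  annotations
}
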