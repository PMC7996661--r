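# End-to-end orchestration: read -> age gate -> sections -> mentions ->
# relations -> healthcare filter -> write, plus the one-command run.

#' Pipeline configuration
#'
#' Assembles, validates and (de)serialises the run configuration.  Every
#' completed run writes a resolved copy of its configuration and the input
#' hashes beside its outputs, so a run can be reproduced from its output
#' directory alone.
#'
#' @param corpus_dir Directory of `.txt` documents plus `metadata.tsv`.
#' @param out_dir Output directory.
#' @param gazetteer_path Optional gazetteer TSV (default: shipped gazetteer).
#' @param filter_path Optional healthcare-filter file (default: shipped
#'   list).
#' @param mention_model_path,relation_model_path Optional serialized model
#'   artifacts; `NULL` runs the rule-based-only configuration.
#' @param ph_headers,stop_headers Section header lists.
#' @param matching_mode Evaluation matching mode.
#' @param scope Evaluation scope.
#' @param apply_filter Apply the healthcare filter? (`FALSE` reproduces the
#'   pre-filter condition.)
#' @param rules_enabled Apply cue-rule overrides in relation assignment?
#' @param seed Global seed; per-stage seeds are derived by fixed offsets.
#' @return A list of class `occ_config`.
#' @export
occ_config <- function(corpus_dir = NULL, out_dir = NULL,
                       gazetteer_path = NULL, filter_path = NULL,
                       mention_model_path = NULL,
                       relation_model_path = NULL,
                       ph_headers = default_ph_headers(),
                       stop_headers = default_stop_headers(),
                       matching_mode = "strict_span_and_relation",
                       scope = "all_relations",
                       apply_filter = TRUE, rules_enabled = TRUE,
                       seed = 1L) {
  structure(list(
    corpus_dir = corpus_dir, out_dir = out_dir,
    gazetteer_path = gazetteer_path, filter_path = filter_path,
    mention_model_path = mention_model_path,
    relation_model_path = relation_model_path,
    ph_headers = ph_headers, stop_headers = stop_headers,
    matching_mode = matching_mode, scope = scope,
    apply_filter = apply_filter, rules_enabled = rules_enabled,
    seed = as.integer(seed)
  ), class = "occ_config")
}

#' @rdname occ_config
#' @param path A YAML file mirroring the `occ_config` fields.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(occ_config, x[intersect(names(x), names(formals(occ_config)))])
}

#' @rdname occ_config
#' @param config An `occ_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

load_pipeline_inputs <- function(config) {
  gazetteer <- if (is.null(config$gazetteer_path)) {
    default_gazetteer()
  } else {
    if (!file.exists(config$gazetteer_path)) {
      abort(paste0("gazetteer file not found: ", config$gazetteer_path))
    }
    read_gazetteer(config$gazetteer_path)
  }
  hc_filter <- if (is.null(config$filter_path)) {
    default_healthcare_filter()
  } else {
    if (!file.exists(config$filter_path)) {
      abort(paste0("filter file not found: ", config$filter_path))
    }
    read_healthcare_filter(config$filter_path)
  }
  mention_model <- if (!is.null(config$mention_model_path)) {
    if (!file.exists(config$mention_model_path)) {
      abort(paste0("mention model not found: ", config$mention_model_path))
    }
    read_mention_model(config$mention_model_path)
  }
  relation_model <- if (!is.null(config$relation_model_path)) {
    if (!file.exists(config$relation_model_path)) {
      abort(paste0("relation model not found: ", config$relation_model_path))
    }
    read_relation_model(config$relation_model_path)
  }
  list(gazetteer = gazetteer, filter = hc_filter,
       mention_model = mention_model, relation_model = relation_model)
}

#' Extract occupations from a document set
#'
#' Runs the full extraction pipeline over in-memory documents: section
#' extraction, hybrid mention detection, relation classification, and the
#' healthcare filter (which re-labels, never deletes, so the annotation
#' count is conserved across the filter stage).  Per-stage counts are
#' returned in the log.
#'
#' @param docs A documents tibble (already age-gated by construction).
#' @param mention_model An `occ_mention_model` or `NULL` (rule-based only).
#' @param relation_model An `occ_relation_model` or `NULL` (cue rules +
#'   location fallback only).
#' @param gazetteer Gazetteer tibble.
#' @param filter Healthcare filter labels.
#' @param ph_headers,stop_headers Section header lists.
#' @param apply_filter,rules_enabled Stage switches.
#' @return A list with `extractions` (tibble: `doc_id`, `patient_id`,
#'   `start`, `end`, `surface`, `label`, `mention_kind`, `relation`,
#'   `in_section`), `sections`, and `log` (named per-stage counts).
#' @export
extract_occupations <- function(docs, mention_model = NULL,
                                relation_model = NULL,
                                gazetteer = default_gazetteer(),
                                filter = default_healthcare_filter(),
                                ph_headers = default_ph_headers(),
                                stop_headers = default_stop_headers(),
                                apply_filter = TRUE,
                                rules_enabled = TRUE) {
  cg <- compile_gazetteer(gazetteer)
  secs_all <- list()
  out <- list()
  n_sections <- 0L
  for (i in seq_len(nrow(docs))) {
    doc <- docs[i, ]
    secs <- extract_personal_history(doc$text, ph_headers, stop_headers)
    n_sections <- n_sections + nrow(secs)
    if (nrow(secs)) {
      secs_all[[length(secs_all) + 1L]] <-
        mutate(secs, doc_id = doc$doc_id)
    }
    mentions <- detect_mentions(doc, mention_model, cg, secs)
    if (nrow(mentions) == 0L) next
    mentions <- classify_relation(mentions, doc, relation_model,
                                  rules_enabled = rules_enabled,
                                  sections = secs)
    mentions$in_section <- in_any_section(mentions$start, mentions$end, secs)
    mentions$patient_id <- doc$patient_id
    out[[length(out) + 1L]] <- mentions
  }
  extractions <- bind_rows(out)
  if (nrow(extractions) == 0L) {
    extractions <- mutate(empty_annotations(),
                          in_section = logical(0),
                          patient_id = character(0))
  }
  n_before <- nrow(extractions)
  n_patient_before <- sum(extractions$relation == "patient")
  if (apply_filter) {
    extractions <- apply_healthcare_filter(extractions, filter)
  }
  list(
    extractions = extractions[c("doc_id", "patient_id", "start", "end",
                                "surface", "mention_kind", "label",
                                "relation", "in_section")],
    sections = bind_rows(secs_all),
    log = c(
      n_documents = nrow(docs),
      n_sections = n_sections,
      n_mentions = n_before,
      n_patient_before_filter = n_patient_before,
      n_patient_after_filter = sum(extractions$relation == "patient"),
      n_filter_relabelled = n_patient_before -
        sum(extractions$relation == "patient")
    )
  )
}

#' Run extraction from a configuration
#'
#' Disk-to-disk variant of [extract_occupations()]: reads the corpus (with
#' the age gate applied and logged), checks models and resources before any
#' document is processed, runs the stages in order, and writes per-document
#' `.ann` files, `extractions.tsv`, a per-stage count log, the resolved
#' configuration, and input hashes into the output directory.  Re-running
#' with identical config and inputs is byte-identical.
#'
#' @param config An `occ_config` with `corpus_dir` and `out_dir` set.
#' @return The [extract_occupations()] result, invisibly.
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "occ_config"))
  inputs <- load_pipeline_inputs(config) # fail fast, before reading docs
  docs <- read_documents(config$corpus_dir)
  res <- extract_occupations(
    docs,
    mention_model = inputs$mention_model,
    relation_model = inputs$relation_model,
    gazetteer = inputs$gazetteer, filter = inputs$filter,
    ph_headers = config$ph_headers, stop_headers = config$stop_headers,
    apply_filter = config$apply_filter,
    rules_enabled = config$rules_enabled
  )
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_standoff_dir(res$extractions, docs, file.path(out_dir, "ann"))
  readr::write_tsv(res$extractions, file.path(out_dir, "extractions.tsv"))
  readr::write_lines(
    paste(names(res$log), res$log, sep = "\t"),
    file.path(out_dir, "stage_counts.tsv")
  )
  write_config(config, file.path(out_dir, "config_resolved.yaml"))
  jsonlite::write_json(
    list(
      corpus_hash = rlang::hash(list(docs$doc_id, docs$text)),
      gazetteer_hash = rlang::hash(inputs$gazetteer),
      filter_hash = rlang::hash(inputs$filter)
    ),
    file.path(out_dir, "input_hashes.json"),
    auto_unbox = TRUE
  )
  invisible(res)
}

#' One-command synthetic end-to-end run
#'
#' Generates a synthetic corpus, splits it, trains the mention and relation
#' models on the training split, extracts occupations from the held-out test
#' split, evaluates against gold, builds patient profiles, and writes a
#' summary JSON.  Any stage failure aborts with the stage name.
#'
#' @param out_dir Output directory for the summary and artifacts.
#' @param n_patients Corpus size.
#' @param n_train,n_validation,n_test Split sizes (documents with a
#'   personal-history section).
#' @param seed Global seed.
#' @param config A [synth_config()] overriding the generator defaults
#'   (its `n_patients`/`seed` are taken from the arguments above).
#' @return A list with the summary (also written to
#'   `file.path(out_dir, "summary.json")`), invisibly.
#' @export
run_all <- function(out_dir, n_patients = 500, n_train = 257,
                    n_validation = 77, n_test = 666, seed = 1L,
                    config = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline failed at stage [%s]: %s", name,
                    conditionMessage(e)))
    })
  }
  cfg <- config %||% synth_config()
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  corpus <- stage("synth", generate_corpus(cfg))
  corpus <- stage("split",
                  split_corpus(corpus, n_train, n_validation, n_test, seed))
  mention_model <- stage("train_mention",
                         train_mention_model(corpus, seed = seed))
  relation_model <- stage("train_relation",
                          train_relation_model(corpus, seed = seed))
  test_ids <- corpus$split$doc_id[corpus$split$split == "test"]
  test_docs <- filter(corpus$documents, .data$doc_id %in% test_ids)
  res <- stage("extract", extract_occupations(
    test_docs, mention_model, relation_model
  ))
  gold <- filter(corpus$annotations, .data$doc_id %in% test_ids)
  ev_all <- stage("evaluate",
                  precision_recall(gold, res$extractions,
                                   scope = "all_relations"))
  ev_pat <- precision_recall(gold, res$extractions, scope = "patient_only")
  agree_title <- cohens_kappa(gold, res$extractions, test_docs, "title")
  agree_rel <- cohens_kappa(gold, res$extractions, test_docs, "relation")
  profiles <- stage("profile", build_profiles(
    res$extractions, corpus$structured,
    patients = filter(corpus$patients,
                      .data$patient_id %in% test_docs$patient_id)
  ))
  summary <- list(
    n_documents = nrow(corpus$documents),
    n_test_documents = nrow(test_docs),
    precision_strict = ev_all$precision, recall_strict = ev_all$recall,
    precision_patient = ev_pat$precision, recall_patient = ev_pat$recall,
    agreement_title_kappa = agree_title$kappa,
    agreement_relation_kappa = agree_rel$kappa,
    pct_structured = 100 * mean(!is.na(profiles$structured_status)),
    pct_combined = 100 * mean(profiles$has_occupation),
    seed = as.integer(seed)
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summary = summary, corpus = corpus,
                 mention_model = mention_model,
                 relation_model = relation_model,
                 extractions = res$extractions,
                 profiles = profiles))
}
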