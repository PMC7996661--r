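mention_on <- function(text, word) {
  pos <- as.integer(regexpr(word, text, fixed = TRUE)) - 1L
  tibble::tibble(
    doc_id = "d", start = pos, end = pos + nchar(word),
    surface = word, mention_kind = "title", label = word,
    relation = NA_character_
  )
}

test_that("relation features capture pronouns, cues and section context", {
  txt <- "Personal History:\nHer mother is a teacher."
  doc <- tibble::tibble(doc_id = "d", text = txt)
  f <- featurize_relation(mention_on(txt, "teacher"), doc)
  expect_true(f$kin_cue)
  expect_false(f$clin_cue)
  expect_true(f$in_section)
  expect_equal(f$pronoun, "she")

  txt2 <- "Seen by Dr Smith, consultant psychiatrist."
  doc2 <- tibble::tibble(doc_id = "d", text = txt2)
  f2 <- featurize_relation(mention_on(txt2, "psychiatrist"), doc2)
  expect_true(f2$clin_cue)
  expect_false(f2$kin_cue)
  expect_false(f2$in_section)
  # determinism
  expect_identical(f2, featurize_relation(mention_on(txt2, "psychiatrist"),
                                          doc2))
})

test_that("relation training rejects degenerate inputs", {
  corpus <- small_corpus()
  empty <- corpus
  empty$annotations <- empty$annotations[0, ]
  expect_error(train_relation_model(empty), "no training mentions")
  mono <- corpus
  mono$annotations <- dplyr::mutate(mono$annotations, relation = "patient")
  expect_error(train_relation_model(mono), "one relation label")
})

test_that("relation model beats chance and is reproducible", {
  fx <- trained_fixture()
  vd <- split_docs(fx$corpus, "validation")
  gold <- split_gold(fx$corpus, "validation")
  pred <- purrr::map(seq_len(nrow(vd)), function(i) {
    m <- dplyr::filter(gold, doc_id == vd$doc_id[i])
    if (nrow(m) == 0L) return(NULL)
    classify_relation(m, vd[i, ], fx$relation_model, rules_enabled = FALSE)
  }) |> dplyr::bind_rows()
  joined <- dplyr::inner_join(
    gold, pred, by = c("doc_id", "start", "end"),
    suffix = c("_gold", "_pred")
  )
  recalls <- joined |>
    dplyr::group_by(relation_gold) |>
    dplyr::summarise(r = mean(relation_pred == relation_gold))
  expect_gt(mean(recalls$r), 0.25)

  m2 <- train_relation_model(fx$corpus, seed = 5)
  pred2 <- purrr::map(seq_len(nrow(vd)), function(i) {
    m <- dplyr::filter(gold, doc_id == vd$doc_id[i])
    if (nrow(m) == 0L) return(NULL)
    classify_relation(m, vd[i, ], m2, rules_enabled = FALSE)
  }) |> dplyr::bind_rows()
  expect_identical(pred$relation, pred2$relation)
})

test_that("relation scores behave like probabilities", {
  fx <- trained_fixture()
  txt <- "Personal History:\nShe is a cleaner."
  doc <- tibble::tibble(doc_id = "d", text = txt)
  f <- featurize_relation(mention_on(txt, "cleaner"), doc)
  sc <- occumine:::relation_scores(fx$relation_model, f)
  expect_equal(unname(rowSums(sc)), 1, tolerance = 1e-8)
  expect_true(all(sc >= 0))
  expect_equal(colnames(sc),
               c("patient", "family", "clinician", "other_person"))
})

test_that("cue rules override the model with fixed precedence", {
  # fake model whose predicted label and confidence we control
  make_fake <- function(label, conf) {
    fit <- structure(list(label = label, conf = conf),
                     class = "occumine_fake_svm")
    structure(list(fit = fit, levels = c("patient", "family", "clinician",
                                         "other_person"),
                   all_levels = c("patient", "family", "clinician",
                                  "other_person"),
                   tokenizer = "occumine-tok-1"),
              class = "occ_relation_model")
  }
  assign("predict.occumine_fake_svm", function(object, newdata, ...) {
    n <- nrow(newdata)
    pr <- matrix((1 - object$conf) / 3, n, 4,
                 dimnames = list(NULL, c("patient", "family", "clinician",
                                         "other_person")))
    pr[, object$label] <- object$conf
    structure(rep(object$label, n), probabilities = pr)
  }, envir = globalenv())
  withr::defer(rm("predict.occumine_fake_svm", envir = globalenv()))

  texts <- list(
    none = "Personal History:\nAlex is a builder.",
    kin = "Personal History:\nHis mother is a builder.",
    clin = "Seen by Dr Smith and then a builder."
  )
  oracle <- function(cue, model_label, conf, in_sec) {
    if (cue == "clin") return("clinician")
    if (cue == "kin") return("family")
    if (conf >= 0.4) return(model_label)
    if (in_sec) "patient" else "other_person"
  }
  for (cue in names(texts)) {
    for (lab in c("patient", "family", "clinician", "other_person")) {
      txt <- texts[[cue]]
      doc <- tibble::tibble(doc_id = "d", text = txt)
      out <- classify_relation(mention_on(txt, "builder"), doc,
                               make_fake(lab, 0.9))
      expect_equal(
        out$relation,
        oracle(cue, lab, 0.9, cue != "clin"),
        info = paste(cue, lab)
      )
    }
  }
  # low-confidence fallback depends on section membership
  txt <- texts$none
  doc <- tibble::tibble(doc_id = "d", text = txt)
  out <- classify_relation(mention_on(txt, "builder"), doc,
                           make_fake("family", 0.3))
  expect_equal(out$relation, "patient")
  txt_out <- "Alex is a builder."
  doc_out <- tibble::tibble(doc_id = "d", text = txt_out)
  out2 <- classify_relation(mention_on(txt_out, "builder"), doc_out,
                            make_fake("family", 0.3))
  expect_equal(out2$relation, "other_person")
  # rules disabled: the model label stands even under a kinship cue
  txt_kin <- texts$kin
  doc_kin <- tibble::tibble(doc_id = "d", text = txt_kin)
  out3 <- classify_relation(mention_on(txt_kin, "builder"), doc_kin,
                            make_fake("patient", 0.9),
                            rules_enabled = FALSE)
  expect_equal(out3$relation, "patient")
})

test_that("rule-based-only classification handles the canonical examples", {
  txt <- "Personal History:\nHer husband is an accountant."
  doc <- tibble::tibble(doc_id = "d", text = txt)
  out <- classify_relation(mention_on(txt, "accountant"), doc, model = NULL)
  expect_equal(out$relation, "family")

  txt2 <- "Reviewed by Dr A, psychiatrist."
  doc2 <- tibble::tibble(doc_id = "d", text = txt2)
  out2 <- classify_relation(mention_on(txt2, "psychiatrist"), doc2,
                            model = NULL)
  expect_equal(out2$relation, "clinician")
})

test_that("healthcare filter re-labels patient-attributed clinician jobs", {
  ann <- tibble::tibble(
    doc_id = "d", start = c(0L, 10L), end = c(5L, 17L),
    surface = c("x", "y"), mention_kind = "title",
    label = c("psychiatrist", "builder"),
    relation = c("patient", "patient")
  )
  out <- apply_healthcare_filter(ann)
  expect_equal(out$relation, c("clinician", "patient"))
  expect_equal(nrow(out), 2L) # nothing deleted
  # idempotent
  expect_identical(apply_healthcare_filter(out), out)
  # empty filter warns and is a no-op
  expect_warning(out2 <- apply_healthcare_filter(ann, character(0)),
                 "empty")
  expect_identical(out2, ann)
})

test_that("no patient-attributed healthcare label survives the filter", {
  fx <- trained_fixture()
  td <- split_docs(fx$corpus, "test")
  res <- extract_occupations(td, fx$mention_model, fx$relation_model)
  bad <- dplyr::filter(res$extractions,
                       label %in% default_healthcare_filter(),
                       relation == "patient")
  expect_equal(nrow(bad), 0L)
})
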