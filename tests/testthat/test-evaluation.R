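ann_tbl <- function(start, end, relation, doc_id = "D1") {
  tibble::tibble(
    doc_id = doc_id, start = as.integer(start), end = as.integer(end),
    surface = "x", mention_kind = "title", label = "x", relation = relation
  )
}

test_that("identical annotation sets match completely", {
  g <- ann_tbl(c(0, 10, 20), c(5, 15, 25), c("patient", "family", "patient"))
  m <- match_annotations(g, g)
  expect_equal(nrow(m$pairs), 3L)
  expect_length(m$unmatched_gold, 0L)
  expect_length(m$unmatched_pred, 0L)
})

test_that("strict matching requires both span and relation", {
  g <- ann_tbl(0, 5, "patient")
  p <- ann_tbl(0, 5, "family")
  m <- match_annotations(g, p, "strict_span_and_relation")
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(m$unmatched_gold, 1L)
  expect_equal(m$unmatched_pred, 1L)
  expect_equal(nrow(match_annotations(g, p, "span_only")$pairs), 1L)
})

test_that("lenient mode needs overlap plus relation agreement", {
  g <- ann_tbl(0, 5, "patient")
  expect_equal(nrow(match_annotations(g, ann_tbl(4, 9, "patient"),
                                      "lenient_overlap")$pairs), 1L)
  expect_equal(nrow(match_annotations(g, ann_tbl(5, 9, "patient"),
                                      "lenient_overlap")$pairs), 0L)
  expect_equal(nrow(match_annotations(g, ann_tbl(4, 9, "family"),
                                      "lenient_overlap")$pairs), 0L)
})

test_that("matching equals the exhaustive maximum-matching oracle", {
  withr::local_seed(17)
  for (rep in 1:60) {
    g <- random_annotation_set(sample(0:6, 1))
    p <- random_annotation_set(sample(0:6, 1))
    for (mode in c("strict_span_and_relation", "span_only",
                   "lenient_overlap")) {
      got <- nrow(match_annotations(g, p, mode)$pairs)
      expect_equal(got, oracle_max_matching(g, p, mode),
                   info = paste(mode, rep))
    }
  }
})

test_that("mismatched documents are rejected", {
  g <- ann_tbl(0, 5, "patient", doc_id = "D1")
  p <- ann_tbl(0, 5, "patient", doc_id = "D2")
  expect_error(match_annotations(g, p), "one document")
})

test_that("precision and recall follow the pooled-count definitions", {
  g <- ann_tbl(c(0, 10, 20), c(5, 15, 25), "patient")
  p <- ann_tbl(c(0, 10, 40), c(5, 15, 45), "patient")
  ev <- precision_recall(g, p)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 3)

  ev2 <- precision_recall(g, g[0, ])
  expect_true(is.na(ev2$precision))
  expect_equal(ev2$recall, 0)

  ev3 <- precision_recall(g[0, ], g[0, ])
  expect_true(is.na(ev3$precision))
  expect_true(is.na(ev3$recall))
})

test_that("micro-average equals a per-document summation oracle", {
  corpus <- small_corpus()
  gold <- dplyr::filter(corpus$annotations,
                        doc_id %in% head(unique(doc_id), 50))
  # perturbed predictions: drop some, shift some
  withr::local_seed(4)
  pred <- gold[runif(nrow(gold)) < 0.8, ]
  shift <- runif(nrow(pred)) < 0.2
  pred$start[shift] <- pred$start[shift] + 1L
  ev <- precision_recall(gold, pred)
  tp <- fp <- fn <- 0L
  for (id in union(unique(gold$doc_id), unique(pred$doc_id))) {
    m <- match_annotations(dplyr::filter(gold, doc_id == id),
                           dplyr::filter(pred, doc_id == id))
    tp <- tp + nrow(m$pairs)
    fn <- fn + length(m$unmatched_gold)
    fp <- fp + length(m$unmatched_pred)
  }
  expect_equal(ev$tp, tp)
  expect_equal(ev$precision, tp / (tp + fp))
  expect_equal(ev$recall, tp / (tp + fn))
})

test_that("self-evaluation is perfect in every mode and scope", {
  corpus <- small_corpus()
  gold <- dplyr::filter(corpus$annotations,
                        doc_id %in% head(unique(doc_id), 30))
  for (mode in c("strict_span_and_relation", "span_only",
                 "lenient_overlap")) {
    for (scope in c("all_relations", "patient_only")) {
      ev <- precision_recall(gold, gold, mode, scope)
      expect_equal(ev$precision, 1)
      expect_equal(ev$recall, 1)
    }
  }
})

test_that("lenient scores never fall below strict scores", {
  fx <- trained_fixture()
  vd <- split_docs(fx$corpus, "validation")
  gold <- split_gold(fx$corpus, "validation")
  pred <- extract_occupations(vd, fx$mention_model,
                              fx$relation_model)$extractions
  strict <- precision_recall(gold, pred, "strict_span_and_relation")
  lenient <- precision_recall(gold, pred, "lenient_overlap")
  expect_gte(lenient$precision, strict$precision)
  expect_gte(lenient$recall, strict$recall)
})

test_that("kappa matches the closed form and its bounds", {
  k <- occumine:::kappa_from_table(matrix(c(50, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(k$kappa, oracle_kappa_2x2(50, 10, 10, 30), tolerance = 1e-12)
  expect_equal(k$kappa, 7 / 12, tolerance = 1e-12)
  expect_equal(k$p_o, 0.8)
  # kappa never exceeds raw agreement when chance agreement is positive
  expect_lte(k$kappa, k$p_o)
})

test_that("identical annotators reach kappa of 1", {
  corpus <- small_corpus()
  docs <- head(corpus$documents, 30)
  ann <- dplyr::filter(corpus$annotations, doc_id %in% docs$doc_id)
  kt <- cohens_kappa(ann, ann, docs, unit = "title")
  kr <- cohens_kappa(ann, ann, docs, unit = "relation")
  expect_equal(kt$kappa, 1)
  expect_equal(kr$kappa, 1)
  expect_gt(kr$n_units, 0)
})

test_that("disagreeing relations reduce relation kappa below 1", {
  corpus <- small_corpus()
  docs <- head(corpus$documents, 40)
  a <- dplyr::filter(corpus$annotations, doc_id %in% docs$doc_id)
  b <- a
  withr::local_seed(8)
  flip <- runif(nrow(b)) < 0.3
  b$relation[flip] <- sample(c("patient", "family", "clinician",
                               "other_person"), sum(flip), replace = TRUE)
  k <- cohens_kappa(a, b, docs, unit = "relation")
  expect_lt(k$kappa, 1)
  expect_gt(k$kappa, 0)
  expect_lte(k$kappa, k$p_o)
})

test_that("zero aligned units yields a null kappa", {
  docs <- tibble::tibble(doc_id = "d", patient_id = "p",
                         doc_type = "event", text = "", age = 30L)
  empty <- ann_tbl(0, 1, "patient")[0, ]
  expect_true(is.na(cohens_kappa(empty, empty, docs, "relation")$kappa))
})
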