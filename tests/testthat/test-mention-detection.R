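test_that("tokenization reconstructs the text exactly", {
  expect_equal(nrow(tokenize("a builder")), 2L)
  expect_equal(nrow(tokenize("")), 0L)
  corpus <- small_corpus()
  for (txt in head(corpus$documents$text, 200)) {
    toks <- tokenize(txt)
    expect_identical(substring(txt, toks$start + 1, toks$end), toks$surface)
    # concatenating surfaces with the original gaps reproduces the text
    gaps_start <- c(0L, toks$end)
    gaps_end <- c(toks$start, nchar(txt))
    gaps <- substr(rep(txt, length(gaps_start)), gaps_start + 1, gaps_end)
    expect_identical(
      paste0(paste0(gaps[-length(gaps)], toks$surface, collapse = ""),
             gaps[length(gaps)]),
      txt
    )
  }
})

test_that("gazetteer matching is longest-match and kind-aware", {
  gz <- tibble::tibble(
    surface = c("builder", "construction", "social worker", "worker"),
    label = c("builder", "construction", "social worker", "worker"),
    kind = c("title", "description", "title", "title"),
    is_status = FALSE
  )
  txt <- "he is a builder"
  m <- gazetteer_match(tokenize(txt), gz, txt)
  expect_equal(m$label, "builder")
  expect_equal(m$mention_kind, "title")

  txt <- "construction work suits him"
  m <- gazetteer_match(tokenize(txt), gz, txt)
  expect_equal(m$label, "construction")
  expect_equal(m$mention_kind, "description")

  txt <- "she is a social worker now"
  m <- gazetteer_match(tokenize(txt), gz, txt)
  expect_equal(nrow(m), 1L)
  expect_equal(m$surface, "social worker")
})

test_that("feature extraction flags section, gazetteer and cue context", {
  txt <- "Personal History:\nHer mother is a builder."
  toks <- tokenize(txt)
  secs <- extract_personal_history(txt)
  f <- featurize(toks, default_gazetteer(), secs)
  builder_idx <- which(toks$lower == "builder")
  own <- f$f[f$i == builder_idx]
  expect_true("0|gaz" %in% own)
  expect_true("0|sec" %in% own)
  mother_idx <- which(toks$lower == "mother")
  expect_true("0|kin" %in% f$f[f$i == mother_idx])
  # determinism
  expect_identical(f, featurize(toks, default_gazetteer(), secs))
})

test_that("mention training validates its inputs", {
  corpus <- small_corpus()
  empty <- corpus
  empty$annotations <- empty$annotations[0, ]
  expect_error(train_mention_model(empty), "no annotated")
  few <- corpus
  keep_ids <- head(unique(few$annotations$doc_id), 3)
  few$annotations <- dplyr::filter(few$annotations, doc_id %in% keep_ids)
  expect_error(train_mention_model(few, split = NULL), "at least 10")
})

test_that("mention model training and prediction are deterministic", {
  fx <- trained_fixture()
  m2 <- train_mention_model(fx$corpus, seed = 5)
  vd <- split_docs(fx$corpus, "validation")
  p1 <- extract_occupations(head(vd, 20), fx$mention_model, NULL)$extractions
  p2 <- extract_occupations(head(vd, 20), m2, NULL)$extractions
  expect_identical(p1, p2)
})

test_that("the hybrid detector beats a gazetteer-only baseline on
           out-of-lexicon occupations", {
  fx <- trained_fixture()
  vd <- split_docs(fx$corpus, "validation")
  gold <- split_gold(fx$corpus, "validation")
  hybrid <- extract_occupations(vd, fx$mention_model, NULL)$extractions
  gaz_only <- extract_occupations(vd, NULL, NULL)$extractions
  eh <- precision_recall(gold, hybrid, mode = "span_only")
  eg <- precision_recall(gold, gaz_only, mode = "span_only")
  f1 <- function(e) 2 * e$precision * e$recall / (e$precision + e$recall)
  expect_gt(f1(eh), f1(eg))
  # union property: hybrid recall can never fall below gazetteer-only
  expect_gte(eh$recall, eg$recall)
})

test_that("overlap resolution equals the brute-force precedence oracle", {
  withr::local_seed(99)
  for (rep in 1:50) {
    n <- sample(1:6, 1)
    s <- sample(0:20, n, replace = TRUE)
    cand <- tibble::tibble(
      start = as.integer(s),
      end = as.integer(s + sample(1:5, n, replace = TRUE)),
      surface = "x", mention_kind = "title", label = "x",
      relation = NA_character_,
      from_gaz = sample(0:1, n, replace = TRUE)
    )
    got <- occumine:::resolve_candidates(cand)
    want <- oracle_resolve(cand)
    expect_equal(got[c("start", "end", "from_gaz")],
                 want[c("start", "end", "from_gaz")])
  }
})

test_that("detected spans never overlap and respect precedence rules", {
  fx <- trained_fixture()
  vd <- split_docs(fx$corpus, "test")
  res <- extract_occupations(head(vd, 40), fx$mention_model, NULL)
  by_doc <- split(res$extractions, res$extractions$doc_id)
  for (d in by_doc) {
    d <- dplyr::arrange(d, start)
    if (nrow(d) > 1L) {
      expect_true(all(d$end[-nrow(d)] <= d$start[-1]))
    }
  }
})

test_that("with no model and an empty gazetteer nothing is detected", {
  gz <- default_gazetteer()[0, ]
  doc <- tibble::tibble(doc_id = "d", text = "He works as a builder.")
  expect_equal(nrow(detect_mentions(doc, NULL, gz)), 0L)
})

test_that("distractor-only documents yield no mentions", {
  fx <- trained_fixture()
  doc <- tibble::tibble(doc_id = "d",
                        text = "He is working on his anxiety.")
  out <- detect_mentions(doc, fx$mention_model, default_gazetteer())
  expect_equal(nrow(out), 0L)
})

test_that("CRF-only detections without a normalisation get label 'other'", {
  fx <- trained_fixture()
  # held-out titles are absent from the gazetteer by construction
  doc <- tibble::tibble(
    doc_id = "d",
    text = "Personal History:\nHe works as a scaffolder."
  )
  out <- detect_mentions(doc, fx$mention_model, default_gazetteer())
  expect_equal(nrow(out), 1L)
  expect_equal(out$surface, "scaffolder")
  expect_equal(out$label, "other")
})

test_that("a model refuses text from a different tokenizer version", {
  fx <- trained_fixture()
  m <- fx$mention_model
  m$tokenizer <- "something-else"
  doc <- tibble::tibble(doc_id = "d", text = "She is a nurse.")
  expect_error(detect_mentions(doc, m), "tokenizer")
})

test_that("mention model artifacts round-trip through disk", {
  fx <- trained_fixture()
  f <- withr::local_tempfile(fileext = ".rds")
  write_mention_model(fx$mention_model, f)
  back <- read_mention_model(f)
  expect_identical(back$weights, fx$mention_model$weights)
  expect_identical(back$corpus_hash, fx$mention_model$corpus_hash)
})
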