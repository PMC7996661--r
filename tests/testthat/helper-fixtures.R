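# Shared fixtures and independent oracles for the test suite.

suppressPackageStartupMessages({
  library(dplyr)
})

# Small corpus used across tests; built once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    cfg <- synth_config(n_patients = 120, seed = 42)
    .fixture_env$corpus <- split_corpus(
      generate_corpus(cfg), 60, 30, 100,
      seed = 42
    )
  }
  .fixture_env$corpus
}

# Corpus whose occupation draws include upweighted out-of-lexicon titles,
# plus models trained on it; exercises the CRF beyond the gazetteer.
trained_fixture <- function() {
  if (is.null(.fixture_env$trained)) {
    lex <- occupation_lexicon()
    lex$weight[!lex$in_gazetteer] <- 0.03
    cfg <- synth_config(n_patients = 150, occupation_frequency = lex,
                        seed = 5)
    corpus <- split_corpus(generate_corpus(cfg), 100, 50, 100, seed = 5)
    .fixture_env$trained <- list(
      corpus = corpus,
      mention_model = train_mention_model(corpus, seed = 5),
      relation_model = train_relation_model(corpus, seed = 5)
    )
  }
  .fixture_env$trained
}

split_docs <- function(corpus, which) {
  ids <- corpus$split$doc_id[corpus$split$split == which]
  dplyr::filter(corpus$documents, doc_id %in% ids)
}

split_gold <- function(corpus, which) {
  ids <- corpus$split$doc_id[corpus$split$split == which]
  dplyr::filter(corpus$annotations, doc_id %in% ids)
}

# --- independent oracles -----------------------------------------------------

# maximum one-to-one matching size by exhaustive branch-and-bound
oracle_max_matching <- function(gold, pred, mode) {
  ng <- nrow(gold)
  np <- nrow(pred)
  if (ng == 0L || np == 0L) {
    return(0L)
  }
  compat <- matrix(FALSE, ng, np)
  for (g in seq_len(ng)) {
    compat[g, ] <- occumine:::match_compatible(gold[g, ], pred, mode)
  }
  best <- 0L
  rec <- function(g, used, size) {
    if (size + (ng - g + 1L) <= best) {
      return(invisible())
    }
    if (g > ng) {
      best <<- max(best, size)
      return(invisible())
    }
    for (p in which(compat[g, ] & !used)) {
      used[p] <- TRUE
      rec(g + 1L, used, size + 1L)
      used[p] <- FALSE
    }
    rec(g + 1L, used, size)
  }
  rec(1L, rep(FALSE, np), 0L)
  best
}

random_annotation_set <- function(n, text_len = 60L) {
  s <- sample.int(text_len - 2L, n, replace = TRUE) - 1L
  e <- s + sample.int(6L, n, replace = TRUE)
  tibble::tibble(
    doc_id = "D1", start = as.integer(s), end = as.integer(pmin(e, text_len)),
    surface = "x", mention_kind = "title", label = "x",
    relation = sample(c("patient", "family", "clinician", "other_person"),
                      n, replace = TRUE)
  )
}

# overlap resolution restated independently: repeatedly take the best
# remaining candidate (longest span, gazetteer on ties, then leftmost) and
# discard everything overlapping it.
oracle_resolve <- function(cand) {
  keep <- cand[0, ]
  while (nrow(cand) > 0L) {
    len <- cand$end - cand$start
    best <- order(-len, -cand$from_gaz, cand$start)[1]
    top <- cand[best, ]
    keep <- dplyr::bind_rows(keep, top)
    cand <- cand[!(cand$start < top$end & top$start < cand$end), ]
  }
  dplyr::arrange(keep, start)
}

# closed-form Cohen's kappa for a 2x2 table written independently
oracle_kappa_2x2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  (po - pe) / (1 - pe)
}
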