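tokenizer_version <- function() "occumine-tok-1"

# tokenised gazetteer: list of lowercase token sequences plus metadata,
# indexed by first token for O(1) candidate lookup.
compile_gazetteer <- function(gazetteer) {
  seqs <- purrr::map(gazetteer$surface, ~ tokenize(.x)$lower)
  keep <- lengths(seqs) > 0L
  gz <- gazetteer[keep, ]
  seqs <- seqs[keep]
  first <- vapply(seqs, `[[`, character(1), 1L)
  ord <- order(-lengths(seqs)) # longest first within a first-token bucket
  list(
    seqs = seqs[ord], first = first[ord],
    label = gz$label[ord], kind = gz$kind[ord],
    is_status = gz$is_status[ord]
  )
}

#' Dictionary matching of occupation mentions
#'
#' Case-insensitive, longest-match, left-to-right, non-overlapping matching
#' of gazetteer phrases against a token sequence.  Matching is over whole
#' tokens, so "worker" never fires inside "social worker" and overlapping
#' entries resolve to the longest phrase.
#'
#' @param tokens A token tibble from [tokenize()].
#' @param gazetteer A gazetteer tibble ([default_gazetteer()]).
#' @param text The original document text; used to recover exact surfaces
#'   (if omitted, token surfaces are joined with single spaces).
#' @return An annotations tibble (`relation` is `NA`: relations are assigned
#'   downstream).
#' @export
gazetteer_match <- function(tokens, gazetteer, text = NULL) {
  cg <- if (is.list(gazetteer) && !is.data.frame(gazetteer) &&
              !is.null(gazetteer$seqs)) {
    gazetteer
  } else {
    compile_gazetteer(gazetteer)
  }
  n <- nrow(tokens)
  out <- list()
  i <- 1L
  while (i <= n) {
    cand <- which(cg$first == tokens$lower[i])
    hit <- 0L
    hit_len <- 0L
    for (c in cand) {
      len <- length(cg$seqs[[c]])
      if (len <= hit_len) next # candidates are longest-first per bucket
      if (i + len - 1L <= n &&
          identical(tokens$lower[i:(i + len - 1L)], cg$seqs[[c]])) {
        hit <- c
        hit_len <- len
      }
    }
    if (hit > 0L) {
      s <- tokens$start[i]
      e <- tokens$end[i + hit_len - 1L]
      out[[length(out) + 1L]] <- tibble(
        start = s, end = e,
        surface = if (is.null(text)) {
          paste(tokens$surface[i:(i + hit_len - 1L)], collapse = " ")
        } else {
          slice_text(text, s, e)
        },
        mention_kind = cg$kind[hit], label = cg$label[hit],
        relation = NA_character_
      )
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (length(out)) bind_rows(out) else
    empty_annotations()[, -1] # no doc_id column at this level
}

#' Per-token feature extraction for the sequence tagger
#'
#' Emits sparse string-valued features per token: lowercase form, shape
#' flags (capitalised, digit, punctuation), gazetteer-hit and
#' gazetteer-begin flags, kinship-cue flag, clinician-cue flag and
#' personal-history-section membership — each for the token itself and for
#' its neighbours in a window of two tokens either side (prefixed with the
#' offset), plus a bias feature.  Deterministic for fixed input.
#'
#' @param tokens A token tibble.
#' @param gazetteer A gazetteer tibble or compiled gazetteer.
#' @param sections A section tibble for the document (may be empty).
#' @param window Neighbour window half-width.
#' @return A list with integer vector `i` (token index) and character vector
#'   `f` (feature name), suitable for building a sparse design matrix.
#' @export
featurize <- function(tokens, gazetteer, sections = NULL, window = 2L) {
  n <- nrow(tokens)
  if (n == 0L) {
    return(list(i = integer(), f = character(), n = 0L))
  }
  gm <- gazetteer_match(tokens, gazetteer)
  gaz_in <- rep(FALSE, n)
  gaz_b <- rep(FALSE, n)
  if (nrow(gm)) {
    for (r in seq_len(nrow(gm))) {
      idx <- which(tokens$start >= gm$start[r] & tokens$end <= gm$end[r])
      gaz_in[idx] <- TRUE
      if (length(idx)) gaz_b[idx[1]] <- TRUE
    }
  }
  cols <- list(
    paste0("w=", tokens$lower),
    ifelse(tokens$is_cap, "cap", NA_character_),
    ifelse(tokens$has_digit, "dig", NA_character_),
    ifelse(tokens$is_punct, "punct", NA_character_),
    ifelse(gaz_in, "gaz", NA_character_),
    ifelse(gaz_b, "gazB", NA_character_),
    ifelse(tokens$lower %in% kinship_cues(), "kin", NA_character_),
    ifelse(tokens$lower %in% clinician_cues(), "clin", NA_character_),
    ifelse(in_any_section(tokens$start, tokens$end, sections), "sec",
           NA_character_)
  )
  out_i <- list(seq_len(n))
  out_f <- list(rep("bias", n))
  idx <- seq_len(n)
  for (off in seq.int(-window, window)) {
    pre <- paste0(off, "|")
    src <- idx + off
    ok <- src >= 1L & src <= n
    for (ci in seq_along(cols)) {
      v <- ifelse(ok, cols[[ci]][pmax(pmin(src, n), 1L)], NA_character_)
      keep <- !is.na(v)
      if (ci == 1L) { # pad marker for the word column off the ends
        v[!ok] <- "w=<PAD>"
        keep <- rep(TRUE, n)
      }
      if (any(keep)) {
        out_i[[length(out_i) + 1L]] <- idx[keep]
        out_f[[length(out_f) + 1L]] <- paste0(pre, v[keep])
      }
    }
  }
  list(i = unlist(out_i), f = unlist(out_f), n = n)
}

# BIO tags (O=1, B=2, I=3) for tokens given gold spans
bio_tags <- function(tokens, spans) {
  tags <- rep(1L, nrow(tokens))
  if (!is.null(spans) && nrow(spans)) {
    for (r in seq_len(nrow(spans))) {
      idx <- which(tokens$start >= spans$start[r] &
                     tokens$end <= spans$end[r])
      if (length(idx)) {
        tags[idx] <- 3L
        tags[idx[1]] <- 2L
      }
    }
  }
  tags
}

# decode BIO tag vector to token-index spans (orphan I opens a span)
bio_decode <- function(tags) {
  out <- list()
  s <- NA_integer_
  for (i in seq_along(tags)) {
    if (tags[i] == 2L || (tags[i] == 3L && is.na(s))) {
      if (!is.na(s)) out[[length(out) + 1L]] <- c(s, i - 1L)
      s <- i
    } else if (tags[i] == 1L) {
      if (!is.na(s)) out[[length(out) + 1L]] <- c(s, i - 1L)
      s <- NA_integer_
    }
  }
  if (!is.na(s)) out[[length(out) + 1L]] <- c(s, length(tags))
  out
}

# assemble the sparse design matrix for a list of featurized docs
build_design <- function(feats, feat_index = NULL) {
  f_all <- unlist(purrr::map(feats, "f"))
  n_per <- vapply(feats, function(x) x$n, integer(1))
  offs <- cumsum(c(0L, head(n_per, -1L)))
  i_all <- unlist(purrr::map2(feats, offs, function(x, o) x$i + o))
  if (is.null(feat_index)) {
    feat_index <- setNames(seq_along(unique(f_all)), unique(f_all))
  }
  j <- unname(feat_index[f_all])
  keep <- !is.na(j)
  X <- Matrix::sparseMatrix(
    i = i_all[keep], j = j[keep], x = 1,
    dims = c(sum(n_per), length(feat_index))
  )
  list(X = X, feat_index = feat_index, n_per = n_per,
       starts = offs + 1L)
}

crf_negll <- function(par, X, tags, starts, lens, K, lambda, cache) {
  if (!is.null(cache$par) && identical(par, cache$par)) {
    return(cache)
  }
  n_feat <- ncol(X)
  init <- par[seq_len(K)]
  trans <- matrix(par[K + seq_len(K * K)], K, K)
  W <- matrix(par[K + K * K + seq_len(n_feat * K)], n_feat, K)
  E <- as.matrix(X %*% W)
  fb <- crf_forward_backward(E, starts, lens, trans, init)
  n <- nrow(E)
  gold_emit <- sum(E[cbind(seq_len(n), tags)])
  first <- tags[starts]
  obs_init <- tabulate(first, K)
  prev <- tags[-n]
  cur <- tags[-1]
  within <- !(seq_len(n - 1L) + 1L) %in% starts
  obs_trans <- matrix(0, K, K)
  tt <- table(factor(prev[within], levels = 1:K),
              factor(cur[within], levels = 1:K))
  obs_trans[] <- as.numeric(tt)
  gold <- gold_emit + sum(init[first]) +
    sum(trans * obs_trans)
  nll <- fb$logZ - gold + lambda / 2 * sum(par^2)
  D <- fb$marginals
  D[cbind(seq_len(n), tags)] <- D[cbind(seq_len(n), tags)] - 1
  gW <- as.matrix(Matrix::crossprod(X, D))
  grad <- c(fb$einit - obs_init, as.vector(fb$etrans - obs_trans),
            as.vector(gW)) + lambda * par
  cache$par <- par
  cache$value <- nll
  cache$grad <- grad
  cache
}

#' Train the occupation-mention sequence model
#'
#' Fits an L2-regularised linear-chain conditional random field over BIO
#' tags derived from the gold spans of the corpus's training split.
#' Optimisation is L-BFGS from a zero start, so training is fully
#' deterministic; the seed is recorded in the model metadata alongside the
#' corpus hash, feature template and tokenizer version.
#'
#' @param corpus An `occ_corpus` with a non-empty train split (or set
#'   `split = NULL` to train on all annotated documents).
#' @param gazetteer Gazetteer used for the dictionary-hit features.
#' @param split Which split to train on (default `"train"`).
#' @param lambda L2 regularisation strength.
#' @param maxit Maximum L-BFGS iterations.
#' @param seed Integer seed recorded in metadata.
#' @return An object of class `occ_mention_model`.
#' @export
train_mention_model <- function(corpus, gazetteer = default_gazetteer(),
                                split = "train", lambda = 0.1,
                                maxit = 100L, seed = 1L) {
  stopifnot(inherits(corpus, "occ_corpus"))
  ids <- if (is.null(split)) {
    corpus$documents$doc_id
  } else {
    corpus$split$doc_id[corpus$split$split %in% split]
  }
  docs <- filter(corpus$documents, .data$doc_id %in% ids)
  ann <- filter(corpus$annotations, .data$doc_id %in% ids)
  if (nrow(docs) == 0L || nrow(ann) == 0L) {
    abort("training split contains no annotated documents")
  }
  n_annotated <- length(unique(ann$doc_id))
  if (n_annotated < 10L) {
    abort(sprintf(
      "training requires at least 10 annotated documents (got %d)",
      n_annotated
    ))
  }
  cg <- compile_gazetteer(gazetteer)
  per_doc <- purrr::map(seq_len(nrow(docs)), function(i) {
    txt <- docs$text[i]
    toks <- tokenize(txt)
    secs <- extract_personal_history(txt)
    list(
      feats = featurize(toks, cg, secs),
      tags = bio_tags(toks, filter(ann, .data$doc_id == docs$doc_id[i]))
    )
  })
  per_doc <- purrr::keep(per_doc, ~ .x$feats$n > 0L)
  design <- build_design(purrr::map(per_doc, "feats"))
  tags <- unlist(purrr::map(per_doc, "tags"))
  K <- 3L
  n_par <- K + K * K + ncol(design$X) * K
  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    crf_negll(par, design$X, tags, design$starts, design$n_per, K, lambda,
              cache)$value
  }
  gr <- function(par) {
    crf_negll(par, design$X, tags, design$starts, design$n_per, K, lambda,
              cache)$grad
  }
  opt <- optim(rep(0, n_par), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit))
  structure(list(
    init = opt$par[seq_len(K)],
    trans = matrix(opt$par[K + seq_len(K * K)], K, K),
    weights = matrix(opt$par[K + K * K + seq_len(ncol(design$X) * K)],
                     ncol(design$X), K),
    feat_index = design$feat_index,
    tags = c("O", "B", "I"),
    tokenizer = tokenizer_version(),
    feature_template = "w/shape/gaz/kin/clin/sec, window 2, bias",
    corpus_hash = rlang::hash(list(docs$doc_id, docs$text, ann)),
    n_docs = nrow(docs), n_annotations = nrow(ann),
    lambda = lambda, maxit = maxit, seed = as.integer(seed),
    nll = opt$value, convergence = opt$convergence
  ), class = "occ_mention_model")
}

#' @export
print.occ_mention_model <- function(x, ...) {
  cat(sprintf(
    "<occ_mention_model> CRF over BIO tags: %d features, trained on %d docs (%d annotations)\n",
    nrow(x$weights), x$n_docs, x$n_annotations
  ))
  invisible(x)
}

#' @export
glance.occ_mention_model <- function(x, ...) {
  tibble(
    n_features = nrow(x$weights), n_docs = x$n_docs,
    n_annotations = x$n_annotations, lambda = x$lambda,
    nll = x$nll, converged = x$convergence == 0L
  )
}

#' Read or write a serialized mention model
#' @param model An `occ_mention_model`.
#' @param path File path for the model artifact.
#' @return `read_mention_model()` the model; `write_mention_model()` the
#'   path, invisibly.
#' @export
write_mention_model <- function(model, path) {
  stopifnot(inherits(model, "occ_mention_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_mention_model
#' @export
read_mention_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "occ_mention_model")) {
    abort("not a mention model artifact")
  }
  model
}

crf_predict_tags <- function(model, feats) {
  if (feats$n == 0L) {
    return(integer())
  }
  j <- unname(model$feat_index[feats$f])
  keep <- !is.na(j)
  X <- Matrix::sparseMatrix(
    i = feats$i[keep], j = j[keep], x = 1,
    dims = c(feats$n, length(model$feat_index))
  )
  E <- as.matrix(X %*% model$weights)
  crf_viterbi(E, 1L, feats$n, model$trans, model$init)
}

# precedence for overlapping candidate spans: longer span wins; on equal
# length the gazetteer span wins (it carries a normalisation); remaining
# ties resolve leftmost-first.
resolve_candidates <- function(cand) {
  if (nrow(cand) == 0L) {
    return(cand)
  }
  ord <- order(-(cand$end - cand$start), -cand$from_gaz, cand$start)
  cand <- cand[ord, ]
  chosen <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(spans_overlap(cand$start[i], cand$end[i],
                           cand$start[chosen], cand$end[chosen]))) {
      chosen <- c(chosen, i)
    }
  }
  arrange(cand[chosen, ], .data$start)
}

#' Detect occupation mentions in a document
#'
#' The hybrid detector of the extraction pipeline: the union of
#' sequence-model (CRF) spans and gazetteer spans.  Overlapping candidates
#' resolve by longer-span-wins; equal-length ties go to the gazetteer span,
#' which carries a normalised label.  CRF-only spans whose surface has no
#' gazetteer normalisation receive the special label `"other"` (these are
#' excluded later from patient-level profiles).  With a `NULL` model the
#' detector is purely rule-based.
#'
#' @param doc A one-row documents tibble (or list with `doc_id`, `text`).
#' @param model An `occ_mention_model`, or `NULL` for gazetteer-only.
#' @param gazetteer Gazetteer tibble or compiled gazetteer.
#' @param sections Optional precomputed section tibble for the document.
#' @return An annotations tibble with `relation = NA`.
#' @export
detect_mentions <- function(doc, model = NULL,
                            gazetteer = default_gazetteer(),
                            sections = NULL) {
  text <- doc$text[[1]]
  if (!is.null(model) && !identical(model$tokenizer, tokenizer_version())) {
    abort("model was trained with a different tokenizer version")
  }
  toks <- tokenize(text)
  if (nrow(toks) == 0L) {
    return(empty_annotations())
  }
  sections <- sections %||% extract_personal_history(text)
  cg <- if (is.data.frame(gazetteer)) compile_gazetteer(gazetteer) else
    gazetteer
  gz <- gazetteer_match(toks, cg, text)
  gz$from_gaz <- rep(1L, nrow(gz))
  crf_spans <- NULL
  if (!is.null(model)) {
    feats <- featurize(toks, cg, sections)
    tags <- crf_predict_tags(model, feats)
    spans <- bio_decode(tags)
    if (length(spans)) {
      crf_spans <- purrr::map(spans, function(s) {
        st <- toks$start[s[1]]
        en <- toks$end[s[2]]
        tibble(start = st, end = en, surface = slice_text(text, st, en),
               mention_kind = NA_character_, label = NA_character_,
               relation = NA_character_, from_gaz = 0L)
      }) |> bind_rows()
    }
  }
  cand <- bind_rows(gz, crf_spans)
  if (nrow(cand) == 0L) {
    return(empty_annotations())
  }
  res <- resolve_candidates(cand)
  # normalise CRF-only spans through the gazetteer where possible
  need <- is.na(res$label)
  if (any(need)) {
    lookup <- gazetteer_lookup(cg)
    key <- tolower(res$surface[need])
    hit <- match(key, lookup$surface)
    res$label[need] <- ifelse(is.na(hit), "other", lookup$label[hit])
    res$mention_kind[need] <- ifelse(
      is.na(hit),
      ifelse(grepl(" ", res$surface[need]), "description", "title"),
      lookup$kind[hit]
    )
  }
  res$doc_id <- rep(doc$doc_id[[1]] %||% NA_character_, nrow(res))
  res[c("doc_id", "start", "end", "surface", "mention_kind", "label",
        "relation")]
}

gazetteer_lookup <- function(cg) {
  tibble(
    surface = vapply(cg$seqs, paste, character(1), collapse = " "),
    label = cg$label, kind = cg$kind
  )
}
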