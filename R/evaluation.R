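# Scoring predicted annotations against gold, and inter-annotator agreement.

match_compatible <- function(g, p, mode) {
  switch(mode,
    strict_span_and_relation =
      g$start == p$start & g$end == p$end & g$relation == p$relation,
    span_only = g$start == p$start & g$end == p$end,
    lenient_overlap =
      spans_overlap(g$start, g$end, p$start, p$end) &
        g$relation == p$relation,
    abort(paste0("unknown matching mode: ", mode))
  )
}

#' Match predicted annotations to gold
#'
#' One-to-one matching between a gold and a predicted annotation set over
#' the same document.  `strict_span_and_relation` (the default, and the
#' definition of a true positive throughout) requires identical span and
#' identical relation; `span_only` drops the relation requirement;
#' `lenient_overlap` requires at least one character of span overlap plus a
#' relation match.  Gold annotations are processed greedily by start offset
#' with leftmost-first tie-breaking, with augmenting-path repair so the
#' matching is always of maximum size.
#'
#' @param gold,predicted Annotations tibbles over the same document.
#' @param mode Matching mode.
#' @return A list with `pairs` (tibble of `gold_idx`, `pred_idx`),
#'   `unmatched_gold` and `unmatched_pred` (integer row indices).
#' @export
match_annotations <- function(gold, predicted,
                              mode = c("strict_span_and_relation",
                                       "span_only", "lenient_overlap")) {
  mode <- match.arg(mode)
  if ("doc_id" %in% names(gold) && "doc_id" %in% names(predicted)) {
    ids <- unique(c(gold$doc_id, predicted$doc_id))
    if (length(ids) > 1L) {
      abort("gold and predicted annotations must reference one document")
    }
  }
  ng <- nrow(gold)
  np <- nrow(predicted)
  if (ng == 0L || np == 0L) {
    return(list(
      pairs = tibble(gold_idx = integer(), pred_idx = integer()),
      unmatched_gold = seq_len(ng), unmatched_pred = seq_len(np)
    ))
  }
  # adjacency: for each gold, the compatible predicted indices in start order
  pred_order <- order(predicted$start, predicted$end)
  adj <- purrr::map(seq_len(ng), function(i) {
    ok <- match_compatible(gold[i, ], predicted, mode)
    pred_order[ok[pred_order]]
  })
  match_of_pred <- rep(NA_integer_, np)
  vis <- rep(FALSE, np)
  # Kuhn's augmenting-path algorithm; golds in start order, candidate
  # predictions tried leftmost-first, so ties break leftmost while the
  # matching stays maximum.
  try_augment <- function(g) {
    for (p in adj[[g]]) {
      if (vis[p]) next
      vis[p] <<- TRUE
      if (is.na(match_of_pred[p]) || try_augment(match_of_pred[p])) {
        match_of_pred[p] <<- g
        return(TRUE)
      }
    }
    FALSE
  }
  for (g in order(gold$start, gold$end)) {
    vis <- rep(FALSE, np)
    try_augment(g)
  }
  pairs <- tibble(
    gold_idx = match_of_pred[!is.na(match_of_pred)],
    pred_idx = which(!is.na(match_of_pred))
  ) |> arrange(.data$gold_idx)
  list(
    pairs = pairs,
    unmatched_gold = setdiff(seq_len(ng), pairs$gold_idx),
    unmatched_pred = setdiff(seq_len(np), pairs$pred_idx)
  )
}

#' Precision and recall over a corpus
#'
#' Micro-averaged precision and recall: true-positive, false-positive and
#' false-negative counts are pooled over documents and the ratios computed
#' once.  `scope = "patient_only"` restricts both gold and predicted
#' annotations to `relation == "patient"` before matching.  Undefined ratios
#' (0/0) are reported as `NA`, never as 0: an empty run must not masquerade
#' as perfect or as failing.
#'
#' @param gold,predicted Annotations tibbles with `doc_id` columns.
#' @param mode Matching mode (see [match_annotations()]).
#' @param scope `"all_relations"` or `"patient_only"`.
#' @return A one-row tibble of class `occ_eval` with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `mode`, `scope`.
#' @export
precision_recall <- function(gold, predicted,
                             mode = "strict_span_and_relation",
                             scope = c("all_relations", "patient_only")) {
  scope <- match.arg(scope)
  if (scope == "patient_only") {
    gold <- filter(gold, .data$relation == "patient")
    predicted <- filter(predicted, .data$relation == "patient")
  }
  ids <- union(unique(gold$doc_id), unique(predicted$doc_id))
  tp <- fp <- fn <- 0L
  for (id in ids) {
    g <- filter(gold, .data$doc_id == id)
    p <- filter(predicted, .data$doc_id == id)
    m <- match_annotations(g, p, mode)
    tp <- tp + nrow(m$pairs)
    fn <- fn + length(m$unmatched_gold)
    fp <- fp + length(m$unmatched_pred)
  }
  out <- tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
    mode = mode, scope = scope
  )
  class(out) <- c("occ_eval", class(out))
  out
}

#' @export
print.occ_eval <- function(x, ...) {
  cat(sprintf(
    "<occ_eval> %s / %s: P=%s R=%s (tp=%d fp=%d fn=%d)\n",
    x$mode, x$scope,
    format(round(x$precision, 3)), format(round(x$recall, 3)),
    x$tp, x$fp, x$fn
  ))
  invisible(x)
}

# Cohen's kappa from a square agreement table
kappa_from_table <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n == 0) {
    return(list(kappa = NA_real_, p_o = NA_real_, p_e = NA_real_, n = 0L))
  }
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(kappa = kappa, p_o = p_o, p_e = p_e, n = as.integer(n))
}

#' Inter-annotator agreement (Cohen's kappa)
#'
#' Chance-corrected agreement between two annotators over the same
#' documents.  For `unit = "title"` the units are per-token binary
#' decisions: is the token inside any occupation mention?  For
#' `unit = "relation"` the units are mention pairs aligned by span overlap
#' between the two annotators, and the categories are the relation labels.
#' kappa = (p_o - p_e) / (1 - p_e) with marginal-based expected agreement.
#' Zero aligned units yield an `NA` kappa.
#'
#' @param annotator_a,annotator_b Annotations tibbles with `doc_id`.
#' @param docs The documents tibble both annotators cover.
#' @param unit `"title"` or `"relation"`.
#' @return A one-row tibble of class `occ_agreement`: `unit`, `kappa`,
#'   `p_o`, `p_e`, `n_units`.
#' @export
cohens_kappa <- function(annotator_a, annotator_b, docs,
                         unit = c("title", "relation")) {
  unit <- match.arg(unit)
  if (unit == "title") {
    a_all <- logical(0)
    b_all <- logical(0)
    for (i in seq_len(nrow(docs))) {
      toks <- tokenize(docs$text[i])
      if (nrow(toks) == 0L) next
      ga <- filter(annotator_a, .data$doc_id == docs$doc_id[i])
      gb <- filter(annotator_b, .data$doc_id == docs$doc_id[i])
      inside <- function(ann) {
        if (nrow(ann) == 0L) {
          return(rep(FALSE, nrow(toks)))
        }
        vapply(seq_len(nrow(toks)), function(t) {
          any(ann$start <= toks$start[t] & toks$end[t] <= ann$end)
        }, logical(1))
      }
      a_all <- c(a_all, inside(ga))
      b_all <- c(b_all, inside(gb))
    }
    tab <- table(factor(a_all, levels = c(FALSE, TRUE)),
                 factor(b_all, levels = c(FALSE, TRUE)))
    k <- kappa_from_table(tab)
  } else {
    labs <- relation_levels()
    a_lab <- character(0)
    b_lab <- character(0)
    for (id in unique(docs$doc_id)) {
      ga <- filter(annotator_a, .data$doc_id == id)
      gb <- filter(annotator_b, .data$doc_id == id)
      if (nrow(ga) == 0L || nrow(gb) == 0L) next
      m <- match_annotations(ga, gb, "span_only")
      ov <- m$pairs
      # span_only requires identical spans; extend to any-overlap alignment
      rest_g <- m$unmatched_gold
      rest_p <- m$unmatched_pred
      if (length(rest_g) && length(rest_p)) {
        mo <- match_annotations(
          mutate(ga[rest_g, ], relation = "x"),
          mutate(gb[rest_p, ], relation = "x"),
          "lenient_overlap"
        )
        ov <- bind_rows(ov, tibble(
          gold_idx = rest_g[mo$pairs$gold_idx],
          pred_idx = rest_p[mo$pairs$pred_idx]
        ))
      }
      a_lab <- c(a_lab, ga$relation[ov$gold_idx])
      b_lab <- c(b_lab, gb$relation[ov$pred_idx])
    }
    tab <- table(factor(a_lab, levels = labs), factor(b_lab, levels = labs))
    k <- kappa_from_table(tab)
  }
  out <- tibble(
    unit = unit, kappa = k$kappa, p_o = k$p_o, p_e = k$p_e, n_units = k$n
  )
  class(out) <- c("occ_agreement", class(out))
  out
}

#' @export
print.occ_agreement <- function(x, ...) {
  cat(sprintf(
    "<occ_agreement> unit=%s kappa=%s (p_o=%s, p_e=%s, n=%d)\n",
    x$unit, format(round(x$kappa, 3)), format(round(x$p_o, 3)),
    format(round(x$p_e, 3)), x$n_units
  ))
  invisible(x)
}
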