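#' Synthetic corpus configuration
#'
#' Parameters for the seeded synthetic psychiatric-note generator.  The
#' generator is template-based: sentence templates with slots filled from the
#' occupation lexicon, so every emitted mention has an exact gold annotation
#' and every distractor is guaranteed annotation-free.
#'
#' @param n_patients Number of patients.
#' @param docs_per_patient Poisson mean; each patient receives
#'   `rpois(1, docs_per_patient) + 1` documents.
#' @param p_personal_history_section Probability a document contains a
#'   personal-history section.
#' @param p_patient_mention,p_family_mention,p_clinician_trap Per-sentence
#'   emission probabilities inside a personal-history section for a
#'   patient-occupation sentence, a family/other-person sentence, and a
#'   clinician "trap" sentence ("Seen by Dr X, consultant psychiatrist").
#'   Clinician traps are also emitted at rate `p_clinician_trap` in the
#'   out-of-section narrative.
#' @param occupation_frequency Optional tibble like [occupation_lexicon()]
#'   providing the sampling weights; defaults to the shipped lexicon, whose
#'   weights make "student" and "unemployed" the dominant patient
#'   occupations.
#' @param structured_field_completeness Probability a patient has a coded
#'   occupational status in the structured field (13 categories).  The
#'   default 0.14 mirrors the sparsely completed structured fields that
#'   motivate text mining.
#' @param noise Per-sentence probability of a distractor sentence using a
#'   non-occupational "work" idiom (e.g. "working on his anxiety"); these
#'   never receive gold annotations.
#' @param seed Integer seed; one global seed drives all randomness.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_patients = 200,
                         docs_per_patient = 2,
                         p_personal_history_section = 0.7,
                         p_patient_mention = 0.5,
                         p_family_mention = 0.2,
                         p_clinician_trap = 0.1,
                         occupation_frequency = NULL,
                         structured_field_completeness = 0.14,
                         noise = 0.1,
                         seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("`n_patients` must be >= 1")
  }
  for (nm in c("p_personal_history_section", "p_patient_mention",
               "p_family_mention", "p_clinician_trap",
               "structured_field_completeness", "noise")) {
    assert_prob(get(nm), nm)
  }
  if (p_patient_mention + p_family_mention + p_clinician_trap + noise > 1) {
    abort("per-sentence probabilities must sum to at most 1")
  }
  lex <- occupation_frequency %||% occupation_lexicon()
  structure(list(
    n_patients = as.integer(n_patients),
    docs_per_patient = docs_per_patient,
    p_personal_history_section = p_personal_history_section,
    p_patient_mention = p_patient_mention,
    p_family_mention = p_family_mention,
    p_clinician_trap = p_clinician_trap,
    occupation_frequency = lex,
    structured_field_completeness = structured_field_completeness,
    noise = noise,
    seed = as.integer(seed)
  ), class = "synth_config")
}

surnames <- function() {
  c("Smith", "Patel", "Jones", "Okafor", "Nguyen", "Brown", "Khan",
    "Taylor", "Williams", "Olsen", "Martin", "Campbell", "Ahmed",
    "Murphy", "Clarke", "Osei", "Kowalski", "Evans", "Singh", "Moretti")
}

# sentence builders ----------------------------------------------------------
# each returns list(text=, ann=tibble(rel_start, rel_end, surface,
# mention_kind, label, relation)) with offsets relative to the sentence.

tpl_mention <- function(before, occ_surface, after, kind, label, relation) {
  list(
    text = paste0(before, occ_surface, after),
    ann = tibble(
      rel_start = nchar(before),
      rel_end = nchar(before) + nchar(occ_surface),
      surface = occ_surface, mention_kind = kind,
      label = label, relation = relation
    )
  )
}

tpl_plain <- function(text) list(text = text, ann = NULL)

sent_patient <- function(occ, pro) {
  Pro <- capitalise(pro)
  if (occ$is_status && occ$label %in% c("unemployed", "retired",
                                        "self-employed")) {
    pick <- sample(2L, 1L)
    if (pick == 1L) {
      tpl_mention(paste0(Pro, " is currently "), occ$surface, ".",
                  occ$kind, occ$label, "patient")
    } else {
      tpl_mention(paste0(Pro, " has been "), occ$surface, " for some time.",
                  occ$kind, occ$label, "patient")
    }
  } else if (occ$kind == "description") {
    pick <- sample(2L, 1L)
    if (pick == 1L) {
      tpl_mention(paste0(Pro, " works in "), occ$surface, ".",
                  occ$kind, occ$label, "patient")
    } else {
      tpl_mention(paste0(Pro, " has a background in "), occ$surface, ".",
                  occ$kind, occ$label, "patient")
    }
  } else {
    pick <- sample(3L, 1L)
    before <- switch(pick,
      paste0(Pro, " works as a "),
      paste0(Pro, " is a "),
      paste0(Pro, " previously worked as a ")
    )
    tpl_mention(before, occ$surface, ".", occ$kind, occ$label, "patient")
  }
}

sent_family <- function(occ, poss) {
  other <- runif(1) < 0.15
  who <- if (other) sample(other_person_cues(), 1L) else
    sample(kinship_cues(), 1L)
  relation <- if (other) "other_person" else "family"
  Poss <- capitalise(poss)
  if (occ$kind == "description") {
    tpl_mention(paste0(Poss, " ", who, " works in "), occ$surface, ".",
                occ$kind, occ$label, relation)
  } else if (occ$is_status && occ$label %in% c("unemployed", "retired",
                                               "self-employed")) {
    tpl_mention(paste0(Poss, " ", who, " is currently "), occ$surface, ".",
                occ$kind, occ$label, relation)
  } else {
    pick <- sample(2L, 1L)
    before <- if (pick == 1L) paste0(Poss, " ", who, " is a ") else
      paste0(Poss, " ", who, " works as a ")
    tpl_mention(before, occ$surface, ".", occ$kind, occ$label, relation)
  }
}

sent_trap <- function(lex) {
  hc <- lex[lex$is_healthcare, ]
  row <- hc[sample(nrow(hc), 1L), ]
  verb <- sample(c("Seen by", "Reviewed by", "Assessed by"), 1L)
  name <- sample(surnames(), 1L)
  tpl_mention(paste0(verb, " Dr ", name, ", "), row$surface, ".",
              "title", row$label, "clinician")
}

sent_noise <- function(pro, poss) {
  pool <- c(
    paste0(capitalise(pro), " is working on ", poss, " anxiety."),
    paste0(capitalise(pro), " has been working through some difficult feelings."),
    "They discussed working towards recovery goals.",
    paste0(capitalise(pro), " is working on sleep hygiene."),
    "The plan is to keep working on coping strategies."
  )
  tpl_plain(sample(pool, 1L))
}

sent_filler <- function(pro) {
  pool <- c(
    "Sleep has been poor recently.",
    "Appetite remains stable.",
    paste0(capitalise(pro), " attended on time."),
    "Mood was reported as low.",
    "No concerns were raised today.",
    paste0(capitalise(pro), " engaged well in the session.")
  )
  tpl_plain(sample(pool, 1L))
}

capitalise <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# join sentence pieces with a separator, accumulating annotation offsets
join_pieces <- function(pieces, offset0, sep = " ") {
  texts <- character(length(pieces))
  anns <- list()
  off <- offset0
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    texts[i] <- p$text
    if (!is.null(p$ann)) {
      a <- p$ann
      a$start <- as.integer(a$rel_start + off)
      a$end <- as.integer(a$rel_end + off)
      anns[[length(anns) + 1L]] <- a[c("start", "end", "surface",
                                       "mention_kind", "label", "relation")]
    }
    off <- off + nchar(p$text) + if (i < length(pieces)) nchar(sep) else 0L
  }
  list(text = paste(texts, collapse = sep), ann = bind_rows(anns))
}

#' Generate a synthetic annotated corpus
#'
#' Produces seeded synthetic psychiatric notes with exact gold-standard
#' occupation annotations, planted personal-history sections, a patient
#' covariate table and a structured occupational-status field table.
#' Deterministic given the config seed: the same config yields byte-identical
#' corpora.
#'
#' @param config A [synth_config()].
#' @return An object of class `occ_corpus`: a list with tibbles `documents`,
#'   `annotations` (gold), `sections` (planted personal-history spans),
#'   `patients` (covariates), `structured` (patient_id, status_code 1-13),
#'   `split` (all `"unassigned"` until [split_corpus()]), and the `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lex <- config$occupation_frequency
  patient_pool <- lex[lex$weight > 0, ]
  family_pool <- lex
  family_pool$weight[family_pool$is_healthcare] <-
    mean(patient_pool$weight)
  withr::with_seed(stage_seed(config$seed, "corpus"), {
    docs <- list()
    anns <- list()
    secs <- list()
    patients <- list()
    structured <- list()
    doc_counter <- 0L
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%05d", i)
      age <- sample(16:90, 1L)
      gender <- sample(c("male", "female", "other_not_known"), 1L,
                       prob = c(0.48, 0.50, 0.02))
      pro <- switch(gender, male = "he", female = "she", "they")
      poss <- switch(gender, male = "his", female = "her", "their")
      n_occ <- sample(1:4, 1L)
      occ_rows <- patient_pool[
        sample(nrow(patient_pool), n_occ, prob = patient_pool$weight), ]
      patients[[i]] <- tibble(
        patient_id = pid, age = age, gender = gender,
        age_band = cut(age, c(15, 29, 49, 69, 89, Inf),
                       labels = c("16-29", "30-49", "50-69", "70-89", "90+")),
        ethnicity = sample(
          c("white_british", "black_caribbean", "black_african", "other",
            "not_known"), 1L, prob = c(0.40, 0.10, 0.05, 0.18, 0.27)),
        marital = sample(
          c("married", "single", "divorced", "widowed", "not_known"), 1L,
          prob = c(0.14, 0.41, 0.05, 0.05, 0.35)),
        deprivation = sample(
          c("least_deprived", "q3", "q2", "most_deprived", "not_known"), 1L,
          prob = c(0.233, 0.233, 0.233, 0.234, 0.067)),
        diagnosis = sample(
          c("mood", "organic", "substance", "schizophrenia", "neurotic",
            "other", "not_known"), 1L,
          prob = c(0.11, 0.09, 0.08, 0.05, 0.09, 0.36, 0.22)),
        events_quartile = sample(
          c("no_events", "least_events", "q2", "q3", "most_events"), 1L,
          prob = c(0.15, 0.25, 0.18, 0.20, 0.22)),
        beddays_band = sample(
          c("none", "low", "moderate", "high"), 1L,
          prob = c(0.91, 0.005, 0.031, 0.054))
      )
      if (runif(1) < config$structured_field_completeness) {
        structured[[length(structured) + 1L]] <- tibble(
          patient_id = pid, status_code = sample(1:13, 1L)
        )
      }
      n_docs <- rpois(1L, config$docs_per_patient) + 1L
      for (d in seq_len(n_docs)) {
        doc_counter <- doc_counter + 1L
        did <- sprintf("D%06d", doc_counter)
        doc_type <- sample(doc_types(), 1L,
                           prob = c(0.35, 0.35, 0.12, 0.08, 0.10))
        piece_open <- list(tpl_plain(sample(c(
          "Attended outpatient clinic today.",
          "Routine review appointment.",
          "Telephone consultation with the community team.",
          "Ward round entry."
        ), 1L)))
        if (runif(1) < config$p_clinician_trap) {
          piece_open[[2L]] <- sent_trap(lex)
        } else if (runif(1) < config$noise) {
          piece_open[[2L]] <- sent_noise(pro, poss)
        } else {
          piece_open[[2L]] <- sent_filler(pro)
        }
        opening <- join_pieces(piece_open, 0L)
        text <- paste0(opening$text, "\n")
        doc_ann <- list(opening$ann)
        has_ph <- runif(1) < config$p_personal_history_section
        if (has_ph) {
          header <- "Personal History:\n"
          sec_start <- nchar(text) + nchar(header)
          n_sent <- sample(3:6, 1L)
          ph_pieces <- purrr::map(seq_len(n_sent), function(s) {
            u <- runif(1)
            p1 <- config$p_patient_mention
            p2 <- p1 + config$p_family_mention
            p3 <- p2 + config$p_clinician_trap
            p4 <- p3 + config$noise
            if (u < p1) {
              sent_patient(occ_rows[sample(nrow(occ_rows), 1L), ], pro)
            } else if (u < p2) {
              sent_family(
                family_pool[sample(nrow(family_pool), 1L,
                                   prob = family_pool$weight), ], poss)
            } else if (u < p3) {
              sent_trap(lex)
            } else if (u < p4) {
              sent_noise(pro, poss)
            } else {
              sent_filler(pro)
            }
          })
          ph <- join_pieces(ph_pieces, sec_start)
          text <- paste0(text, header, ph$text, "\n")
          doc_ann[[length(doc_ann) + 1L]] <- ph$ann
          secs[[length(secs) + 1L]] <- tibble(
            doc_id = did, start = sec_start, end = nchar(text),
            header_matched = "Personal History"
          )
        }
        text <- paste0(text, "Medication:\nSertraline 50mg daily.\n",
                       "Plan:\nContinue current care plan.\n")
        docs[[doc_counter]] <- tibble(
          doc_id = did, patient_id = pid, doc_type = doc_type,
          text = text, age = age
        )
        da <- bind_rows(doc_ann)
        if (nrow(da)) {
          da$doc_id <- did
          anns[[length(anns) + 1L]] <- da[c(
            "doc_id", "start", "end", "surface", "mention_kind", "label",
            "relation"
          )]
        }
      }
    }
    documents <- clinical_documents(bind_rows(docs))
    corpus <- structure(list(
      documents = documents,
      annotations = bind_rows(anns) %||% empty_annotations(),
      sections = bind_rows(secs),
      patients = bind_rows(patients),
      structured = bind_rows(structured) %||%
        tibble(patient_id = character(), status_code = integer()),
      split = tibble(doc_id = documents$doc_id, split = "unassigned"),
      config = config
    ), class = "occ_corpus")
    if (nrow(corpus$annotations) == 0L) {
      corpus$annotations <- empty_annotations()
    }
    if (nrow(corpus$structured) == 0L) {
      corpus$structured <- tibble(patient_id = character(),
                                  status_code = integer())
    }
    corpus
  })
}

#' @export
print.occ_corpus <- function(x, ...) {
  cat(sprintf(
    "<occ_corpus> %d documents, %d patients, %d gold annotations\n",
    nrow(x$documents), nrow(x$patients), nrow(x$annotations)
  ))
  spl <- table(x$split$split)
  cat("  splits:", paste(names(spl), spl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Split a corpus into train/validation/test
#'
#' Assigns documents that contain a personal-history section to disjoint
#' train/validation/test splits.  Splitting is by patient: all of one
#' patient's eligible documents land in the same split, so no patient can
#' leak between training and evaluation.  Split sizes therefore may deviate
#' from the requested counts only by whole-patient rounding; with the
#' synthetic generator's small per-patient document counts the requested
#' sizes are normally hit exactly.
#'
#' @param corpus An `occ_corpus`.
#' @param n_train,n_validation,n_test Requested document counts.
#' @param seed Integer seed for the patient shuffle.
#' @return The corpus with an updated `split` tibble.
#' @export
split_corpus <- function(corpus, n_train, n_validation, n_test, seed = 1L) {
  stopifnot(inherits(corpus, "occ_corpus"))
  sections <- corpus$sections %||% extract_sections(corpus$documents)
  eligible <- corpus$documents |>
    filter(.data$doc_id %in% unique(sections$doc_id)) |>
    select("doc_id", "patient_id")
  need <- c(train = n_train, validation = n_validation, test = n_test)
  if (sum(need) > nrow(eligible)) {
    abort(sprintf(
      "requested %d documents but only %d contain a personal-history section",
      sum(need), nrow(eligible)
    ))
  }
  counts <- eligible |> count(.data$patient_id)
  withr::with_seed(stage_seed(seed, "split"), {
    counts <- counts[sample(nrow(counts)), ]
  })
  assignment <- setNames(rep("unassigned", nrow(counts)), counts$patient_id)
  avail <- rep(TRUE, nrow(counts))
  for (split_name in names(need)) {
    r <- need[[split_name]]
    while (r > 0L && any(avail)) {
      idx <- which(avail & counts$n <= r)
      if (length(idx) == 0L) {
        # no patient fits exactly: accept the smallest overshoot
        cand <- which(avail)
        idx <- cand[which.min(counts$n[cand])]
      } else {
        idx <- idx[1L]
      }
      assignment[counts$patient_id[idx]] <- split_name
      avail[idx] <- FALSE
      r <- r - counts$n[idx]
    }
  }
  split <- corpus$documents |>
    select("doc_id", "patient_id") |>
    left_join(tibble(patient_id = names(assignment), s = unname(assignment)),
              by = "patient_id") |>
    mutate(
      split = if_else(
        .data$doc_id %in% eligible$doc_id & !is.na(.data$s),
        .data$s, "unassigned"
      ),
      split = if_else(is.na(.data$split), "unassigned", .data$split)
    ) |>
    select("doc_id", "split")
  corpus$split <- split
  corpus
}

#' Simulate patient profiles with known associations
#'
#' Generates patient-level occupation-recording outcomes from a logistic
#' model with a known odds ratio for the highest service-contact band, for
#' parameter-recovery checks of [fit_association_models()].  All other
#' covariates are null by construction.
#'
#' @param n_patients Number of patients.
#' @param or_most_events True odds ratio of occupation recording for the
#'   `most_events` band versus `no_events`; intermediate bands interpolate
#'   the log odds linearly.
#' @param baseline_p Probability of occupation recording in the reference
#'   band.
#' @param seed Integer seed.
#' @return A profiles tibble with `patient_id`, `has_occupation`, and factor
#'   covariates `events_quartile`, `beddays_band`, `gender`, `age_band`.
#' @export
simulate_profiles <- function(n_patients = 2000, or_most_events = 2,
                              baseline_p = 0.35, seed = 1L) {
  ev_levels <- c("no_events", "least_events", "q2", "q3", "most_events")
  withr::with_seed(stage_seed(seed, "profile"), {
    ev <- factor(sample(ev_levels, n_patients, replace = TRUE),
                 levels = ev_levels)
    beta <- seq(0, log(or_most_events), length.out = 5L)
    eta <- stats::qlogis(baseline_p) + beta[as.integer(ev)]
    tibble(
      patient_id = sprintf("P%05d", seq_len(n_patients)),
      has_occupation = runif(n_patients) < plogis(eta),
      events_quartile = ev,
      beddays_band = factor(
        sample(c("none", "low", "moderate", "high"), n_patients, TRUE,
               prob = c(0.7, 0.1, 0.1, 0.1)),
        levels = c("none", "low", "moderate", "high")
      ),
      gender = factor(sample(c("male", "female"), n_patients, TRUE)),
      age_band = factor(sample(c("16-29", "30-49", "50-69", "70+"),
                               n_patients, TRUE))
    )
  })
}
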