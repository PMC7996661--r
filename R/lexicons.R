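# Occupation lexicon, gazetteer accessors and cue lexicons.
#
# The lexicon covers three kinds of extraction target: occupation *titles*
# ("builder"), occupation *descriptions* ("construction"), and occupational
# *statuses* ("student", "unemployed", ...).  Statuses are legitimate targets:
# at patient level the dominant recorded "occupations" in mental-health
# records are statuses.  Healthcare entries are flagged so the
# healthcare-occupation filter and the synthetic generator can treat them
# specially.  A small set of titles is deliberately excluded from the default
# gazetteer (`in_gazetteer = FALSE`): the generator still emits them, so a
# purely dictionary-based detector must miss them and a trained sequence
# model can prove its worth on context alone.

occ_titles <- c(
  "builder", "teacher", "accountant", "chef", "cleaner", "electrician",
  "plumber", "carpenter", "mechanic", "hairdresser", "barber", "waiter",
  "waitress", "bartender", "shop assistant", "retail worker", "cashier",
  "security guard", "taxi driver", "bus driver", "lorry driver",
  "delivery driver", "postman", "warehouse operative", "factory worker",
  "labourer", "painter", "decorator", "gardener", "farmer", "fisherman",
  "butcher", "baker", "florist", "tailor", "jeweller", "optician",
  "pharmacist", "dentist", "veterinary surgeon", "engineer",
  "software developer", "programmer", "web designer", "graphic designer",
  "architect", "surveyor", "estate agent", "banker", "financial analyst",
  "economist", "lawyer", "solicitor", "barrister", "paralegal",
  "journalist", "editor", "writer", "author", "translator", "librarian",
  "teaching assistant", "lecturer", "professor", "researcher", "scientist",
  "lab technician", "pilot", "flight attendant", "sailor", "soldier",
  "police officer", "firefighter", "paramedic", "musician", "actor",
  "actress", "dancer", "photographer", "artist", "sculptor", "tattooist",
  "chauffeur", "courier", "removal man", "window cleaner", "caretaker",
  "receptionist", "secretary", "personal assistant", "call handler",
  "customer adviser", "sales representative", "shopkeeper", "market trader",
  "dry cleaner", "launderette attendant", "kitchen porter", "dinner lady",
  "nursery assistant", "childminder", "dog walker", "fitness instructor",
  "personal trainer", "lifeguard", "referee", "bookmaker", "croupier",
  "drug dealer", "sex worker", "busker", "fortune teller"
)

occ_titles_holdout <- c(
  "panel beater", "scaffolder", "locksmith", "bricklayer", "glazier",
  "roofer", "welder", "upholsterer", "stonemason", "french polisher",
  "signwriter", "fishmonger"
)

occ_descriptions <- c(
  "construction", "catering", "retail", "finance", "marketing",
  "advertising", "insurance", "hospitality", "manufacturing",
  "engineering", "childcare", "cleaning", "security", "transport",
  "logistics", "administration", "accountancy", "journalism", "farming",
  "plumbing"
)

occ_statuses <- c("student", "unemployed", "retired", "carer", "self-employed")

# healthcare entries: label -> surface variants (all gazetteer entries)
occ_healthcare <- list(
  psychiatrist = c("psychiatrist", "consultant psychiatrist",
                   "trainee psychiatrist"),
  doctor = c("doctor", "gp", "general practitioner", "junior doctor"),
  nurse = c("nurse", "mental health nurse", "staff nurse",
            "community psychiatric nurse"),
  `social worker` = "social worker",
  therapist = c("therapist", "occupational therapist", "psychotherapist"),
  psychologist = c("psychologist", "clinical psychologist"),
  counsellor = "counsellor",
  `support worker` = "support worker",
  `care coordinator` = "care coordinator"
)

#' Occupation lexicon
#'
#' The full lexicon used by both the synthetic-note generator and the default
#' gazetteer, with sampling weights.  Statuses carry most of the mass
#' ("student" and "unemployed" dominate, as they do at patient level in
#' mental-health registers); titles and descriptions share the remaining mass
#' on a Zipf-like tail.
#'
#' @return A tibble with columns `surface`, `label`, `kind`
#'   (`"title"`/`"description"`/`"status"` collapsed to title/description for
#'   annotation purposes via `mention_kind`), `is_status`, `is_healthcare`,
#'   `in_gazetteer`, `weight`.
#' @export
occupation_lexicon <- function() {
  base <- bind_rows(
    tibble(
      surface = occ_titles, label = occ_titles, kind = "title",
      is_status = FALSE, is_healthcare = FALSE, in_gazetteer = TRUE
    ),
    tibble(
      surface = occ_titles_holdout, label = occ_titles_holdout,
      kind = "title", is_status = FALSE, is_healthcare = FALSE,
      in_gazetteer = FALSE
    ),
    tibble(
      surface = occ_descriptions, label = occ_descriptions,
      kind = "description", is_status = FALSE, is_healthcare = FALSE,
      in_gazetteer = TRUE
    ),
    tibble(
      surface = occ_statuses, label = occ_statuses, kind = "title",
      is_status = TRUE, is_healthcare = FALSE, in_gazetteer = TRUE
    ),
    tibble(
      surface = unlist(occ_healthcare, use.names = FALSE),
      label = rep(names(occ_healthcare), lengths(occ_healthcare)),
      kind = "title", is_status = FALSE, is_healthcare = TRUE,
      in_gazetteer = TRUE
    )
  )
  # sampling weights over distinct labels (per-label, split over surfaces)
  status_w <- c(
    student = 0.20, unemployed = 0.20, carer = 0.12,
    `self-employed` = 0.08, retired = 0.07
  )
  lab <- unique(base$label[!base$is_healthcare & !base$is_status])
  tail_w <- 0.33 / seq_along(lab)
  tail_w <- tail_w / sum(tail_w) * 0.33
  w <- c(status_w, setNames(tail_w, lab))
  base$weight <- unname(w[base$label])
  base$weight[base$is_healthcare] <- 0 # never drawn as a patient occupation
  base
}

#' Default gazetteer
#'
#' The subset of [occupation_lexicon()] shipped for dictionary matching.
#' @return A tibble with columns `surface`, `label`, `kind`, `is_status`.
#' @seealso [read_gazetteer()], [write_gazetteer()]
#' @export
default_gazetteer <- function() {
  occupation_lexicon() |>
    filter(.data$in_gazetteer) |>
    select("surface", "label", "kind", "is_status") |>
    arrange(.data$surface)
}

#' Read or write a gazetteer file
#'
#' TSV with header `surface`, `normalized_label`, `kind`, `is_status`;
#' surfaces are lowercased on read.
#' @param path Path to a gazetteer TSV.
#' @param gazetteer A gazetteer tibble as from [default_gazetteer()].
#' @return `read_gazetteer()` a gazetteer tibble; `write_gazetteer()` the
#'   path, invisibly.
#' @export
read_gazetteer <- function(path) {
  gz <- readr::read_tsv(path, col_types = readr::cols(
    surface = readr::col_character(), normalized_label = readr::col_character(),
    kind = readr::col_character(), is_status = readr::col_logical()
  ))
  gz |>
    mutate(surface = tolower(.data$surface)) |>
    rename(label = "normalized_label")
}

#' @rdname read_gazetteer
#' @export
write_gazetteer <- function(gazetteer, path) {
  gazetteer |>
    rename(normalized_label = "label") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Healthcare occupation filter list
#'
#' Normalised labels for health and social care occupations that must never
#' be attributed to the patient: variations on psychiatrists and doctors,
#' therapists, nurses and social workers.  The list is a configurable starter
#' set; [read_healthcare_filter()] loads one label per line from a plain-text
#' file.
#' @param path Path to a plain-text filter file (one lowercase label per line).
#' @return A character vector of normalised labels.
#' @export
default_healthcare_filter <- function() {
  sort(names(occ_healthcare))
}

#' @rdname default_healthcare_filter
#' @export
read_healthcare_filter <- function(path) {
  x <- readr::read_lines(path)
  x <- tolower(trimws(x))
  x[nzchar(x)]
}

# Cue lexicons ---------------------------------------------------------------

kinship_cues <- function() {
  c(
    "mother", "father", "mum", "dad", "brother", "sister", "son",
    "daughter", "wife", "husband", "partner", "aunt", "uncle",
    "grandmother", "grandfather", "cousin", "stepfather", "stepmother"
  )
}

clinician_cues <- function() {
  c("dr", "consultant", "cpn", "seen", "reviewed", "assessed", "clinic")
}

other_person_cues <- function() {
  c("friend", "neighbour", "flatmate", "colleague", "landlord", "lodger")
}
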