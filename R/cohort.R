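# Patient-level aggregation: profiles, occupation rankings, and logistic
# models of occupation recording.

#' Build patient occupation profiles
#'
#' Merges text-mined annotations with the structured occupational-status
#' field into one row per patient.  `extracted_labels` keeps only
#' patient-relation extractions, excluding the low-precision `"other"`
#' label and any label on the healthcare filter list.  `has_occupation` is
#' TRUE when the patient has a structured status or at least one qualifying
#' extraction — the binary outcome modelled by
#' [fit_association_models()].
#'
#' @param annotations Annotations tibble with `patient_id` (e.g. the
#'   `extractions` output of [run_extract()], or gold annotations joined to
#'   documents).
#' @param structured Tibble with `patient_id`, `status_code` (1-13).
#'   Duplicate rows per patient keep the first, with a warning.
#' @param filter Healthcare filter labels.
#' @param patients Optional patient roster (tibble with `patient_id` and any
#'   covariate columns, carried through).  Defaults to the union of patients
#'   seen in either source; pass the full roster so that percentage
#'   denominators cover all patients.
#' @return A tibble of class `occ_profiles`: `patient_id`,
#'   `structured_status`, `extracted_labels` (list column), `n_distinct`,
#'   `has_occupation`, plus any covariates.
#' @export
build_profiles <- function(annotations, structured,
                           filter = default_healthcare_filter(),
                           patients = NULL) {
  if (anyDuplicated(structured$patient_id)) {
    warn("duplicate structured rows per patient: keeping the first")
    structured <- structured[!duplicated(structured$patient_id), ]
  }
  ann <- dplyr::filter(
    annotations,
    .data$relation == "patient",
    .data$label != "other",
    !(.data$label %in% .env$filter)
  )
  by_patient <- ann |>
    group_by(.data$patient_id) |>
    summarise(extracted_labels = list(sort(unique(.data$label))),
              .groups = "drop")
  roster <- if (is.null(patients)) {
    tibble(patient_id = union(structured$patient_id,
                              unique(annotations$patient_id)))
  } else {
    as_tibble(patients)
  }
  out <- roster |>
    left_join(select(structured, "patient_id",
                     structured_status = "status_code"),
              by = "patient_id") |>
    left_join(by_patient, by = "patient_id") |>
    mutate(
      extracted_labels = purrr::map(.data$extracted_labels,
                                    ~ .x %||% character(0)),
      n_distinct = lengths(.data$extracted_labels),
      has_occupation = !is.na(.data$structured_status) | .data$n_distinct > 0L
    )
  class(out) <- c("occ_profiles", class(out))
  out
}

#' Rank extracted occupations across patients
#'
#' Patient-level counting: a label counts once per patient regardless of how
#' many times it was extracted.  Percentages are computed over all patients
#' in the profile table (pass the full roster to [build_profiles()] to make
#' that "all patients", the denominator used when profiling a register).
#' Ordering is by patient count, ties broken alphabetically.
#'
#' @param profiles An `occ_profiles` tibble.
#' @param k Number of rows to return; a `k` beyond the number of distinct
#'   labels returns the full table.
#' @return A tibble with `label`, `n_patients`, `pct_patients`.
#' @export
top_occupations <- function(profiles, k = 5L) {
  n_total <- nrow(profiles)
  tab <- profiles |>
    select("patient_id", "extracted_labels") |>
    tidyr::unnest(cols = "extracted_labels") |>
    count(label = .data$extracted_labels, name = "n_patients") |>
    arrange(dplyr::desc(.data$n_patients), .data$label) |>
    mutate(pct_patients = 100 * .data$n_patients / n_total)
  head(tab, k)
}

#' Summarise distinct occupation counts per patient
#'
#' Median and quartiles of the number of distinct extracted occupation
#' labels among patients with at least one extraction.  Both the
#' interquartile endpoints and the width are reported, so the summary is
#' unambiguous.
#'
#' @param profiles An `occ_profiles` tibble.
#' @return A one-row tibble: `n_patients`, `median`, `q1`, `q3`,
#'   `iqr_width` (all `NA` when no patient has an extraction).
#' @export
distinct_count_summary <- function(profiles) {
  x <- profiles$n_distinct[profiles$n_distinct > 0L]
  if (length(x) == 0L) {
    return(tibble(n_patients = 0L, median = NA_real_, q1 = NA_real_,
                  q3 = NA_real_, iqr_width = NA_real_))
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(
    n_patients = length(x), median = q[2], q1 = q[1], q3 = q[3],
    iqr_width = q[3] - q[1]
  )
}

# fit one glm and extract OR rows for `var`, with Wald 95% CIs and an LRT
or_rows <- function(data, var, adjust_vars) {
  rhs <- paste(c(var, adjust_vars), collapse = " + ")
  full <- glm(as.formula(paste("has_occupation ~", rhs)),
              data = data, family = binomial())
  reduced_rhs <- if (length(adjust_vars)) {
    paste(adjust_vars, collapse = " + ")
  } else {
    "1"
  }
  reduced <- glm(as.formula(paste("has_occupation ~", reduced_rhs)),
                 data = data, family = binomial())
  lrt <- anova(reduced, full, test = "LRT")
  lrt_p <- lrt$`Pr(>Chi)`[2]
  cf <- coef(full)
  se <- sqrt(diag(vcov(full)))
  lv <- levels(factor(data[[var]]))
  nm <- paste0(var, lv)
  est <- cf[nm]
  s <- se[nm]
  # perfect separation / rank deficiency: flag, report NA
  bad <- !is.na(est) & (abs(est) > 10 | s > 100)
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf("possible separation for %s: estimate(s) reported as NA",
                 var))
  }
  or <- exp(est)
  lo <- exp(est - 1.96 * s)
  hi <- exp(est + 1.96 * s)
  or[bad] <- lo[bad] <- hi[bad] <- NA_real_
  tibble(
    variable = var, level = lv,
    or = if_else(lv == lv[1], 1, unname(or)),
    ci_low = if_else(lv == lv[1], NA_real_, unname(lo)),
    ci_high = if_else(lv == lv[1], NA_real_, unname(hi)),
    lrt_p = lrt_p
  )
}

#' Logistic models of occupation recording
#'
#' For each categorical predictor, fits three logistic regressions of the
#' binary "occupation recorded" outcome: crude (the predictor alone),
#' service-adjusted (plus the service-contact variables, i.e. events and
#' bed-days bands), and fully adjusted (plus every other predictor).  Odds
#' ratios carry Wald 95 percent confidence intervals; each variable's
#' overall association is tested with a likelihood-ratio test against the
#' nested model without it.  Reference levels are reported with OR 1 and an
#' empty interval.  Collinearity among predictors is the caller's concern;
#' suspected separation is flagged per level and reported as `NA`.
#'
#' @param profiles An `occ_profiles` tibble (needs `has_occupation` plus the
#'   predictor columns).
#' @param predictors Character vector of predictor column names.
#' @param service_vars The service-contact adjustment set (must be a subset
#'   of `predictors` columns present in `profiles`).
#' @return A tibble of class `occ_associations`: one row per predictor
#'   level per model, with `model` in `"crude"`, `"service_adjusted"`,
#'   `"fully_adjusted"`.
#' @export
fit_association_models <- function(profiles,
                                   predictors = c("age_band", "gender",
                                                  "events_quartile",
                                                  "beddays_band"),
                                   service_vars = c("events_quartile",
                                                    "beddays_band")) {
  missing_cols <- setdiff(c("has_occupation", predictors), names(profiles))
  if (length(missing_cols)) {
    abort(paste0("profiles are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(profiles)
  for (v in predictors) {
    data[[v]] <- factor(data[[v]])
    if (nlevels(droplevels(data[[v]])) < 2L) {
      abort(sprintf("predictor %s has fewer than 2 observed levels", v))
    }
    data[[v]] <- droplevels(data[[v]])
  }
  counts <- purrr::map(predictors, function(v) {
    data |>
      group_by(level = as.character(.data[[v]])) |>
      summarise(
        n = dplyr::n(),
        pct_recorded = 100 * mean(.data$has_occupation),
        .groups = "drop"
      ) |>
      mutate(variable = v)
  }) |> bind_rows()
  out <- purrr::map(predictors, function(v) {
    crude <- or_rows(data, v, character(0)) |> mutate(model = "crude")
    service <- or_rows(data, v, setdiff(service_vars, v)) |>
      mutate(model = "service_adjusted")
    full <- or_rows(data, v, setdiff(predictors, v)) |>
      mutate(model = "fully_adjusted")
    bind_rows(crude, service, full)
  }) |>
    bind_rows() |>
    left_join(counts, by = c("variable", "level")) |>
    select("variable", "level", "n", "pct_recorded", "model", "or",
           "ci_low", "ci_high", "lrt_p")
  class(out) <- c("occ_associations", class(out))
  out
}

#' @export
tidy.occ_associations <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.occ_associations <- function(x, ...) {
  tibble(
    n_variables = length(unique(x$variable)),
    n_levels = nrow(x) / length(unique(x$model)),
    models = paste(unique(x$model), collapse = ";")
  )
}

#' @export
tidy.occ_profiles <- function(x, ...) {
  as_tibble(x) |>
    select(-"extracted_labels") |>
    mutate(n_distinct = x$n_distinct)
}

#' @export
glance.occ_profiles <- function(x, ...) {
  tibble(
    n_patients = nrow(x),
    pct_structured = 100 * mean(!is.na(x$structured_status)),
    pct_extracted = 100 * mean(x$n_distinct > 0),
    pct_any = 100 * mean(x$has_occupation)
  )
}
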