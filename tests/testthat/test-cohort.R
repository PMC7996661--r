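prof_ann <- function(patient_id, label, relation = "patient") {
  tibble::tibble(
    doc_id = "d", patient_id = patient_id, start = 0L,
    end = nchar(label), surface = label, mention_kind = "title",
    label = label, relation = relation
  )
}

test_that("profiles merge structured and text-mined occupations", {
  ann <- dplyr::bind_rows(
    prof_ann("p1", "builder"),
    prof_ann("p2", "other"),
    prof_ann("p3", "psychiatrist"),
    prof_ann("p4", "teacher", relation = "family")
  )
  structured <- tibble::tibble(patient_id = "p5", status_code = 2L)
  prof <- build_profiles(ann, structured)
  get <- function(p) prof[prof$patient_id == p, ]
  expect_true(get("p1")$has_occupation)
  expect_equal(get("p1")$extracted_labels[[1]], "builder")
  # 'other' extractions never count
  expect_false(get("p2")$has_occupation)
  # healthcare labels never count toward the patient
  expect_false(get("p3")$has_occupation)
  # family occupations never count toward the patient
  expect_false(get("p4")$has_occupation)
  # structured-only patients count
  expect_true(get("p5")$has_occupation)
  expect_equal(get("p5")$n_distinct, 0L)
})

test_that("duplicate structured rows keep the first with a warning", {
  structured <- tibble::tibble(patient_id = c("p1", "p1"),
                               status_code = c(3L, 9L))
  expect_warning(
    prof <- build_profiles(prof_ann("p2", "chef"), structured),
    "duplicate"
  )
  expect_equal(prof$structured_status[prof$patient_id == "p1"], 3L)
})

test_that("retrieval counts obey set arithmetic", {
  corpus <- small_corpus()
  gold <- dplyr::left_join(
    corpus$annotations,
    corpus$documents[c("doc_id", "patient_id")], by = "doc_id"
  )
  prof <- build_profiles(gold, corpus$structured,
                         patients = corpus$patients)
  s_only <- sum(!is.na(prof$structured_status) & prof$n_distinct == 0L)
  t_only <- sum(is.na(prof$structured_status) & prof$n_distinct > 0L)
  both <- sum(!is.na(prof$structured_status) & prof$n_distinct > 0L)
  expect_equal(sum(prof$has_occupation), s_only + t_only + both)
  # combined retrieval can never fall below structured-only retrieval
  expect_gte(mean(prof$has_occupation),
             mean(!is.na(prof$structured_status)))
})

test_that("top occupations are counted once per patient over all patients", {
  ann <- dplyr::bind_rows(
    prof_ann("p1", "student"), prof_ann("p1", "student"),
    prof_ann("p2", "student"), prof_ann("p3", "builder")
  )
  prof <- build_profiles(
    ann, tibble::tibble(patient_id = character(), status_code = integer()),
    patients = tibble::tibble(patient_id = c("p1", "p2", "p3", "p4"))
  )
  top <- top_occupations(prof, 10)
  expect_equal(top$label[1], "student")
  expect_equal(top$n_patients[1], 2L)
  expect_equal(top$pct_patients[1], 50) # over all 4 patients
  # alphabetical tie-break
  ann2 <- dplyr::bind_rows(prof_ann("p1", "zoo keeper"),
                           prof_ann("p2", "baker"))
  prof2 <- build_profiles(
    ann2, tibble::tibble(patient_id = character(), status_code = integer())
  )
  expect_equal(top_occupations(prof2, 2)$label, c("baker", "zoo keeper"))
})

test_that("student and unemployed dominate under default frequencies", {
  corpus <- generate_corpus(synth_config(n_patients = 500, seed = 7))
  gold <- dplyr::left_join(
    corpus$annotations,
    corpus$documents[c("doc_id", "patient_id")], by = "doc_id"
  )
  prof <- build_profiles(gold, corpus$structured,
                         patients = corpus$patients)
  top <- top_occupations(prof, 5)
  expect_setequal(top$label[1:2], c("student", "unemployed"))
})

test_that("distinct-count summaries handle the edge cases", {
  prof1 <- build_profiles(
    dplyr::bind_rows(prof_ann("p1", "chef"), prof_ann("p2", "baker")),
    tibble::tibble(patient_id = character(), status_code = integer())
  )
  s <- distinct_count_summary(prof1)
  expect_equal(s$median, 1)
  expect_equal(s$iqr_width, 0)
  empty <- build_profiles(
    prof_ann("p", "chef")[0, ],
    tibble::tibble(patient_id = character(), status_code = integer())
  )
  expect_true(is.na(distinct_count_summary(empty)$median))
})

test_that("association models recover a built-in odds ratio", {
  prof <- simulate_profiles(n_patients = 4000, or_most_events = 2,
                            seed = 31)
  res <- fit_association_models(prof,
                                predictors = c("events_quartile", "gender"))
  crude <- dplyr::filter(res, variable == "events_quartile",
                         model == "crude", level == "most_events")
  expect_true(crude$ci_low < 2 & 2 < crude$ci_high)
  # reference rows are OR 1 with empty intervals
  ref <- dplyr::filter(res, level %in% c("no_events"), model == "crude")
  expect_equal(ref$or, 1)
  expect_true(is.na(ref$ci_low))
  # a null predictor should not show association
  gender_p <- dplyr::filter(res, variable == "gender",
                            model == "crude")$lrt_p[1]
  expect_gt(gender_p, 0.001)
})

test_that("association fitting validates degenerate predictors", {
  prof <- simulate_profiles(n_patients = 200, seed = 1)
  prof$gender <- factor("male", levels = c("male", "female"))
  expect_error(fit_association_models(prof, predictors = "gender"),
               "fewer than 2")
})

test_that("tidiers summarise profiles and associations", {
  prof <- simulate_profiles(n_patients = 500, seed = 2)
  res <- fit_association_models(prof, predictors = c("events_quartile",
                                                     "gender"))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("variable", "level", "model", "or", "lrt_p") %in%
                    names(td)))
  gl <- glance(res)
  expect_equal(gl$n_variables, 2L)
})
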