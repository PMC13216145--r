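test_that("duration categories follow the stated band edges", {
  expect_equal(duration_category(2), 0L)
  expect_equal(duration_category(c(4, 24)), c(1L, 1L))  # boundaries to lower band
  expect_equal(duration_category(c(24.5, 72)), c(2L, 2L))
  expect_equal(duration_category(100), 3L)
  expect_error(duration_category(0), "> 0")
})

test_that("C1 intensity bands, including the overlapping boundary at 4", {
  expect_equal(score_intensity_change(5, 5), 0)
  expect_equal(score_intensity_change(4, 7), 2)
  expect_equal(score_intensity_change(3, 8), 4)
  expect_equal(score_intensity_change(4, 8), 4)   # exactly 4 takes the >= 4 band
  expect_equal(score_intensity_change(8, 3), 0)   # improvement never scores
  expect_error(score_intensity_change(11, 5), "\\[0, 10\\]")
})

test_that("C2 lateralization: strict table vs lenient prose variant", {
  expect_equal(score_lateralization("contralateral", "ipsilateral"), 2L)
  expect_equal(score_lateralization("ipsilateral", "ipsilateral"), 0L)
  expect_equal(score_lateralization("ipsilateral", "contralateral"), 0L)
  expect_equal(score_lateralization("bilateral", "ipsilateral"), 0L)
  lenient <- scoring_config(lenient_lateralization = TRUE)
  expect_equal(score_lateralization("bilateral", "ipsilateral", lenient), 2L)
  expect_equal(score_lateralization("ipsilateral", "ipsilateral", lenient), 0L)
})

test_that("C3 duration transitions score 1 per category, 4 for multi-jumps", {
  expect_equal(score_duration_change(12, 12), 0)
  expect_equal(score_duration_change(12, 48), 1)
  expect_equal(score_duration_change(2, 100), 4)
  expect_equal(score_duration_change(100, 2), 0)
  ## the printed-table variant (+5) stays available through configuration
  cfg5 <- scoring_config(c3_multi_jump_points = 5)
  expect_equal(score_duration_change(2, 100, cfg5), 5)
})

test_that("C4 counts new symptoms only, nausea double", {
  expect_equal(score_symptom_change(character(0), "nausea"), 2)
  expect_equal(score_symptom_change("photophobia", "photophobia"), 0)
  expect_equal(score_symptom_change("nausea", c("vomiting", "photophobia")), 2)
  expect_equal(score_symptom_change(character(0),
                                    c("nausea", "vomiting", "photophobia",
                                      "phonophobia", "visual_disturbances")), 6)
  expect_error(score_symptom_change(character(0), "dizziness"),
               "unknown symptom")
})

test_that("C5 requires both the 5-day floor and the 50% relative increase", {
  expect_equal(score_frequency_change(4, 10), 4)
  expect_equal(score_frequency_change(10, 14), 0)  # fails both conditions
  expect_equal(score_frequency_change(12, 17), 0)  # 5 days but only 42%
  expect_equal(score_frequency_change(8, 13), 4)   # 5 days and 62.5%
  expect_equal(score_frequency_change(0, 6), 4)    # headache-free baseline
  expect_equal(score_frequency_change(0, 4), 0)    # still needs 5 days
  expect_error(score_frequency_change(-1, 5), ">= 0")
})

test_that("C6 converts similarity to dissimilarity before banding", {
  expect_equal(score_dissimilarity(9, "dissimilarity"), 4)
  expect_equal(score_dissimilarity(3, "dissimilarity"), 0)
  expect_equal(score_dissimilarity(3, "similarity"), 2)  # d = 7
  expect_equal(score_dissimilarity(1, "similarity"), 4)  # d = 9
  expect_error(score_dissimilarity(12, "similarity"), "\\[0, 10\\]")
})

test_that("compute_score: the three pathways", {
  ## headache-naive with post headache: diagnostic 9 points
  naive <- mk_record(prior_headache_diagnosis = "none", pre_present = FALSE,
                     pre_nrs = NA, pre_mhd = NA, pre_duration_h = NA,
                     pre_laterality = NA, pre_symptoms = NA, pre_amn = NA,
                     similarity_rating = NA,
                     patient_reported_direction = "not_applicable")
  b <- compute_score(naive)
  expect_equal(b$pathway, "new_onset_B")
  expect_equal(b$total, 9)
  expect_true(b$is_post_pipeline)

  ## worked pre-existing example: components (2,2,1,2,4,2), total 13
  worked <- mk_record(pre_nrs = 4, post3m_nrs = 7,
                      pre_laterality = "contralateral",
                      post3m_laterality = "ipsilateral",
                      pre_duration_h = 12, post3m_duration_h = 48,
                      pre_symptoms = "none", post3m_symptoms = "nausea",
                      pre_mhd = 4, post3m_mhd = 10,
                      similarity_rating = 3,  # dissimilarity 7
                      patient_reported_direction = "worse")
  b <- compute_score(worked)
  expect_equal(unlist(b[c("c1_intensity", "c2_lateralization", "c3_duration",
                          "c4_symptoms", "c5_frequency", "c6_dissimilarity")],
                      use.names = FALSE),
               c(2, 2, 1, 2, 4, 2))
  expect_equal(b$total, 13)
  expect_true(b$is_post_pipeline)

  ## all bands below their floors
  quiet <- mk_record(pre_nrs = 5, post3m_nrs = 6, similarity_rating = 7)
  b <- compute_score(quiet)
  expect_equal(b$total, 0)
  expect_false(b$is_post_pipeline)

  ## no post headache
  none <- mk_record(post3m_present = FALSE, post3m_nrs = NA, post3m_mhd = NA,
                    post3m_duration_h = NA, post3m_laterality = NA,
                    post3m_symptoms = NA, post3m_amn = NA,
                    similarity_rating = NA,
                    patient_reported_direction = "improved")
  b <- compute_score(none)
  expect_equal(b$pathway, "not_applicable")
  expect_equal(b$total, 0)
  expect_false(b$is_post_pipeline)
})

test_that("missing inputs on an applicable criterion raise, never score 0", {
  rec <- mk_record(similarity_rating = NA)
  expect_error(compute_score(rec), "insufficient data")
  expect_error(compute_score(rec), "similarity_rating")
  rec2 <- mk_record(post3m_mhd = NA)
  expect_error(compute_score(rec2), "post3m_mhd")
})

test_that("outcome classification implements the five-way taxonomy", {
  classify1 <- function(rec) {
    s <- compute_score(rec)
    as.character(classify_outcome(rec, s))
  }
  never <- mk_record(prior_headache_diagnosis = "none", pre_present = FALSE,
                     pre_nrs = NA, pre_mhd = NA, pre_duration_h = NA,
                     pre_laterality = NA, pre_symptoms = NA, pre_amn = NA,
                     post3m_present = FALSE, post3m_nrs = NA, post3m_mhd = NA,
                     post3m_duration_h = NA, post3m_laterality = NA,
                     post3m_symptoms = NA, post3m_amn = NA,
                     similarity_rating = NA, criterion_A = NA, criterion_D = NA,
                     patient_reported_direction = "not_applicable")
  expect_equal(classify1(never), "never")

  ## improvement wins regardless of feature changes
  imp <- mk_record(patient_reported_direction = "improved",
                   post3m_nrs = 9, post3m_mhd = 20, similarity_rating = 0)
  expect_equal(classify1(imp), "improvement")

  ## minimal worsening below threshold is "no change"
  minimal <- mk_record(patient_reported_direction = "worse", post3m_nrs = 8)
  s <- compute_score(minimal)
  expect_lt(s$total, 9)
  expect_equal(as.character(classify_outcome(minimal, s)), "no_change")

  ## worsening above threshold
  worse <- mk_record(patient_reported_direction = "worse",
                     pre_nrs = 3, post3m_nrs = 8, pre_mhd = 4, post3m_mhd = 12,
                     similarity_rating = 1)
  expect_equal(classify1(worse), "worsening")

  ## transient naive headache has no bucket: error by default, flag on demand
  transient <- mk_record(prior_headache_diagnosis = "none", pre_present = FALSE,
                         pre_nrs = NA, pre_mhd = NA, pre_duration_h = NA,
                         pre_laterality = NA, pre_symptoms = NA, pre_amn = NA,
                         similarity_rating = NA, criterion_A = FALSE,
                         patient_reported_direction = "not_applicable")
  st <- compute_score(transient)
  expect_error(classify_outcome(transient, st), "unclassified_transient")
  expect_equal(as.character(classify_outcome(transient, st, transient = "flag")),
               "unclassified_transient")
})

test_that("every record gets exactly one category and counts conserve n", {
  for (seed in c(11, 12)) {
    sim <- simulate_cohort(sim_config(n_patients = 150), seed = seed)
    sc <- score_cohort(sim$cohort)
    oc <- classify_cohort(sim$cohort, sc)
    expect_false(anyNA(oc))
    expect_equal(sum(table(oc)), 150)
    ## is_post_pipeline <=> category in {new_onset, worsening}
    expect_equal(sc$is_post_pipeline, oc %in% c("new_onset", "worsening"))
  }
})

test_that("total is bounded by the configured component maxima", {
  cohort <- random_scoreable_cohort(400, seed = 7)
  sc <- score_cohort(cohort)
  px <- sc$pathway == "preexisting_C"
  expect_true(all(sc$total[px] >= 0 & sc$total[px] <= max(24, 25)))
  expect_true(all(sc$total[px] <= postpipe:::max_preexisting_total()))
  expect_true(all(sc$total[sc$pathway == "new_onset_B"] == 9))
  expect_true(all(sc$total[sc$pathway == "not_applicable"] == 0))
  ## B and C pathways are mutually exclusive in the breakdown
  expect_true(all(sc$b_naive[px] == 0))
  comp <- sc$c1_intensity + sc$c2_lateralization + sc$c3_duration +
    sc$c4_symptoms + sc$c5_frequency + sc$c6_dissimilarity
  expect_true(all(comp[sc$b_naive > 0] == 0))
  expect_equal(sc$total, sc$b_naive + comp)
})
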