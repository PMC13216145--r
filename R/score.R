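## The post-pipe score: a composite of clinician-required criteria (A:
## persistence >= 3 months, D: no better ICHD-3 explanation) plus either a
## diagnostic 9 points for headache-naive patients (criterion B) or six
## change criteria C1-C6 comparing the pre-procedural headache with the
## 3-month post-procedural one. Diagnostic threshold: A + D + B/C >= 9.

#' Scoring configuration
#'
#' All band edges and point values live in one object so the ROC machinery
#' can sweep cut-offs without touching scoring code.
#'
#' @param threshold Diagnostic threshold on the total score (default 9).
#' @param c3_multi_jump_points Points for a jump of two or more duration
#'   categories. The published table and prose disagree (5 vs 4); the default
#'   follows the unambiguous prose value 4.
#' @param lenient_lateralization If `FALSE` (default) only a
#'   contralateral-to-ipsilateral shift scores C2, the strict table reading;
#'   if `TRUE`, any shift from a non-ipsilateral laterality to ipsilateral
#'   scores, mirroring the looser "toward the aneurysm side" phrasing.
#' @param intensity_bands NRS-difference edges for +2 / +4 (default `c(2, 4)`;
#'   a difference of exactly 4 earns +4).
#' @param dissimilarity_bands Dissimilarity edges for +2 / +4 (default
#'   `c(6, 8)`).
#' @param duration_breaks Attack-duration category edges in hours; categories
#'   are `<4`, `[4,24]`, `(24,72]`, `>72` (boundaries assigned to the lower
#'   band, ICHD-style inclusive upper limits).
#' @param frequency_min_days Minimum absolute increase in monthly headache
#'   days for C5 (default 5).
#' @param frequency_min_rel Minimum relative increase for C5 (default 0.5).
#' @param naive_points Diagnostic points on the headache-naive pathway B.
#' @return A list of class `pp_scoring_config`.
#' @export
scoring_config <- function(threshold = 9,
                           c3_multi_jump_points = 4,
                           lenient_lateralization = FALSE,
                           intensity_bands = c(2, 4),
                           dissimilarity_bands = c(6, 8),
                           duration_breaks = c(4, 24, 72),
                           frequency_min_days = 5,
                           frequency_min_rel = 0.5,
                           naive_points = 9) {
  stopifnot(threshold > 0, c3_multi_jump_points >= 0,
            length(intensity_bands) == 2, diff(intensity_bands) > 0,
            length(dissimilarity_bands) == 2, diff(dissimilarity_bands) > 0,
            length(duration_breaks) == 3, all(diff(duration_breaks) > 0))
  structure(list(threshold = threshold,
                 c3_multi_jump_points = c3_multi_jump_points,
                 lenient_lateralization = isTRUE(lenient_lateralization),
                 intensity_bands = intensity_bands,
                 dissimilarity_bands = dissimilarity_bands,
                 duration_breaks = duration_breaks,
                 frequency_min_days = frequency_min_days,
                 frequency_min_rel = frequency_min_rel,
                 naive_points = naive_points),
            class = "pp_scoring_config")
}

## Largest total reachable on the pre-existing pathway under a configuration:
## C1 4 + C2 2 + C3 max(1, multi) + C4 6 (four +1 symptoms plus nausea +2) +
## C5 4 + C6 4.
max_preexisting_total <- function(config = scoring_config()) {
  4 + 2 + max(1, config$c3_multi_jump_points) + 6 + 4 + 4
}

#' Attack-duration category
#'
#' Categories `<4 h`, `4-24 h`, `24-72 h`, `>72 h`, indexed 0..3. Touching
#' printed labels are disambiguated by assigning boundaries to the lower
#' band: 24 h is category 1, 72 h category 2.
#'
#' @param hours Typical attack duration in hours, > 0 (vectorised).
#' @param config A [scoring_config()].
#' @return Integer category index in 0..3.
#' @export
duration_category <- function(hours, config = scoring_config()) {
  if (any(is.na(hours)) || any(hours <= 0))
    stop("attack duration must be > 0 hours")
  b <- config$duration_breaks
  as.integer((hours >= b[1]) + (hours > b[2]) + (hours > b[3]))
}

#' C1: pain-intensity change
#'
#' Difference `post - pre` on the 0-10 NRS: +2 for a difference in
#' `[2, 4)`, +4 for `>= 4` (the overlapping printed labels "2-4" and ">= 4"
#' are resolved in favour of the higher band at exactly 4). Decreases score 0;
#' the score measures worsening only.
#'
#' @param pre_nrs,post_nrs Mean pain intensity, 0-10.
#' @param config A [scoring_config()].
#' @return Points in `{0, 2, 4}`.
#' @export
score_intensity_change <- function(pre_nrs, post_nrs,
                                   config = scoring_config()) {
  if (any(is.na(pre_nrs)) || any(is.na(post_nrs)) ||
      any(pre_nrs < 0 | pre_nrs > 10) || any(post_nrs < 0 | post_nrs > 10))
    stop("NRS intensity must be in [0, 10]")
  d <- post_nrs - pre_nrs
  b <- config$intensity_bands
  ifelse(d >= b[2], 4, ifelse(d >= b[1], 2, 0))
}

#' C2: lateralization change with respect to the aneurysm side
#'
#' Strict reading: +2 only for contralateral to ipsilateral; every other
#' transition, including any involving bilateral or unknown, scores 0. With
#' `lenient_lateralization = TRUE` any non-ipsilateral pre laterality moving
#' to ipsilateral scores +2.
#'
#' @param pre_lat,post_lat Relative laterality (`"ipsilateral"`,
#'   `"contralateral"`, `"bilateral"`, `"unknown"`).
#' @param config A [scoring_config()].
#' @return Points in `{0, 2}`.
#' @export
score_lateralization <- function(pre_lat, post_lat,
                                 config = scoring_config()) {
  ok <- function(x) x %in% .pp_lateralities
  if (!all(ok(pre_lat)) || !all(ok(post_lat)))
    stop("laterality must be one of: ", paste(.pp_lateralities, collapse = ", "))
  if (config$lenient_lateralization)
    2L * as.integer(post_lat == "ipsilateral" & pre_lat != "ipsilateral")
  else
    2L * as.integer(pre_lat == "contralateral" & post_lat == "ipsilateral")
}

#' C3: attack-duration category change
#'
#' One point for a single upward category transition, `c3_multi_jump_points`
#' (default 4) for two or more; shortening scores 0.
#'
#' @param pre_hours,post_hours Typical attack duration in hours, > 0.
#' @param config A [scoring_config()].
#' @return Points.
#' @export
score_duration_change <- function(pre_hours, post_hours,
                                  config = scoring_config()) {
  k <- duration_category(post_hours, config) -
    duration_category(pre_hours, config)
  ifelse(k >= 2, config$c3_multi_jump_points, ifelse(k == 1, 1, 0))
}

#' C4: new-onset associated symptoms
#'
#' Symptoms present after but not before the procedure: +1 each for
#' vomiting, photophobia, phonophobia and visual disturbances; +2 for
#' nausea. Lost symptoms contribute 0.
#'
#' @param pre_symptoms,post_symptoms Character vectors (one symptom set) or
#'   lists of such vectors.
#' @return Points (0..6 per record).
#' @export
score_symptom_change <- function(pre_symptoms, post_symptoms) {
  if (!is.list(pre_symptoms)) pre_symptoms <- list(pre_symptoms)
  if (!is.list(post_symptoms)) post_symptoms <- list(post_symptoms)
  pts <- c(nausea = 2, vomiting = 1, photophobia = 1, phonophobia = 1,
           visual_disturbances = 1)
  mapply(function(pre, post) {
    pre <- as.character(pre[!is.na(pre)])
    post <- as.character(post[!is.na(post)])
    unknown <- setdiff(c(pre, post), .pp_symptoms)
    if (length(unknown) > 0)
      stop("unknown symptom token: ", paste(unknown, collapse = ", "))
    sum(pts[setdiff(post, pre)])
  }, pre_symptoms, post_symptoms)
}

#' C5: headache-frequency change
#'
#' +4 when frequency increased by at least `frequency_min_days` monthly
#' headache days AND by at least `frequency_min_rel` relative to baseline.
#' A baseline of 0 days (patient headache-free in the reference window)
#' satisfies the relative condition; the absolute floor still applies.
#'
#' @param pre_mhd,post_mhd Monthly headache days, >= 0.
#' @param config A [scoring_config()].
#' @return Points in `{0, 4}`.
#' @export
score_frequency_change <- function(pre_mhd, post_mhd,
                                   config = scoring_config()) {
  if (any(is.na(pre_mhd)) || any(is.na(post_mhd)) ||
      any(pre_mhd < 0) || any(post_mhd < 0))
    stop("monthly headache days must be >= 0")
  d <- post_mhd - pre_mhd
  rel_ok <- pre_mhd == 0 | d / ifelse(pre_mhd == 0, 1, pre_mhd) >=
    config$frequency_min_rel
  4L * as.integer(d >= config$frequency_min_days & rel_ok)
}

#' C6: subjective dissimilarity
#'
#' Patients rate the similarity between the post-procedural headache and
#' their usual headache from 0 (very different) to 10 (identical); the score
#' bands apply to the dissimilarity scale `d = 10 - rating`: +4 for
#' `d >= 8`, +2 for `6 <= d < 8`, else 0. A rating already expressed as a
#' dissimilarity can be passed with `scale = "dissimilarity"`.
#'
#' @param rating Patient-reported rating, 0-10.
#' @param scale Scale the rating was collected on.
#' @param config A [scoring_config()].
#' @return Points in `{0, 2, 4}`.
#' @export
score_dissimilarity <- function(rating, scale = c("similarity", "dissimilarity"),
                                config = scoring_config()) {
  scale <- match.arg(scale)
  if (any(is.na(rating)) || any(rating < 0 | rating > 10))
    stop("similarity/dissimilarity rating must be in [0, 10]")
  d <- if (scale == "similarity") 10 - rating else rating
  b <- config$dissimilarity_bands
  ifelse(d >= b[2], 4, ifelse(d >= b[1], 2, 0))
}

## Score computation ----------------------------------------------------------

.pp_score_cols <- c("patient_id", "pathway", "b_naive", "c1_intensity",
                    "c2_lateralization", "c3_duration", "c4_symptoms",
                    "c5_frequency", "c6_dissimilarity", "total",
                    "criterion_A", "criterion_D", "is_post_pipeline")

#' Score a whole cohort
#'
#' Applies the post-pipe score to every record. Three pathways:
#' \describe{
#'   \item{new_onset_B}{headache-naive patient with a post-procedural
#'     headache: the diagnostic 9 points; post-pipeline iff criteria A and D
#'     hold.}
#'   \item{preexisting_C}{pre-existing headache: C1-C6 computed from the pre
#'     vs 3-month profiles; post-pipeline iff A, D and total >= threshold.}
#'   \item{not_applicable}{no post-procedural headache: total 0, never
#'     post-pipeline.}
#' }
#' A criterion whose inputs are missing is never silently scored 0: the
#' record fails with an explicit insufficient-data error naming the fields.
#'
#' @param cohort A validated cohort data.frame (see [validate_cohort()]).
#' @param config A [scoring_config()].
#' @return A `pp_scores` data.frame, one row per patient: per-criterion
#'   points, total, pathway, criteria A/D and the diagnostic decision
#'   `is_post_pipeline`.
#' @export
score_cohort <- function(cohort, config = scoring_config()) {
  n <- nrow(cohort)
  pre <- !is.na(cohort$pre_present) & cohort$pre_present
  post <- !is.na(cohort$post3m_present) & cohort$post3m_present
  pathway <- ifelse(!post, "not_applicable",
                    ifelse(pre, "preexisting_C", "new_onset_B"))
  A <- ifelse(is.na(cohort$criterion_A), FALSE, cohort$criterion_A)
  D <- ifelse(is.na(cohort$criterion_D), FALSE, cohort$criterion_D)

  out <- data.frame(patient_id = cohort$patient_id, pathway = pathway,
                    b_naive = 0, c1_intensity = 0, c2_lateralization = 0,
                    c3_duration = 0, c4_symptoms = 0, c5_frequency = 0,
                    c6_dissimilarity = 0, total = 0, criterion_A = A,
                    criterion_D = D, is_post_pipeline = FALSE,
                    stringsAsFactors = FALSE)

  nb <- pathway == "new_onset_B"
  out$b_naive[nb] <- config$naive_points
  out$total[nb] <- config$naive_points
  out$is_post_pipeline[nb] <- A[nb] & D[nb]

  px <- which(pathway == "preexisting_C")
  if (length(px) > 0) {
    need <- c("pre_nrs", "post3m_nrs", "pre_laterality", "post3m_laterality",
              "pre_duration_h", "post3m_duration_h", "pre_symptoms",
              "post3m_symptoms", "pre_mhd", "post3m_mhd", "similarity_rating")
    for (i in px) {
      miss <- need[vapply(need, function(f) is.na(cohort[[f]][i]), logical(1))]
      if (length(miss) > 0)
        stop("insufficient data to score patient '", cohort$patient_id[i],
             "' on the pre-existing pathway; missing field(s): ",
             paste(miss, collapse = ", "))
    }
    out$c1_intensity[px] <- score_intensity_change(
      cohort$pre_nrs[px], cohort$post3m_nrs[px], config)
    out$c2_lateralization[px] <- score_lateralization(
      cohort$pre_laterality[px], cohort$post3m_laterality[px], config)
    out$c3_duration[px] <- score_duration_change(
      cohort$pre_duration_h[px], cohort$post3m_duration_h[px], config)
    out$c4_symptoms[px] <- score_symptom_change(
      parse_symptoms(cohort$pre_symptoms[px]),
      parse_symptoms(cohort$post3m_symptoms[px]))
    out$c5_frequency[px] <- score_frequency_change(
      cohort$pre_mhd[px], cohort$post3m_mhd[px], config)
    out$c6_dissimilarity[px] <- score_dissimilarity(
      cohort$similarity_rating[px], "similarity", config)
    out$total[px] <- out$c1_intensity[px] + out$c2_lateralization[px] +
      out$c3_duration[px] + out$c4_symptoms[px] + out$c5_frequency[px] +
      out$c6_dissimilarity[px]
    out$is_post_pipeline[px] <- A[px] & D[px] &
      out$total[px] >= config$threshold
  }
  class(out) <- unique(c("pp_scores", class(out)))
  attr(out, "config") <- config
  out
}

#' Score a single patient record
#'
#' @param record A one-row cohort data.frame.
#' @param config A [scoring_config()].
#' @return A one-row `pp_scores` data.frame (the `ScoreBreakdown`).
#' @export
compute_score <- function(record, config = scoring_config()) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  score_cohort(record, config)
}

## Outcome classification -----------------------------------------------------

.pp_outcomes <- c("never", "new_onset", "improvement", "no_change", "worsening")

#' Classify five-way post-procedural headache outcome
#'
#' \itemize{
#'   \item no headache before or after: `never`;
#'   \item headache-naive with a post-procedural headache meeting the
#'     diagnosis: `new_onset`;
#'   \item pre-existing headache reported improved: `improvement`, regardless
#'     of feature changes;
#'   \item pre-existing headache reported worse AND meeting the diagnosis:
#'     `worsening`;
#'   \item otherwise (reported unchanged, or minimal worsening below the
#'     diagnostic threshold -- within normal fluctuation of a primary
#'     headache disorder): `no_change`.
#' }
#' A headache-naive patient whose new headache fails criterion A or D
#' (a transient post-procedural headache) has no bucket in this taxonomy; it
#' is surfaced as `unclassified_transient` -- an error by default, or a sixth
#' factor level with `transient = "flag"`.
#'
#' @param cohort A validated cohort data.frame.
#' @param scores The matching [score_cohort()] result.
#' @param transient `"error"` (default) or `"flag"`.
#' @return A factor with levels `never`, `new_onset`, `improvement`,
#'   `no_change`, `worsening` (plus `unclassified_transient` when flagged).
#' @export
classify_cohort <- function(cohort, scores, transient = c("error", "flag")) {
  transient <- match.arg(transient)
  stopifnot(nrow(cohort) == nrow(scores),
            identical(as.character(cohort$patient_id),
                      as.character(scores$patient_id)))
  pre <- !is.na(cohort$pre_present) & cohort$pre_present
  post <- !is.na(cohort$post3m_present) & cohort$post3m_present
  dir <- cohort$patient_reported_direction
  ipp <- scores$is_post_pipeline
  out <- rep(NA_character_, nrow(cohort))
  out[!pre & !post] <- "never"
  out[!pre & post & ipp] <- "new_onset"
  trans <- !pre & post & !ipp
  out[pre & dir == "improved"] <- "improvement"
  out[pre & dir == "worse" & ipp] <- "worsening"
  out[pre & (dir == "same" | (dir == "worse" & !ipp))] <- "no_change"
  if (any(trans)) {
    if (transient == "error")
      stop("unclassified_transient: patient(s) ",
           paste(cohort$patient_id[trans], collapse = ", "),
           " are headache-naive with a post-procedural headache failing ",
           "criterion A or D; no outcome bucket applies -- review required ",
           "(use transient = \"flag\" to keep them as a separate level)")
    out[trans] <- "unclassified_transient"
  }
  if (anyNA(out))
    stop("unclassifiable record(s): ",
         paste(cohort$patient_id[is.na(out)], collapse = ", "))
  levels <- c(.pp_outcomes, if (transient == "flag") "unclassified_transient")
  factor(out, levels = levels)
}

#' @rdname classify_cohort
#' @param record A one-row cohort data.frame.
#' @param breakdown The matching [compute_score()] result.
#' @export
classify_outcome <- function(record, breakdown,
                             transient = c("error", "flag")) {
  classify_cohort(record, breakdown, transient)
}

#' Outcome transition counts
#'
#' Tabulates outcome categories (the numbers behind a Sankey-style
#' transition diagram), with the pre-procedural headache status as origin.
#'
#' @param cohort A validated cohort data.frame.
#' @param outcomes The matching [classify_cohort()] factor.
#' @return A data.frame with `prior_status`, `outcome`, `n`.
#' @export
outcome_transitions <- function(cohort, outcomes) {
  prior <- ifelse(!is.na(cohort$pre_present) & cohort$pre_present,
                  "pre_existing_headache", "headache_naive")
  agg <- as.data.frame(table(prior_status = prior, outcome = outcomes),
                       stringsAsFactors = FALSE)
  names(agg)[3] <- "n"
  agg[agg$n > 0, , drop = FALSE]
}
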