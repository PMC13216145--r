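## Synthetic cohorts: (a) a stochastic generator with the statistical
## structure the analysis assumes (lognormal aneurysm dimensions, a
## neck-size logit for the post-pipeline outcome, phenotype changes drawn to
## satisfy the score), and (b) a deterministic 137-record fixture whose
## derived categorical marginals reproduce the published counts exactly.

## Run an expression under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## Lognormal parameters matching a target mean and sd exactly in expectation.
lnorm_params <- function(mean, sd) {
  sig2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sig2 / 2, sdlog = sqrt(sig2))
}

#' Simulation configuration
#'
#' Defaults are the published cohort's stated conditions: 137 patients, age
#' 58.29 +/- 12.70 years, 19% male, 88/137 with a prior headache disorder
#' (46 migraine / 24 tension-type / 18 suspected aneurysm-attributed
#' secondary), lognormal neck and dome sizes with mean +/- SD 5.09 +/- 2.53
#' and 10.90 +/- 6.62 mm, and an outcome model
#' `logit P(post-pipeline) = beta0 + beta_neck * neck_mm` with
#' `beta_neck = 0.388` and `beta0` calibrated so the marginal prevalence is
#' 0.212. Worseners' phenotype changes are drawn to satisfy the scoring
#' threshold with probability `p_signal` (default 1).
#'
#' @param n_patients Cohort size.
#' @param p_prior_headache Probability of a pre-procedural headache history.
#' @param prior_mix Named probabilities over migraine / tension_type /
#'   secondary_to_aneurysm, conditional on a prior history.
#' @param age_mean,age_sd,p_male Demographics.
#' @param neck_mean,neck_sd,dome_mean,dome_sd Aneurysm-size targets (mm);
#'   matched in expectation by moment-matched lognormals.
#' @param prevalence Target marginal post-pipeline prevalence.
#' @param beta_neck Log-odds per millimetre of neck size.
#' @param beta0 Intercept; `NULL` (default) calibrates it to `prevalence`
#'   by quadrature over the neck distribution.
#' @param p_signal Probability a true worsener's phenotype is drawn to reach
#'   the scoring threshold.
#' @param p_improve_given_benign Probability a pre-existing headache improves
#'   given the patient is not a post-pipeline case (default 41/71).
#' @param p_minimal_worsening Probability a non-improving benign course is
#'   reported as "worse" yet scores below threshold (minimal worsening).
#' @param rater_fn,rater_fp,n_label_raters Class-conditional flip rates and
#'   number of simulated clinical raters.
#' @param panel_raters,likert_probs Expert-panel size and Likert(1..4)
#'   distribution (default puts 0.96 mass on ratings >= 3).
#' @param scoring A [scoring_config()] the generator must satisfy.
#' @return A list of class `pp_sim_config`.
#' @export
sim_config <- function(n_patients = 137,
                       p_prior_headache = 88 / 137,
                       prior_mix = c(migraine = 46, tension_type = 24,
                                     secondary_to_aneurysm = 18) / 88,
                       age_mean = 58.29, age_sd = 12.70, p_male = 0.19,
                       neck_mean = 5.09, neck_sd = 2.53,
                       dome_mean = 10.90, dome_sd = 6.62,
                       prevalence = 0.212, beta_neck = 0.388, beta0 = NULL,
                       p_signal = 1.0,
                       p_improve_given_benign = 41 / 71,
                       p_minimal_worsening = 5 / 30,
                       rater_fn = 0.16, rater_fp = 0.02, n_label_raters = 3,
                       panel_raters = 11,
                       likert_probs = c(0.01, 0.03, 0.31, 0.65),
                       scoring = scoring_config()) {
  stopifnot(n_patients >= 1, p_prior_headache >= 0, p_prior_headache <= 1,
            abs(sum(prior_mix) - 1) < 1e-8, p_signal >= 0, p_signal <= 1,
            rater_fn >= 0, rater_fn <= 1, rater_fp >= 0, rater_fp <= 1,
            abs(sum(likert_probs) - 1) < 1e-8, panel_raters >= 2)
  if (scoring$threshold > max_preexisting_total(scoring))
    stop("infeasible configuration: scoring threshold ", scoring$threshold,
         " exceeds the maximum reachable pre-existing-pathway total ",
         max_preexisting_total(scoring))
  neck <- lnorm_params(neck_mean, neck_sd)
  dome <- lnorm_params(dome_mean, dome_sd)
  if (is.null(beta0)) {
    q <- stats::qlnorm(seq(5e-4, 1 - 5e-4, by = 1e-3),
                       neck["meanlog"], neck["sdlog"])
    f <- function(b0) mean(stats::plogis(b0 + beta_neck * q)) - prevalence
    beta0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  }
  structure(list(n_patients = n_patients,
                 p_prior_headache = p_prior_headache, prior_mix = prior_mix,
                 age_mean = age_mean, age_sd = age_sd, p_male = p_male,
                 neck_mean = neck_mean, neck_sd = neck_sd,
                 neck_lnorm = neck, dome_mean = dome_mean, dome_sd = dome_sd,
                 dome_lnorm = dome, prevalence = prevalence,
                 beta_neck = beta_neck, beta0 = beta0, p_signal = p_signal,
                 p_improve_given_benign = p_improve_given_benign,
                 p_minimal_worsening = p_minimal_worsening,
                 rater_fn = rater_fn, rater_fp = rater_fp,
                 n_label_raters = n_label_raters,
                 panel_raters = panel_raters, likert_probs = likert_probs,
                 scoring = scoring),
            class = "pp_sim_config")
}

## Deterministic map from a C1..C6 component vector to a pre/post phenotype
## pair realising exactly those points under the default band edges.
recipe_profiles <- function(comp) {
  stopifnot(ncol(comp) == 6)
  n <- nrow(comp)
  pick <- function(values, idx) values[idx]
  c1 <- comp[, 1]; c2 <- comp[, 2]; c3 <- comp[, 3]
  c4 <- comp[, 4]; c5 <- comp[, 5]; c6 <- comp[, 6]
  stopifnot(all(c1 %in% c(0, 2, 4)), all(c2 %in% c(0, 2)),
            all(c3 %in% c(0, 1, 4)), all(c4 %in% 0:3),
            all(c5 %in% c(0, 4)), all(c6 %in% c(0, 2, 4)))
  data.frame(
    pre_nrs = ifelse(c1 == 4, 4, 5),
    post_nrs = ifelse(c1 == 4, 8, ifelse(c1 == 2, 7, 5)),
    pre_laterality = ifelse(c2 == 2, "contralateral", "ipsilateral"),
    post_laterality = "ipsilateral",
    pre_duration_h = ifelse(c3 == 4, 2, 12),
    post_duration_h = ifelse(c3 == 4, 100, ifelse(c3 == 1, 48, 12)),
    pre_symptoms = ifelse(c4 == 0, "photophobia", "none"),
    post_symptoms = pick(c("photophobia", "vomiting", "nausea",
                           "nausea;vomiting"), c4 + 1),
    pre_mhd = ifelse(c5 == 4, 4, 6),
    post_mhd = ifelse(c5 == 4, 10, 6),
    similarity = pick(c(8, NA, 3, NA, 1), c6 + 1),
    stringsAsFactors = FALSE)
}

## Escalation order used to push a worsener's components over the threshold.
escalate_components <- function(comp, threshold, c3_pts) {
  total <- rowSums(comp)
  for (i in which(total < threshold)) {
    steps <- list(c(1, 4), c(5, 4), c(6, 4), c(3, 4), c(2, 2), c(4, 3))
    for (s in steps) {
      if (sum(comp[i, ]) >= threshold) break
      comp[i, s[1]] <- max(comp[i, s[1]], s[2])
    }
    if (sum(comp[i, ]) < threshold)
      stop("infeasible configuration: cannot reach scoring threshold ",
           threshold, " with realisable phenotype changes")
  }
  comp
}

rand_subset <- function(n, pool, max_size = 2) {
  vapply(seq_len(n), function(i) {
    k <- sample(0:max_size, 1)
    if (k == 0) "none" else paste(sort(sample(pool, k)), collapse = ";")
  }, character(1))
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort under a [sim_config()]: demographics, lognormal aneurysm
#' dimensions, a neck-size logit for the ground-truth post-pipeline flag,
#' and pre/post headache phenotypes consistent with that flag (worseners'
#' phenotype deltas realise a score above threshold with probability
#' `p_signal`; benign courses improve, stay unchanged, or worsen minimally
#' below threshold). Reproducible given `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `pp_simulation`: `cohort` (a validated
#'   `pp_cohort`) and `truth`, a sidecar data.frame (`patient_id`, logical
#'   `truth`) that is NOT part of the cohort schema, so pipeline stages
#'   cannot accidentally read it.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "pp_sim_config"))
  with_seed(seed, {
    n <- config$n_patients
    cohort <- cohort_template(n)
    cohort$patient_id <- sprintf("S%05d", seq_len(n))
    cohort$age <- pmin(95, pmax(18, round(stats::rnorm(n, config$age_mean,
                                                       config$age_sd))))
    cohort$sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
    prior <- stats::runif(n) < config$p_prior_headache
    dx <- rep("none", n)
    if (any(prior))
      dx[prior] <- sample(names(config$prior_mix), sum(prior), TRUE,
                          config$prior_mix)
    cohort$prior_headache_diagnosis <- dx
    cohort$neck_mm <- round(stats::rlnorm(n, config$neck_lnorm["meanlog"],
                                          config$neck_lnorm["sdlog"]), 2)
    cohort$dome_mm <- round(stats::rlnorm(n, config$dome_lnorm["meanlog"],
                                          config$dome_lnorm["sdlog"]), 2)
    cohort$aspect_ratio <- round(cohort$dome_mm / cohort$neck_mm, 2)
    loc_tab <- fixture_topography_counts()
    cohort$aneurysm_location <- sample(loc_tab$location, n, TRUE,
                                       loc_tab$overall / sum(loc_tab$overall))
    cohort$anterior_circulation <-
      !cohort$aneurysm_location %in% posterior_locations()
    cohort$coils_used <- stats::runif(n) < 0.22
    cohort$dapt_months <- round(pmax(1, stats::rnorm(n, 3.79, 1.99)), 1)
    cohort$mapt_used <- stats::runif(n) < 0.81
    cohort$mapt_months <- ifelse(cohort$mapt_used,
                                 round(pmax(0.5, stats::rnorm(n, 5.35, 3.61)), 1), 0)
    cohort$steroids_postop <- stats::runif(n) < 0.64
    cohort$reintervention <- stats::runif(n) < 0.04
    cohort$partial_thrombosis <- stats::runif(n) < 0.10

    truth <- stats::runif(n) <
      stats::plogis(config$beta0 + config$beta_neck * cohort$neck_mm)

    ## Pre-procedural phenotype for patients with a headache history.
    idx_pre <- which(prior)
    np <- length(idx_pre)
    if (np > 0) {
      cohort$pre_present[idx_pre] <- TRUE
      cohort$pre_nrs[idx_pre] <- sample(3:8, np, TRUE)
      cohort$pre_mhd[idx_pre] <- sample(2:12, np, TRUE)
      cohort$pre_duration_h[idx_pre] <- sample(c(2, 6, 12, 24, 48), np, TRUE)
      cohort$pre_laterality[idx_pre] <- sample(
        c("ipsilateral", "contralateral", "bilateral"), np, TRUE,
        c(0.3, 0.3, 0.4))
      cohort$pre_symptoms[idx_pre] <- rand_subset(np, .pp_symptoms)
      cohort$pre_amn[idx_pre] <- sample(0:10, np, TRUE)
    }
    cohort$pre_present[!prior] <- FALSE
    cohort$post3m_present <- FALSE
    cohort$patient_reported_direction <- "not_applicable"

    ## Worseners: pre-existing headache, truth positive.
    thr <- config$scoring$threshold
    idx_w <- which(prior & truth)
    if (length(idx_w) > 0) {
      nw <- length(idx_w)
      comp <- cbind(sample(c(0, 2, 4), nw, TRUE),
                    sample(c(0, 2), nw, TRUE, c(0.7, 0.3)),
                    sample(c(0, 1, 4), nw, TRUE),
                    sample(0:3, nw, TRUE),
                    sample(c(0, 4), nw, TRUE),
                    sample(c(0, 2, 4), nw, TRUE))
      signal <- stats::runif(nw) < config$p_signal
      comp[signal, ] <- escalate_components(comp[signal, , drop = FALSE],
                                            thr, config$scoring$c3_multi_jump_points)
      rec <- recipe_profiles(comp)
      cohort$pre_nrs[idx_w] <- rec$pre_nrs
      cohort$pre_laterality[idx_w] <- rec$pre_laterality
      cohort$pre_duration_h[idx_w] <- rec$pre_duration_h
      cohort$pre_symptoms[idx_w] <- rec$pre_symptoms
      cohort$pre_mhd[idx_w] <- rec$pre_mhd
      cohort$post3m_present[idx_w] <- TRUE
      cohort$post3m_nrs[idx_w] <- rec$post_nrs
      cohort$post3m_laterality[idx_w] <- rec$post_laterality
      cohort$post3m_duration_h[idx_w] <- rec$post_duration_h
      cohort$post3m_symptoms[idx_w] <- rec$post_symptoms
      cohort$post3m_mhd[idx_w] <- rec$post_mhd
      cohort$post3m_amn[idx_w] <- sample(2:12, nw, TRUE)
      cohort$similarity_rating[idx_w] <- rec$similarity
      cohort$similarity_rating[idx_w][is.na(rec$similarity)] <- 5
      cohort$patient_reported_direction[idx_w] <- "worse"
      cohort$criterion_A[idx_w] <- TRUE
      cohort$criterion_D[idx_w] <- TRUE
    }

    ## Benign pre-existing courses: improvement, no change, minimal worsening.
    idx_b <- which(prior & !truth)
    if (length(idx_b) > 0) {
      improved <- stats::runif(length(idx_b)) < config$p_improve_given_benign
      idx_imp <- idx_b[improved]
      idx_nc <- idx_b[!improved]
      cohort$patient_reported_direction[idx_imp] <- "improved"
      resolved <- stats::runif(length(idx_imp)) < 0.5
      keep <- idx_imp[!resolved]     # improved but persisting
      if (length(keep) > 0) {
        cohort$post3m_present[keep] <- TRUE
        cohort$post3m_nrs[keep] <- pmax(0, cohort$pre_nrs[keep] - 3)
        cohort$post3m_laterality[keep] <- cohort$pre_laterality[keep]
        cohort$post3m_duration_h[keep] <- cohort$pre_duration_h[keep]
        cohort$post3m_symptoms[keep] <- cohort$pre_symptoms[keep]
        cohort$post3m_mhd[keep] <- pmax(0, cohort$pre_mhd[keep] - 3)
        cohort$post3m_amn[keep] <- 1
        cohort$similarity_rating[keep] <- sample(8:10, length(keep), TRUE)
        cohort$criterion_A[keep] <- TRUE
        cohort$criterion_D[keep] <- TRUE
      }
      if (length(idx_nc) > 0) {
        minimal <- stats::runif(length(idx_nc)) < config$p_minimal_worsening
        cohort$patient_reported_direction[idx_nc] <-
          ifelse(minimal, "worse", "same")
        cohort$post3m_present[idx_nc] <- TRUE
        cohort$post3m_nrs[idx_nc] <- cohort$pre_nrs[idx_nc]
        cohort$post3m_laterality[idx_nc] <- cohort$pre_laterality[idx_nc]
        cohort$post3m_duration_h[idx_nc] <- cohort$pre_duration_h[idx_nc]
        cohort$post3m_symptoms[idx_nc] <- cohort$pre_symptoms[idx_nc]
        cohort$post3m_mhd[idx_nc] <- cohort$pre_mhd[idx_nc]
        cohort$post3m_amn[idx_nc] <- cohort$pre_amn[idx_nc]
        cohort$similarity_rating[idx_nc] <- sample(8:10, length(idx_nc), TRUE)
        ## minimal worseners: nudge intensity by 2 (scores C1=2 < threshold)
        nudge <- idx_nc[minimal]
        cohort$post3m_nrs[nudge] <- pmin(10, cohort$post3m_nrs[nudge] + 2)
        cohort$criterion_A[idx_nc] <- TRUE
        cohort$criterion_D[idx_nc] <- TRUE
      }
    }

    ## Headache-naive: new-onset if truth positive, never otherwise.
    idx_new <- which(!prior & truth)
    if (length(idx_new) > 0) {
      nn <- length(idx_new)
      cohort$post3m_present[idx_new] <- TRUE
      cohort$post3m_nrs[idx_new] <- sample(4:8, nn, TRUE)
      cohort$post3m_mhd[idx_new] <- sample(5:15, nn, TRUE)
      cohort$post3m_duration_h[idx_new] <- sample(c(6, 12, 24, 48), nn, TRUE)
      cohort$post3m_laterality[idx_new] <- sample(
        c("ipsilateral", "bilateral"), nn, TRUE, c(0.7, 0.3))
      cohort$post3m_symptoms[idx_new] <- rand_subset(nn, .pp_symptoms)
      cohort$post3m_amn[idx_new] <- sample(2:12, nn, TRUE)
      cohort$criterion_A[idx_new] <- TRUE
      cohort$criterion_D[idx_new] <- TRUE
    }

    cohort <- validate_cohort(cohort)
    structure(list(cohort = cohort,
                   truth = data.frame(patient_id = cohort$patient_id,
                                      truth = truth,
                                      stringsAsFactors = FALSE),
                   seed = seed, config = config),
              class = "pp_simulation")
  })
}

## Fixture --------------------------------------------------------------------

posterior_locations <- function() {
  ## Marginal-matching choice: four labels are coded posterior so that the
  ## printed topography counts AND the printed 118 = 91 + 27 anterior split
  ## hold simultaneously (see package docs).
  c("Vertebral-Basilar", "Vertebral-PICA", "Basilar-P1", "P2-P3")
}

#' Published topography level counts
#'
#' @return A data.frame with `location`, `overall`, `non_pp`, `pp` counts.
#' @export
fixture_topography_counts <- function() {
  data.frame(
    location = .pp_locations,
    overall = c(14, 2, 2, 1, 4, 5, 1, 1, 13, 68, 1, 18, 2, 1, 2, 1, 1),
    non_pp = c(13, 2, 1, 1, 4, 3, 1, 1, 10, 52, 1, 14, 1, 1, 1, 1, 1),
    pp = c(1, 0, 1, 0, 0, 2, 0, 0, 3, 16, 0, 4, 1, 0, 1, 0, 0),
    stringsAsFactors = FALSE)
}

## Deterministic per-group continuous fill: lognormal quantiles moment-matched
## to the printed group mean and SD (only categorical counts are promised
## exactly; record-level continuous data are unrecoverable from mean +/- SD).
det_lnorm <- function(n, mean, sd) {
  p <- lnorm_params(mean, sd)
  round(stats::qlnorm((seq_len(n) - 0.5) / n, p["meanlog"], p["sdlog"]), 2)
}

det_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(hi, pmax(lo, round(mean + sd * stats::qnorm((seq_len(n) - 0.5) / n), 1)))
}

## Deterministic decorrelating permutation (stride co-prime with n), so the
## per-variable quantile fills are not comonotone within a group -- which
## would make the groups linearly separable and the regression degenerate.
det_scramble <- function(x, stride) {
  n <- length(x)
  while (n %% stride == 0 || gcd2(n, stride) != 1) stride <- stride + 1
  x[(((seq_len(n) - 1) * stride) %% n) + 1]
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

## The 17 worsener component vectors (C1, C2, C3, C4, C5, C6). Totals
## 9..16, mean 10.82, matching the reported mean worsener score.
fixture_worsener_components <- function() {
  m <- rbind(
    c(4, 0, 1, 0, 4, 0),   # 9
    c(2, 2, 1, 0, 0, 4),   # 9
    c(0, 2, 1, 2, 4, 0),   # 9
    c(4, 0, 0, 1, 0, 4),   # 9
    c(2, 0, 4, 1, 0, 2),   # 9
    c(4, 2, 0, 0, 4, 0),   # 10
    c(2, 0, 4, 0, 4, 0),   # 10
    c(0, 2, 4, 0, 0, 4),   # 10
    c(4, 0, 1, 1, 4, 0),   # 10
    c(4, 2, 1, 0, 4, 0),   # 11
    c(2, 0, 4, 1, 4, 0),   # 11
    c(4, 0, 1, 2, 0, 4),   # 11
    c(0, 2, 1, 2, 4, 2),   # 11
    c(4, 0, 4, 0, 4, 0),   # 12
    c(4, 2, 1, 2, 4, 0),   # 13
    c(4, 0, 4, 2, 4, 0),   # 14
    c(4, 2, 4, 2, 4, 0))   # 16
  stopifnot(identical(rowSums(m), c(9, 9, 9, 9, 9, 10, 10, 10, 10, 11, 11,
                                    11, 11, 12, 13, 14, 16)))
  m
}

## Small component vectors for reported-worse-but-below-threshold records.
fixture_minimal_components <- function() {
  rbind(c(2, 0, 1, 0, 0, 2),   # 5
        c(0, 0, 1, 2, 0, 0),   # 3
        c(2, 0, 0, 0, 0, 2),   # 4
        c(0, 0, 0, 2, 0, 0),   # 2
        c(4, 0, 1, 0, 0, 0))   # 5
}

#' Deterministic fixture cohort (n = 137)
#'
#' A record-level stand-in for the (undeposited) study cohort, labelled
#' synthetic: it is constructed, without randomness, so that running the
#' real scoring and classification code reproduces the published categorical
#' marginals exactly -- prior-headache split 88/49; outcomes improvement 41,
#' no change 30, worsening 17, new onset 12, never 37 (post-pipeline 29);
#' 18 suspected aneurysm-attributed secondary headaches of which 3 worsen;
#' 26 males splitting 23/3 by post-pipeline status; anterior circulation
#' 118 splitting 91/27; topography level counts as published. Worsening
#' records score >= 9 (totals averaging 10.82) and reported-worse no-change
#' records < 9 under the default scoring configuration. Continuous fields
#' are deterministic moment-matched quantile fills near the printed group
#' means; they carry no exact promise.
#'
#' @return A validated `pp_cohort` with 137 rows.
#' @export
make_fixture_cohort <- function() {
  sizes <- c(never = 37, new_onset = 12, improvement = 41, no_change = 30,
             worsening = 17)
  n <- sum(sizes)
  group <- rep(names(sizes), sizes)
  cohort <- cohort_template(n)
  cohort$patient_id <- sprintf("F%03d", seq_len(n))

  is_pp <- group %in% c("new_onset", "worsening")
  ## Sex: 26 males, 3 of them post-pipeline (1 new-onset, 2 worsening).
  cohort$sex <- "female"
  male_idx <- c(which(group == "never")[1:9],
                which(group == "improvement")[1:9],
                which(group == "no_change")[1:5],
                which(group == "new_onset")[1],
                which(group == "worsening")[1:2])
  cohort$sex[male_idx] <- "male"

  ## Topography: published per-group level counts, laid out deterministically.
  topo <- fixture_topography_counts()
  cohort$aneurysm_location[is_pp] <- rep(topo$location, topo$pp)
  cohort$aneurysm_location[!is_pp] <- rep(topo$location, topo$non_pp)
  cohort$anterior_circulation <-
    !cohort$aneurysm_location %in% posterior_locations()

  ## Prior diagnosis.
  dx <- rep("none", n)
  dx[group == "improvement"] <-
    rep(c("secondary_to_aneurysm", "migraine", "tension_type"), c(15, 18, 8))
  dx[group == "no_change"] <- rep(c("migraine", "tension_type"), c(18, 12))
  dx[group == "worsening"] <-
    rep(c("secondary_to_aneurysm", "migraine", "tension_type"), c(3, 10, 4))
  cohort$prior_headache_diagnosis <- dx
  pre <- dx != "none"
  cohort$pre_present <- pre
  cohort$post3m_present <- FALSE
  cohort$patient_reported_direction <- "not_applicable"

  ## Continuous fields: deterministic quantile fills per post-pipeline group,
  ## targeting the printed group means/SDs.
  for (g in list(list(sel = !is_pp, age = c(58.60, 12.38),
                      neck = c(4.83, 2.20), dome = c(10.14, 5.85),
                      dapt = c(3.59, 1.34)),
                 list(sel = is_pp, age = c(57.11, 14.07),
                      neck = c(6.03, 3.39), dome = c(13.68, 8.47),
                      dapt = c(4.48, 3.50)))) {
    k <- sum(g$sel)
    cohort$age[g$sel] <- det_norm(k, g$age[1], g$age[2], lo = 18, hi = 95)
    cohort$neck_mm[g$sel] <- det_scramble(det_lnorm(k, g$neck[1], g$neck[2]), 7)
    cohort$dome_mm[g$sel] <- det_scramble(det_lnorm(k, g$dome[1], g$dome[2]), 11)
    cohort$dapt_months[g$sel] <-
      det_scramble(det_norm(k, g$dapt[1], g$dapt[2], lo = 1), 17)
  }
  cohort$aspect_ratio <- round(cohort$dome_mm / cohort$neck_mm, 2)

  ## Treatment details (plausible fills; no exact split promised).
  cohort$coils_used <- rep(c(TRUE, FALSE, NA), c(29, 103, 5))
  cohort$steroids_postop <- rep(c(TRUE, FALSE, NA), c(88, 45, 4))
  cohort$mapt_used <- rep(c(TRUE, FALSE, NA), c(107, 25, 5))
  cohort$mapt_months <- ifelse(!is.na(cohort$mapt_used) & cohort$mapt_used,
                               det_scramble(det_norm(n, 5.35, 3.61, lo = 0.5), 19),
                               0)
  cohort$mapt_months[is.na(cohort$mapt_used)] <- NA
  cohort$reintervention <- rep(c(TRUE, FALSE, NA), c(4, 92, 41))
  ## Partial thrombosis: kept as an optional boolean with no derivation;
  ## TRUE cases placed in both outcome groups so the full regression model
  ## stays estimable on complete cases.
  cohort$partial_thrombosis <- FALSE
  cohort$partial_thrombosis[c(5, 20, 40, 95, 125, 130)] <- TRUE
  cohort$partial_thrombosis[60:90] <- NA

  ## never: nothing before or after.
  ## new-onset: post-procedural headache, criteria A and D met.
  i_new <- which(group == "new_onset")
  cohort$post3m_present[i_new] <- TRUE
  cohort$post3m_nrs[i_new] <- rep(c(5, 6, 7), length.out = 12)
  cohort$post3m_mhd[i_new] <- rep(c(6, 8, 10, 12), length.out = 12)
  cohort$post3m_duration_h[i_new] <- rep(c(6, 12, 24), length.out = 12)
  cohort$post3m_laterality[i_new] <- rep(c("ipsilateral", "bilateral"),
                                         c(8, 4))
  cohort$post3m_symptoms[i_new] <- rep(c("photophobia", "none", "nausea"),
                                       times = c(5, 4, 3))
  cohort$post3m_amn[i_new] <- rep(c(4, 6, 8), length.out = 12)
  cohort$criterion_A[i_new] <- TRUE
  cohort$criterion_D[i_new] <- TRUE

  ## improvement: 21 persisting-but-better, 20 resolved.
  i_imp <- which(group == "improvement")
  cohort$patient_reported_direction[i_imp] <- "improved"
  cohort$pre_nrs[i_imp] <- 6
  cohort$pre_mhd[i_imp] <- 8
  cohort$pre_duration_h[i_imp] <- 24
  cohort$pre_laterality[i_imp] <- rep(c("bilateral", "ipsilateral"),
                                      length.out = 41)
  cohort$pre_symptoms[i_imp] <- rep(c("photophobia;nausea", "none"),
                                    length.out = 41)
  cohort$pre_amn[i_imp] <- 5
  persist <- i_imp[1:21]
  cohort$post3m_present[persist] <- TRUE
  cohort$post3m_nrs[persist] <- 3
  cohort$post3m_mhd[persist] <- 4
  cohort$post3m_duration_h[persist] <- 12
  cohort$post3m_laterality[persist] <- cohort$pre_laterality[persist]
  cohort$post3m_symptoms[persist] <- cohort$pre_symptoms[persist]
  cohort$post3m_amn[persist] <- 2
  cohort$similarity_rating[persist] <- 8
  cohort$criterion_A[persist] <- TRUE
  cohort$criterion_D[persist] <- TRUE
  cohort$criterion_A[setdiff(i_imp, persist)] <- FALSE

  ## no change: 5 reported worse but below threshold, 25 reported unchanged.
  i_nc <- which(group == "no_change")
  cohort$pre_amn[i_nc] <- 4
  minimal <- i_nc[1:5]
  same <- i_nc[-(1:5)]
  mc <- fixture_minimal_components()
  rec <- recipe_profiles(mc)
  cohort$pre_nrs[minimal] <- rec$pre_nrs
  cohort$pre_laterality[minimal] <- rec$pre_laterality
  cohort$pre_duration_h[minimal] <- rec$pre_duration_h
  cohort$pre_symptoms[minimal] <- rec$pre_symptoms
  cohort$pre_mhd[minimal] <- rec$pre_mhd
  cohort$post3m_present[minimal] <- TRUE
  cohort$post3m_nrs[minimal] <- rec$post_nrs
  cohort$post3m_laterality[minimal] <- rec$post_laterality
  cohort$post3m_duration_h[minimal] <- rec$post_duration_h
  cohort$post3m_symptoms[minimal] <- rec$post_symptoms
  cohort$post3m_mhd[minimal] <- rec$post_mhd
  cohort$post3m_amn[minimal] <- 5
  cohort$similarity_rating[minimal] <- ifelse(is.na(rec$similarity), 6,
                                              rec$similarity)
  cohort$patient_reported_direction[minimal] <- "worse"
  cohort$criterion_A[minimal] <- TRUE
  cohort$criterion_D[minimal] <- TRUE
  cohort$pre_nrs[same] <- 5
  cohort$pre_mhd[same] <- 6
  cohort$pre_duration_h[same] <- 12
  cohort$pre_laterality[same] <- rep(c("bilateral", "ipsilateral"),
                                     length.out = 25)
  cohort$pre_symptoms[same] <- "photophobia"
  for (f in c("nrs", "mhd", "duration_h", "laterality", "symptoms"))
    cohort[[paste0("post3m_", f)]][same] <- cohort[[paste0("pre_", f)]][same]
  cohort$post3m_present[same] <- TRUE
  cohort$post3m_amn[same] <- 4
  cohort$similarity_rating[same] <- 9
  cohort$patient_reported_direction[same] <- "same"
  cohort$criterion_A[same] <- TRUE
  cohort$criterion_D[same] <- TRUE

  ## worsening: 17 component recipes, all scoring >= 9, A and D met.
  i_w <- which(group == "worsening")
  wc <- fixture_worsener_components()
  rec <- recipe_profiles(wc)
  cohort$pre_nrs[i_w] <- rec$pre_nrs
  cohort$pre_laterality[i_w] <- rec$pre_laterality
  cohort$pre_duration_h[i_w] <- rec$pre_duration_h
  cohort$pre_symptoms[i_w] <- rec$pre_symptoms
  cohort$pre_mhd[i_w] <- rec$pre_mhd
  cohort$pre_amn[i_w] <- 6
  cohort$post3m_present[i_w] <- TRUE
  cohort$post3m_nrs[i_w] <- rec$post_nrs
  cohort$post3m_laterality[i_w] <- rec$post_laterality
  cohort$post3m_duration_h[i_w] <- rec$post_duration_h
  cohort$post3m_symptoms[i_w] <- rec$post_symptoms
  cohort$post3m_mhd[i_w] <- rec$post_mhd
  cohort$post3m_amn[i_w] <- 9
  cohort$similarity_rating[i_w] <- ifelse(is.na(rec$similarity), 5,
                                          rec$similarity)
  cohort$patient_reported_direction[i_w] <- "worse"
  cohort$criterion_A[i_w] <- TRUE
  cohort$criterion_D[i_w] <- TRUE

  ## pre_amn for remaining pre-existing records.
  cohort$pre_amn[pre & is.na(cohort$pre_amn)] <- 4
  validate_cohort(cohort)
}

## Raters and panel -----------------------------------------------------------

#' Simulate clinical rater labels by class-conditional flips
#'
#' Each simulated rater labels every patient with the ground truth flipped
#' independently: a true post-pipeline case is missed with probability
#' `fn_rate`, a true negative mislabelled positive with probability
#' `fp_rate`. By construction the rater's expected agreement with truth is
#' `(1 - fn_rate, 1 - fp_rate)` -- see [rater_agreement()].
#'
#' @param truth A data.frame with `patient_id` and logical `truth` (the
#'   sidecar from [simulate_cohort()]).
#' @param n_raters Number of raters.
#' @param fn_rate,fp_rate Class-conditional flip probabilities, recycled
#'   across raters.
#' @param seed Integer seed.
#' @return A validated rater-label data.frame.
#' @export
simulate_raters <- function(truth, n_raters = 3, fn_rate = 0.16,
                            fp_rate = 0.02, seed = 1L) {
  stopifnot(all(fn_rate >= 0 & fn_rate <= 1), all(fp_rate >= 0 & fp_rate <= 1))
  fn_rate <- rep_len(fn_rate, n_raters)
  fp_rate <- rep_len(fp_rate, n_raters)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_raters), function(r) {
      flip_p <- ifelse(truth$truth, fn_rate[r], fp_rate[r])
      flip <- stats::runif(nrow(truth)) < flip_p
      data.frame(rater_id = sprintf("rater%d", r),
                 patient_id = truth$patient_id,
                 label = xor(truth$truth, flip), stringsAsFactors = FALSE)
    }))
    validate_raters(out)
  })
}

#' Simulate an expert content-validity panel
#'
#' Independent Likert(1..4) draws per rater, item and scale from a
#' configured categorical distribution (default mass 0.96 on ratings >= 3,
#' so the expected S-CVI/Ave is 0.96).
#'
#' @param n_raters Panel size (>= 2).
#' @param items Item identifiers.
#' @param likert_probs Probabilities of ratings 1..4.
#' @param seed Integer seed.
#' @return A validated panel data.frame.
#' @export
simulate_panel <- function(n_raters = 11, items = .pp_items,
                           likert_probs = c(0.01, 0.03, 0.31, 0.65),
                           seed = 1L) {
  stopifnot(n_raters >= 2, abs(sum(likert_probs) - 1) < 1e-8)
  with_seed(seed, {
    grid <- expand.grid(rater_id = sprintf("expert%02d", seq_len(n_raters)),
                        item_id = items, stringsAsFactors = FALSE)
    grid$relevance <- sample(1:4, nrow(grid), TRUE, likert_probs)
    grid$clarity <- sample(1:4, nrow(grid), TRUE, likert_probs)
    validate_panel(grid)
  })
}
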