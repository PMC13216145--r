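test_that("I-CVI is the proportion of ratings >= 3", {
  expect_equal(item_cvi(c(4, 4, 4, 4)), 1.0)
  expect_equal(item_cvi(c(4, 3, 3, 2)), 0.75)
  expect_equal(item_cvi(c(rep(4, 10), 2)), 10 / 11)
  expect_error(item_cvi(integer(0)), "empty")
  expect_error(item_cvi(c(4, 5)), "1..4")
  ## invariant under rater permutation
  r <- c(4, 2, 3, 1, 4, 3, 4, 4, 2, 3, 4)
  expect_equal(item_cvi(r), item_cvi(rev(r)))
  expect_equal(item_cvi(r), item_cvi(sample(r)))
})

test_that("S-CVI/Ave is the item mean and bounded by item extremes", {
  expect_equal(scale_cvi_ave(c(1.0, 1.0)), 1.0)
  expect_equal(scale_cvi_ave(c(0.8, 1.0)), 0.9)
  expect_equal(scale_cvi_ave(c(rep(1.0, 8), 0.82)), 0.98)
  expect_error(scale_cvi_ave(numeric(0)), "empty")
  set.seed(1)
  for (i in 1:20) {
    v <- runif(sample(2:10, 1))
    s <- scale_cvi_ave(v)
    expect_gte(s, min(v)); expect_lte(s, max(v))
  }
})

test_that("cvi_report aggregates a panel per item and scale", {
  panel <- simulate_panel(n_raters = 11, seed = 3)
  rep <- cvi_report(panel)
  expect_equal(rep$n_raters, 11)
  expect_equal(nrow(rep$items), 10)
  expect_true(all(rep$items$i_cvi_relevance >= 0 &
                    rep$items$i_cvi_relevance <= 1))
  expect_equal(rep$s_cvi_ave_relevance, mean(rep$items$i_cvi_relevance))
  expect_equal(rep$s_cvi_ave_overall,
               mean(c(rep$items$i_cvi_relevance, rep$items$i_cvi_clarity)))
  ## all-4 panel: perfect validity downstream
  all4 <- panel; all4$relevance <- 4L; all4$clarity <- 4L
  expect_equal(cvi_report(all4)$s_cvi_ave_overall, 1.0)
})

test_that("confusion at a cut-off: counts, sens/spec and single-threshold AUC", {
  scores <- data.frame(patient_id = sprintf("p%d", 1:8),
                       pathway = rep("preexisting_C", 8),
                       total = c(12, 10, 9, 8, 6, 3, 9, 11),
                       criterion_A = TRUE, criterion_D = TRUE,
                       is_post_pipeline = c(12, 10, 9, 8, 6, 3, 9, 11) >= 9)
  ## perfect agreement
  lab <- data.frame(rater_id = "r1", patient_id = scores$patient_id,
                    label = scores$total >= 9)
  cv <- confusion_at_cutoff(scores, lab, 9)
  expect_equal(cv$sensitivity, 1.0)
  expect_equal(cv$specificity, 1.0)
  expect_equal(cv$auc, 1.0)
  ## ties at the cut-off predict positive
  expect_equal(cv$tp, 5)
  ## all-negative predictions against mixed labels
  cv20 <- confusion_at_cutoff(scores, lab, 20)
  expect_equal(cv20$sensitivity, 0)
  expect_equal(cv20$specificity, 1)
  expect_equal(cv20$auc, 0.5)
  ## unknown patient
  bad <- rbind(lab, data.frame(rater_id = "r1", patient_id = "ghost",
                               label = TRUE))
  expect_error(confusion_at_cutoff(scores, bad, 9), "unknown patient")
})

test_that("the printed operating point gives AUC 0.91, matching the trapezoid", {
  ## (sens, spec) = (0.84, 0.98) -> (sens + spec)/2 = 0.91, and the
  ## three-point trapezoidal area agrees
  sens <- 0.84; spec <- 0.98
  expect_equal((sens + spec) / 2, 0.91)
  expect_equal(auc_trapezoid(c(0, 1 - spec, 1), c(0, sens, 1)), 0.91)
})

test_that("single-threshold AUC equals the trapezoid oracle on random data", {
  set.seed(42)
  for (i in 1:25) {
    n <- 60
    total <- sample(0:16, n, TRUE)
    scores <- data.frame(patient_id = sprintf("p%d", 1:n),
                         pathway = "preexisting_C", total = total,
                         criterion_A = TRUE, criterion_D = TRUE,
                         is_post_pipeline = total >= 9)
    lab <- data.frame(rater_id = "r1", patient_id = scores$patient_id,
                      label = runif(n) < plogis((total - 8) / 2))
    if (all(lab$label) || !any(lab$label)) next
    cv <- confusion_at_cutoff(scores, lab, sample(6:12, 1))
    expect_equal(cv$auc,
                 auc_trapezoid(c(0, 1 - cv$specificity, 1),
                               c(0, cv$sensitivity, 1)))
  }
})

test_that("raising the cutoff never raises sensitivity nor lowers specificity", {
  set.seed(99)
  for (i in 1:10) {
    sim <- simulate_cohort(sim_config(n_patients = 120), seed = 100 + i)
    sc <- score_cohort(sim$cohort)
    labels <- simulate_raters(sim$truth, n_raters = 1, seed = 200 + i)
    sweep <- validate_cutoffs(sc, labels, cutoffs = 5:14)
    expect_true(all(diff(sweep$sensitivity) <= 1e-12))
    expect_true(all(diff(sweep$specificity) >= -1e-12))
  }
})

test_that("binormal fit: closed-form identities and affine invariance", {
  ## identical distributions: chance line
  set.seed(5)
  x <- rnorm(200)
  f <- fit_binormal(x, x)
  expect_equal(f$a, 0)
  expect_equal(f$b, 1)
  expect_equal(f$auc_smooth, 0.5)
  ## mean separation = common sd: a = 1, b = 1, AUC = Phi(1/sqrt(2))
  neg <- c(1, 2, 3, 4, 5)
  f <- fit_binormal(neg + sd(neg), neg)
  expect_equal(f$a, 1)
  expect_equal(f$b, 1)
  expect_equal(f$auc_smooth, pnorm(1 / sqrt(2)))
  expect_equal(round(f$auc_smooth, 3), 0.760)
  ## separation to infinity drives AUC to 1
  f2 <- fit_binormal(neg + 1000 * sd(neg), neg)
  expect_gt(f2$auc_smooth, 0.999)
  ## common affine rescaling leaves the fit invariant
  set.seed(6)
  pos <- rnorm(50, 11, 2); neg <- rnorm(80, 8, 3)
  f1 <- fit_binormal(pos, neg)
  f3 <- fit_binormal(5 + 2.5 * pos, 5 + 2.5 * neg)
  expect_equal(f1$a, f3$a)
  expect_equal(f1$b, f3$b)
  expect_equal(f1$auc_smooth, f3$auc_smooth)
  expect_true(f1$auc_smooth > 0 && f1$auc_smooth < 1)
  ## degenerate input
  expect_error(fit_binormal(c(1, 1, 1), neg), "distinct")
  ## curve points satisfy ROC(t) = Phi(a + b Phi^-1(t))
  cur <- binormal_curve(f1, fpr = c(0.1, 0.5))
  expect_equal(cur$tpr, pnorm(f1$a + f1$b * qnorm(c(0.1, 0.5))))
})

test_that("rater agreement measures the flip model's operating point", {
  truth <- data.frame(patient_id = sprintf("p%d", 1:1000),
                      truth = rep(c(TRUE, FALSE), c(300, 700)))
  labels <- simulate_raters(truth, n_raters = 1, fn_rate = 0, fp_rate = 0,
                            seed = 1)
  ag <- rater_agreement(labels, truth)
  expect_equal(ag$sensitivity, 1)
  expect_equal(ag$specificity, 1)
})
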