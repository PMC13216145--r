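test_that("shapiro_wilk: domain checks and location/scale invariance", {
  set.seed(1)
  x <- rnorm(40)
  a <- shapiro_wilk(x)
  b <- shapiro_wilk(3 + 2.5 * x)
  expect_equal(a$W, b$W)
  expect_equal(a$p_value, b$p_value)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  ## exact normal quantiles look extremely normal
  q <- qnorm((1:50 - 0.5) / 50)
  expect_gt(shapiro_wilk(q)$W, 0.99)
})

test_that("fisher 2x2: balanced table, published sex table, degenerate margin", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  ## sex split 23/85 vs 3/26 by post-pipeline status; the probability-mass
  ## two-sided p, verified by full enumeration (the printed table reports a
  ## different value not reproducible under any Fisher convention)
  sex_tab <- matrix(c(23, 3, 85, 26), 2, 2)
  expect_equal(fisher_exact_2x2(sex_tab), 0.2851603, tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(sex_tab), oracle_fisher_enum(sex_tab))
  expect_warning(p <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("fisher 2x2 equals enumeration and is label-symmetric (random tables)", {
  set.seed(7)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:12, 1)) + 1, 2)
    p <- fisher_exact_2x2(tab)
    expect_equal(p, oracle_fisher_enum(tab), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(tab[2:1, ]), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(t(tab)), tolerance = 1e-12)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("Monte-Carlo r x c test: determinism, cross-oracle, null behaviour", {
  tab <- matrix(c(8, 2, 5, 1, 9, 4), 2, 3)
  a <- fisher_exact_rxc(tab, n_mc = 2000, seed = 11)
  b <- fisher_exact_rxc(tab, n_mc = 2000, seed = 11)
  expect_identical(a$p_value, b$p_value)   # bit-identical under a fixed seed
  expect_error(fisher_exact_rxc(tab, n_mc = 500), ">= 1000")
  ## 2x2 input agrees with the exact test within 3 MC standard errors
  tab2 <- matrix(c(9, 3, 4, 10), 2)
  exact <- fisher_exact_2x2(tab2)
  mc <- fisher_exact_rxc(tab2, n_mc = 20000, seed = 5)
  expect_lt(abs(mc$p_value - exact), 3 * mc$se + 1e-4)
  ## identical row distributions: p near 1
  tab_null <- matrix(c(10, 10, 20, 20, 5, 5), 2, 3)
  expect_gt(fisher_exact_rxc(tab_null, n_mc = 2000, seed = 2)$p_value, 0.8)
})

test_that("Mann-Whitney: exact small-sample p, symmetry, ties", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)
  ## identical multisets: p = 1
  expect_equal(mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))$p_value, 1,
               tolerance = 0.05)
  ## swapping samples maps U -> nx*ny - U with the same p
  set.seed(3)
  x <- rnorm(6); y <- rnorm(9)
  rx <- mann_whitney_u(x, y); ry <- mann_whitney_u(y, x)
  expect_equal(rx$U + ry$U, length(x) * length(y))
  expect_equal(rx$p_value, ry$p_value)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney exact path equals permutation enumeration", {
  set.seed(21)
  for (i in 1:30) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- sample(1:1000, nx); y <- sample(1001:2000, ny) - sample(0:900, ny, TRUE)
    if (anyDuplicated(c(x, y))) next
    r <- mann_whitney_u(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_mw_perm(x, y), tolerance = 1e-12)
  }
  ## the tie-corrected normal approximation tracks enumeration loosely at
  ## n = 7 per group (it is an approximation; deviations to ~0.13 occur
  ## with heavy ties and are expected)
  for (i in 1:10) {
    x <- sample(1:6, 7, TRUE); y <- sample(1:6, 7, TRUE)
    if (length(unique(c(x, y))) == 1) next
    rt <- mann_whitney_u(x, y)
    expect_equal(rt$method, "normal")
    expect_lt(abs(rt$p_value - oracle_mw_perm(x, y)), 0.15)
  }
})

test_that("summarize_cohort mirrors the comparison-table layout", {
  fx <- make_fixture_cohort()
  sc <- score_cohort(fx)
  s <- summarize_cohort(fx, sc, n_mc = 2000)
  expect_equal(s$n_post_pipeline, 29)
  expect_equal(s$n_non_post_pipeline, 108)
  ## anterior circulation split 91 vs 27
  ant <- s$categorical[s$categorical$variable == "anterior_circulation" &
                         s$categorical$level == "yes", ]
  expect_equal(ant$count_neg, 91)
  expect_equal(ant$count_pos, 27)
  expect_equal(ant$count, 118)
  ## percentages recompute from counts within 0.05
  cat_ <- s$categorical
  expect_true(all(abs(cat_$percent - 100 * cat_$count / cat_$n_available)
                  < 0.05))
  ## topography uses the seeded Monte-Carlo exact test
  topo <- s$categorical[s$categorical$variable == "topography", ]
  expect_true(all(topo$test == "fisher_mc"))
  expect_true(all(topo$p_value >= 0 & topo$p_value <= 1))
  ## continuous variables report both groups and a Mann-Whitney p
  expect_true(all(s$continuous$p_value >= 0 & s$continuous$p_value <= 1))
  neck <- s$continuous[s$continuous$variable == "neck_mm", ]
  expect_gt(neck$mean_pos, neck$mean_neg)
})

test_that("one empty group suppresses tests instead of failing", {
  fx <- make_fixture_cohort()[1:20, ]   # all never/new-onset region
  fx <- validate_cohort(as.data.frame(fx)[1:10, ]) # only 'never' records
  sc <- score_cohort(fx)
  s <- summarize_cohort(fx, sc)
  expect_true(s$tests_suppressed)
  expect_true(all(is.na(s$continuous$p_value)))
})
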