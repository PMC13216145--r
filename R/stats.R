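## Nonparametric / exact machinery behind the group-comparison table:
## Shapiro-Wilk normality gate, two-sided Fisher exact tests (2x2 exact,
## r x c by margin-conditional Monte Carlo), Mann-Whitney U.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the AS R94 approximation (the reference algorithm for
#' this test), with the domain checks made explicit.
#'
#' @param x Numeric sample, `3 <= n <= 5000`.
#' @return A list with `W` and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("shapiro_wilk requires 3 <= n <= 5000")
  if (diff(range(x)) == 0) stop("shapiro_wilk: degenerate constant sample")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-mass convention: the two-sided p-value is the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (with relative
#' tolerance 1e-7 on the comparison, so ties at the observed mass are
#' included). This is the common default convention; mid-p and doubling
#' variants differ and are not used.
#'
#' @param table A 2x2 matrix of nonnegative counts.
#' @return The two-sided p-value. A zero margin is degenerate: p = 1 with a
#'   warning.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != round(table)))
    stop("fisher_exact_2x2 expects a 2x2 matrix of nonnegative integer counts")
  r <- rowSums(table); cs <- colSums(table)
  if (any(r == 0) || any(cs == 0)) {
    warning("degenerate 2x2 table (zero margin): p = 1")
    return(1)
  }
  n <- sum(table)
  support <- max(0, cs[1] - r[2]):min(r[1], cs[1])
  probs <- stats::dhyper(support, r[1], r[2], cs[1])
  obs <- stats::dhyper(table[1, 1], r[1], r[2], cs[1])
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

## Log-probability of an r x c table conditional on its margins.
.pp_log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte-Carlo Fisher exact test for an r x c table
#'
#' Estimates the exact conditional (margins-fixed) two-sided p-value by the
#' probability-mass criterion, sampling tables with the observed margins.
#' The estimate is `(1 + #{sampled tables at most as probable}) / (n_mc + 1)`
#' with a binomial standard error; the seed is part of the result so reports
#' are reproducible bit-for-bit.
#'
#' @param table An r x c matrix of nonnegative counts.
#' @param n_mc Number of Monte-Carlo tables (>= 1000).
#' @param seed Integer seed.
#' @return A list with `p_value`, `se`, `n_mc`, `seed`.
#' @export
fisher_exact_rxc <- function(table, n_mc = 10000, seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("fisher_exact_rxc expects nonnegative integer counts")
  if (n_mc < 1000) stop("fisher_exact_rxc: n_mc must be >= 1000")
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  tab <- table[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("degenerate table after dropping empty margins: p = 1")
    return(list(p_value = 1, se = 0, n_mc = n_mc, seed = seed))
  }
  obs <- .pp_log_table_prob(tab)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sims <- stats::r2dtable(n_mc, rowSums(tab), colSums(tab))
  logp <- vapply(sims, .pp_log_table_prob, numeric(1))
  hits <- sum(logp <= obs + 1e-7)
  p <- (1 + hits) / (n_mc + 1)
  list(p_value = p, se = sqrt(p * (1 - p) / n_mc), n_mc = n_mc, seed = seed)
}

#' Mann-Whitney U test
#'
#' U computed from midranks. Two-sided p-value: exact from the null
#' distribution of U when there are no ties and `n_x * n_y <= 400`,
#' otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y Nonempty numeric samples.
#' @return A list with `U` (for `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney_u: both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && nx * ny <= 400) {
    m <- nx * ny
    p <- if (U < m / 2) 2 * stats::pwilcox(U, nx, ny)
    else if (U > m / 2) 2 * (1 - stats::pwilcox(U - 1, nx, ny))
    else 1
    return(list(U = U, p_value = min(1, p), method = "exact"))
  }
  N <- nx + ny
  tab <- table(c(x, y))
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  if (sigma2 == 0) return(list(U = U, p_value = 1, method = "normal"))
  mu <- nx * ny / 2
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

## Cohort summary -------------------------------------------------------------

.pp_summary_continuous <- c(age = "age", neck_mm = "neck_mm",
                            dome_mm = "dome_mm", aspect_ratio = "aspect_ratio",
                            dapt_months = "dapt_months",
                            mapt_months = "mapt_months")
.pp_summary_categorical <- c(sex = "sex", topography = "aneurysm_location",
                             anterior_circulation = "anterior_circulation",
                             coils_used = "coils_used",
                             mapt_used = "mapt_used",
                             steroids_postop = "steroids_postop",
                             reintervention = "reintervention")

summ_cont <- function(x) {
  x <- x[!is.na(x)]
  c(n = length(x), mean = mean(x), sd = stats::sd(x),
    median = stats::median(x), iqr = stats::IQR(x))
}

#' Descriptive and inferential group-comparison summary
#'
#' Produces the machinery behind a demographics/clinical/radiological
#' comparison table split by post-pipeline status: mean, SD, median and IQR
#' for continuous variables (compared with Mann-Whitney U), level counts and
#' percentages for categorical variables (compared with Fisher's exact test;
#' variables with more than two levels use the margin-conditional Monte-Carlo
#' version with a recorded seed). Percentages are always recomputed from
#' counts and per-variable denominators, so partially missing variables
#' report their available n. Normality (Shapiro-Wilk) is exposed as metadata
#' only: following the source analysis, continuous comparisons are always
#' nonparametric.
#'
#' @param cohort A validated cohort data.frame.
#' @param scores The matching [score_cohort()] result.
#' @param mc_seed Seed for the Monte-Carlo exact test.
#' @param n_mc Monte-Carlo iterations.
#' @return A list of class `pp_cohort_summary` with `continuous` and
#'   `categorical` data.frames and the group sizes.
#' @export
summarize_cohort <- function(cohort, scores, mc_seed = 20260910L,
                             n_mc = 10000) {
  stopifnot(nrow(cohort) == nrow(scores))
  grp <- scores$is_post_pipeline
  n_pos <- sum(grp); n_neg <- sum(!grp)
  both <- n_pos > 0 && n_neg > 0

  cont <- do.call(rbind, lapply(names(.pp_summary_continuous), function(v) {
    x <- cohort[[.pp_summary_continuous[[v]]]]
    s0 <- summ_cont(x[!grp]); s1 <- summ_cont(x[grp])
    sw_p <- tryCatch(
      min(shapiro_wilk(x[!grp])$p_value, shapiro_wilk(x[grp])$p_value),
      error = function(e) NA_real_)
    p <- if (both && s0[["n"]] > 0 && s1[["n"]] > 0)
      mann_whitney_u(x[!grp], x[grp])$p_value else NA_real_
    data.frame(variable = v, n_available = sum(!is.na(x)),
               mean_neg = s0[["mean"]], sd_neg = s0[["sd"]],
               median_neg = s0[["median"]], iqr_neg = s0[["iqr"]],
               mean_pos = s1[["mean"]], sd_pos = s1[["sd"]],
               median_pos = s1[["median"]], iqr_pos = s1[["iqr"]],
               shapiro_min_p = sw_p, test = "mann_whitney",
               p_value = p, stringsAsFactors = FALSE)
  }))

  cat_rows <- list()
  for (v in names(.pp_summary_categorical)) {
    x <- cohort[[.pp_summary_categorical[[v]]]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    keep <- !is.na(x)
    lev <- sort(unique(x[keep]))
    tab <- table(factor(x[keep], levels = lev), factor(grp[keep], c(FALSE, TRUE)))
    p <- NA_real_; test <- "none"; seed_used <- NA_integer_
    if (both && length(lev) >= 2 && all(colSums(tab) > 0)) {
      if (length(lev) == 2) {
        p <- fisher_exact_2x2(tab); test <- "fisher_exact"
      } else {
        mc <- fisher_exact_rxc(tab, n_mc = n_mc, seed = mc_seed)
        p <- mc$p_value; test <- "fisher_mc"; seed_used <- mc_seed
      }
    }
    denom <- sum(keep)
    for (l in lev) {
      n_l <- sum(x[keep] == l)
      cat_rows[[length(cat_rows) + 1]] <- data.frame(
        variable = v, level = l, n_available = denom,
        count = n_l, percent = 100 * n_l / denom,
        count_neg = tab[l, 1], percent_neg = 100 * tab[l, 1] / sum(tab[, 1]),
        count_pos = tab[l, 2], percent_pos = 100 * tab[l, 2] / sum(tab[, 2]),
        test = test, p_value = p, mc_seed = seed_used,
        stringsAsFactors = FALSE)
    }
  }

  structure(list(continuous = cont,
                 categorical = do.call(rbind, cat_rows),
                 n_non_post_pipeline = n_neg, n_post_pipeline = n_pos,
                 tests_suppressed = !both),
            class = "pp_cohort_summary")
}

#' @export
print.pp_cohort_summary <- function(x, ...) {
  cat("Cohort comparison: non-post-pipeline n =", x$n_non_post_pipeline,
      "vs post-pipeline n =", x$n_post_pipeline, "\n")
  if (x$tests_suppressed) cat("(one group empty: tests suppressed)\n")
  cat("\nContinuous (mean/sd, Mann-Whitney p):\n")
  print(x$continuous[, c("variable", "n_available", "mean_neg", "sd_neg",
                         "mean_pos", "sd_pos", "p_value")],
        row.names = FALSE, digits = 3)
  cat("\nCategorical (n (%), Fisher p):\n")
  print(x$categorical[, c("variable", "level", "count_neg", "count_pos",
                          "p_value")], row.names = FALSE, digits = 3)
  invisible(x)
}
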