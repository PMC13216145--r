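## Multivariable logistic regression of post-pipeline status: hand-written
## IRLS maximum likelihood with Wald intervals, so convergence criteria and
## separation diagnostics are explicit and testable.

.pp_design_builders <- list(
  age = function(d) d$age,
  sex = function(d) as.numeric(d$sex == "male"),            # male = 1 vs female = 0
  dome_mm = function(d) d$dome_mm,
  anterior_circulation = function(d) as.numeric(d$anterior_circulation),
  neck_mm = function(d) d$neck_mm,
  dapt_months = function(d) d$dapt_months,
  mapt_months = function(d) d$mapt_months,
  partial_thrombosis = function(d) as.numeric(d$partial_thrombosis),
  aspect_ratio = function(d) d$aspect_ratio,
  coils_used = function(d) as.numeric(d$coils_used),
  steroids_postop = function(d) as.numeric(d$steroids_postop),
  mapt_used = function(d) as.numeric(d$mapt_used)
)

#' Model specifications
#'
#' `"model0"` is the baseline specification restricted to age and sex;
#' `"full"` is the eight-covariate specification of the published
#' odds-ratio table.
#'
#' @param name `"model0"` or `"full"`.
#' @return Character vector of covariate names.
#' @export
model_spec <- function(name = c("model0", "full")) {
  name <- match.arg(name)
  if (name == "model0") c("age", "sex")
  else c("age", "sex", "dome_mm", "anterior_circulation", "neck_mm",
         "dapt_months", "mapt_months", "partial_thrombosis")
}

#' Build a logistic-regression design matrix
#'
#' Coding: sex male = 1 vs female = 0; anterior = 1 vs posterior = 0;
#' booleans 0/1; continuous covariates unscaled (mm, months, years), so a
#' neck-size odds ratio is per millimetre.
#'
#' @param cohort A validated cohort data.frame.
#' @param covariates Covariate names (see [model_spec()]).
#' @return A numeric matrix with named columns (no intercept; missing values
#'   propagate as `NA` for complete-case handling downstream).
#' @export
build_design <- function(cohort, covariates = model_spec("full")) {
  unknown <- setdiff(covariates, names(.pp_design_builders))
  if (length(unknown) > 0)
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  X <- vapply(covariates, function(v) .pp_design_builders[[v]](cohort),
              numeric(nrow(cohort)))
  X <- matrix(X, nrow = nrow(cohort),
              dimnames = list(NULL, covariates))
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na))
    stop("covariate(s) entirely missing: ",
         paste(covariates[all_na], collapse = ", "))
  X
}

neg_loglik_logistic <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  -sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
}

#' Fit a logistic regression by IRLS and build the odds-ratio table
#'
#' Newton-Raphson/IRLS maximum likelihood. Convergence when the largest
#' score component is below `tol_score` or the relative log-likelihood
#' change is below `tol_ll`, within `max_iter` iterations. Standard errors
#' are Wald, from the inverse observed information, with 95% intervals
#' `exp(beta +/- 1.96 se)`. Rows with any missing covariate or outcome are
#' dropped (complete-case analysis; `n_used` reports what remained).
#' Perfect separation is detected and reported as an error naming the most
#' implicated covariate, rather than returning divergent estimates.
#'
#' @param outcome Logical or 0/1 outcome per patient.
#' @param design Covariate matrix with named columns (see [build_design()]);
#'   the intercept is added internally.
#' @param max_iter,tol_score,tol_ll Convergence controls.
#' @return A data.frame of class `pp_ortable` with `term`, `beta`, `se`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `p_wald`; attributes `n_used`,
#'   `converged`, `log_lik`, `ll_trace`, `iterations`.
#' @export
fit_logistic <- function(outcome, design, max_iter = 50,
                         tol_score = 1e-8, tol_ll = 1e-10) {
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(outcome)
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  n_used <- length(y)
  if (n_used < ncol(X) + 2) stop("too few complete cases (", n_used, ")")
  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(X)[const], collapse = ", "))
  Xi <- cbind(`(intercept)` = 1, X)
  p_dim <- ncol(Xi)
  beta <- numeric(p_dim)
  ll <- function(b) -neg_loglik_logistic(b, Xi, y)
  ll_trace <- ll(beta)
  converged <- FALSE
  info <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(Xi, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(Xi * w, Xi)
    step <- tryCatch(solve(info, score), error = function(e)
      stop("IRLS failed: singular information matrix (iteration ", it, ")"))
    ## Step-halving keeps the log-likelihood monotone.
    ll_old <- ll_trace[length(ll_trace)]
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- ll(cand)
      if (ll_new >= ll_old - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- cand
    ll_trace <- c(ll_trace, ll_new)
    ## Separation: diverging linear predictor with perfect classification
    ## (a margin-positive separating hyperplane means the MLE diverges).
    eta <- drop(Xi %*% beta)
    if (max(abs(eta)) > 15 && all((eta > 0) == (y == 1))) {
      sds <- apply(X, 2, stats::sd)
      culprit <- colnames(X)[which.max(abs(beta[-1]) * sds)]
      stop("perfect separation detected; covariate most implicated: ",
           culprit)
    }
    if (max(abs(score)) < tol_score ||
        abs(ll_new - ll_old) < tol_ll * (abs(ll_old) + tol_ll)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("logistic regression did not converge in ", max_iter,
         " iterations; log-likelihood trace: ",
         paste(sprintf("%.6f", ll_trace), collapse = ", "))
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  out <- data.frame(term = colnames(Xi), beta = beta, se = se,
                    odds_ratio = exp(beta),
                    ci_lower = exp(beta - 1.96 * se),
                    ci_upper = exp(beta + 1.96 * se),
                    p_wald = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_used") <- n_used
  attr(out, "converged") <- converged
  attr(out, "log_lik") <- ll_trace[length(ll_trace)]
  attr(out, "ll_trace") <- ll_trace
  attr(out, "iterations") <- it
  class(out) <- c("pp_ortable", class(out))
  out
}

#' Format an odds-ratio table the way the published table prints it
#'
#' @param x A `pp_ortable`.
#' @param digits Decimal places (default 3).
#' @return A character data.frame with `term`, `beta`, `se`,
#'   `odds_ratio_ci`, `p_value`.
#' @export
format_ortable <- function(x, digits = 3) {
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  data.frame(term = x$term, beta = fmt(x$beta), se = fmt(x$se),
             odds_ratio_ci = sprintf("%s (%s-%s)", fmt(x$odds_ratio),
                                     fmt(x$ci_lower), fmt(x$ci_upper)),
             p_value = fmt(x$p_wald), stringsAsFactors = FALSE)
}

#' @export
print.pp_ortable <- function(x, ...) {
  cat("Logistic regression (n =", attr(x, "n_used"), ", log-likelihood",
      sprintf("%.3f", attr(x, "log_lik")), ",",
      attr(x, "iterations"), "IRLS iterations)\n")
  print(format_ortable(x), row.names = FALSE)
  invisible(x)
}
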