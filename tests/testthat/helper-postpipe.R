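## Shared fixtures and independent oracles. Oracles deliberately avoid the
## code paths they check: enumeration via lchoose, scoring via plain
## if-chains, likelihoods via generic optimisation.

## One-row cohort record with sensible defaults, overridable field by field.
mk_record <- function(...) {
  rec <- cohort_template(1)
  rec$patient_id <- "T001"
  rec$age <- 55
  rec$sex <- "female"
  rec$prior_headache_diagnosis <- "migraine"
  rec$pre_present <- TRUE
  rec$pre_nrs <- 5; rec$pre_mhd <- 6; rec$pre_duration_h <- 12
  rec$pre_laterality <- "ipsilateral"; rec$pre_symptoms <- "photophobia"
  rec$pre_amn <- 4
  rec$post3m_present <- TRUE
  rec$post3m_nrs <- 5; rec$post3m_mhd <- 6; rec$post3m_duration_h <- 12
  rec$post3m_laterality <- "ipsilateral"; rec$post3m_symptoms <- "photophobia"
  rec$post3m_amn <- 4
  rec$similarity_rating <- 9
  rec$criterion_A <- TRUE; rec$criterion_D <- TRUE
  rec$patient_reported_direction <- "same"
  rec$aneurysm_location <- "Ophthalmic"
  rec$anterior_circulation <- TRUE
  rec$neck_mm <- 5; rec$dome_mm <- 10; rec$aspect_ratio <- 2
  over <- list(...)
  for (f in names(over)) rec[[f]] <- over[[f]]
  rec
}

## Random scoreable cohort (mix of naive / pre-existing / no-post records),
## valid for score_cohort without further validation.
random_scoreable_cohort <- function(n, seed) {
  set.seed(seed)
  cohort <- cohort_template(n)
  cohort$patient_id <- sprintf("R%05d", seq_len(n))
  cohort$age <- sample(18:90, n, TRUE)
  cohort$sex <- sample(c("male", "female"), n, TRUE)
  kind <- sample(c("naive_post", "naive_never", "pre"), n, TRUE,
                 prob = c(0.15, 0.15, 0.7))
  pre <- kind == "pre"
  cohort$prior_headache_diagnosis <- ifelse(pre, "migraine", "none")
  cohort$pre_present <- pre
  cohort$post3m_present <- kind != "naive_never"
  lats <- c("ipsilateral", "contralateral", "bilateral", "unknown")
  syms <- c("nausea", "vomiting", "photophobia", "phonophobia",
            "visual_disturbances")
  rsym <- function(k) vapply(seq_len(k), function(i) {
    s <- sample(syms, sample(0:3, 1))
    if (length(s) == 0) "none" else paste(sort(s), collapse = ";")
  }, character(1))
  np <- sum(pre)
  cohort$pre_nrs[pre] <- sample(0:10, np, TRUE)
  cohort$pre_mhd[pre] <- sample(0:31, np, TRUE)
  cohort$pre_duration_h[pre] <- sample(c(0.5, 2, 4, 12, 24, 36, 72, 100), np, TRUE)
  cohort$pre_laterality[pre] <- sample(lats, np, TRUE)
  cohort$pre_symptoms[pre] <- rsym(np)
  cohort$pre_amn[pre] <- sample(0:10, np, TRUE)
  post <- cohort$post3m_present
  npo <- sum(post)
  cohort$post3m_nrs[post] <- sample(0:10, npo, TRUE)
  cohort$post3m_mhd[post] <- sample(0:31, npo, TRUE)
  cohort$post3m_duration_h[post] <- sample(c(0.5, 2, 4, 12, 24, 36, 72, 100), npo, TRUE)
  cohort$post3m_laterality[post] <- sample(lats, npo, TRUE)
  cohort$post3m_symptoms[post] <- rsym(npo)
  cohort$post3m_amn[post] <- sample(0:10, npo, TRUE)
  both <- pre & post
  cohort$similarity_rating[both] <- sample(0:10, sum(both), TRUE)
  cohort$criterion_A[post] <- sample(c(TRUE, FALSE), npo, TRUE)
  cohort$criterion_D[post] <- sample(c(TRUE, FALSE), npo, TRUE)
  cohort$patient_reported_direction <- ifelse(pre,
    sample(c("improved", "same", "worse"), n, TRUE), "not_applicable")
  cohort
}

## Independent brute-force scorer: plain if-chains over one record.
oracle_score_record <- function(row, threshold = 9, c3multi = 4) {
  post <- isTRUE(row$post3m_present)
  pre <- isTRUE(row$pre_present)
  A <- isTRUE(row$criterion_A); D <- isTRUE(row$criterion_D)
  if (!post) return(list(total = 0, is_pp = FALSE))
  if (!pre) return(list(total = 9, is_pp = A && D))
  cat_of <- function(h) {
    if (h < 4) 0 else if (h <= 24) 1 else if (h <= 72) 2 else 3
  }
  d <- row$post3m_nrs - row$pre_nrs
  c1 <- if (d >= 4) 4 else if (d >= 2) 2 else 0
  c2 <- if (row$pre_laterality == "contralateral" &&
            row$post3m_laterality == "ipsilateral") 2 else 0
  k <- cat_of(row$post3m_duration_h) - cat_of(row$pre_duration_h)
  c3 <- if (k >= 2) c3multi else if (k == 1) 1 else 0
  split1 <- function(s) if (s == "none") character(0) else
    strsplit(s, ";", fixed = TRUE)[[1]]
  new_s <- setdiff(split1(row$post3m_symptoms), split1(row$pre_symptoms))
  c4 <- sum(ifelse(new_s == "nausea", 2, 1))
  dd <- row$post3m_mhd - row$pre_mhd
  c5 <- if (dd >= 5 && (row$pre_mhd == 0 || dd / row$pre_mhd >= 0.5)) 4 else 0
  dis <- 10 - row$similarity_rating
  c6 <- if (dis >= 8) 4 else if (dis >= 6) 2 else 0
  total <- c1 + c2 + c3 + c4 + c5 + c6
  list(total = total, is_pp = A && D && total >= threshold)
}

## Enumeration oracle for the two-sided (probability-mass) Fisher 2x2 p.
oracle_fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[support == tab[1, 1]]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

## Permutation-enumeration oracle for the exact Mann-Whitney two-sided p.
oracle_mw_perm <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  idx <- utils::combn(nx + ny, nx)
  U_all <- apply(idx, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
}

## Generic-optimiser oracle for logistic maximum likelihood.
oracle_logistic_bfgs <- function(y, X) {
  Xi <- cbind(1, X)
  nll <- function(b) {
    eta <- drop(Xi %*% b)
    -sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
  }
  grad <- function(b) -drop(crossprod(Xi, y - stats::plogis(drop(Xi %*% b))))
  stats::optim(numeric(ncol(Xi)), nll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))$par
}
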