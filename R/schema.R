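#' @keywords internal
"_PACKAGE"

## Controlled vocabularies ----------------------------------------------------

.pp_schema_version <- "1.0"

.pp_lateralities <- c("ipsilateral", "contralateral", "bilateral", "unknown")
.pp_symptoms <- c("nausea", "vomiting", "photophobia", "phonophobia",
                  "visual_disturbances")
.pp_sexes <- c("male", "female")
.pp_prior_dx <- c("none", "migraine", "tension_type", "secondary_to_aneurysm")
.pp_directions <- c("improved", "same", "worse", "not_applicable")
.pp_items <- c("A", "B", "C1", "C2", "C3", "C4", "C5", "C6", "D", "threshold")

## Aneurysm topography labels mirroring the published Table 2 rows.
.pp_locations <- c(
  "Vertebral-Basilar", "Vertebral-PICA", "Basilar-P1", "ACA A1-A2", "Acom",
  "A2-A3", "ICA Cervical", "Petrous", "Cavernous", "Ophthalmic", "Choroidal",
  "Pcom", "A1", "M1", "MCA M1-M2", "PCA P1-Pcom", "P2-P3")

## Profile fields are stored per epoch with a prefix (pre_, post3m_, post12m_).
.pp_profile_fields <- c(present = "logical", nrs = "numeric", mhd = "numeric",
                        duration_h = "numeric", laterality = "character",
                        symptoms = "character", amn = "numeric")

.pp_epochs <- c("pre", "post3m", "post12m")

#' Column schema of a cohort table
#'
#' One row per column of `cohort.csv`: name, storage type and whether the
#' column is mandatory in the file. Headache-profile fields appear three
#' times, prefixed `pre_` (six months before implantation), `post3m_`
#' (three-month assessment, the diagnostic window) and `post12m_`
#' (twelve-month follow-up, optional).
#'
#' @return A data.frame with columns `column`, `type`, `required`.
#' @export
cohort_schema <- function() {
  base <- data.frame(
    column = c("patient_id", "age", "sex", "prior_headache_diagnosis"),
    type = c("character", "numeric", "character", "character"),
    required = TRUE, stringsAsFactors = FALSE)
  prof <- do.call(rbind, lapply(.pp_epochs, function(ep) {
    data.frame(column = paste(ep, names(.pp_profile_fields), sep = "_"),
               type = unname(.pp_profile_fields),
               required = ep != "post12m", stringsAsFactors = FALSE)
  }))
  rest <- data.frame(
    column = c("similarity_rating", "criterion_A", "criterion_D",
               "patient_reported_direction", "aneurysm_location",
               "anterior_circulation", "neck_mm", "dome_mm", "aspect_ratio",
               "coils_used", "dapt_months", "mapt_used", "mapt_months",
               "steroids_postop", "reintervention", "partial_thrombosis"),
    type = c("numeric", "logical", "logical", "character", "character",
             "logical", "numeric", "numeric", "numeric", "logical", "numeric",
             "logical", "numeric", "logical", "logical", "logical"),
    required = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  rbind(base, prof, rest)
}

#' Empty cohort table
#'
#' @param n Number of (all-missing) rows to pre-allocate.
#' @return A zero- or `n`-row data.frame with every schema column, typed.
#' @export
cohort_template <- function(n = 0L) {
  sch <- cohort_schema()
  cols <- lapply(seq_len(nrow(sch)), function(i)
    rep(as.vector(NA, mode = sch$type[i]), n))
  names(cols) <- sch$column
  as.data.frame(cols, stringsAsFactors = FALSE)
}

## Symptom sets travel as a single CSV cell: ";"-joined tokens, "none" for an
## explicitly empty set (so that an empty cell keeps meaning "profile absent").
parse_symptoms <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s) || identical(s, "none")) return(character(0))
    strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

format_symptoms <- function(sets) {
  vapply(sets, function(s) {
    if (length(s) == 0) "none" else paste(s, collapse = ";")
  }, character(1))
}

#' Laterality relative to the treated aneurysm
#'
#' The scoring system defines lateralization change relative to the aneurysm
#' side, so cohorts store relative laterality. This helper converts an
#' absolute headache side plus the aneurysm side into that encoding;
#' bilateral or midline headache maps to `"bilateral"`, anything
#' undetermined to `"unknown"`.
#'
#' @param headache_side `"left"`, `"right"`, `"bilateral"` or `NA`.
#' @param aneurysm_side `"left"`, `"right"` or `NA`.
#' @return One of `"ipsilateral"`, `"contralateral"`, `"bilateral"`,
#'   `"unknown"` (vectorised).
#' @export
relative_laterality <- function(headache_side, aneurysm_side) {
  n <- max(length(headache_side), length(aneurysm_side))
  hs <- rep_len(as.character(headache_side), n)
  as_ <- rep_len(as.character(aneurysm_side), n)
  ok <- c("left", "right", "bilateral")
  bad <- !is.na(hs) & !hs %in% ok
  if (any(bad)) stop("unknown headache side: ", paste(unique(hs[bad]), collapse = ", "))
  bad <- !is.na(as_) & !as_ %in% c("left", "right")
  if (any(bad)) stop("unknown aneurysm side: ", paste(unique(as_[bad]), collapse = ", "))
  out <- rep("unknown", n)
  out[!is.na(hs) & hs == "bilateral"] <- "bilateral"
  uni <- !is.na(hs) & hs != "bilateral" & !is.na(as_)
  out[uni & hs == as_] <- "ipsilateral"
  out[uni & hs != as_] <- "contralateral"
  out
}

## Validation -----------------------------------------------------------------

## Each rule returns a data.frame(row, field, message) of violations.
.pp_issue <- function(rows, field, message, cohort) {
  if (length(rows) == 0) return(NULL)
  data.frame(row = rows,
             patient_id = as.character(cohort$patient_id[rows]),
             field = field, message = message, stringsAsFactors = FALSE)
}

.pp_profile_issues <- function(cohort, ep) {
  pfx <- function(f) cohort[[paste(ep, f, sep = "_")]]
  present <- pfx("present")
  iss <- list()
  add <- function(rows, field, msg)
    iss[[length(iss) + 1]] <<- .pp_issue(rows, paste(ep, field, sep = "_"), msg, cohort)
  if (ep != "post12m")
    add(which(is.na(present)), "present", "must be TRUE/FALSE")
  on <- which(!is.na(present) & present)
  off <- which(!is.na(present) & !present)
  nrs <- pfx("nrs"); mhd <- pfx("mhd"); dur <- pfx("duration_h")
  lat <- pfx("laterality"); amn <- pfx("amn")
  sym <- pfx("symptoms")
  ## present = FALSE => numeric fields absent/zero, symptoms empty
  nonzero <- function(x) !is.na(x) & x != 0
  add(off[nonzero(nrs[off]) | nonzero(mhd[off]) | nonzero(dur[off]) |
            nonzero(amn[off])],
      "present", "present=FALSE requires numeric headache fields absent/zero")
  add(off[!is.na(lat[off]) | (!is.na(sym[off]) & sym[off] != "none")],
      "present", "present=FALSE requires laterality and symptoms empty")
  add(on[!is.na(nrs[on]) & (nrs[on] < 0 | nrs[on] > 10)], "nrs",
      "0 <= nrs <= 10")
  add(on[!is.na(mhd[on]) & (mhd[on] < 0 | mhd[on] > 31)], "mhd",
      "0 <= monthly headache days <= 31")
  add(on[!is.na(dur[on]) & dur[on] <= 0], "duration_h",
      "attack duration must be > 0 hours")
  add(on[!is.na(amn[on]) & amn[on] < 0], "amn", "analgesic count must be >= 0")
  add(on[!is.na(lat[on]) & !lat[on] %in% .pp_lateralities], "laterality",
      paste("laterality must be one of:", paste(.pp_lateralities, collapse = ", ")))
  toks <- parse_symptoms(sym)
  bad <- which(vapply(toks, function(t) any(!t %in% .pp_symptoms), logical(1)))
  add(intersect(bad, on), "symptoms",
      paste("symptoms must be a subset of:", paste(.pp_symptoms, collapse = ", ")))
  do.call(rbind, iss)
}

#' Validate a cohort table against the documented invariants
#'
#' Checks every record-level invariant (age, vocabularies, profile
#' consistency, the prior-diagnosis/pre-profile equivalence, similarity-rating
#' availability, positive aneurysm dimensions, unique patient ids). All
#' violations are collected and reported together with row number, patient id
#' and field; valid rows are never rejected.
#'
#' @param cohort A data.frame following [cohort_schema()].
#' @return `cohort`, invisibly, with class `pp_cohort` added.
#' @export
validate_cohort <- function(cohort) {
  sch <- cohort_schema()
  missing_cols <- setdiff(sch$column[sch$required], names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(sch$column, names(cohort)))
    cohort[[col]] <- rep(as.vector(NA, mode = sch$type[sch$column == col]),
                         nrow(cohort))
  cohort <- cohort[, sch$column]
  iss <- list()
  add <- function(rows, field, msg)
    iss[[length(iss) + 1]] <<- .pp_issue(rows, field, msg, cohort)

  add(which(is.na(cohort$patient_id) | !nzchar(cohort$patient_id)),
      "patient_id", "must be nonmissing")
  add(which(duplicated(cohort$patient_id)), "patient_id", "must be unique")
  add(which(!is.na(cohort$age) & cohort$age < 18), "age", "age >= 18")
  add(which(is.na(cohort$age)), "age", "must be present")
  add(which(!cohort$sex %in% .pp_sexes), "sex", "must be male or female")
  add(which(!cohort$prior_headache_diagnosis %in% .pp_prior_dx),
      "prior_headache_diagnosis",
      paste("must be one of:", paste(.pp_prior_dx, collapse = ", ")))
  ## prior_headache_diagnosis = none <=> no pre-procedural headache profile
  pre <- cohort$pre_present
  none <- cohort$prior_headache_diagnosis %in% "none"
  add(which(none & !is.na(pre) & pre), "prior_headache_diagnosis",
      "prior diagnosis 'none' requires pre_present=FALSE")
  add(which(!none & !is.na(cohort$prior_headache_diagnosis) &
              !is.na(pre) & !pre),
      "prior_headache_diagnosis",
      "a prior headache diagnosis requires pre_present=TRUE")
  for (ep in .pp_epochs)
    iss[[length(iss) + 1]] <- .pp_profile_issues(cohort, ep)
  both <- !is.na(pre) & pre & !is.na(cohort$post3m_present) & cohort$post3m_present
  add(which(!is.na(cohort$similarity_rating) & !both), "similarity_rating",
      "similarity rating requires both pre and post3m headache present")
  add(which(!is.na(cohort$similarity_rating) &
              (cohort$similarity_rating < 0 | cohort$similarity_rating > 10)),
      "similarity_rating", "0 <= similarity <= 10")
  add(which(!is.na(cohort$patient_reported_direction) &
              !cohort$patient_reported_direction %in% .pp_directions),
      "patient_reported_direction",
      paste("must be one of:", paste(.pp_directions, collapse = ", ")))
  add(which(!is.na(pre) & pre &
              (is.na(cohort$patient_reported_direction) |
                 cohort$patient_reported_direction == "not_applicable")),
      "patient_reported_direction",
      "patients with a pre-existing headache must report improved/same/worse")
  add(which(!is.na(cohort$aneurysm_location) &
              !cohort$aneurysm_location %in% .pp_locations),
      "aneurysm_location", "unknown topography label")
  for (f in c("neck_mm", "dome_mm", "aspect_ratio"))
    add(which(!is.na(cohort[[f]]) & cohort[[f]] <= 0), f, "must be > 0")
  for (f in c("dapt_months", "mapt_months"))
    add(which(!is.na(cohort[[f]]) & cohort[[f]] < 0), f, "must be >= 0")
  post <- cohort$post3m_present
  for (f in c("criterion_A", "criterion_D"))
    add(which(!is.na(post) & post & is.na(cohort[[f]])), f,
        "required when a post-procedural headache is present")

  iss <- do.call(rbind, iss)
  if (!is.null(iss) && nrow(iss) > 0) {
    iss <- iss[order(iss$row), ]
    shown <- utils::head(iss, 10)
    stop("cohort validation failed (", nrow(iss), " issue(s)):\n",
         paste(sprintf("  row %d [%s] %s: %s", shown$row, shown$patient_id,
                       shown$field, shown$message), collapse = "\n"),
         if (nrow(iss) > 10) "\n  ...", call. = FALSE)
  }
  class(cohort) <- unique(c("pp_cohort", class(cohort)))
  invisible(cohort)
}

## I/O ------------------------------------------------------------------------

#' Read a cohort CSV
#'
#' The first line of the file is a schema guard
#' (`# postpipe_cohort_schema=<version>`); a mismatch stops with an error so
#' silent column drift cannot occur. Empty cells are missing values -- `0` is
#' always a legal value and never means "missing".
#'
#' @param path Path to a `cohort.csv`.
#' @param schema_version Expected schema version.
#' @return A validated `pp_cohort` data.frame; row numbers of the source file
#'   are kept in attribute `"source_row"` for diagnostics.
#' @export
read_cohort <- function(path, schema_version = .pp_schema_version) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  first <- readLines(path, n = 1)
  tag <- sub("^#\\s*postpipe_cohort_schema=", "", first)
  if (identical(tag, first))
    stop("cohort schema error: missing '# postpipe_cohort_schema=' header line")
  if (!identical(tag, schema_version))
    stop("cohort schema error: file schema version '", tag,
         "' does not match expected '", schema_version, "'")
  sch <- cohort_schema()
  header <- utils::read.csv(path, skip = 1, nrows = 1, header = TRUE,
                            check.names = FALSE)
  missing_cols <- setdiff(sch$column[sch$required], names(header))
  if (length(missing_cols) > 0)
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  classes <- stats::setNames(sch$type, sch$column)[names(header)]
  classes[is.na(classes)] <- "character"
  df <- utils::read.csv(path, skip = 1, header = TRUE, check.names = FALSE,
                        na.strings = c("NA", ""), colClasses = unname(classes),
                        stringsAsFactors = FALSE)
  out <- validate_cohort(df)
  attr(out, "source_row") <- seq_len(nrow(out)) + 2L
  out
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: optional missing fields become empty cells
#' (never zeros), and `read_cohort(write_cohort(x))` reproduces `x`
#' field-for-field.
#'
#' @param cohort A validated cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write cohort file: ", path)
  on.exit(close(con))
  writeLines(paste0("# postpipe_cohort_schema=", .pp_schema_version), con)
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or validate expert-panel ratings
#'
#' Long format, one judgment per row: `rater_id`, `item_id` (A, B, C1-C6, D,
#' threshold), `relevance` and `clarity`, each an integer 1-4 on the Likert
#' relevance/clarity scale.
#'
#' @param path Path to `panel.csv`.
#' @return A validated data.frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  validate_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_panel
#' @param panel A data.frame of expert ratings.
#' @export
validate_panel <- function(panel) {
  need <- c("rater_id", "item_id", "relevance", "clarity")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols) > 0)
    stop("panel schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!panel$item_id %in% .pp_items))
    stop("panel validation: unknown item_id: ",
         paste(setdiff(unique(panel$item_id), .pp_items), collapse = ", "))
  for (f in c("relevance", "clarity"))
    if (any(!panel[[f]] %in% 1:4))
      stop("panel validation: ", f, " must be an integer in 1..4")
  panel
}

#' Read or validate rater labels
#'
#' One binary post-pipeline classification per (rater, patient):
#' `rater_id`, `patient_id`, `label` (TRUE/FALSE).
#'
#' @param path Path to `raters.csv`.
#' @return A validated data.frame.
#' @export
read_raters <- function(path) {
  if (!file.exists(path)) stop("rater file not found: ", path)
  validate_raters(utils::read.csv(path, stringsAsFactors = FALSE,
                                  colClasses = c(label = "logical")))
}

#' @rdname read_raters
#' @param labels A data.frame of rater labels.
#' @export
validate_raters <- function(labels) {
  need <- c("rater_id", "patient_id", "label")
  missing_cols <- setdiff(need, names(labels))
  if (length(missing_cols) > 0)
    stop("rater schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.logical(labels$label)) stop("rater labels must be logical")
  if (any(is.na(labels$label))) stop("rater labels must be nonmissing")
  key <- paste(labels$rater_id, labels$patient_id)
  if (anyDuplicated(key))
    stop("rater validation: duplicate (rater, patient) label: ",
         key[duplicated(key)][1])
  labels
}
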