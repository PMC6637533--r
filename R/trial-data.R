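# Trial data model: participant and visit tables, CSV round trip, validation,
# and biomarker subgroup predicates.

#' Construct a trial dataset
#'
#' A `trial_dataset` bundles one row per participant (baseline covariates,
#' baseline biomarker concentrations, the exacerbation count and its exposure
#' time) with an optional long table of per-visit secondary-endpoint values,
#' plus analysis-set metadata (pooling flag, exclusion log).
#'
#' @param participants data.frame with the columns listed in
#'   [load_trial()]; one row per participant.
#' @param visits optional data.frame with columns `participant_id`,
#'   `endpoint`, `week`, `value`; one row per participant-visit-endpoint.
#' @param metadata list; analysis-set label, pooling flag, exclusion log.
#' @param validate run invariant checks (default TRUE).
#' @return an object of class `trial_dataset`.
#' @export
trial_dataset <- function(participants, visits = NULL, metadata = list(),
                          validate = TRUE) {
  participants <- as.data.frame(participants)
  if (!is.null(visits)) visits <- as.data.frame(visits)
  metadata$analysis_set <- metadata$analysis_set %||% "FAS"
  metadata$pooled <- metadata$pooled %||% FALSE
  metadata$exclusions <- metadata$exclusions %||%
    data.frame(participant_id = character(), rule = character(),
               value = numeric(), stringsAsFactors = FALSE)
  x <- structure(list(participants = participants, visits = visits,
                      metadata = metadata), class = "trial_dataset")
  if (validate) validate_trial(x)
  x
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset> ", nrow(x$participants), " participants",
      if (!is.null(x$visits)) paste0(", ", nrow(x$visits), " visit records"),
      "\n", sep = "")
  cat("  analysis set: ", x$metadata$analysis_set,
      if (isTRUE(x$metadata$pooled)) " (placebo arms pooled)", "\n", sep = "")
  cat("  arms: ", paste(names(table(x$participants$arm)), collapse = ", "), "\n",
      sep = "")
  if (nrow(x$metadata$exclusions))
    cat("  exclusions: ", nrow(x$metadata$exclusions), "\n", sep = "")
  invisible(x)
}

validate_trial <- function(x) {
  p <- x$participants
  missing_cols <- setdiff(PARTICIPANT_COLS, names(p))
  if (length(missing_cols))
    stop("schema error: participants table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_fu <- p$participant_id[!is.na(p$followup_years) & p$followup_years <= 0]
  if (length(bad_fu))
    stop("validation error: followup_years must be positive; offending ids: ",
         paste(bad_fu, collapse = ", "), call. = FALSE)
  bad_ct <- p$participant_id[!is.na(p$exacerbation_count) & p$exacerbation_count < 0]
  if (length(bad_ct))
    stop("validation error: exacerbation_count must be non-negative; offending ids: ",
         paste(bad_ct, collapse = ", "), call. = FALSE)
  ok_arms <- c(ARM_LEVELS_4, ARM_LEVELS_3)
  bad_arm <- setdiff(unique(as.character(p$arm)), ok_arms)
  if (length(bad_arm))
    stop("validation error: unknown arm level(s): ",
         paste(bad_arm, collapse = ", "), call. = FALSE)
  if ("age_group" %in% names(p)) {
    expect <- ifelse(p$age_years >= 12 & p$age_years < 18, "adolescent", "adult")
    if (any(!is.na(p$age_group) & p$age_group != expect))
      stop("validation error: age_group inconsistent with age_years ",
           "(adolescent iff 12 <= age < 18)", call. = FALSE)
  }
  if (!is.null(x$visits)) {
    v <- x$visits
    mc <- setdiff(VISIT_COLS, names(v))
    if (length(mc))
      stop("schema error: visits table lacks required column(s): ",
           paste(mc, collapse = ", "), call. = FALSE)
    orphan <- setdiff(unique(v$participant_id), p$participant_id)
    if (length(orphan))
      stop("validation error: visit records for unknown participant(s): ",
           paste(head(orphan, 5), collapse = ", "), call. = FALSE)
    key <- paste(v$participant_id, v$endpoint, v$week)
    if (anyDuplicated(key))
      stop("validation error: duplicate (participant, endpoint, week) visit rows",
           call. = FALSE)
  }
  invisible(x)
}

#' Read a trial dataset from CSV files
#'
#' Files are comma-separated UTF-8 with a header row; missing values are
#' encoded as empty fields and preserved as `NA` (never coerced to zero).
#'
#' @param participants_path path to the participants CSV
#'   (columns: participant_id, arm, feno_ppb, periostin_ng_ml, eos_cells_ul,
#'   dpp4_ng_ml, ige_iu_ml, region, age_years, prior_exacerbations,
#'   exacerbation_count, followup_years, baseline_acq6, baseline_aqlq,
#'   baseline_symptom, baseline_fev1).
#' @param visits_path optional path to the visits CSV
#'   (participant_id, endpoint, week, value).
#' @return a [trial_dataset()].
#' @export
load_trial <- function(participants_path, visits_path = NULL) {
  if (!file.exists(participants_path))
    stop("file not found: ", participants_path, call. = FALSE)
  p <- read.csv(participants_path, na.strings = c("", "NA"),
                stringsAsFactors = FALSE)
  v <- NULL
  if (!is.null(visits_path)) {
    if (!file.exists(visits_path))
      stop("file not found: ", visits_path, call. = FALSE)
    v <- read.csv(visits_path, na.strings = c("", "NA"),
                  stringsAsFactors = FALSE)
  }
  p$participant_id <- as.character(p$participant_id)
  if (!is.null(v)) v$participant_id <- as.character(v$participant_id)
  trial_dataset(p, v)
}

#' Write a trial dataset to CSV files
#'
#' Inverse of [load_trial()]; missing values are written as empty fields so
#' that a write/read round trip is lossless.
#'
#' @param data a [trial_dataset()].
#' @param participants_path,visits_path output paths; visits written only
#'   when present and a path is given.
#' @return invisibly, the paths written.
#' @export
write_trial <- function(data, participants_path, visits_path = NULL) {
  stopifnot(inherits(data, "trial_dataset"))
  write.csv(data$participants[, intersect(c(PARTICIPANT_COLS,
                                            setdiff(names(data$participants), PARTICIPANT_COLS)),
                                          names(data$participants))],
            participants_path, row.names = FALSE, na = "")
  out <- participants_path
  if (!is.null(data$visits) && !is.null(visits_path)) {
    write.csv(data$visits, visits_path, row.names = FALSE, na = "")
    out <- c(out, visits_path)
  }
  invisible(out)
}

# ---- subgroups ---------------------------------------------------------------

#' Define a biomarker subgroup by cut-off
#'
#' A subgroup is a membership predicate over participants with a non-missing
#' value of the biomarker: either above the cut-off or at-or-below it. With
#' `strict = TRUE` "above" means `x > cutoff` (its complement `x <= cutoff`);
#' with `strict = FALSE` "above" means `x >= cutoff`. Compound subgroups
#' (intersections over several covariates, as produced by deeper SIDES
#' searches) hold several conditions that must all be met.
#'
#' @param biomarker column name, e.g. `"feno_ppb"`.
#' @param cutoff numeric cut-off.
#' @param direction `"above"` or `"at_or_below"`.
#' @param strict logical; whether "above" is strict (`>`) or inclusive (`>=`).
#' @return an object of class `subgroup`.
#' @export
subgroup <- function(biomarker, cutoff,
                     direction = c("above", "at_or_below"), strict = TRUE) {
  direction <- match.arg(direction)
  structure(list(conditions = data.frame(
    biomarker = biomarker, direction = direction, cutoff = cutoff,
    strict = strict, stringsAsFactors = FALSE)), class = "subgroup")
}

#' Intersect two subgroups into a compound subgroup
#' @param a,b `subgroup` objects.
#' @return a `subgroup` whose membership is the conjunction of both.
#' @export
intersect_subgroups <- function(a, b) {
  stopifnot(inherits(a, "subgroup"), inherits(b, "subgroup"))
  structure(list(conditions = rbind(a$conditions, b$conditions)),
            class = "subgroup")
}

#' @export
format.subgroup <- function(x, ...) {
  one <- function(i) {
    cn <- x$conditions[i, ]
    lab <- BIOMARKER_LABELS[cn$biomarker]
    if (is.na(lab)) lab <- cn$biomarker
    un <- BIOMARKER_UNITS[cn$biomarker]
    un <- if (is.na(un)) "" else paste0(" ", un)
    op <- if (cn$direction == "above") {
      if (cn$strict) ">" else ">="
    } else {
      if (cn$strict) "<=" else "<"
    }
    sprintf("%s %s %s%s", lab, op, format(cn$cutoff, digits = 4), un)
  }
  paste(vapply(seq_len(nrow(x$conditions)), one, ""), collapse = " & ")
}

#' @export
print.subgroup <- function(x, ...) {
  cat("<subgroup> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Subgroup membership
#'
#' @param data a `trial_dataset` or participants data.frame.
#' @param sg a [subgroup()].
#' @return logical vector, one per participant; `NA` where any biomarker in
#'   the definition is missing.
#' @export
in_subgroup <- function(data, sg) {
  df <- if (inherits(data, "trial_dataset")) data$participants else data
  memb <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(sg$conditions))) {
    cn <- sg$conditions[i, ]
    x <- df[[cn$biomarker]]
    if (is.null(x)) stop("unknown biomarker in subgroup: ", cn$biomarker)
    above <- if (cn$strict) x > cn$cutoff else x >= cn$cutoff
    memb <- memb & (if (cn$direction == "above") above else !above)
  }
  memb
}

#' Complement of a single-condition subgroup
#' @param sg a one-condition [subgroup()].
#' @return the complementary `subgroup` (same cut-off, flipped direction).
#' @export
complement_subgroup <- function(sg) {
  stopifnot(nrow(sg$conditions) == 1)
  cn <- sg$conditions
  subgroup(cn$biomarker, cn$cutoff,
           direction = if (cn$direction == "above") "at_or_below" else "above",
           strict = cn$strict)
}
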