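# Cohort assembly: eligibility filtering, panel construction, and the
# descriptive tabulations (baseline phenotype mix, observed transitions).

# round half away from zero, matching how the printed tables round
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct a panel dataset of phenotype state sequences
#'
#' A panel holds, per subject, the ordered sequence of (visit time, state,
#' covariates) used by the multistate likelihood. Visit times are years since
#' the subject's first visit and must be strictly increasing; every subject
#' must have at least two visits.
#'
#' @param data A data.frame with columns \code{subject_id}, \code{visit_time},
#'   \code{state} (integer 1-6) and optionally covariate columns (see
#'   \code{\link{mwt_covariates}}).
#' @return An object of class \code{mwm_panel}: the data sorted by subject and
#'   time, with an attribute giving the covariate columns present.
#' @export
as_mwm_panel <- function(data) {
  data <- as.data.frame(data)
  need <- c("subject_id", "visit_time", "state")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(data$state %in% 1:6)) stop("state indices must be in 1..6")
  data <- data[order(data$subject_id, data$visit_time), , drop = FALSE]
  rownames(data) <- NULL
  nv <- table(data$subject_id)
  if (any(nv < 2)) stop("every subject needs at least two visits")
  dt <- stats::ave(data$visit_time, data$subject_id,
                   FUN = function(t) c(1, diff(t)))
  if (any(dt <= 0)) stop("visit times must be strictly increasing per subject")
  covs <- intersect(mwt_covariates(), names(data))
  structure(data, class = c("mwm_panel", "data.frame"), covariates = covs)
}

#' @export
print.mwm_panel <- function(x, ...) {
  ns <- length(unique(x$subject_id))
  cat(sprintf("Phenotype panel: %d subjects, %d visits, %d observed transitions\n",
              ns, nrow(x), nrow(x) - ns))
  covs <- attr(x, "covariates")
  if (length(covs)) cat("Covariates:", paste(covs, collapse = ", "), "\n")
  invisible(x)
}

#' Apply the study eligibility rules to phenotyped check-up records
#'
#' Subjects are retained when, at baseline, BMI >= 18.5 kg/m^2, age is within
#' \code{baseline_age_range}, no excluded disease history is flagged at any
#' visit, no required measurement is missing at baseline, and at least two
#' visits were made. Rules are applied in that order, so each excluded
#' subject is counted under exactly one (the first violated) reason.
#'
#' @param records A data.frame of check-up records, ideally already passed
#'   through \code{\link{classify_checkups}}; rows grouped by subject and
#'   time-sorted. Must contain \code{subject_id}, \code{visit_time},
#'   \code{bmi}, \code{age} and (if present) \code{excluded_disease_history}.
#' @param baseline_age_range Two-element numeric, default \code{c(20, 60)}.
#' @return A list with \code{panel} (an \code{\link{as_mwm_panel}} object of
#'   the retained subjects, phenotyped on the fly if needed) and
#'   \code{exclusions}, a named integer vector of counts per reason
#'   (\code{underweight}, \code{age_out_of_range}, \code{disease_history},
#'   \code{missing_data}, \code{too_few_visits}).
#' @export
filter_eligible <- function(records, baseline_age_range = c(20, 60)) {
  records <- as.data.frame(records)
  reasons <- c("underweight", "age_out_of_range", "disease_history",
               "missing_data", "too_few_visits")
  excl <- stats::setNames(integer(length(reasons)), reasons)
  if (nrow(records) == 0)
    return(list(panel = NULL, exclusions = excl))
  records <- records[order(records$subject_id, records$visit_time), ,
                     drop = FALSE]
  if (!"excluded_disease_history" %in% names(records))
    records$excluded_disease_history <- FALSE
  required <- c("sex", "age", "bmi", "sbp", "dbp", "fpg", "tg", "hdl",
                "alt", "ast", "scr", "ua")
  required <- intersect(required, names(records))
  keep <- character(0)
  for (sid in unique(records$subject_id)) {
    rows <- records[records$subject_id == sid, , drop = FALSE]
    base <- rows[1L, ]
    reason <-
      if (is.na(base$bmi) || base$bmi < 18.5) "underweight"
      else if (is.na(base$age) || base$age < baseline_age_range[1] ||
               base$age > baseline_age_range[2]) "age_out_of_range"
      else if (any(rows$excluded_disease_history %in% TRUE)) "disease_history"
      else if (anyNA(base[required])) "missing_data"
      else if (nrow(rows) < 2) "too_few_visits"
      else NA_character_
    if (is.na(reason)) keep <- c(keep, sid) else excl[reason] <- excl[reason] + 1L
  }
  kept <- records[records$subject_id %in% keep, , drop = FALSE]
  if (nrow(kept) == 0) return(list(panel = NULL, exclusions = excl))
  if (!"state" %in% names(kept)) kept <- classify_checkups(kept)
  cols <- c("subject_id", "visit_time", "state",
            intersect(mwt_covariates(), names(kept)))
  list(panel = as_mwm_panel(kept[, cols, drop = FALSE]), exclusions = excl)
}

#' Tabulate observed visit-to-visit transitions
#'
#' Counts, over every subject and every pair of consecutive visits, moves
#' from the phenotype at one visit to the phenotype at the next. Row
#' percentages are reported to two decimals (half-up rounding).
#'
#' @param panel An \code{mwm_panel}.
#' @return A list of class \code{mwm_transition_table}: \code{counts} (6x6
#'   integer) and \code{row_percent} (6x6, rows summing to 100 within
#'   rounding).
#' @export
tabulate_transitions <- function(panel) {
  from <- panel$state[-nrow(panel)]
  to <- panel$state[-1L]
  same <- panel$subject_id[-nrow(panel)] == panel$subject_id[-1L]
  counts <- matrix(0L, 6, 6, dimnames = list(mwt_states(), mwt_states()))
  tab <- table(factor(from[same], levels = 1:6), factor(to[same], levels = 1:6))
  counts[] <- as.integer(tab)
  rs <- rowSums(counts)
  pct <- counts / ifelse(rs > 0, rs, NA_real_) * 100
  structure(list(counts = counts, row_percent = round_half_up(pct, 2)),
            class = "mwm_transition_table")
}

#' @export
print.mwm_transition_table <- function(x, ...) {
  cat("Observed transitions (origin rows, next-visit columns): n (row %)\n")
  out <- matrix(sprintf("%d (%.2f)", x$counts, x$row_percent), 6, 6,
                dimnames = dimnames(x$counts))
  print(out, quote = FALSE)
  invisible(x)
}

#' Baseline phenotype composition and metabolic-health summary
#'
#' @param panel An \code{mwm_panel}.
#' @return A list with \code{counts} (baseline count per phenotype),
#'   \code{percent} (of all subjects, 2 dp), \code{unhealthy_percent}
#'   (overall share metabolically unhealthy) and
#'   \code{unhealthy_by_weight} (share unhealthy within the normal-weight,
#'   overweight and obese strata).
#' @export
baseline_summary <- function(panel) {
  base <- panel[!duplicated(panel$subject_id), , drop = FALSE]
  counts <- stats::setNames(tabulate(base$state, 6L), mwt_states())
  n <- sum(counts)
  unhealthy <- .mwt_metab_of_state[base$state] == 1L
  wl <- .mwt_weight_of_state[base$state]
  by_w <- vapply(0:2, function(w) {
    d <- sum(wl == w)
    if (d == 0) NA_real_ else round_half_up(100 * sum(unhealthy & wl == w) / d, 2)
  }, numeric(1))
  list(counts = counts,
       percent = round_half_up(100 * counts / n, 2),
       unhealthy_percent = round_half_up(100 * mean(unhealthy), 2),
       unhealthy_by_weight = stats::setNames(by_w, c("normal", "overweight", "obese")))
}

#' Split a panel into sex-by-age subgroups
#'
#' Partitions subjects by their baseline covariate values, the subgrouping
#' used for the sensitivity refits.
#'
#' @param panel An \code{mwm_panel} with \code{female} and/or
#'   \code{middle_aged} covariates.
#' @param by Character vector of baseline covariates to stratify on; default
#'   both sex and age group (four strata).
#' @return Named list of \code{mwm_panel} objects (possibly with zero rows
#'   represented as \code{NULL} when a stratum is empty).
#' @export
stratify_panel <- function(panel, by = c("female", "middle_aged")) {
  miss <- setdiff(by, names(panel))
  if (length(miss)) stop("panel lacks covariates: ", paste(miss, collapse = ", "))
  base <- panel[!duplicated(panel$subject_id), , drop = FALSE]
  levs <- expand.grid(rep(list(0:1), length(by)))
  names(levs) <- by
  out <- list()
  for (i in seq_len(nrow(levs))) {
    sel <- rep(TRUE, nrow(base))
    for (v in by) sel <- sel & base[[v]] == levs[i, v]
    label <- paste(vapply(by, function(v)
      paste0(v, "=", levs[i, v]), character(1)), collapse = ",")
    sids <- base$subject_id[sel]
    out[[label]] <- if (length(sids))
      as_mwm_panel(panel[panel$subject_id %in% sids, , drop = FALSE]) else NULL
  }
  out
}
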