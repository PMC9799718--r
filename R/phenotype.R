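# Phenotype classification from raw check-up measurements.
#
# Weight categories use the Chinese adult BMI cut-offs (24 and 28 kg/m^2);
# metabolic status uses the revised NCEP ATP III criteria without the
# abdominal-obesity component: a subject meeting two or more of the four
# criteria (elevated blood pressure, elevated fasting/post-load glucose,
# raised triglycerides, low HDL cholesterol) is metabolically unhealthy.

#' Classify weight category from BMI
#'
#' @param bmi Numeric vector of body mass index values (kg/m^2).
#' @return Integer vector: 0 = normal weight (18.5 <= BMI < 24),
#'   1 = overweight (24 <= BMI < 28), 2 = obese (BMI >= 28). Lower bounds are
#'   closed, upper bounds open.
#' @details BMI below 18.5 kg/m^2 is an eligibility matter, not a category:
#'   underweight subjects are excluded from the cohort, so such values raise
#'   an error here.
#' @export
#' @examples
#' classify_weight(c(21.48, 24, 28))
classify_weight <- function(bmi) {
  if (any(!is.finite(bmi))) stop("non-finite BMI")
  if (any(bmi < 18.5)) stop("underweight-ineligible: BMI < 18.5 kg/m^2")
  ifelse(bmi >= 28, 2L, ifelse(bmi >= 24, 1L, 0L))
}

#' Classify metabolic status from check-up measurements
#'
#' Counts the four metabolic-syndrome criteria and returns 1 (metabolically
#' unhealthy) when two or more are met, 0 (healthy) otherwise:
#' \enumerate{
#'   \item blood pressure: SBP >= 130 mmHg or DBP >= 85 mmHg or on
#'     antihypertensive medication;
#'   \item glucose: FPG >= 5.6 mmol/L or 2-h post-load glucose >= 7.8 mmol/L
#'     or on hypoglycemic medication;
#'   \item triglycerides: TG >= 1.7 mmol/L;
#'   \item HDL cholesterol: < 1.0 mmol/L (male) or < 1.3 mmol/L (female).
#' }
#'
#' @param sex Character vector, \code{"male"} or \code{"female"}.
#' @param sbp,dbp Systolic/diastolic blood pressure, mmHg.
#' @param fpg Fasting plasma glucose, mmol/L.
#' @param tg Triglycerides, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @param pg2h Optional 2-h post-load glucose, mmol/L; \code{NA} (the usual
#'   case in check-up data) contributes false to the glucose criterion unless
#'   \code{require_pg2h} is set.
#' @param on_antihypertensive,on_hypoglycemic Logical medication flags.
#' @param require_pg2h If \code{TRUE}, a missing 2-h glucose is treated as an
#'   incomplete record instead of a false clause.
#' @return Integer vector, 1 = metabolically unhealthy, 0 = healthy.
#' @export
#' @examples
#' classify_metabolic("female", sbp = 118, dbp = 76, fpg = 5.2,
#'                    tg = 1.90, hdl = 1.01)  # TG + HDL criteria -> 1
classify_metabolic <- function(sex, sbp, dbp, fpg, tg, hdl, pg2h = NA_real_,
                               on_antihypertensive = FALSE,
                               on_hypoglycemic = FALSE,
                               require_pg2h = FALSE) {
  n <- max(length(sex), length(sbp))
  sex <- rep_len(sex, n); sbp <- rep_len(sbp, n); dbp <- rep_len(dbp, n)
  fpg <- rep_len(fpg, n); tg <- rep_len(tg, n); hdl <- rep_len(hdl, n)
  pg2h <- rep_len(pg2h, n)
  on_antihypertensive <- rep_len(as.logical(on_antihypertensive), n)
  on_hypoglycemic <- rep_len(as.logical(on_hypoglycemic), n)
  if (!all(sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  req <- cbind(sbp, dbp, fpg, tg, hdl)
  if (any(is.na(req)) || any(is.na(on_antihypertensive)) ||
      any(is.na(on_hypoglycemic)))
    stop("incomplete record: missing a required metabolic measurement")
  if (any(req <= 0)) stop("pressures and concentrations must be positive")
  if (require_pg2h && any(is.na(pg2h)))
    stop("incomplete record: 2-h glucose required but missing")
  c1 <- sbp >= 130 | dbp >= 85 | on_antihypertensive
  c2 <- fpg >= 5.6 | (!is.na(pg2h) & pg2h >= 7.8) | on_hypoglycemic
  c3 <- tg >= 1.7
  c4 <- ifelse(sex == "male", hdl < 1.0, hdl < 1.3)
  as.integer((c1 + c2 + c3 + c4) >= 2)
}

#' Combine weight and metabolic levels into a phenotype state
#'
#' @param weight_level Integer 0/1/2 (normal/overweight/obese).
#' @param metabolic_level Integer 0/1 (healthy/unhealthy).
#' @return Integer state index 1-6 with the label attached via
#'   \code{mwt_states()}: MHNW=1, MHOW=2, MHO=3, MUNW=4, MUOW=5, MUO=6.
#' @export
#' @examples
#' mwt_states()[classify_phenotype(2, 1)]  # "MUO"
classify_phenotype <- function(weight_level, metabolic_level) {
  if (any(!weight_level %in% 0:2) || any(!metabolic_level %in% 0:1))
    stop("invalid weight or metabolic level")
  as.integer(3L * metabolic_level + weight_level + 1L)
}

#' Dichotomize covariates used in the transition model
#'
#' Produces the six binary covariates entered in the proportional-intensity
#' model: \code{female}; \code{middle_aged} (age > 45 years); and elevated
#' liver/renal markers with strict cut-offs - ALT > 40 U/L, AST > 40 U/L,
#' SCr > 133 (male) / > 106 (female) umol/L, UA > 420 (male) / > 360 (female)
#' umol/L. Values at a threshold belong to the normal/young group.
#'
#' @param sex,age,alt,ast,scr,ua Vectors of sex, age (years), ALT and AST
#'   (U/L), serum creatinine and uric acid (umol/L).
#' @return A data.frame with integer 0/1 columns \code{female},
#'   \code{middle_aged}, \code{alt_elevated}, \code{ast_elevated},
#'   \code{scr_elevated}, \code{ua_elevated}.
#' @export
dichotomize_covariates <- function(sex, age, alt, ast, scr, ua) {
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n); age <- rep_len(age, n); alt <- rep_len(alt, n)
  ast <- rep_len(ast, n); scr <- rep_len(scr, n); ua <- rep_len(ua, n)
  if (!all(sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  if (any(is.na(age)) || any(is.na(alt)) || any(is.na(ast)) ||
      any(is.na(scr)) || any(is.na(ua)))
    stop("incomplete record: missing a covariate measurement")
  male <- sex == "male"
  data.frame(
    female = as.integer(!male),
    middle_aged = as.integer(age > 45),
    alt_elevated = as.integer(alt > 40),
    ast_elevated = as.integer(ast > 40),
    scr_elevated = as.integer(ifelse(male, scr > 133, scr > 106)),
    ua_elevated = as.integer(ifelse(male, ua > 420, ua > 360))
  )
}

#' Names of the six model covariates
#' @return Character vector in the fixed order used by the model.
#' @export
mwt_covariates <- function() {
  c("female", "middle_aged", "alt_elevated", "ast_elevated",
    "scr_elevated", "ua_elevated")
}

#' Phenotype a table of check-up records
#'
#' Augments a long-format check-up table (one row per subject-visit) with
#' weight level, metabolic level, phenotype label and index, and the six
#' dichotomized covariates.
#'
#' @param records A data.frame with columns \code{subject_id},
#'   \code{visit_time} (years since the subject's first visit), \code{sex},
#'   \code{age}, \code{bmi}, \code{sbp}, \code{dbp}, \code{fpg}, \code{tg},
#'   \code{hdl}, \code{alt}, \code{ast}, \code{scr}, \code{ua}; optional
#'   \code{pg2h}, \code{on_antihypertensive}, \code{on_hypoglycemic},
#'   \code{excluded_disease_history}.
#' @param col_map Optional named character vector mapping the expected column
#'   names to the names actually present, e.g.
#'   \code{c(subject_id = "id", fpg = "glucose")}.
#' @param require_pg2h Passed to \code{\link{classify_metabolic}}.
#' @return The input data.frame (standard names) with added columns
#'   \code{weight_level}, \code{metabolic_level}, \code{state} (index 1-6),
#'   \code{phenotype} (label) and the six covariate columns.
#' @export
classify_checkups <- function(records, col_map = NULL, require_pg2h = FALSE) {
  records <- as.data.frame(records)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      have <- col_map[[std]]
      if (!have %in% names(records))
        stop(sprintf("mapped column '%s' not found", have))
      names(records)[names(records) == have] <- std
    }
  }
  needed <- c("subject_id", "visit_time", "sex", "age", "bmi", "sbp", "dbp",
              "fpg", "tg", "hdl", "alt", "ast", "scr", "ua")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (opt in c("on_antihypertensive", "on_hypoglycemic",
                "excluded_disease_history"))
    if (!opt %in% names(records)) records[[opt]] <- FALSE
  if (!"pg2h" %in% names(records)) records$pg2h <- NA_real_

  records$weight_level <- classify_weight(records$bmi)
  records$metabolic_level <- classify_metabolic(
    records$sex, records$sbp, records$dbp, records$fpg, records$tg,
    records$hdl, records$pg2h, records$on_antihypertensive,
    records$on_hypoglycemic, require_pg2h = require_pg2h)
  records$state <- classify_phenotype(records$weight_level,
                                      records$metabolic_level)
  records$phenotype <- mwt_states()[records$state]
  cov <- dichotomize_covariates(records$sex, records$age, records$alt,
                                records$ast, records$scr, records$ua)
  cbind(records, cov)
}

#' Read / write check-up CSV files
#'
#' Thin CSV wrappers fixing the dialect the package uses: comma-separated,
#' header row, no row names. \code{read_checkups} can rename columns via
#' \code{col_map} and optionally convert glucose/lipids from mg/dL to mmol/L.
#'
#' @param path File path.
#' @param col_map As in \code{\link{classify_checkups}}.
#' @param units_mgdl If \code{TRUE}, FPG/2hPG, TG and HDL are assumed to be
#'   in mg/dL and are converted to mmol/L on load (glucose / 18.016,
#'   TG / 88.57, HDL / 38.67).
#' @return \code{read_checkups}: a data.frame of check-up records.
#' @export
read_checkups <- function(path, col_map = NULL, units_mgdl = FALSE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (std in names(col_map))
      names(x)[names(x) == col_map[[std]]] <- std
  if (units_mgdl) {
    for (col in intersect(c("fpg", "pg2h"), names(x))) x[[col]] <- x[[col]] / 18.016
    if ("tg" %in% names(x)) x$tg <- x$tg / 88.57
    if ("hdl" %in% names(x)) x$hdl <- x$hdl / 38.67
  }
  x
}

#' @rdname read_checkups
#' @param records Data.frame to write.
#' @export
write_checkups <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
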