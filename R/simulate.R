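# Synthetic cohort generation.
#
# Latent dynamics are simulated exactly (event-driven: exponential holding
# times, categorical jump destinations), then observed at jittered roughly
# annual check-up visits, mirroring the panel-observation scheme the
# likelihood assumes. A measurement emitter turns latent states into raw
# check-up records guaranteed to classify back to the generating phenotype.

#' Configuration of the cohort simulator
#'
#' Defaults emulate the reference check-up cohort: baseline phenotype mix
#' equal to the published baseline proportions, latent generator
#' \code{\link{default_intensities}}, female prevalence 52.27\%, middle-aged
#' (> 45 years) prevalence 25.3\%, roughly annual visits (12 months plus
#' month-granular jitter, clamped to 9-15 months), 2-8 visits per subject
#' with mean about 3.7, and follow-up capped at 8 years.
#'
#' @param n_subjects Number of subjects.
#' @param baseline_distribution 6-vector of baseline state probabilities
#'   (normalised internally).
#' @param Q0 Baseline 6x6 intensity matrix.
#' @param beta Optional 14 x k matrix of per-edge log hazard ratios with
#'   covariate names as column names; covariates multiply the edge rates by
#'   \code{exp(beta' z)} per subject.
#' @param covariate_prevalence Named vector of Bernoulli prevalences for the
#'   binary covariates drawn at baseline.
#' @param visit_probs Named numeric vector: probability of each total visit
#'   count (names are the counts, minimum 2).
#' @param jitter_sd_months Standard deviation of the month-granular interval
#'   jitter (intervals are 12 plus a rounded normal draw, clamped to 9-15
#'   months).
#' @param followup_cap Maximum follow-up in years; later visits are dropped.
#' @param seed RNG seed; mandatory, for reproducibility.
#' @return A list of class \code{mwm_config}.
#' @export
cohort_config <- function(n_subjects = 2000,
                          baseline_distribution = c(0.4503, 0.1808, 0.0360,
                                                    0.0942, 0.1593, 0.0793),
                          Q0 = default_intensities(),
                          beta = NULL,
                          covariate_prevalence = c(
                            female = 0.5227, middle_aged = 0.253,
                            alt_elevated = 0.10, ast_elevated = 0.03,
                            scr_elevated = 0.01, ua_elevated = 0.15),
                          visit_probs = c("2" = 0.30, "3" = 0.22, "4" = 0.16,
                                          "5" = 0.12, "6" = 0.09, "7" = 0.06,
                                          "8" = 0.05),
                          jitter_sd_months = 1,
                          followup_cap = 8,
                          seed) {
  if (missing(seed) || !is.finite(seed)) stop("a numeric seed is required")
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (length(baseline_distribution) != 6 || any(baseline_distribution < 0) ||
      sum(baseline_distribution) <= 0)
    stop("baseline_distribution must be 6 non-negative probabilities")
  validate_intensity(Q0)
  if (!is.null(beta)) {
    if (!is.matrix(beta) || nrow(beta) != 14L || is.null(colnames(beta)))
      stop("beta must be a 14 x k matrix with covariate names as colnames")
    if (!all(colnames(beta) %in% names(covariate_prevalence)))
      stop("beta columns must name covariates with a configured prevalence")
  }
  if (is.null(names(visit_probs)) || any(as.integer(names(visit_probs)) < 2))
    stop("visit_probs must be named by visit counts >= 2")
  structure(list(
    n_subjects = as.integer(n_subjects),
    baseline_distribution = baseline_distribution / sum(baseline_distribution),
    Q0 = Q0, beta = beta, covariate_prevalence = covariate_prevalence,
    visit_probs = visit_probs / sum(visit_probs),
    jitter_sd_months = jitter_sd_months, followup_cap = followup_cap,
    seed = as.integer(seed)
  ), class = "mwm_config")
}

#' Simulate one exact trajectory of the latent chain
#'
#' Event-driven simulation: from state r, draw an exponential holding time
#' with rate -q_rr, then a destination with probability q_rs / (-q_rr);
#' repeat until the horizon. A state with no exit intensity is held to the
#' horizon.
#'
#' @param Q 6x6 intensity matrix.
#' @param start_state Initial state index.
#' @param horizon Simulation horizon in years (> 0).
#' @return A list with \code{times} (jump times, starting at 0) and
#'   \code{states} (state after each jump). Uses the current RNG stream.
#' @export
simulate_trajectory <- function(Q, start_state, horizon) {
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  validate_intensity(Q)
  times <- 0; states <- as.integer(start_state); t <- 0; s <- start_state
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) break
    t <- t + stats::rexp(1, rate)
    if (t >= horizon) break
    dest <- which(Q[s, ] > 0 & seq_len(6) != s)
    s <- if (length(dest) == 1) dest else
      dest[sample.int(length(dest), 1, prob = Q[s, dest])]
    times <- c(times, t); states <- c(states, as.integer(s))
  }
  list(times = times, states = states)
}

# latent state at arbitrary times, by last-jump lookup
state_at <- function(path, t) path$states[findInterval(t, path$times)]

#' Simulate a panel-observed synthetic cohort
#'
#' Draws baseline states and covariates, simulates each subject's exact
#' latent trajectory under the (covariate-adjusted) generator, and records
#' the state at jittered check-up visit times. Fully reproducible from the
#' configured seed.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return An object of class \code{mwm_cohort}: \code{panel} (an
#'   \code{mwm_panel} with covariate columns), \code{subjects} (baseline
#'   table with sex and baseline age), \code{latent} (per-subject exact jump
#'   paths) and \code{config}.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "mwm_config")) stop("config must come from cohort_config()")
  set.seed(config$seed)
  n <- config$n_subjects
  covn <- names(config$covariate_prevalence)
  cov <- vapply(covn, function(v)
    stats::rbinom(n, 1, config$covariate_prevalence[[v]]), integer(n))
  cov <- matrix(cov, nrow = n, dimnames = list(NULL, covn))
  base_state <- sample.int(6, n, replace = TRUE,
                           prob = config$baseline_distribution)
  sid <- sprintf("S%06d", seq_len(n))
  baseline_age <- ifelse(cov[, "middle_aged"] == 1,
                         stats::runif(n, 45.5, 59.5), stats::runif(n, 20, 44.9))
  sex <- ifelse(cov[, "female"] == 1, "female", "male")

  nv <- as.integer(names(config$visit_probs))[
    sample.int(length(config$visit_probs), n, replace = TRUE,
               prob = config$visit_probs)]
  rates0 <- edge_rates(config$Q0)

  rows <- vector("list", n)
  latent <- vector("list", n)
  for (i in seq_len(n)) {
    months <- 12 + round(stats::rnorm(nv[i] - 1L, 0, config$jitter_sd_months))
    months <- pmin(pmax(months, 9), 15)
    vt <- c(0, cumsum(months) / 12)
    vt <- vt[vt <= config$followup_cap]
    if (length(vt) < 2) vt <- vt[1:2]  # first interval always within cap
    Qi <- config$Q0
    if (!is.null(config$beta)) {
      z <- cov[i, colnames(config$beta)]
      Qi <- intensity_matrix(rates0 * exp(as.vector(config$beta %*% z)))
    }
    path <- simulate_trajectory(Qi, base_state[i], max(vt) + 1e-9)
    latent[[i]] <- path
    rows[[i]] <- data.frame(subject_id = sid[i], visit_time = vt,
                            state = state_at(path, vt))
  }
  panel <- do.call(rbind, rows)
  panel <- cbind(panel, cov[rep(seq_len(n), times = vapply(rows, nrow, 1L)), ,
                            drop = FALSE])
  structure(list(
    panel = as_mwm_panel(panel),
    subjects = data.frame(subject_id = sid, sex = sex,
                          baseline_age = baseline_age, cov),
    latent = stats::setNames(latent, sid),
    config = config
  ), class = "mwm_cohort")
}

#' @export
print.mwm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (seed %d)\n",
              x$config$n_subjects, x$config$seed))
  print(x$panel)
  invisible(x)
}

# truncated-normal draw by inverse CDF
rtnorm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

#' Emit measurement-level check-up records from a simulated cohort
#'
#' For every visit, draws raw measurements from state-conditional
#' distributions constructed to classify back to the visit's latent state:
#' BMI is drawn inside the latent weight category's interval, and exactly the
#' visit's drawn set of metabolic criteria (two or more when metabolically
#' unhealthy, at most one when healthy) are satisfied, each measurement
#' sampled strictly on its side of the defining threshold. ALT/AST/SCr/UA are
#' drawn consistently with the subject's baseline elevated-marker flags, and
#' age advances with visit time. Normal-weight BMI is centred near the
#' reference cohort's MHNW median (21.5 kg/m^2).
#'
#' @param cohort An \code{mwm_cohort}.
#' @param pr_medication Probability that a satisfied blood-pressure (glucose)
#'   criterion is carried by medication with normal measurements.
#' @return A data.frame of check-up records in the dialect
#'   \code{\link{classify_checkups}} reads; classifying it reproduces the
#'   latent panel states exactly.
#' @export
emit_measurements <- function(cohort, pr_medication = 0.1) {
  if (!inherits(cohort, "mwm_cohort")) stop("cohort must come from simulate_cohort()")
  panel <- cohort$panel
  sub <- cohort$subjects[match(panel$subject_id, cohort$subjects$subject_id), ]
  n <- nrow(panel)
  wl <- .mwt_weight_of_state[panel$state]
  ml <- .mwt_metab_of_state[panel$state]
  male <- sub$sex == "male"

  bmi <- numeric(n)
  bmi[wl == 0] <- rtnorm(sum(wl == 0), 21.6, 1.3, 18.55, 23.95)
  bmi[wl == 1] <- rtnorm(sum(wl == 1), 25.7, 1.0, 24.05, 27.95)
  bmi[wl == 2] <- rtnorm(sum(wl == 2), 29.3, 1.2, 28.05, 34.00)

  # choose how many and which metabolic criteria each visit satisfies
  k <- integer(n)
  k[ml == 0] <- sample(0:1, sum(ml == 0), replace = TRUE, prob = c(0.6, 0.4))
  k[ml == 1] <- sample(2:4, sum(ml == 1), replace = TRUE,
                       prob = c(0.70, 0.25, 0.05))
  crit <- matrix(FALSE, n, 4)
  for (i in seq_len(n)) if (k[i] > 0)
    crit[i, sample.int(4, k[i], prob = c(0.30, 0.25, 0.25, 0.20))] <- TRUE

  on_bpmed <- crit[, 1] & stats::runif(n) < pr_medication
  on_glmed <- crit[, 2] & !on_bpmed & stats::runif(n) < pr_medication
  bp_high <- crit[, 1] & !on_bpmed
  gl_high <- crit[, 2] & !on_glmed

  sbp <- ifelse(bp_high, rtnorm(n, 136, 6, 130.1, 175), rtnorm(n, 118, 7, 92, 129.5))
  dbp <- ifelse(bp_high, rtnorm(n, 84, 6, 60, 109), rtnorm(n, 73, 6, 55, 84.5))
  fpg <- ifelse(gl_high, rtnorm(n, 5.9, 0.35, 5.62, 8.5), rtnorm(n, 5.2, 0.25, 4.0, 5.57))
  tg <- ifelse(crit[, 3], rtnorm(n, 2.1, 0.5, 1.72, 5.0), rtnorm(n, 1.0, 0.3, 0.35, 1.67))
  hdl_thr <- ifelse(male, 1.0, 1.3)
  hdl <- ifelse(crit[, 4], rtnorm(n, hdl_thr - 0.15, 0.08, 0.50, hdl_thr - 0.01),
                rtnorm(n, hdl_thr + 0.25, 0.12, hdl_thr + 0.01, 2.5))

  alt <- ifelse(sub$alt_elevated == 1, rtnorm(n, 55, 15, 40.5, 150),
                rtnorm(n, 20, 8, 6, 39.5))
  ast <- ifelse(sub$ast_elevated == 1, rtnorm(n, 48, 10, 40.5, 120),
                rtnorm(n, 22, 6, 9, 39.5))
  scr_thr <- ifelse(male, 133, 106)
  scr <- ifelse(sub$scr_elevated == 1, rtnorm(n, scr_thr + 15, 10, scr_thr + 1, scr_thr + 60),
                rtnorm(n, ifelse(male, 72, 58), 10, 35, scr_thr - 1))
  ua_thr <- ifelse(male, 420, 360)
  ua <- ifelse(sub$ua_elevated == 1, rtnorm(n, ua_thr + 45, 30, ua_thr + 1, ua_thr + 220),
               rtnorm(n, ifelse(male, 310, 265), 45, 130, ua_thr - 1))

  out <- data.frame(
    subject_id = panel$subject_id,
    visit_time = panel$visit_time,
    sex = sub$sex,
    age = sub$baseline_age + panel$visit_time,
    bmi = bmi, sbp = sbp, dbp = dbp, fpg = fpg, pg2h = NA_real_,
    tg = tg, hdl = hdl, alt = alt, ast = ast, scr = scr, ua = ua,
    on_antihypertensive = on_bpmed, on_hypoglycemic = on_glmed,
    excluded_disease_history = FALSE
  )
  check <- classify_phenotype(classify_weight(out$bmi),
                              classify_metabolic(out$sex, out$sbp, out$dbp,
                                                 out$fpg, out$tg, out$hdl,
                                                 out$pg2h, out$on_antihypertensive,
                                                 out$on_hypoglycemic))
  if (any(check != panel$state))
    stop("internal error: emitted measurements do not classify to latent states")
  out
}
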