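# Shared fixtures and small independent oracles.

# random valid 6-state generator on the 14-edge structure
random_Q <- function(max_rate = 1) {
  intensity_matrix(runif(14, 0.01, max_rate))
}

# independent matrix-exponential oracle: scaling + truncated Taylor series
expm_taylor <- function(A, terms = 60) {
  s <- max(0, ceiling(log2(max(1, max(colSums(abs(A)))))))
  As <- A / 2^s
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in seq_len(terms)) {
    term <- term %*% As / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

# two-state chain with rates a (1->2) and b (2->1): closed-form P12(t)
p12_closed <- function(a, b, t) a / (a + b) * (1 - exp(-(a + b) * t))

# embed a two-state problem in the six-state structure using states 1 and 4
# (edge indices 9: 1->4 and 10: 4->1); remaining edges pinned near zero
two_state_theta <- function(a, b, pin = -35) {
  th <- rep(pin, 14)
  th[9] <- log(a)
  th[10] <- if (b > 0) log(b) else pin
  th
}

# panel of n12 subjects observed moving 1 -> 4 over one year and n11 staying
two_state_panel <- function(n11, n12, dt = 1) {
  n <- n11 + n12
  as_mwm_panel(data.frame(
    subject_id = rep(sprintf("x%04d", seq_len(n)), each = 2),
    visit_time = rep(c(0, dt), n),
    state = c(rep(c(1L, 1L), n11), rep(c(1L, 4L), n12))
  ))
}

# a small hand-built check-up record with every field normal (male)
normal_record <- function(subject_id = "a", visit_time = 0, sex = "male") {
  data.frame(
    subject_id = subject_id, visit_time = visit_time, sex = sex, age = 35,
    bmi = 21.5, sbp = 114, dbp = 69, fpg = 5.18, pg2h = NA_real_, tg = 0.8,
    hdl = 1.41, alt = 15, ast = 19, scr = 59, ua = 266,
    on_antihypertensive = FALSE, on_hypoglycemic = FALSE,
    excluded_disease_history = FALSE
  )
}

# a hand-made fit object for checking the reporting formulas in isolation
fake_fit <- function(logq, beta = NULL, covariates = character(0),
                     vcov = NULL) {
  edges <- transition_structure()$edges
  structure(list(
    logq = setNames(logq, rownames(edges)), beta = beta,
    theta = c(logq, as.vector(beta)), Q = intensity_matrix(exp(logq)),
    covariates = covariates, vcov = vcov, loglik = NA_real_,
    converged = TRUE, grad_norm = 0, n_subjects = 0L, n_transitions = 0L
  ), class = "mwm_fit")
}

# memoised expensive fixtures shared across test files
.fixture_env <- new.env(parent = emptyenv())

# intensity-recovery fit: 2,000 subjects, 6 roughly annual visits, default
# generator, no covariate effects
recovery_fixture <- function() {
  if (is.null(.fixture_env$recovery)) {
    cfg <- cohort_config(n_subjects = 2000, visit_probs = c("6" = 1),
                         jitter_sd_months = 0, seed = 20260101)
    cohort <- simulate_cohort(cfg)
    fit <- fit_mwm(cohort$panel)
    .fixture_env$recovery <- list(config = cfg, cohort = cohort, fit = fit)
  }
  .fixture_env$recovery
}

# covariate-recovery fit: beta = log 2 for females on the MHOW -> MHNW edge
covariate_fixture <- function() {
  if (is.null(.fixture_env$covariate)) {
    beta <- matrix(0, 14, 1, dimnames = list(NULL, "female"))
    beta[2, 1] <- log(2)  # edge order puts MHOW -> MHNW second
    cfg <- cohort_config(n_subjects = 4000, visit_probs = c("6" = 1),
                         beta = beta, seed = 20260102)
    cohort <- simulate_cohort(cfg)
    fit <- fit_mwm(cohort$panel, covariates = "female")
    .fixture_env$covariate <- list(config = cfg, cohort = cohort, fit = fit)
  }
  .fixture_env$covariate
}
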