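# Maximum-likelihood fitting of the panel-observed six-state model and the
# S3 surface of the fitted object.

#' Fit the six-state metabolism-weight transition model
#'
#' Maximises the panel log-likelihood over the 14 baseline log-intensities
#' and, optionally, proportional-intensity covariate coefficients (one log
#' hazard ratio per edge per covariate, all edges jointly by default).
#' Optimisation is quasi-Newton (BFGS with central-difference gradients)
#' followed by Newton polishing steps on the numerically differentiated
#' observed information, which also provides the covariance matrix of the
#' estimates.
#'
#' @param panel An \code{\link{as_mwm_panel}} object (or a data.frame
#'   coercible to one).
#' @param covariates Covariates entering the model: a character vector of
#'   panel columns, or a one-sided formula such as \code{~ female +
#'   middle_aged}. \code{NULL} fits the baseline (intensities-only) model.
#' @param init Initial values: \code{"crude"} (default, see
#'   \code{\link{crude_init}}; covariate coefficients start at 0) or a full
#'   numeric parameter vector.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param grad_tol Gradient-norm threshold for declaring convergence
#'   (default 1e-4).
#' @param max_iter Maximum BFGS iterations.
#' @return An object of class \code{mwm_fit} with components \code{logq}
#'   (baseline log-intensities), \code{beta} (14 x n_covariates matrix or
#'   \code{NULL}), \code{Q} (baseline intensity matrix), \code{vcov},
#'   \code{loglik}, \code{converged}, \code{grad_norm}, \code{n_subjects},
#'   \code{n_transitions}. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{logLik}, \code{vcov}, \code{predict},
#'   \code{simulate}, \code{plot}.
#' @seealso \code{\link{intensity_table}}, \code{\link{sojourn_table}},
#'   \code{\link{hazard_ratio_table}}, \code{\link{prevalence_series}}
#' @export
fit_mwm <- function(panel, covariates = NULL, init = "crude", tol = 1e-8,
                    grad_tol = 1e-4, max_iter = 500) {
  if (!inherits(panel, "mwm_panel")) panel <- as_mwm_panel(panel)
  if (inherits(covariates, "formula")) covariates <- all.vars(covariates)
  likdata <- build_likdata(panel, covariates)
  ncov <- length(likdata$covariates)
  npar <- 14L * (1L + ncov)

  if (identical(init, "crude")) {
    theta0 <- c(crude_init(panel), rep(0, 14L * ncov))
  } else {
    theta0 <- as.numeric(init)
    if (length(theta0) != npar) stop("init has wrong length")
  }

  fn <- function(theta) {
    ll <- loglik_likdata(theta, likdata)
    if (!is.finite(ll)) -1e12 else ll
  }
  gr <- function(theta) num_gradient(fn, theta)

  opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                      control = list(fnscale = -1, maxit = max_iter,
                                     reltol = tol))
  theta <- opt$par
  ll <- opt$value

  # Newton polishing on the observed information, which we need anyway
  H <- num_hessian(fn, theta)
  g <- gr(theta)
  for (it in seq_len(10L)) {
    if (sqrt(sum(g^2)) <= grad_tol) break
    step <- tryCatch(solve(-H, g), error = function(e)
      tryCatch(solve(-H + diag(1e-8, length(g)), g),  # singular information
               error = function(e) NULL))
    if (is.null(step)) break
    cand <- theta + step
    llc <- fn(cand)
    if (!is.finite(llc) || llc < ll - abs(ll) * 1e-9) break
    theta <- cand; ll <- llc
    H <- num_hessian(fn, theta)
    g <- gr(theta)
  }
  grad_norm <- sqrt(sum(g^2))
  vcov <- tryCatch({
    V <- solve(-H)
    if (any(!is.finite(V)) || any(diag(V) < 0)) NULL else V
  }, error = function(e) NULL)

  par <- split_theta(theta, ncov)
  edges <- transition_structure()$edges
  parnames <- c(paste0("logq:", rownames(edges)),
                if (ncov) as.vector(outer(rownames(edges), likdata$covariates,
                                          function(e, c) paste0("beta:", c, ":", e))))
  names(theta) <- parnames
  if (!is.null(vcov)) dimnames(vcov) <- list(parnames, parnames)

  structure(list(
    logq = stats::setNames(par$logq, rownames(edges)),
    beta = if (ncov) {
      b <- par$beta; dimnames(b) <- list(rownames(edges), likdata$covariates); b
    },
    theta = theta,
    Q = intensity_matrix(exp(par$logq)),
    covariates = likdata$covariates,
    vcov = vcov,
    loglik = ll,
    converged = opt$convergence == 0 && grad_norm <= grad_tol,
    grad_norm = grad_norm,
    optim_convergence = opt$convergence,
    n_subjects = likdata$n_subjects,
    n_transitions = likdata$n_transitions,
    call = match.call()
  ), class = "mwm_fit")
}

#' Per-covariate univariable fits
#'
#' Convenience wrapper fitting one single-covariate model per covariate, the
#' alternative to the joint multivariable fit.
#'
#' @inheritParams fit_mwm
#' @param covariates Character vector; one model is fitted per element.
#' @return Named list of \code{mwm_fit} objects.
#' @export
fit_mwm_univariable <- function(panel, covariates, ...) {
  stats::setNames(lapply(covariates, function(v) fit_mwm(panel, v, ...)),
                  covariates)
}

#' Refit the model within sex-by-age subgroups
#'
#' @inheritParams fit_mwm
#' @param by Baseline covariates defining the strata (see
#'   \code{\link{stratify_panel}}).
#' @return Named list of \code{mwm_fit} objects (\code{NULL} for empty
#'   strata).
#' @export
fit_stratified <- function(panel, by = c("female", "middle_aged"), ...) {
  lapply(stratify_panel(panel, by), function(p)
    if (is.null(p)) NULL else fit_mwm(p, ...))
}

se_of <- function(fit, idx) {
  if (is.null(fit$vcov)) return(rep(NA_real_, length(idx)))
  sqrt(diag(fit$vcov)[idx])
}

#' Transition-intensity estimates with confidence intervals
#'
#' Baseline (covariates at reference level) per-year intensities for the 14
#' allowed transitions, with 95\% intervals from a normal approximation on
#' the log scale.
#'
#' @param fit An \code{mwm_fit}.
#' @return Data.frame with columns \code{from}, \code{to}, \code{estimate},
#'   \code{lower}, \code{upper} (intervals \code{NA} when the covariance
#'   matrix is unavailable).
#' @export
intensity_table <- function(fit) {
  edges <- transition_structure()$edges
  se <- se_of(fit, seq_len(14L))
  st <- mwt_states()
  data.frame(
    from = st[edges[, 1]], to = st[edges[, 2]],
    estimate = exp(fit$logq),
    lower = exp(fit$logq - 1.96 * se),
    upper = exp(fit$logq + 1.96 * se),
    row.names = NULL
  )
}

#' Mean sojourn times with delta-method confidence intervals
#'
#' The mean sojourn time in state r is the reciprocal of its total exit
#' intensity at reference covariate values. Standard errors come from the
#' delta method applied to the log total exit rate, giving asymmetric
#' intervals on the natural scale.
#'
#' @param fit An \code{mwm_fit}.
#' @return Data.frame with one row per state: \code{state}, \code{mean}
#'   (years), \code{se}, \code{lower}, \code{upper}.
#' @export
sojourn_table <- function(fit) {
  edges <- transition_structure()$edges
  q <- exp(fit$logq)
  out <- data.frame(state = mwt_states(), mean = NA_real_, se = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  V <- if (!is.null(fit$vcov)) fit$vcov[1:14, 1:14] else NULL
  for (r in 1:6) {
    ex <- which(edges[, 1] == r)
    d <- sum(q[ex])
    out$mean[r] <- 1 / d
    if (!is.null(V)) {
      # gradient of log(mean) = -log(sum exit rates) wrt log q_e
      gvec <- numeric(14); gvec[ex] <- -q[ex] / d
      se_log <- sqrt(drop(t(gvec) %*% V %*% gvec))
      out$se[r] <- out$mean[r] * se_log
      out$lower[r] <- exp(log(out$mean[r]) - 1.96 * se_log)
      out$upper[r] <- exp(log(out$mean[r]) + 1.96 * se_log)
    }
  }
  out
}

#' Hazard ratios for covariate effects on each transition
#'
#' One entry per (edge, covariate): exp(beta) with normal-approximation 95\%
#' intervals on the log scale. A hazard ratio above 1 means the covariate
#' raises the instantaneous rate of that particular transition.
#'
#' @param fit An \code{mwm_fit} fitted with covariates.
#' @return Data.frame with columns \code{from}, \code{to}, \code{covariate},
#'   \code{hr}, \code{lower}, \code{upper}.
#' @export
hazard_ratio_table <- function(fit) {
  if (is.null(fit$beta)) stop("fit has no covariates")
  edges <- transition_structure()$edges
  ncov <- length(fit$covariates)
  idx <- 14L + seq_len(14L * ncov)
  se <- matrix(se_of(fit, idx), 14L, ncov)
  st <- mwt_states()
  out <- expand.grid(edge = seq_len(14L), covariate = fit$covariates,
                     stringsAsFactors = FALSE)
  data.frame(
    from = st[edges[out$edge, 1]], to = st[edges[out$edge, 2]],
    covariate = out$covariate,
    hr = exp(as.vector(fit$beta)),
    lower = exp(as.vector(fit$beta) - 1.96 * as.vector(se)),
    upper = exp(as.vector(fit$beta) + 1.96 * as.vector(se)),
    row.names = NULL
  )
}

#' @export
print.mwm_fit <- function(x, ...) {
  cat("Six-state metabolism-weight transition model\n")
  cat(sprintf("  %d subjects, %d observed transitions\n",
              x$n_subjects, x$n_transitions))
  cat(sprintf("  log-likelihood %.3f, %s (gradient norm %.2g)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$grad_norm))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("\nBaseline intensities (per year):\n")
  print(round(x$Q, 4))
  invisible(x)
}

#' @export
summary.mwm_fit <- function(object, ...) {
  structure(list(
    fit = object,
    intensities = intensity_table(object),
    sojourn = sojourn_table(object),
    hazard_ratios = if (!is.null(object$beta)) hazard_ratio_table(object)
  ), class = "summary.mwm_fit")
}

#' @export
print.summary.mwm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTransition intensities, 95% CI:\n")
  print(transform(x$intensities, estimate = round(estimate, 4),
                  lower = round(lower, 4), upper = round(upper, 4)))
  cat("\nMean sojourn times (years), 95% CI:\n")
  print(transform(x$sojourn, mean = round(mean, 2), se = round(se, 2),
                  lower = round(lower, 2), upper = round(upper, 2)))
  if (!is.null(x$hazard_ratios)) {
    cat("\nHazard ratios (per edge and covariate), 95% CI:\n")
    print(transform(x$hazard_ratios, hr = round(hr, 2),
                    lower = round(lower, 2), upper = round(upper, 2)))
  }
  invisible(x)
}

#' @export
coef.mwm_fit <- function(object, ...) object$theta

#' @export
vcov.mwm_fit <- function(object, ...) object$vcov

#' @export
logLik.mwm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta),
            nobs = object$n_transitions, class = "logLik")
}

# covariate-adjusted generator implied by a fit
fitted_intensity <- function(fit, covariate_values = NULL) {
  lq <- fit$logq
  if (length(fit$covariates)) {
    z <- stats::setNames(rep(0, length(fit$covariates)), fit$covariates)
    if (!is.null(covariate_values)) {
      bad <- setdiff(names(covariate_values), fit$covariates)
      if (length(bad)) stop("unknown covariate: ", paste(bad, collapse = ", "))
      z[names(covariate_values)] <- unlist(covariate_values)
    }
    lq <- lq + as.vector(fit$beta %*% z)
  } else if (!is.null(covariate_values) && length(covariate_values)) {
    stop("fit has no covariates")
  }
  intensity_matrix(exp(lq))
}

#' Predict multi-year transition probabilities from a fitted model
#'
#' @param object An \code{mwm_fit}.
#' @param origin Origin state(s), indices or labels; default all six.
#' @param horizon Horizon in years (default 6).
#' @param step Grid step in years (default 1).
#' @param covariate_values Optional named list of covariate values for the
#'   adjusted generator (reference 0 otherwise).
#' @param ... Unused.
#' @return Long-format data.frame: \code{origin}, \code{time},
#'   \code{destination}, \code{probability}.
#' @export
predict.mwm_fit <- function(object, origin = mwt_states(), horizon = 6,
                            step = 1, covariate_values = NULL, ...) {
  Q <- fitted_intensity(object, covariate_values)
  if (is.numeric(origin)) origin <- mwt_states()[origin]
  out <- do.call(rbind, lapply(origin, function(o) {
    wide <- predict_state_distribution(Q, o, horizon, step)
    data.frame(origin = o, time = wide$time,
               utils::stack(wide[, -1])[, c(2, 1)])
  }))
  names(out) <- c("origin", "time", "destination", "probability")
  out$destination <- as.character(out$destination)
  rownames(out) <- NULL
  out
}

#' Simulate cohorts from a fitted model
#'
#' Draws new synthetic cohorts whose latent dynamics follow the fitted
#' baseline generator, using the simulator's default visit schedule unless
#' overridden. Baseline states are drawn from the fitted panel's observed
#' baseline mix when available, otherwise uniformly.
#'
#' @param object An \code{mwm_fit}.
#' @param nsim Number of cohorts.
#' @param seed RNG seed (required for reproducibility).
#' @param n_subjects Subjects per cohort.
#' @param baseline_distribution Optional 6-vector of baseline state
#'   probabilities.
#' @param ... Further \code{\link{cohort_config}} overrides.
#' @return A list of \code{mwm_cohort} objects (length \code{nsim}), or a
#'   single cohort when \code{nsim = 1}.
#' @export
simulate.mwm_fit <- function(object, nsim = 1, seed = NULL,
                             n_subjects = 1000,
                             baseline_distribution = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  bd <- baseline_distribution %||% rep(1 / 6, 6)
  cohorts <- lapply(seq_len(nsim), function(i) {
    cfg <- cohort_config(n_subjects = n_subjects, Q0 = object$Q,
                         baseline_distribution = bd,
                         seed = sample.int(.Machine$integer.max, 1), ...)
    simulate_cohort(cfg)
  })
  if (nsim == 1) cohorts[[1]] else cohorts
}

#' Plot predicted transition-probability curves
#'
#' One panel per origin phenotype showing the probability of occupying each
#' destination state over the horizon.
#'
#' @param x An \code{mwm_fit}.
#' @param horizon,step Prediction grid in years.
#' @param ... Passed to \code{matplot}.
#' @export
plot.mwm_fit <- function(x, horizon = 6, step = 0.25, ...) {
  st <- mwt_states()
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (o in st) {
    wide <- predict_state_distribution(x$Q, o, horizon, step)
    graphics::matplot(wide$time, as.matrix(wide[, -1]), type = "l", lty = 1,
                      col = seq_len(6), ylim = c(0, 1), xlab = "years",
                      ylab = "probability", main = paste("from", o), ...)
    graphics::legend("topright", legend = st, col = seq_len(6), lty = 1,
                     cex = 0.6, bty = "n")
  }
  invisible(x)
}
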