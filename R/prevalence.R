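# Goodness-of-fit: observed versus model-expected phenotype prevalence over
# follow-up time. The assessment is visual/descriptive - the package reports
# the two series and their largest per-state gap, not a formal test.

#' Observed phenotype prevalence over time
#'
#' At each grid time t, every subject still under observation (last visit at
#' or after t) contributes the state of their most recent visit at or before
#' t; percentages are over contributing subjects.
#'
#' @param panel An \code{mwm_panel}.
#' @param times Numeric grid of times in years (default 0..7 yearly).
#' @return Data.frame: \code{time}, \code{n} (subjects under observation) and
#'   one percentage column per state (rows sum to 100 where n > 0).
#' @export
observed_prevalence <- function(panel, times = 0:7) {
  if (any(times < 0)) stop("grid times must be non-negative")
  subj <- split(panel[, c("visit_time", "state")], panel$subject_id)
  out <- matrix(NA_real_, length(times), 6,
                dimnames = list(NULL, mwt_states()))
  n_obs <- integer(length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    states <- vapply(subj, function(d) {
      if (max(d$visit_time) < t) return(NA_integer_)
      d$state[max(which(d$visit_time <= t))]
    }, integer(1))
    states <- states[!is.na(states)]
    n_obs[j] <- length(states)
    if (n_obs[j] > 0)
      out[j, ] <- 100 * tabulate(states, 6L) / n_obs[j]
  }
  if (all(n_obs == 0)) stop("no subject under observation at any grid time")
  data.frame(time = times, n = n_obs, out, check.names = FALSE)
}

#' Model-expected phenotype prevalence over time
#'
#' At each grid time t, averages - over subjects under observation at t - the
#' transition-probability row from the subject's baseline state over elapsed
#' time t, using the fitted generator at the subject's baseline covariates.
#'
#' @param fit An \code{mwm_fit}.
#' @param panel The panel the model was fitted to (or any \code{mwm_panel}).
#' @param times Numeric grid of times in years.
#' @return Data.frame in the same shape as
#'   \code{\link{observed_prevalence}}.
#' @export
expected_prevalence <- function(fit, panel, times = 0:7) {
  if (any(times < 0)) stop("grid times must be non-negative")
  base <- panel[!duplicated(panel$subject_id), , drop = FALSE]
  last <- stats::ave(panel$visit_time, panel$subject_id, FUN = max)
  last <- last[!duplicated(panel$subject_id)]
  ncov <- length(fit$covariates)
  # one generator per distinct baseline covariate pattern
  if (ncov) {
    Z <- as.matrix(base[, fit$covariates, drop = FALSE])
    key <- apply(Z, 1, paste, collapse = ",")
    upat <- !duplicated(key)
    Qs <- lapply(which(upat), function(i)
      intensity_matrix(exp(fit$logq + as.vector(fit$beta %*% Z[i, ]))))
    pat <- match(key, key[upat])
  } else {
    Qs <- list(fit$Q)
    pat <- rep(1L, nrow(base))
  }
  out <- matrix(NA_real_, length(times), 6,
                dimnames = list(NULL, mwt_states()))
  n_obs <- integer(length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    under <- last >= t
    n_obs[j] <- sum(under)
    if (n_obs[j] == 0) next
    Ps <- lapply(Qs, function(Q) transition_probability(Q, t))
    rows <- t(vapply(which(under), function(i)
      Ps[[pat[i]]][base$state[i], ], numeric(6)))
    out[j, ] <- 100 * colMeans(rows)
  }
  data.frame(time = times, n = n_obs, out, check.names = FALSE)
}

#' Observed and expected prevalence series with discrepancy summary
#'
#' @inheritParams expected_prevalence
#' @return Object of class \code{mwm_prevalence}: long-format data.frame
#'   (\code{time}, \code{state}, \code{observed}, \code{expected}, \code{n})
#'   plus an attribute \code{max_gap}, the largest absolute
#'   observed-minus-expected gap (percentage points) per state.
#' @export
prevalence_series <- function(fit, panel, times = 0:7) {
  obs <- observed_prevalence(panel, times)
  exp_ <- expected_prevalence(fit, panel, times)
  st <- mwt_states()
  long <- data.frame(
    time = rep(times, times = 6),
    state = rep(st, each = length(times)),
    observed = unlist(obs[st], use.names = FALSE),
    expected = unlist(exp_[st], use.names = FALSE),
    n = rep(obs$n, times = 6)
  )
  gap <- vapply(st, function(s) {
    d <- abs(long$observed[long$state == s] - long$expected[long$state == s])
    max(d, na.rm = TRUE)
  }, numeric(1))
  structure(long, class = c("mwm_prevalence", "data.frame"), max_gap = gap)
}

#' @export
print.mwm_prevalence <- function(x, ...) {
  cat("Observed vs expected phenotype prevalence (%)\n")
  print.data.frame(x, digits = 4)
  cat("\nMax |observed - expected| per state (percentage points):\n")
  print(round(attr(x, "max_gap"), 2))
  invisible(x)
}

#' Plot observed and expected prevalence curves
#'
#' One panel per phenotype: observed percentages as points/solid line,
#' model-expected percentages as a dashed line.
#'
#' @param x An \code{mwm_prevalence}.
#' @param ... Passed to \code{plot}.
#' @export
plot.mwm_prevalence <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in mwt_states()) {
    d <- x[x$state == s, ]
    ylim <- range(c(d$observed, d$expected), na.rm = TRUE)
    graphics::plot(d$time, d$observed, type = "b", pch = 16, ylim = ylim,
                   xlab = "years", ylab = "prevalence (%)", main = s, ...)
    graphics::lines(d$time, d$expected, lty = 2)
  }
  invisible(x)
}
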