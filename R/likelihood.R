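# Panel-data likelihood for the six-state model.
#
# States are observed only at visit snapshots, so each consecutive visit
# pair contributes P(dt)[s_k, s_{k+1}] with the interval's covariate-adjusted
# generator: q_rs(z) = q_rs(0) * exp(beta_rs' z), covariates taken at the
# interval's start. Intervals sharing (dt, covariate pattern) reuse one
# matrix exponential, and identical (from, to) cells within such a group are
# collapsed to counts, so one likelihood evaluation costs one expm per
# distinct (dt, pattern) pair.

# Pre-digest a panel into grouped interval data.
# Returns list(patterns = npat x ncov matrix (possibly 0-col),
#              groups = list of (dt, pat, idx = linear 6x6 cell indices,
#                                n = counts)),
# plus bookkeeping counts.
build_likdata <- function(panel, covariates = NULL) {
  if (!inherits(panel, "mwm_panel")) panel <- as_mwm_panel(panel)
  covariates <- covariates %||% character(0)
  miss <- setdiff(covariates, names(panel))
  if (length(miss)) stop("panel lacks covariates: ", paste(miss, collapse = ", "))
  n <- nrow(panel)
  same <- panel$subject_id[-n] == panel$subject_id[-1L]
  dt <- (panel$visit_time[-1L] - panel$visit_time[-n])[same]
  from <- panel$state[-n][same]
  to <- panel$state[-1L][same]
  if (length(covariates)) {
    Z <- as.matrix(panel[-n, covariates, drop = FALSE])[same, , drop = FALSE]
    patkey <- apply(Z, 1, paste, collapse = "\r")
  } else {
    Z <- matrix(0, length(dt), 0)
    patkey <- rep("", length(dt))
  }
  upat <- !duplicated(patkey)
  patterns <- Z[upat, , drop = FALSE]
  rownames(patterns) <- NULL
  pat <- match(patkey, patkey[upat])
  dtr <- signif(dt, 12)
  gkey <- paste(dtr, pat)
  groups <- lapply(split(seq_along(dt), gkey), function(i) {
    cell <- (to[i] - 1L) * 6L + from[i]
    tab <- table(cell)
    list(dt = dt[i[1L]], pat = pat[i[1L]],
         idx = as.integer(names(tab)), n = as.integer(tab))
  })
  list(patterns = patterns, groups = groups, covariates = covariates,
       n_subjects = length(unique(panel$subject_id)), n_transitions = length(dt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# theta layout: 14 baseline log-intensities, then beta as a 14 x ncov matrix
# stored column-major (all 14 edges for covariate 1, then covariate 2, ...)
split_theta <- function(theta, ncov) {
  if (length(theta) != 14L * (1L + ncov)) stop("parameter vector has wrong length")
  list(logq = theta[1:14],
       beta = if (ncov) matrix(theta[-(1:14)], 14L, ncov) else NULL)
}

loglik_likdata <- function(theta, likdata) {
  # -Inf log-intensities mean a structurally zero rate and are permitted
  if (any(is.na(theta)) || any(theta == Inf)) stop("non-finite parameters")
  ncov <- ncol(likdata$patterns)
  par <- split_theta(theta, ncov)
  npat <- nrow(likdata$patterns)
  Qs <- vector("list", max(npat, 1L))
  for (p in seq_len(max(npat, 1L))) {
    lq <- par$logq
    if (ncov) lq <- lq + as.vector(par$beta %*% likdata$patterns[p, ])
    rates <- exp(lq)
    if (any(!is.finite(rates))) return(-Inf)  # overflow: reject the point
    Qs[[p]] <- intensity_matrix(rates)
  }
  ll <- 0
  for (g in likdata$groups) {
    P <- mat_expm(Qs[[g$pat]] * g$dt)
    pr <- P[g$idx]
    # reject numerically broken exponentials (extreme generators can
    # overflow into entries outside [0, 1])
    if (any(!is.finite(pr)) || any(pr <= 0) || any(pr > 1 + 1e-8))
      return(-Inf)
    ll <- ll + sum(g$n * log(pr))
  }
  ll
}

#' Panel log-likelihood of the six-state model
#'
#' Sums, over subjects and consecutive visit pairs, the log transition
#' probability of the observed state change over the observed interval,
#' using the covariate-adjusted generator at the interval's start. Returns
#' \code{-Inf} when any observed transition has probability zero under the
#' parameters.
#'
#' @param theta Parameter vector: 14 baseline log-intensities in the order of
#'   \code{transition_structure()$edges}, followed (column-major) by a
#'   14 x n_covariates block of log hazard-ratio coefficients.
#' @param panel An \code{mwm_panel}.
#' @param covariates Character vector of covariate columns entering the
#'   proportional-intensity model (possibly empty).
#' @return Scalar log-likelihood.
#' @export
panel_loglik <- function(theta, panel, covariates = NULL) {
  loglik_likdata(theta, build_likdata(panel, covariates))
}

#' Crude initial intensities from observed moves and person-time
#'
#' For each allowed edge, the initial rate is the number of observed
#' visit-to-visit moves along that edge divided by the person-time spent in
#' the origin state (approximated by attributing each interval to its
#' starting state). Edges with no observed moves are floored at 1e-3 per
#' year so the optimizer starts at a finite point.
#'
#' @param panel An \code{mwm_panel}.
#' @return Numeric vector of 14 log-rates in edge order.
#' @export
crude_init <- function(panel) {
  if (!inherits(panel, "mwm_panel")) panel <- as_mwm_panel(panel)
  n <- nrow(panel)
  if (n == 0) stop("empty panel")
  same <- panel$subject_id[-n] == panel$subject_id[-1L]
  dt <- (panel$visit_time[-1L] - panel$visit_time[-n])[same]
  from <- panel$state[-n][same]
  to <- panel$state[-1L][same]
  ptime <- vapply(1:6, function(r) sum(dt[from == r]), numeric(1))
  if (sum(ptime) <= 0) stop("zero total person-time")
  edges <- transition_structure()$edges
  rates <- vapply(seq_len(14L), function(e) {
    r <- edges[e, 1L]; s <- edges[e, 2L]
    if (ptime[r] <= 0) return(1e-3)
    max(sum(from == r & to == s) / ptime[r], 1e-3)
  }, numeric(1))
  log(rates)
}

# central-difference gradient with relative step
num_gradient <- function(fn, theta, step = 1e-5) {
  h <- step * pmax(1, abs(theta))
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h[i]; tm[i] <- tm[i] - h[i]
    (fn(tp) - fn(tm)) / (2 * h[i])
  }, numeric(1))
}

# central-difference Hessian (observed information = -H at the MLE)
num_hessian <- function(fn, theta, step = 1e-5) {
  p <- length(theta)
  h <- step * pmax(1, abs(theta))
  H <- matrix(NA_real_, p, p)
  f0 <- fn(theta)
  for (i in seq_len(p)) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h[i]; tm[i] <- tm[i] - h[i]
    H[i, i] <- (fn(tp) - 2 * f0 + fn(tm)) / h[i]^2
    if (i < p) for (j in seq((i + 1), p)) {
      tpp <- theta; tpm <- theta; tmp <- theta; tmm <- theta
      tpp[c(i, j)] <- theta[c(i, j)] + h[c(i, j)]
      tmm[c(i, j)] <- theta[c(i, j)] - h[c(i, j)]
      tpm[i] <- theta[i] + h[i]; tpm[j] <- theta[j] - h[j]
      tmp[i] <- theta[i] - h[i]; tmp[j] <- theta[j] + h[j]
      H[i, j] <- H[j, i] <-
        (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) / (4 * h[i] * h[j])
    }
  }
  H
}
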