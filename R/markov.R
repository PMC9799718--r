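# Continuous-time Markov machinery: matrix exponential, transition
# probabilities, sojourn times and multi-year state-distribution predictions.

# Matrix exponential by scaling-and-squaring with a (13,13) Pade approximant
# (Higham 2005). Generators here are small (6x6) with modest norms, so the
# lower-order approximants are usually selected.
mat_expm <- function(A) {
  n <- nrow(A)
  I <- diag(n)
  nrmA <- max(colSums(abs(A)))  # 1-norm
  theta <- c(1.495585217958292e-2, 2.539398330063230e-1,
             9.504178996162932e-1, 2.097847961257068, 5.371920351148152)
  b3 <- c(120, 60, 12, 1)
  b5 <- c(30240, 15120, 3360, 420, 30, 1)
  b7 <- c(17297280, 8648640, 1995840, 277200, 25200, 1512, 56, 1)
  b9 <- c(17643225600, 8821612800, 2075673600, 302702400, 30270240,
          2162160, 110880, 3960, 90, 1)
  b13 <- c(64764752532480000, 32382376266240000, 7771770303897600,
           1187353796428800, 129060195264000, 10559470521600, 670442572800,
           33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  pade_uv <- function(b, A) {
    m <- (length(b) - 1L)
    A2 <- A %*% A
    # even/odd polynomial split: U = A * (odd coeffs in A2), V = even coeffs
    U <- b[2] * I; V <- b[1] * I
    Apow <- I
    for (k in seq_len(m %/% 2)) {
      Apow <- Apow %*% A2
      V <- V + b[2 * k + 1] * Apow
      if (2 * k + 2 <= length(b)) U <- U + b[2 * k + 2] * Apow
    }
    list(U = A %*% U, V = V)
  }
  if (nrmA <= theta[4]) {
    b <- if (nrmA <= theta[1]) b3 else if (nrmA <= theta[2]) b5
         else if (nrmA <= theta[3]) b7 else b9
    uv <- pade_uv(b, A)
    return(solve(uv$V - uv$U, uv$V + uv$U))
  }
  s <- max(0L, ceiling(log2(nrmA / theta[5])))
  As <- A / 2^s
  A2 <- As %*% As; A4 <- A2 %*% A2; A6 <- A2 %*% A4
  U <- As %*% (A6 %*% (b13[14] * A6 + b13[12] * A4 + b13[10] * A2) +
               b13[8] * A6 + b13[6] * A4 + b13[4] * A2 + b13[2] * I)
  V <- A6 %*% (b13[13] * A6 + b13[11] * A4 + b13[9] * A2) +
       b13[7] * A6 + b13[5] * A4 + b13[3] * A2 + b13[1] * I
  P <- solve(V - U, V + U)
  for (k in seq_len(s)) P <- P %*% P
  P
}

#' Transition probability matrix over an interval
#'
#' Solves the Kolmogorov forward equations for a time-homogeneous generator:
#' P(t) = exp(Q t). Entry (r, s) is the probability of occupying state s a
#' time t after being in state r, accounting for any number of intermediate
#' jumps - so phenotype pairs that are not adjacent (structurally zero in Q)
#' still acquire positive probability for t > 0.
#'
#' @param Q A 6x6 intensity matrix (see \code{\link{intensity_matrix}}).
#' @param t Non-negative time in years.
#' @return A 6x6 stochastic matrix; rows sum to 1.
#' @export
#' @examples
#' Q <- default_intensities()
#' rowSums(transition_probability(Q, 1))
transition_probability <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("t must be a non-negative time in years")
  validate_intensity(Q)
  if (t == 0) return(diag(6) + 0 * Q)  # keep dimnames
  P <- mat_expm(Q * t)
  # clip tiny negative round-off
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Mean sojourn times implied by an intensity matrix
#'
#' The holding time in state r is exponential with rate -q_rr, so the mean
#' continuous residence time before any jump is -1/q_rr.
#'
#' @param Q A 6x6 intensity matrix.
#' @return Named numeric vector of per-state mean sojourn times in years;
#'   \code{Inf} (with a warning) for a state with no exit intensity.
#' @export
sojourn_times <- function(Q) {
  validate_intensity(Q)
  d <- -diag(Q)
  if (any(d == 0)) warning("state with zero exit rate: infinite sojourn time")
  stats::setNames(ifelse(d > 0, 1 / d, Inf), mwt_states())
}

#' Predict the state distribution from a given origin over time
#'
#' Evaluates the origin row of P(t) on a time grid - the multi-year
#' transition-probability curves for a cohort starting in one phenotype.
#'
#' @param Q A 6x6 intensity matrix.
#' @param origin Origin state index 1-6 or label.
#' @param horizon Prediction horizon in years (> 0).
#' @param step Grid step in years (default 1).
#' @return A data.frame with columns \code{time} and one probability column
#'   per destination state; each row sums to 1.
#' @export
#' @examples
#' predict_state_distribution(default_intensities(), "MHNW", horizon = 6)
predict_state_distribution <- function(Q, origin, horizon, step = 1) {
  if (is.character(origin)) origin <- match(origin, mwt_states())
  if (is.na(origin) || !origin %in% 1:6) stop("invalid origin state")
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (!is.finite(step) || step <= 0 || step > horizon)
    stop("step must be in (0, horizon]")
  times <- seq(0, horizon, by = step)
  rows <- t(vapply(times, function(t) transition_probability(Q, t)[origin, ],
                   numeric(6)))
  out <- data.frame(time = times, rows)
  names(out) <- c("time", mwt_states())
  out
}
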