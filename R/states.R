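#' @keywords internal
"_PACKAGE"

#' Six metabolism-weight phenotype labels
#'
#' The fixed state order used everywhere in the package: metabolically healthy
#' normal weight (MHNW), overweight (MHOW) and obesity (MHO), then the
#' metabolically unhealthy counterparts (MUNW, MUOW, MUO). State indices 1-6
#' follow this order in every matrix, table and file the package produces.
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' mwt_states()
mwt_states <- function() {
  c("MHNW", "MHOW", "MHO", "MUNW", "MUOW", "MUO")
}

# weight level (0 normal, 1 overweight, 2 obese) and metabolic level
# (0 healthy, 1 unhealthy) for each state index 1..6
.mwt_weight_of_state <- c(0L, 1L, 2L, 0L, 1L, 2L)
.mwt_metab_of_state <- c(0L, 0L, 0L, 1L, 1L, 1L)

#' Allowed-transition structure of the six-state model
#'
#' Instantaneous transitions are permitted only between adjacent phenotypes:
#' horizontally between neighbouring weight categories within a metabolic
#' status (MHNW-MHOW, MHOW-MHO, MUNW-MUOW, MUOW-MUO) and vertically between
#' metabolic statuses within a weight category (MHNW-MUNW, MHOW-MUOW,
#' MHO-MUO). Both directions of each pair are allowed, giving 14 permitted
#' transitions; diagonal moves (e.g. MHNW to MUOW) can only occur through a
#' sequence of adjacent jumps.
#'
#' @return A list with components \code{allowed} (6x6 logical mask, diagonal
#'   \code{FALSE}) and \code{edges} (14x2 integer matrix of (from, to) state
#'   indices in a fixed order, with informative rownames).
#' @export
#' @examples
#' ts <- transition_structure()
#' sum(ts$allowed)  # 14
transition_structure <- function() {
  edges <- rbind(
    c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L),
    c(4L, 5L), c(5L, 4L), c(5L, 6L), c(6L, 5L),
    c(1L, 4L), c(4L, 1L), c(2L, 5L), c(5L, 2L),
    c(3L, 6L), c(6L, 3L)
  )
  colnames(edges) <- c("from", "to")
  st <- mwt_states()
  rownames(edges) <- paste0(st[edges[, 1]], "-", st[edges[, 2]])
  allowed <- matrix(FALSE, 6, 6, dimnames = list(st, st))
  allowed[edges] <- TRUE
  list(allowed = allowed, edges = edges)
}

#' Build an intensity matrix from per-edge rates
#'
#' Places the 14 per-year transition rates on their edges (in the order of
#' \code{transition_structure()$edges}), zeros elsewhere off-diagonal, and
#' sets each diagonal entry to minus the row's total exit rate, so every row
#' sums to zero.
#'
#' @param rates Numeric vector of 14 non-negative per-year rates.
#' @return A 6x6 intensity (generator) matrix with state labels.
#' @export
intensity_matrix <- function(rates) {
  if (length(rates) != 14L || any(!is.finite(rates)) || any(rates < 0))
    stop("'rates' must be 14 finite non-negative per-year rates")
  ts <- transition_structure()
  st <- mwt_states()
  Q <- matrix(0, 6, 6, dimnames = list(st, st))
  Q[ts$edges] <- rates
  diag(Q) <- -rowSums(Q)
  Q
}

# validate a 6x6 generator against the 14-edge mask
validate_intensity <- function(Q, tol = 1e-8) {
  if (!is.matrix(Q) || any(dim(Q) != 6L) || any(!is.finite(Q)))
    stop("Q must be a finite 6x6 matrix")
  ts <- transition_structure()
  off <- Q; diag(off) <- 0
  if (any(off < -tol)) stop("off-diagonal intensities must be non-negative")
  if (any(abs(off[!ts$allowed & !diag(6)]) > tol))
    stop("Q has positive intensity on a disallowed (non-adjacent) transition")
  if (any(abs(rowSums(Q)) > tol)) stop("rows of Q must sum to zero")
  invisible(Q)
}

# rates on the 14 edges, in edge order
edge_rates <- function(Q) Q[transition_structure()$edges]
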