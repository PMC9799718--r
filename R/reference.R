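# Bundled reference tabulations from a health check-up cohort of 9,742
# Chinese adults followed over ~8 years with roughly annual visits. These
# published summary tables (baseline phenotype mix; observed visit-to-visit
# transition counts) anchor the simulator defaults and serve as worked
# examples and validation fixtures; the underlying raw records are not
# publicly deposited.

#' Reference baseline phenotype counts
#'
#' Baseline composition of the reference check-up cohort (n = 9,742).
#'
#' @return Named integer vector of baseline counts per phenotype.
#' @export
reference_baseline_counts <- function() {
  stats::setNames(c(4387L, 1761L, 351L, 918L, 1552L, 773L), mwt_states())
}

#' Reference observed transition counts
#'
#' Visit-to-visit transition frequencies observed in the reference cohort
#' (consecutive check-ups roughly one year apart; 25,985 transitions).
#'
#' @return 6x6 integer matrix, origin phenotype in rows, phenotype at the
#'   next visit in columns.
#' @export
reference_transition_counts <- function() {
  m <- matrix(c(
    9234L,  877L,  23L, 1069L,  278L,   32L,
     660L, 2904L, 192L,  107L, 1017L,  102L,
      18L,  149L, 449L,    4L,   54L,  300L,
     943L,  148L,   3L, 1164L,  231L,    6L,
     251L,  948L,  68L,  201L, 2380L,  236L,
      28L,  104L, 275L,    7L,  197L, 1326L),
    nrow = 6, byrow = TRUE, dimnames = list(mwt_states(), mwt_states()))
  m
}

#' Reference mean sojourn times
#'
#' Published per-state mean sojourn times (years) with standard errors and
#' 95\% confidence intervals for the reference cohort.
#'
#' @return Data.frame with columns \code{state}, \code{mean}, \code{se},
#'   \code{lower}, \code{upper}.
#' @export
reference_sojourn_times <- function() {
  data.frame(
    state = mwt_states(),
    mean = c(3.84, 1.56, 1.16, 1.23, 1.59, 2.34),
    se = c(0.09, 0.04, 0.06, 0.04, 0.04, 0.11),
    lower = c(3.69, 1.48, 1.06, 1.16, 1.51, 2.15),
    upper = c(4.02, 1.63, 1.28, 1.30, 1.68, 2.56)
  )
}

#' Reconstruct minimal panels reproducing the reference tabulations
#'
#' \code{reference_transition_panel} builds a panel whose pooled
#' visit-to-visit transition counts equal \code{reference_transition_counts()}
#' exactly (one two-visit subject per observed transition);
#' \code{reference_baseline_panel} builds a panel whose baseline composition
#' equals \code{reference_baseline_counts()} (two stationary visits per
#' subject). They reproduce the published percentages, not the cohort's
#' longitudinal trajectories.
#'
#' @return An \code{mwm_panel}.
#' @export
reference_transition_panel <- function() {
  counts <- reference_transition_counts()
  from <- integer(0); to <- integer(0)
  for (r in 1:6) for (s in 1:6) {
    n <- counts[r, s]
    from <- c(from, rep(r, n)); to <- c(to, rep(s, n))
  }
  n <- length(from)
  as_mwm_panel(data.frame(
    subject_id = rep(sprintf("T%05d", seq_len(n)), each = 2),
    visit_time = rep(c(0, 1), n),
    state = as.vector(rbind(from, to))
  ))
}

#' @rdname reference_transition_panel
#' @export
reference_baseline_panel <- function() {
  counts <- reference_baseline_counts()
  st <- rep(1:6, times = counts)
  n <- length(st)
  as_mwm_panel(data.frame(
    subject_id = rep(sprintf("B%05d", seq_len(n)), each = 2),
    visit_time = rep(c(0, 1), n),
    state = rep(st, each = 2)
  ))
}

#' Default six-state intensity matrix
#'
#' The generator anchoring the cohort simulator. The six metabolic-transition
#' intensities are the reference cohort's published values (deterioration
#' MHNW to MUNW 0.15, MHOW to MUOW 0.38, MHO to MUO 0.56; improvement MUNW to
#' MHNW 0.64, MUOW to MHOW 0.44, MUO to MHO 0.27). The eight weight-transition
#' intensities are derived, not published: each state's total exit rate is set
#' to the reciprocal of its published mean sojourn time, and where a state has
#' two weight edges the remaining exit mass is split in proportion to the
#' observed transition counts.
#'
#' @return A 6x6 intensity matrix.
#' @export
default_intensities <- function() {
  exit <- 1 / reference_sojourn_times()$mean
  counts <- reference_transition_counts()
  q14 <- 0.15; q25 <- 0.38; q36 <- 0.56
  q41 <- 0.64; q52 <- 0.44; q63 <- 0.27
  q12 <- exit[1] - q14
  rem2 <- exit[2] - q25
  q21 <- rem2 * counts[2, 1] / (counts[2, 1] + counts[2, 3])
  q23 <- rem2 - q21
  q32 <- exit[3] - q36
  q45 <- exit[4] - q41
  rem5 <- exit[5] - q52
  q54 <- rem5 * counts[5, 4] / (counts[5, 4] + counts[5, 6])
  q56 <- rem5 - q54
  q65 <- exit[6] - q63
  # edge order: (1,2),(2,1),(2,3),(3,2),(4,5),(5,4),(5,6),(6,5),
  #             (1,4),(4,1),(2,5),(5,2),(3,6),(6,3)
  intensity_matrix(c(q12, q21, q23, q32, q45, q54, q56, q65,
                     q14, q41, q25, q52, q36, q63))
}
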