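test_that("panel construction enforces ordering and minimum visits", {
  expect_error(as_mwm_panel(data.frame(subject_id = "a", visit_time = 0,
                                       state = 1L)), "two visits")
  expect_error(as_mwm_panel(data.frame(subject_id = c("a", "a"),
                                       visit_time = c(0, 0), state = c(1L, 2L))),
               "strictly increasing")
  expect_error(as_mwm_panel(data.frame(subject_id = c("a", "a"),
                                       visit_time = c(0, 1), state = c(1L, 7L))),
               "1..6")
})

test_that("eligibility rules drop subjects for the first violated reason", {
  mk <- function(id, n = 2, bmi = 21.5, age = 35, disease_at = NULL) {
    rows <- do.call(rbind, lapply(seq_len(n) - 1, function(t)
      normal_record(id, t)))
    rows$bmi <- bmi; rows$age <- age + rows$visit_time
    if (!is.null(disease_at))
      rows$excluded_disease_history[disease_at] <- TRUE
    rows
  }
  recs <- rbind(mk("s1"), mk("s2", bmi = 18.2), mk("s3", n = 1),
                mk("s4"), mk("s5"), mk("s6"))
  res <- filter_eligible(recs)
  expect_identical(length(unique(res$panel$subject_id)), 4L)
  expect_identical(res$exclusions[["underweight"]], 1L)
  expect_identical(res$exclusions[["too_few_visits"]], 1L)

  # disease flagged mid-follow-up excludes the whole subject
  res2 <- filter_eligible(rbind(mk("s1"), mk("s7", n = 3, disease_at = 3)))
  expect_false("s7" %in% res2$panel$subject_id)
  expect_identical(res2$exclusions[["disease_history"]], 1L)

  # baseline age outside 20-60
  res3 <- filter_eligible(rbind(mk("s1"), mk("s8", age = 61)))
  expect_identical(res3$exclusions[["age_out_of_range"]], 1L)

  # all-eligible fixture passes through unchanged
  res4 <- filter_eligible(rbind(mk("s1"), mk("s4")))
  expect_identical(sort(unique(res4$panel$subject_id)), c("s1", "s4"))
  expect_true(all(res4$exclusions == 0L))

  # empty input
  res5 <- filter_eligible(normal_record()[0, ])
  expect_null(res5$panel)
  expect_true(all(res5$exclusions == 0L))
})

test_that("transition tabulation counts consecutive visit pairs", {
  p <- as_mwm_panel(data.frame(subject_id = c("a", "a"), visit_time = c(0, 1),
                               state = c(1L, 1L)))
  tab <- tabulate_transitions(p)
  expect_identical(tab$counts[1, 1], 1L)
  expect_equal(tab$row_percent[1, 1], 100)

  p <- as_mwm_panel(data.frame(subject_id = rep("a", 3), visit_time = 0:2,
                               state = c(1L, 2L, 1L)))
  tab <- tabulate_transitions(p)
  expect_identical(tab$counts[1, 2], 1L)
  expect_identical(tab$counts[2, 1], 1L)
  expect_identical(sum(tab$counts), 2L)
})

test_that("total transitions equal visits minus subjects; tabulation is invariant to order and time shifts", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 80, seed = 5))
  p <- cohort$panel
  tab <- tabulate_transitions(p)
  expect_identical(sum(tab$counts),
                   nrow(p) - length(unique(p$subject_id)))
  # shuffle subjects and shift all times uniformly
  p2 <- p[order(rev(seq_len(nrow(p)))), ]
  p2$visit_time <- p2$visit_time + 3
  tab2 <- tabulate_transitions(as_mwm_panel(p2))
  expect_identical(tab2$counts, tab$counts)
  # row percentages sum to 100 where a row has transitions
  rs <- rowSums(tab$counts)
  expect_true(all(abs(rowSums(tab$row_percent)[rs > 0] - 100) < 0.05))
})

test_that("reference reconstruction reproduces every printed transition percentage", {
  tab <- tabulate_transitions(reference_transition_panel())
  expect_identical(tab$counts, reference_transition_counts())
  printed <- matrix(c(
    80.20,  7.62, 0.20,  9.29,  2.41,  0.28,
    13.25, 58.29, 3.85,  2.15, 20.41,  2.05,
     1.85, 15.30, 46.10, 0.41,  5.54, 30.80,
    37.80,  5.93, 0.12, 46.65,  9.26,  0.24,
     6.15, 23.21, 1.67,  4.92, 58.28,  5.78,
     1.45,  5.37, 14.20, 0.36, 10.17, 68.46),
    nrow = 6, byrow = TRUE, dimnames = list(mwt_states(), mwt_states()))
  expect_equal(tab$row_percent, printed, tolerance = 1e-12)
})

test_that("baseline summary reproduces the published composition", {
  s <- baseline_summary(reference_baseline_panel())
  expect_identical(s$counts, reference_baseline_counts())
  expect_equal(unname(s$percent),
               c(45.03, 18.08, 3.60, 9.42, 15.93, 7.93))
  expect_equal(s$unhealthy_percent, 33.29)
  expect_equal(unname(s$unhealthy_by_weight[["obese"]]), 68.77)
  expect_equal(unname(s$unhealthy_by_weight[["overweight"]]), 46.85)

  single <- as_mwm_panel(data.frame(subject_id = c("a", "a"),
                                    visit_time = 0:1, state = 6L))
  ss <- baseline_summary(single)
  expect_equal(unname(ss$percent[6]), 100)
  expect_equal(ss$unhealthy_percent, 100)
})

test_that("stratification partitions subjects by baseline subgroup", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 60, seed = 11))
  strata <- stratify_panel(cohort$panel)
  expect_identical(length(strata), 4L)
  ids <- unlist(lapply(strata, function(p) if (!is.null(p)) unique(p$subject_id)))
  expect_setequal(ids, unique(cohort$panel$subject_id))
  expect_identical(anyDuplicated(ids), 0L)
  # all-female panel: only the two female strata are non-empty
  fem <- cohort$panel[cohort$panel$female == 1, ]
  sf <- stratify_panel(as_mwm_panel(fem))
  expect_true(all(vapply(sf[grepl("female=0", names(sf))], is.null, logical(1))))
})
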