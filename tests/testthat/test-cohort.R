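test_that("step_transition follows the within-cycle event order", {
  cal <- fixture_cal()
  pol <- fixture_policy()
  base <- list(death = 0.999, onset = 0.999, attendance = 0.999,
               detection = 0.999, clinical = 0.999, progression = 0.999,
               regression = 0.999)

  # forced death wins over everything
  d <- base; d$death <- 0; d$onset <- 0
  expect_identical(
    step_transition("HEALTHY", 60, NA, cal, NULL, d)$state,
    "DEAD_OTHER_CAUSE")

  # DCIS, no exam: clinical and progression fail, regression succeeds
  d <- base; d$regression <- 0.01
  st <- step_transition("DCIS", 45, 2L, cal, pol, d)
  expect_identical(st$state, "HEALTHY")
  expect_identical(st$event, "regression")

  # DCIS at an exam age: attended and detected
  d <- base; d$attendance <- 0.5; d$detection <- 0.5
  st <- step_transition("DCIS", 50, 1L, cal, pol, d)
  expect_identical(st$state, "DCIS_SCREEN_DETECTED")
  expect_identical(st$grade, 1L)

  # onset ends the cycle: no same-year screen detection
  d <- base; d$onset <- 0.01; d$attendance <- 0; d$detection <- 0
  st <- step_transition("HEALTHY", 50, NA, cal, pol, d)
  expect_identical(st$state, "DCIS")
  expect_identical(st$event, "onset")
  expect_true(st$attended)

  expect_error(step_transition("HEALTHY", 50, NA, cal, NULL,
                               modifyList(base, list(death = 1.0))),
               "contract violation")
  expect_identical(
    cycle_event_order(),
    c("death", "onset", "screen", "clinical", "progression", "regression"))
})

test_that("records partition the cohort and modes are conserved", {
  arm <- simulate_arm(toy_cal(1), toy_policy(), n = 5000, n_cohorts = 3,
                      seed = 2)
  expect_identical(nrow(arm$records), 15000L)
  expect_identical(anyDuplicated(arm$records[c("cohort", "id")]), 0L)
  expect_true(all(arm$records$mode %in%
                    c("SCREEN", "CLINICAL", "IBC_PROGRESSION", "NONE")))
  none <- arm$records$mode == "NONE"
  expect_true(all(is.na(arm$records$age[none])))
  expect_true(all(!is.na(arm$records$age[!none])))
  expect_true(all(!is.na(arm$records$grade[!none])))
})

test_that("simulation is reproducible and cohort-order independent", {
  a <- simulate_arm(toy_cal(2), toy_policy(), n = 4000, n_cohorts = 2,
                    seed = 9)
  b <- simulate_arm(toy_cal(2), toy_policy(), n = 4000, n_cohorts = 2,
                    seed = 9)
  expect_identical(a, b)
  # cohort 2 alone reproduces its slice of the two-cohort run
  solo <- simulate_arm(toy_cal(2), toy_policy(), n = 4000, seed = 9,
                       cohorts = 2L)
  slice <- a$records[a$records$cohort == 2L, ]
  rownames(slice) <- NULL
  expect_identical(solo$records, slice)
  expect_identical(solo$n_screened, a$n_screened["2"])
})

test_that("no screening policy or zero sensitivity yields no screen detections", {
  expect_identical(
    sum(simulate_arm(toy_cal(1), NULL, n = 3000, seed = 4)$records$mode ==
          "SCREEN"), 0L)
  expect_identical(
    sum(simulate_arm(toy_cal(1), toy_policy(sensitivity = 0), n = 3000,
                     seed = 4)$records$mode == "SCREEN"), 0L)
})

test_that("zero participation makes the arms identical", {
  p <- simulate_paired(toy_cal(1), toy_policy(participation = 0),
                       n = 3000, n_cohorts = 2, seed = 6)
  expect_identical(p$screened$records, p$unscreened$records)
  expect_identical(sum(p$screened$n_screened), 0L)
})

test_that("the unscreened arm of a pair equals a standalone unscreened run", {
  p <- simulate_paired(toy_cal(2), toy_policy(), n = 3000, n_cohorts = 2,
                       seed = 8)
  solo <- simulate_arm(toy_cal(2), NULL, n = 3000, n_cohorts = 2, seed = 8)
  expect_identical(p$unscreened$records, solo$records)
})

test_that("screening intercepts, never delays, for every woman", {
  for (seed in c(1, 2, 3)) {
    p <- simulate_paired(toy_cal(3), toy_policy(), n = 4000, n_cohorts = 1,
                         seed = seed)
    sa <- ifelse(is.na(p$screened$records$age), Inf, p$screened$records$age)
    ua <- ifelse(is.na(p$unscreened$records$age), Inf,
                 p$unscreened$records$age)
    expect_true(all(sa <= ua))
    expect_true(all(p$unscreened$records$mode[
      p$screened$records$mode == "NONE"] == "NONE"))
  }
})

test_that("an invalid calibration is refused with its violation report", {
  cal <- toy_cal(1)
  cal$mortality[3] <- 2
  expect_error(simulate_arm(cal, NULL, n = 10, seed = 1),
               "invalid calibration")
})

test_that("scripted fixture reproduces the hand-enumerated records", {
  p <- fixture_paired()
  expect_identical(
    p$screened$records,
    data.frame(cohort = 1L, id = 1:4,
               mode = c("SCREEN", "CLINICAL", "IBC_PROGRESSION", "NONE"),
               age = c(50L, 51L, 53L, NA),
               grade = c(1L, 2L, 3L, NA)))
  expect_identical(
    p$unscreened$records,
    data.frame(cohort = 1L, id = 1:4,
               mode = c("NONE", "CLINICAL", "IBC_PROGRESSION", "NONE"),
               age = c(NA, 51L, 53L, NA),
               grade = c(NA, 2L, 3L, NA)))
})

test_that("terminal-mode frequencies match the exact oracle on a toy chain", {
  cal <- toy_cal(1)
  n <- 500000L
  for (pol in list(NULL, toy_policy())) {
    o <- oracle_mode_probabilities(cal, pol)
    arm <- simulate_arm(cal, pol, n = n, seed = 13)
    freq <- table(factor(arm$records$mode,
                         levels = names(o$mode_prob))) / n
    se <- sqrt(o$mode_prob * (1 - o$mode_prob) / n)
    expect_true(all(abs(as.numeric(freq) - o$mode_prob) <= 3 * se + 1e-12))
  }
})
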