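# Small calibrations and scripted fixtures shared across the suite.

const_sched <- function(max_age, by_grade) {
  matrix(rep(by_grade, each = max_age + 1L), ncol = 3L)
}

# Three small, fully exercised chains for oracle/Monte-Carlo comparison.
toy_cal <- function(which = 1L) {
  max_age <- 8L
  ages <- 0:max_age
  switch(which,
    {
      q <- rep(0.02, 9); q[9] <- 1
      onset <- const_sched(8L, c(0.05, 0.04, 0.03))
      onset[1:2, ] <- 0
      dcis_calibration(q, onset, const_sched(8L, c(0.05, 0.10, 0.15)),
                       label = "toy-1")
    },
    {
      q <- seq(0, 0.1, length.out = 9); q[9] <- 1
      onset <- const_sched(8L, c(0.02, 0.06, 0.04))
      dcis_calibration(q, onset, const_sched(8L, c(0.02, 0.08, 0.20)),
                       scalars = list(regression = 0.2,
                                      clinical_detection = 0.1,
                                      screen_sensitivity = 0.6,
                                      participation = 0.5),
                       label = "toy-2")
    },
    {
      q <- rep(0.01, 9); q[9] <- 1
      onset <- const_sched(8L, c(0.01, 0.03, 0.08))
      dcis_calibration(q, onset, const_sched(8L, c(0.10, 0.20, 0.30)),
                       scalars = list(regression = 0),
                       label = "toy-3")
    })
}

toy_policy <- function(participation = NULL, sensitivity = NULL) {
  screening_policy(start_age = 4L, end_age = 7L, interval = 2L,
                   participation = participation, sensitivity = sensitivity)
}

# ---- 4-woman scripted fixture --------------------------------------------
#
# Hand-enumerated expectations (grades in parentheses, ages at diagnosis):
#   woman 1: grade-1 onset at 49; screened arm intercepts at the age-50
#            exam (SCREEN@50); unscreened arm regresses at 50 and dies
#            undiagnosed (NONE).
#   woman 2: grade-2 onset at 47; misses the age-50 exam; clinically
#            detected at 51 in both arms (CLINICAL@51).
#   woman 3: grade-3 onset at 51; does not attend the age-52 exam;
#            progresses to IBC at 53 in both arms (IBC_PROGRESSION@53).
#   woman 4: never develops DCIS; dies at the horizon (NONE).
# Only woman 1 attends a screen, so n_screened = 1.

fixture_cal <- function() {
  max_age <- 60L
  q <- rep(0, max_age + 1L); q[max_age + 1L] <- 1
  onset <- matrix(0, max_age + 1L, 3L)
  onset[41:60, ] <- 0.05            # ages 40..59, all grades
  prog <- const_sched(max_age, c(0.02, 0.05, 0.10))
  dcis_calibration(q, onset, prog, label = "fixture")
}

fixture_policy <- function() {
  screening_policy(start_age = 50L, end_age = 54L, interval = 2L)
}

# Scripted uniform draws: default 0.999 (no event fires), with overrides
# keyed "<id>.<age>.<draw>". Natural draws are shared between arms;
# attendance/detection are consumed only by the screened arm.
fixture_draws <- function() {
  ov <- c(
    "1.49.onset" = 0.01,        # grade 1 (cum thresholds .05/.10/.15)
    "1.50.attendance" = 0.5, "1.50.detection" = 0.5,
    "1.50.regression" = 0.01,   # unscreened arm regresses at 50
    "2.47.onset" = 0.07,        # grade 2
    "2.50.attendance" = 0.9,    # misses the exam
    "2.51.clinical" = 0.01,
    "3.51.onset" = 0.12,        # grade 3
    "3.52.attendance" = 0.9,
    "3.53.progression" = 0.01
  )
  function(id, age, draw) {
    key <- paste(id, age, draw, sep = ".")
    if (key %in% names(ov)) unname(ov[key]) else 0.999
  }
}

# Run one woman through the chain with step_transition and scripted draws.
run_scripted_woman <- function(id, cal, policy, draw_fun) {
  state <- "HEALTHY"; grade <- NA_integer_
  for (age in 0:cal$max_age) {
    draws <- lapply(setNames(nm = c("death", "onset", "attendance",
                                    "detection", "clinical", "progression",
                                    "regression")),
                    function(d) draw_fun(id, age, d))
    st <- step_transition(state, age, grade, cal, policy, draws)
    state <- st$state; grade <- st$grade
    if (st$event == "death")
      return(data.frame(cohort = 1L, id = id, mode = "NONE",
                        age = NA_integer_, grade = NA_integer_))
    if (st$event == "screen_detected")
      return(data.frame(cohort = 1L, id = id, mode = "SCREEN",
                        age = age, grade = grade))
    if (st$event == "clinical_detected")
      return(data.frame(cohort = 1L, id = id, mode = "CLINICAL",
                        age = age, grade = grade))
    if (st$event == "progression")
      return(data.frame(cohort = 1L, id = id, mode = "IBC_PROGRESSION",
                        age = age, grade = grade))
  }
  data.frame(cohort = 1L, id = id, mode = "NONE", age = NA_integer_,
             grade = NA_integer_)
}

fixture_paired <- function() {
  cal <- fixture_cal(); pol <- fixture_policy(); dr <- fixture_draws()
  scr <- do.call(rbind, lapply(1:4, run_scripted_woman, cal = cal,
                               policy = pol, draw_fun = dr))
  uns <- do.call(rbind, lapply(1:4, run_scripted_woman, cal = cal,
                               policy = NULL, draw_fun = dr))
  paired_result(
    arm_result(scr, n = 4L, n_screened = 1L, arm = "screened"),
    arm_result(uns, n = 4L, n_screened = 0L, arm = "unscreened"),
    policy = pol, max_age = cal$max_age)
}

expect_no_violations <- function(cal) {
  testthat::expect_identical(validate_calibration(cal), character(0))
}
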