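#' Construct a screening policy
#'
#' Defaults represent biennial invitation of women aged 50--75. Leaving
#' `participation` or `sensitivity` `NULL` means "inherit from the
#' calibration's scalar parameters" when the policy is used in a
#' simulation; this keeps the sensitivity analyses, which perturb the
#' calibration scalars, a single source of truth.
#'
#' @param start_age first invitation age (default 50).
#' @param end_age last age of the invitation window (default 75).
#' @param interval years between invitations (default 2).
#' @param participation per-invitation attendance probability, or `NULL`
#'   to inherit the calibration's value.
#' @param sensitivity per-exam detection probability for prevalent DCIS,
#'   or `NULL` to inherit.
#' @return An object of class `dcis_policy`.
#' @export
screening_policy <- function(start_age = 50L, end_age = 75L, interval = 2L,
                             participation = NULL, sensitivity = NULL) {
  if (start_age >= end_age)
    stop("invalid policy: start_age must be < end_age")
  if (interval < 1) stop("invalid policy: interval must be >= 1")
  for (p in list(participation, sensitivity))
    if (!is.null(p) && (p < 0 || p > 1))
      stop("participation and sensitivity must be in [0, 1]")
  structure(list(start_age = as.integer(start_age),
                 end_age = as.integer(end_age),
                 interval = as.integer(interval),
                 participation = participation,
                 sensitivity = sensitivity),
            class = "dcis_policy")
}

# Fill inherited participation/sensitivity from the calibration scalars.
effective_policy <- function(policy, cal) {
  if (is.null(policy)) return(NULL)
  policy$participation <- policy$participation %||% cal$scalars$participation
  policy$sensitivity <- policy$sensitivity %||% cal$scalars$screen_sensitivity
  if (policy$end_age > cal$max_age)
    stop("policy end_age exceeds the calibration's max_age")
  policy
}

#' Exam ages implied by a policy
#'
#' The arithmetic sequence `start_age, start_age + interval, ...` up to and
#' including `end_age` where it is hit exactly; for the default biennial
#' 50--75 policy this is the 13 ages 50, 52, ..., 74.
#'
#' @param policy a `dcis_policy`.
#' @return Integer vector of exam ages.
#' @export
exam_ages <- function(policy) {
  stopifnot(inherits(policy, "dcis_policy"))
  seq.int(policy$start_age, policy$end_age, by = policy$interval)
}

#' Outcome of a single screening invitation
#'
#' @param has_undetected_dcis does the woman harbour undetected DCIS at the
#'   exam?
#' @param attendance_draw,detection_draw uniforms in `[0, 1)`.
#' @param policy a `dcis_policy` with concrete `participation` and
#'   `sensitivity` values.
#' @return One of `"DETECTED"`, `"MISSED"`, `"NOT_ATTENDED"`,
#'   `"NOT_APPLICABLE"` (no DCIS present).
#' @export
exam_outcome <- function(has_undetected_dcis, attendance_draw,
                         detection_draw, policy) {
  check_draw(attendance_draw, "attendance_draw")
  check_draw(detection_draw, "detection_draw")
  if (is.null(policy$participation) || is.null(policy$sensitivity))
    stop("exam_outcome needs a policy with concrete participation and sensitivity")
  if (!has_undetected_dcis) return("NOT_APPLICABLE")
  if (attendance_draw >= policy$participation) return("NOT_ATTENDED")
  if (detection_draw < policy$sensitivity) "DETECTED" else "MISSED"
}

check_draw <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x >= 1))
    stop("contract violation: ", what, " must be a uniform in [0, 1)")
  invisible(x)
}

#' @export
print.dcis_policy <- function(x, ...) {
  cat(sprintf("<dcis_policy> ages %d-%d every %d year(s)\n",
              x$start_age, x$end_age, x$interval))
  cat(sprintf("  participation = %s, sensitivity = %s\n",
              x$participation %||% "(from calibration)",
              x$sensitivity %||% "(from calibration)"))
  invisible(x)
}
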