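#' Exact terminal-mode probabilities by dynamic programming
#'
#' Propagates the full state distribution of the discrete-time chain age
#' by age -- healthy and the three DCIS grades, each split by whether the
#' woman has ever attended a screen -- applying the identical within-cycle
#' event order as the Monte-Carlo engine ([cycle_event_order()]). Returns
#' the exact expected probability of each terminal mode, resolved by grade
#' and age at the terminal event, for one arm. Serves as the independent
#' verification oracle for [simulate_arm()] and the overdiagnosis
#' estimators; it is exact up to floating-point rounding, so agreement is
#' checked against Monte-Carlo binomial error only.
#'
#' Probability mass is conserved at every step; the result records the
#' total as a self-check (`abs(total - 1) < 1e-12`).
#'
#' @param cal a valid `dcis_calibration` (invalid sets are refused with
#'   the validation report).
#' @param policy a `dcis_policy` or `NULL` for the unscreened arm.
#' @return `dcis_oracle`: list with `events` (3 modes x 3 grades x ages
#'   array of expected probabilities), `none` (probability of death or
#'   horizon censoring without diagnosis), `mode_prob` (named totals over
#'   `SCREEN`, `CLINICAL`, `IBC_PROGRESSION`, `NONE`), `screened_prob`
#'   (probability of attending at least one exam), `expected_onsets`
#'   (expected DCIS episodes per woman), `arm`.
#' @export
oracle_mode_probabilities <- function(cal, policy = NULL) {
  stop_if_invalid(cal)
  eff <- effective_policy(policy, cal)
  A <- cal$max_age
  exams <- if (!is.null(eff)) exam_ages(eff) else integer(0)
  r <- cal$scalars$regression
  cd <- cal$scalars$clinical_detection

  # transient mass: rows HEALTHY, DCIS g1..g3; cols never/ever screened
  m <- matrix(0, 4, 2)
  m[1, 1] <- 1
  ev <- array(0, dim = c(3, 3, A + 1L),
              dimnames = list(mode = .DETECT_MODES, grade = .GRADES,
                              age = 0:A))
  none <- 0
  flagged_abs <- 0   # absorbed mass that had attended >= 1 exam
  onsets <- 0

  for (a in 0:A) {
    i <- a + 1L
    # (1) death
    qa <- cal$mortality[i]
    none <- none + qa * sum(m)
    flagged_abs <- flagged_abs + qa * sum(m[, 2])
    m <- m * (1 - qa)
    # (2) onset; new mass skips the rest of the cycle (except attendance)
    h <- cal$onset[i, ]
    newm <- outer(h, m[1, ])
    onsets <- onsets + sum(newm)
    m[1, ] <- m[1, ] * (1 - sum(h))
    # (3) screening exam
    if (a %in% exams) {
      pi_ <- eff$participation
      S <- eff$sensitivity
      m[1, 2] <- m[1, 2] + pi_ * m[1, 1]
      m[1, 1] <- (1 - pi_) * m[1, 1]
      newm[, 2] <- newm[, 2] + pi_ * newm[, 1]
      newm[, 1] <- (1 - pi_) * newm[, 1]
      for (g in .GRADES) {
        tot <- m[g + 1L, 1] + m[g + 1L, 2]
        scr <- pi_ * S * tot
        ev["SCREEN", g, i] <- ev["SCREEN", g, i] + scr
        flagged_abs <- flagged_abs + scr
        m[g + 1L, 2] <- m[g + 1L, 2] * (1 - pi_) + pi_ * (1 - S) * tot
        m[g + 1L, 1] <- m[g + 1L, 1] * (1 - pi_)
      }
    }
    # (4) clinical detection
    dcis <- m[2:4, , drop = FALSE]
    ev["CLINICAL", , i] <- ev["CLINICAL", , i] + cd * rowSums(dcis)
    flagged_abs <- flagged_abs + cd * sum(dcis[, 2])
    m[2:4, ] <- dcis * (1 - cd)
    # (5) progression
    p <- cal$progression[i, ]
    dcis <- m[2:4, , drop = FALSE]
    ev["IBC_PROGRESSION", , i] <- ev["IBC_PROGRESSION", , i] +
      p * rowSums(dcis)
    flagged_abs <- flagged_abs + sum(p * dcis[, 2])
    m[2:4, ] <- dcis * (1 - p)
    # (6) regression
    m[1, ] <- m[1, ] + r * colSums(m[2:4, , drop = FALSE])
    m[2:4, ] <- m[2:4, ] * (1 - r)
    # merge this cycle's onsets
    m[2:4, ] <- m[2:4, ] + newm
  }
  # horizon censoring of any remaining transient mass
  none <- none + sum(m)
  flagged_abs <- flagged_abs + sum(m[, 2])

  mode_prob <- c(SCREEN = sum(ev["SCREEN", , ]),
                 CLINICAL = sum(ev["CLINICAL", , ]),
                 IBC_PROGRESSION = sum(ev["IBC_PROGRESSION", , ]),
                 NONE = none)
  total <- sum(mode_prob)
  if (abs(total - 1) > 1e-12)
    stop("internal error: probability mass not conserved (total = ",
         format(total, digits = 17), ")")
  structure(list(events = ev, none = none, mode_prob = mode_prob,
                 screened_prob = flagged_abs, expected_onsets = onsets,
                 arm = if (is.null(policy)) "unscreened" else "screened"),
            class = "dcis_oracle")
}

oracle_count <- function(or, modes, window, grades = .GRADES) {
  if (length(modes) == 0L) return(c(rep(0, 3), total = 0))
  ages <- as.integer(dimnames(or$events)$age)
  sel_age <- ages >= window[1] & ages <= window[2]
  by_grade <- vapply(.GRADES, function(g)
    sum(or$events[modes, g, sel_age]), numeric(1))
  c(setNames(by_grade, .GRADES), total = sum(by_grade))
}

#' Exact expected overdiagnosis estimate
#'
#' Evaluates both arms with [oracle_mode_probabilities()] and combines
#' them exactly as [estimate_overdiagnosis()] combines the Monte-Carlo
#' arms: expected numerator-mode diagnoses in the screened arm minus
#' expected non-screen numerator diagnoses in the unscreened arm, inside
#' the perspective window. Valid as the expectation of the
#' common-random-number estimator because expectations are linear and
#' pre-screening dynamics are arm-identical.
#'
#' @param cal a valid `dcis_calibration`.
#' @param policy a `dcis_policy`.
#' @param spec a `dcis_definition`.
#' @param n cohort size used only to scale probabilities to expected
#'   counts (default 100,000).
#' @return list with `number`, `denominator`, `proportion`, `rate`,
#'   `n_screened` (expected), `by_grade` data frame, and the two
#'   `dcis_oracle` arm results.
#' @export
oracle_overdiagnosis <- function(cal, policy, spec = base_definition(),
                                 n = 100000) {
  scr <- oracle_mode_probabilities(cal, policy)
  uns <- oracle_mode_probabilities(cal, NULL)
  eff <- effective_policy(policy, cal)
  window <- perspective_window(spec$perspective, eff, cal$max_age)
  num_s <- oracle_count(scr, spec$numerator, window)
  num_u <- oracle_count(uns, setdiff(spec$numerator, "SCREEN"), window)
  den <- oracle_count(scr, spec$denominator, window)
  number <- n * (num_s - num_u)
  denominator <- n * den
  proportion <- ifelse(denominator == 0, NA_real_, number / denominator)
  n_screened <- n * scr$screened_prob
  by_grade <- data.frame(
    grade = c("1", "2", "3", "all"),
    number = number, denominator = denominator, proportion = proportion,
    row.names = NULL, stringsAsFactors = FALSE)
  list(number = unname(number["total"]),
       denominator = unname(denominator["total"]),
       proportion = unname(proportion["total"]),
       rate = unname(number["total"]) / n_screened * 1e5,
       n_screened = n_screened,
       by_grade = by_grade,
       screened = scr, unscreened = uns)
}

#' @export
print.dcis_oracle <- function(x, ...) {
  cat(sprintf("<dcis_oracle> %s arm\n", x$arm))
  print(round(x$mode_prob, 6))
  cat(sprintf("  P(attended >= 1 screen) = %.6f; E[onsets] = %.6f\n",
              x$screened_prob, x$expected_onsets))
  invisible(x)
}
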