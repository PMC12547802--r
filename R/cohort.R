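#' Within-cycle event order
#'
#' Events inside one annual cycle are tested in a fixed order; the first
#' success absorbs the woman or applies its transition and the remainder of
#' the cycle is skipped. In particular a DCIS onset (a transition) ends the
#' cycle, so a lesion cannot be screen-detected in the same year it arises.
#' The order is shared verbatim by the Monte-Carlo engine
#' ([simulate_arm()]) and the exact oracle
#' ([oracle_mode_probabilities()]), without which their comparison would be
#' meaningless.
#'
#' @return Character vector naming the events in order.
#' @export
cycle_event_order <- function() {
  c("death", "onset", "screen", "clinical", "progression", "regression")
}

#' Advance one woman through one annual cycle
#'
#' Pure function: deterministic given the state, age, calibration, policy
#' and the uniform draws for the cycle. Used directly for scripted
#' fixtures; [simulate_arm()] applies the identical logic vectorised.
#'
#' @param state `"HEALTHY"` or `"DCIS"` (absorbing states cannot be
#'   stepped).
#' @param age current age in years.
#' @param grade DCIS grade 1--3 when `state == "DCIS"`, else `NA`.
#' @param cal a valid `dcis_calibration`.
#' @param policy a `dcis_policy` or `NULL` for the unscreened arm.
#' @param draws named list of uniforms in `[0, 1)`: `death`, `onset`,
#'   `attendance`, `detection`, `clinical`, `progression`, `regression`.
#'   Only the draws the cycle actually reaches are consulted.
#' @return list with `state` (possibly an absorbing state name), `grade`,
#'   `event` (one of `"death"`, `"onset"`, `"screen_detected"`,
#'   `"clinical_detected"`, `"progression"`, `"regression"`, `"none"`) and
#'   `attended` (did she attend a screen this cycle).
#' @export
step_transition <- function(state, age, grade = NA_integer_, cal,
                            policy = NULL, draws) {
  stopifnot(state %in% c("HEALTHY", "DCIS"))
  eff <- effective_policy(policy, cal)
  for (nm in names(draws)) check_draw(draws[[nm]], nm)
  i <- age + 1L
  exam_today <- !is.null(eff) && age %in% exam_ages(eff)
  attended <- FALSE
  out <- function(state, grade, event)
    list(state = state, grade = grade, event = event, attended = attended)

  # (1) other-cause death
  if (draws$death < cal$mortality[i])
    return(out("DEAD_OTHER_CAUSE", NA_integer_, "death"))
  # (2) onset, healthy women only; ends the cycle
  if (state == "HEALTHY") {
    hcum <- cumsum(cal$onset[i, ])
    if (draws$onset < hcum[3]) {
      g <- findInterval(draws$onset, hcum) + 1L
      if (exam_today) attended <- draws$attendance < eff$participation
      return(out("DCIS", g, "onset"))
    }
    if (exam_today) attended <- draws$attendance < eff$participation
    return(out("HEALTHY", NA_integer_, "none"))
  }
  # (3) screening exam, prevalent DCIS only
  if (exam_today) {
    oc <- exam_outcome(TRUE, draws$attendance, draws$detection, eff)
    attended <- oc %in% c("DETECTED", "MISSED")
    if (oc == "DETECTED")
      return(out("DCIS_SCREEN_DETECTED", grade, "screen_detected"))
  }
  # (4) clinical detection
  if (draws$clinical < cal$scalars$clinical_detection)
    return(out("DCIS_CLINICALLY_DETECTED", grade, "clinical_detected"))
  # (5) progression to IBC
  if (draws$progression < cal$progression[i, grade])
    return(out("IBC_DIAGNOSED", grade, "progression"))
  # (6) regression to healthy
  if (draws$regression < cal$scalars$regression)
    return(out("HEALTHY", NA_integer_, "regression"))
  out("DCIS", grade, "none")
}

# One cohort, one arm, vectorised over women. Natural-history draws come
# from the substream (seed, cohort, NATURAL, age) and are byte-identical
# between arms; screening draws come from (seed, cohort, SCREEN, age) and
# are consumed only when a policy is present.
sim_one_cohort <- function(cal, policy, n, seed, cohort) {
  eff <- effective_policy(policy, cal)
  A <- cal$max_age
  q <- cal$mortality
  H <- cal$onset
  P <- cal$progression
  r <- cal$scalars$regression
  cd <- cal$scalars$clinical_detection
  exams <- if (!is.null(eff)) exam_ages(eff) else integer(0)

  state <- integer(n)              # 0 healthy, 1..3 DCIS grade
  absorbed <- integer(n)           # 0 active, 1 SCREEN, 2 CLINICAL, 3 IBC, 4 DEAD
  abs_age <- rep(NA_integer_, n)
  abs_grade <- rep(NA_integer_, n)
  ever_screened <- logical(n)
  episodes <- 0L

  for (a in 0:A) {
    act <- absorbed == 0L
    if (!any(act)) break
    set.seed(mix_seed(seed, cohort, .STREAM_NATURAL, a))
    d_death <- runif(n); d_onset <- runif(n); d_clin <- runif(n)
    d_prog <- runif(n); d_reg <- runif(n)

    # (1) death
    dies <- act & d_death < q[a + 1L]
    absorbed[dies] <- 4L
    act[dies] <- FALSE

    # (2) onset (ends the cycle for the women concerned)
    onset_now <- logical(n)
    hcum <- cumsum(H[a + 1L, ])
    if (hcum[3] > 0) {
      hea <- which(act & state == 0L)
      if (length(hea)) {
        g <- findInterval(d_onset[hea], hcum) + 1L
        ons <- hea[g <= 3L]
        if (length(ons)) {
          state[ons] <- g[g <= 3L]
          onset_now[ons] <- TRUE
          episodes <- episodes + length(ons)
        }
      }
    }

    # (3) screening exam: attendance recorded for every active woman,
    #     detection only for DCIS prevalent before this cycle's onset
    if (a %in% exams) {
      set.seed(mix_seed(seed, cohort, .STREAM_SCREEN, a))
      d_att <- runif(n); d_det <- runif(n)
      att <- d_att < eff$participation
      ever_screened <- ever_screened | (act & att)
      det <- act & att & !onset_now & state > 0L & d_det < eff$sensitivity
      absorbed[det] <- 1L
      abs_age[det] <- a
      abs_grade[det] <- state[det]
      act[det] <- FALSE
    }

    # (4) clinical detection
    dcis <- act & !onset_now & state > 0L
    clin <- dcis & d_clin < cd
    absorbed[clin] <- 2L
    abs_age[clin] <- a
    abs_grade[clin] <- state[clin]
    act[clin] <- FALSE

    # (5) progression to IBC (carries the precursor grade)
    dcis <- which(act & !onset_now & state > 0L)
    if (length(dcis)) {
      prog <- dcis[d_prog[dcis] < P[cbind(a + 1L, state[dcis])]]
      if (length(prog)) {
        absorbed[prog] <- 3L
        abs_age[prog] <- a
        abs_grade[prog] <- state[prog]
        act[prog] <- FALSE
      }
    }

    # (6) regression
    dcis <- absorbed == 0L & !onset_now & state > 0L
    reg <- dcis & d_reg < r
    state[reg] <- 0L
  }

  # women still active at the horizon are censored without diagnosis
  code <- ifelse(absorbed == 0L, 4L, absorbed)
  list(
    records = data.frame(
      cohort = cohort,
      id = seq_len(n),
      mode = .MODES[code],
      age = abs_age,
      grade = abs_grade,
      stringsAsFactors = FALSE
    ),
    n_screened = sum(ever_screened),
    episodes = episodes
  )
}

#' Simulate one arm (screened or unscreened)
#'
#' Follows `n` women per cohort from birth to their first absorbing event:
#' other-cause death (recorded as mode `NONE`), screen-detected DCIS,
#' clinically detected DCIS, or IBC arising from DCIS (recorded as a
#' diagnosed DCIS of the precursor grade). Deterministic given `seed`; the
#' unscreened arm (`policy = NULL`) never consumes screening draws, so it
#' is identical whether simulated standalone or inside
#' [simulate_paired()].
#'
#' @param cal a valid `dcis_calibration` (validated on entry; an invalid
#'   set is refused with the full violation report).
#' @param policy a `dcis_policy`, or `NULL` for no screening.
#' @param n women per cohort (default 100,000).
#' @param n_cohorts number of independent cohorts (default 1).
#' @param seed run seed.
#' @param cohorts cohort indices to simulate (default `1:n_cohorts`).
#' @return `dcis_arm`: list with `records` (one diagnosis record per woman:
#'   `cohort`, `id`, `mode`, `age`, `grade`), `n`, `cohorts`,
#'   `n_screened` (per cohort, women attending at least one exam),
#'   `episodes` (per cohort, DCIS onsets), `arm`, `seed`.
#' @export
simulate_arm <- function(cal, policy = NULL, n = 100000L, n_cohorts = 1L,
                         seed = 1L, cohorts = seq_len(n_cohorts)) {
  stop_if_invalid(cal)
  stopifnot(n >= 1)
  res <- lapply(cohorts, function(k) sim_one_cohort(cal, policy, n, seed, k))
  structure(list(
    records = do.call(rbind, lapply(res, `[[`, "records")),
    n = as.integer(n),
    cohorts = as.integer(cohorts),
    n_screened = setNames(vapply(res, `[[`, integer(1), "n_screened"),
                          cohorts),
    episodes = setNames(vapply(res, `[[`, integer(1), "episodes"), cohorts),
    arm = if (is.null(policy)) "unscreened" else "screened",
    policy = policy,
    seed = as.integer(seed)
  ), class = "dcis_arm")
}

#' Simulate paired screened and unscreened cohorts
#'
#' Both arms are built from identical natural-history draws (common random
#' numbers), so every difference in diagnoses is attributable to screening.
#' The pairing guarantee -- screening can only intercept a diagnosis,
#' never delay or create one that changes a woman's pre-screening course --
#' is asserted woman-by-woman on every run: the screened-arm diagnosis age
#' is at most the unscreened-arm age (treating no-diagnosis as infinity),
#' which also forces "screened NONE implies unscreened NONE".
#'
#' @inheritParams simulate_arm
#' @param policy a `dcis_policy` (default biennial 50--75).
#' @param n_cohorts number of replicate cohorts (default 10).
#' @return `dcis_paired`: list with `screened` and `unscreened`
#'   (`dcis_arm`), `n`, `cohorts`, `seed`, `policy`.
#' @export
simulate_paired <- function(cal, policy = screening_policy(), n = 100000L,
                            n_cohorts = 10L, seed = 1L) {
  if (is.null(policy)) stop("simulate_paired needs a screening policy")
  screened <- simulate_arm(cal, policy, n, n_cohorts, seed)
  unscreened <- simulate_arm(cal, NULL, n, n_cohorts, seed)
  sa <- ifelse(is.na(screened$records$age), Inf, screened$records$age)
  ua <- ifelse(is.na(unscreened$records$age), Inf, unscreened$records$age)
  if (!all(sa <= ua))
    stop("internal error: interception property violated (screened-arm ",
         "diagnosis later than unscreened)")
  structure(list(screened = screened, unscreened = unscreened,
                 n = as.integer(n), cohorts = screened$cohorts,
                 seed = as.integer(seed), policy = policy,
                 max_age = cal$max_age),
            class = "dcis_paired")
}

#' Assemble arm / paired results from externally produced records
#'
#' Builds the same containers [simulate_arm()] and [simulate_paired()]
#' return, from diagnosis records produced elsewhere (scripted fixtures,
#' an external simulator). Records need columns `cohort`, `id`, `mode`
#' (one of `SCREEN`, `CLINICAL`, `IBC_PROGRESSION`, `NONE`), `age`,
#' `grade`.
#'
#' @param records diagnosis-record data frame (one row per woman).
#' @param n women per cohort.
#' @param n_screened per-cohort counts of women attending at least one
#'   exam.
#' @param episodes per-cohort DCIS onset counts (optional).
#' @param arm `"screened"` or `"unscreened"`.
#' @param seed seed label.
#' @return A `dcis_arm`.
#' @export
arm_result <- function(records, n, n_screened, episodes = NA_integer_,
                       arm = "screened", seed = NA_integer_) {
  stopifnot(all(c("cohort", "id", "mode", "age", "grade") %in%
                  names(records)),
            all(records$mode %in% .MODES))
  cohorts <- sort(unique(records$cohort))
  structure(list(records = records, n = as.integer(n),
                 cohorts = as.integer(cohorts),
                 n_screened = rep_len(n_screened, length(cohorts)),
                 episodes = rep_len(episodes, length(cohorts)),
                 arm = arm, policy = NULL, seed = seed),
            class = "dcis_arm")
}

#' @rdname arm_result
#' @param screened,unscreened `dcis_arm` objects forming the pair.
#' @param policy the `dcis_policy` the screened arm was run under.
#' @param max_age grid horizon age.
#' @return `paired_result()`: a `dcis_paired`.
#' @export
paired_result <- function(screened, unscreened, policy, max_age,
                          seed = NA_integer_) {
  structure(list(screened = screened, unscreened = unscreened,
                 n = screened$n, cohorts = screened$cohorts,
                 seed = seed, policy = policy,
                 max_age = as.integer(max_age)),
            class = "dcis_paired")
}

#' Fraction of DCIS episodes that progress to IBC
#'
#' Terminal IBC diagnoses divided by all DCIS onsets in the arm. In an
#' unscreened cohort this is the model's natural progression fraction;
#' the synthetic generator targets roughly 0.20.
#'
#' @param arm a `dcis_arm`.
#' @return Numeric fraction.
#' @export
progression_fraction <- function(arm) {
  sum(arm$records$mode == "IBC_PROGRESSION") / sum(arm$episodes)
}

#' @export
print.dcis_arm <- function(x, ...) {
  cat(sprintf("<dcis_arm> %s, %d x %d women (seed %d)\n", x$arm,
              length(x$cohorts), x$n, x$seed))
  print(table(x$records$mode))
  invisible(x)
}

#' @export
print.dcis_paired <- function(x, ...) {
  cat(sprintf("<dcis_paired> %d cohorts x %d women (seed %d)\n",
              length(x$cohorts), x$n, x$seed))
  cat("screened:  "); print(table(x$screened$records$mode))
  cat("unscreened:"); print(table(x$unscreened$records$mode))
  invisible(x)
}
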