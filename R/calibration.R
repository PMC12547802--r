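#' Construct a calibration set
#'
#' A calibration set bundles every model input: the age grid (0..max_age,
#' implied by the schedule lengths), the annual other-cause mortality
#' schedule, the annual DCIS onset schedule by grade, the annual
#' DCIS-to-IBC progression schedule by grade, the four scalar parameters,
#' and per-parameter uncertainty intervals for the sensitivity analyses.
#'
#' All schedule entries are annual transition probabilities. Scalars:
#' \describe{
#'   \item{regression}{annual probability that undetected DCIS regresses to
#'     healthy, independent of age and grade (default 0.05).}
#'   \item{screen_sensitivity}{per-exam probability that an attended
#'     mammogram detects prevalent DCIS (default 0.86).}
#'   \item{clinical_detection}{annual probability that undetected DCIS
#'     presents clinically (default 0.05).}
#'   \item{participation}{per-invitation probability of attending a
#'     scheduled screen (default 0.76).}
#' }
#'
#' @param mortality numeric vector of length `max_age + 1`; `mortality[a+1]`
#'   is the annual probability of other-cause death at age `a`.
#' @param onset numeric matrix `(max_age + 1) x 3`; `onset[a+1, g]` is the
#'   annual probability that a healthy woman develops grade-`g` DCIS at age
#'   `a`. Row sums must not exceed 1.
#' @param progression numeric matrix `(max_age + 1) x 3`; annual probability
#'   that undetected grade-`g` DCIS progresses to IBC at age `a`.
#' @param scalars named list overriding any of the four scalar defaults.
#' @param intervals data frame with columns `parameter`, `kind`
#'   (`"scalar"` or `"factor"`), `low`, `high`; defaults from
#'   [default_intervals()].
#' @param label provenance label stored with the set.
#' @return An object of class `dcis_calibration`.
#' @seealso [validate_calibration()], [generate_synthetic_calibration()]
#' @export
dcis_calibration <- function(mortality, onset, progression,
                             scalars = list(), intervals = NULL,
                             label = "custom") {
  mortality <- as.numeric(mortality)
  onset <- as.matrix(onset)
  progression <- as.matrix(progression)
  max_age <- length(mortality) - 1L
  if (max_age < 1L) stop("mortality schedule must cover at least ages 0..1")
  if (nrow(onset) != max_age + 1L || ncol(onset) != 3L)
    stop("onset schedule must be (max_age + 1) x 3")
  if (nrow(progression) != max_age + 1L || ncol(progression) != 3L)
    stop("progression schedule must be (max_age + 1) x 3")
  defaults <- list(regression = 0.05, screen_sensitivity = 0.86,
                   clinical_detection = 0.05, participation = 0.76)
  unknown <- setdiff(names(scalars), names(defaults))
  if (length(unknown))
    stop("unknown scalar parameter(s): ", paste(unknown, collapse = ", "))
  sc <- modifyList(defaults, scalars)
  dimnames(onset) <- dimnames(progression) <- NULL
  structure(list(
    max_age = max_age,
    ages = 0:max_age,
    mortality = unname(mortality),
    onset = onset,
    progression = progression,
    scalars = sc,
    intervals = intervals %||% default_intervals(sc),
    label = label
  ), class = "dcis_calibration")
}

#' Default uncertainty intervals for the sensitivity analyses
#'
#' One interval per swept parameter: the four scalars get +/-40 % relative
#' bounds clipped to `[0, 1]`; the three schedules (mortality, onset,
#' progression) are swept by a single multiplicative factor with bounds
#' 0.8 and 1.2 (point value 1). These are configurable stand-ins used when
#' no externally derived 95 % confidence intervals are supplied.
#'
#' @param scalars named list with the four scalar point values.
#' @return data frame with columns `parameter`, `kind`, `low`, `high`.
#' @export
default_intervals <- function(scalars = list(regression = 0.05,
                                             screen_sensitivity = 0.86,
                                             clinical_detection = 0.05,
                                             participation = 0.76)) {
  sc_names <- c("regression", "clinical_detection",
                "screen_sensitivity", "participation")
  pts <- vapply(sc_names, function(p) scalars[[p]], numeric(1))
  data.frame(
    parameter = c(sc_names, "mortality", "onset", "progression"),
    kind = c(rep("scalar", 4L), rep("factor", 3L)),
    low = c(pmin(pmax(pts * 0.6, 0), 1), rep(0.8, 3L)),
    high = c(pmin(pmax(pts * 1.4, 0), 1), rep(1.2, 3L)),
    stringsAsFactors = FALSE
  )
}

#' Validate a calibration set
#'
#' Checks every structural invariant and returns a character vector of
#' violation descriptions (empty when the set is valid). Validation reports,
#' it never throws; each message names the offending field and, where
#' applicable, the age/grade index and the rule broken.
#'
#' Rules: all probabilities in `[0, 1]`; onset row sums at most 1;
#' progression non-decreasing in grade at every age (grade 3 at least grade
#' 2 at least grade 1); scalar point values inside their stated intervals.
#'
#' @param cal a `dcis_calibration`.
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_calibration <- function(cal) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  A <- cal$max_age
  chk01 <- function(x, what, idx_age, idx_grade = NULL) {
    bad <- which(!is.finite(x) | x < 0 | x > 1)
    for (i in bad) {
      age <- idx_age[(i - 1L) %% length(idx_age) + 1L]
      if (is.null(idx_grade)) {
        add(sprintf("%s: value %g at age %d outside [0, 1]", what, x[i], age))
      } else {
        g <- idx_grade[(i - 1L) %/% length(idx_age) + 1L]
        add(sprintf("%s: value %g at age %d, grade %d outside [0, 1]",
                    what, x[i], age, g))
      }
    }
  }
  chk01(cal$mortality, "mortality q(a)", cal$ages)
  chk01(as.vector(cal$onset), "onset h(a,g)", cal$ages, .GRADES)
  chk01(as.vector(cal$progression), "progression p(a,g)", cal$ages, .GRADES)
  rs <- rowSums(cal$onset)
  for (i in which(rs > 1 + 1e-12))
    add(sprintf("onset h(a,g): grade sum %g at age %d exceeds 1", rs[i], i - 1L))
  p <- cal$progression
  bad <- which(p[, 3] < p[, 2] - 1e-12 | p[, 2] < p[, 1] - 1e-12)
  for (i in bad)
    add(sprintf(
      "progression p(a,g): grade monotonicity p(%d,3) >= p(%d,2) >= p(%d,1) violated",
      i - 1L, i - 1L, i - 1L))
  for (p_name in names(cal$scalars)) {
    x <- cal$scalars[[p_name]]
    if (!is.finite(x) || x < 0 || x > 1)
      add(sprintf("scalar %s: value %g outside [0, 1]", p_name, x))
  }
  iv <- cal$intervals
  if (!is.null(iv)) {
    for (i in seq_len(nrow(iv))) {
      pt <- if (iv$kind[i] == "scalar") cal$scalars[[iv$parameter[i]]] else 1
      if (is.null(pt)) next
      if (iv$low[i] > pt + 1e-12 || iv$high[i] < pt - 1e-12)
        add(sprintf("interval %s: point value %g outside [low = %g, high = %g]",
                    iv$parameter[i], pt, iv$low[i], iv$high[i]))
    }
  }
  v
}

stop_if_invalid <- function(cal) {
  v <- validate_calibration(cal)
  if (length(v))
    stop("invalid calibration:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  invisible(cal)
}

# Parameters the synthetic generator understands as overrides.
.SYNTH_PARAMS <- c(
  "regression", "screen_sensitivity", "clinical_detection", "participation",
  "onset_peak_age", "onset_width", "lifetime_onset", "grade_mix",
  "progression_base", "progression_age_slope",
  "mortality_rate", "mortality_shape"
)

#' Generate a synthetic calibration set
#'
#' Builds a fully valid input parameter set emulating the qualitative shape
#' of registry-derived inputs for a Western screening population:
#' Gompertz other-cause mortality rising with age (absorbing at the
#' horizon, `q(max_age) = 1`); unimodal DCIS onset peaking inside the
#' screening ages (mode in 55--70) and zero before age 25; DCIS-to-IBC
#' progression increasing with grade (grade 3 highest) and mildly with
#' age; and the four scalar parameters at their defaults of 0.05
#' (regression), 0.86 (screen sensitivity), 0.05 (clinical detection) and
#' 0.76 (participation). The progression level is designed so that in an
#' unscreened cohort roughly one in five DCIS episodes progresses to IBC.
#'
#' The generator is deterministic given `seed`: the seed perturbs the shape
#' hyper-parameters (onset peak/width/lifetime mass, grade mix, mortality
#' level, progression level) within narrow realistic ranges, so distinct
#' seeds give distinct but always-valid calibrations.
#'
#' @param seed non-negative integer; fully determines the output.
#' @param overrides named list pinning any hyper-parameter or scalar:
#'   `regression`, `screen_sensitivity`, `clinical_detection`,
#'   `participation`, `onset_peak_age`, `onset_width`, `lifetime_onset`,
#'   `grade_mix` (length-3 shares), `progression_base` (length-3 annual
#'   probabilities for grades 1..3), `progression_age_slope`,
#'   `mortality_rate`, `mortality_shape`. Unknown names are rejected.
#' @param max_age horizon age (default 100).
#' @return A valid `dcis_calibration`.
#' @examples
#' cal <- generate_synthetic_calibration(seed = 1)
#' validate_calibration(cal)
#' @export
generate_synthetic_calibration <- function(seed, overrides = list(),
                                           max_age = 100L) {
  if (seed < 0) stop("seed must be >= 0")
  unknown <- setdiff(names(overrides), .SYNTH_PARAMS)
  if (length(unknown))
    stop("unknown override parameter(s): ", paste(unknown, collapse = ", "))
  set.seed(mix_seed(seed, 97L))
  hp <- list(
    onset_peak_age = runif(1, 59, 66),
    onset_width = runif(1, 8.5, 11),
    lifetime_onset = runif(1, 0.022, 0.030),
    grade_mix = {
      m <- c(0.24, 0.40, 0.36) * exp(runif(3, -0.08, 0.08))
      m / sum(m)
    },
    progression_base = c(0.012, 0.026, 0.050) * runif(1, 0.95, 1.05),
    progression_age_slope = runif(1, 0.008, 0.015),
    mortality_rate = 3e-5 * exp(runif(1, -0.15, 0.15)),
    mortality_shape = runif(1, 0.090, 0.098)
  )
  hp <- modifyList(hp, overrides[intersect(names(overrides), names(hp))])

  a <- 0:max_age
  q <- pmin(1, hp$mortality_rate * exp(hp$mortality_shape * a))
  q[max_age + 1L] <- 1  # absorbing horizon

  shape <- exp(-(a - hp$onset_peak_age)^2 / (2 * hp$onset_width^2))
  shape[a < 25] <- 0
  h_total <- hp$lifetime_onset * shape / sum(shape)
  onset <- outer(h_total, hp$grade_mix)

  age_factor <- pmax(0.5, 1 + hp$progression_age_slope * (a - 62))
  progression <- pmin(outer(age_factor, hp$progression_base), 1)

  scalars <- list(regression = 0.05, screen_sensitivity = 0.86,
                  clinical_detection = 0.05, participation = 0.76)
  sc_over <- overrides[intersect(names(overrides), names(scalars))]
  scalars <- modifyList(scalars, sc_over)

  dcis_calibration(q, onset, progression, scalars = scalars,
                   label = sprintf("synthetic-seed-%d", seed))
}

#' @export
print.dcis_calibration <- function(x, ...) {
  cat("<dcis_calibration> ", x$label, "\n", sep = "")
  cat("  ages 0..", x$max_age, "\n", sep = "")
  cat(sprintf("  scalars: regression = %.3g, screen_sensitivity = %.3g,\n",
              x$scalars$regression, x$scalars$screen_sensitivity))
  cat(sprintf("           clinical_detection = %.3g, participation = %.3g\n",
              x$scalars$clinical_detection, x$scalars$participation))
  cat(sprintf("  lifetime onset mass: %.4f (grades %s)\n",
              sum(x$onset), paste(sprintf("%.3f", colSums(x$onset)),
                                  collapse = " / ")))
  cat("  intervals:", nrow(x$intervals), "parameters\n")
  invisible(x)
}

#' Write a calibration set to disk
#'
#' Schedules go to `path` as a long-format CSV with columns
#' `parameter` (`mortality`, `onset`, `progression`), `age`, `grade`
#' (empty for mortality), `value`. Values are written with 17 significant
#' digits so the round trip through [read_calibration()] is bit-exact.
#' Scalars, intervals, label and `max_age` go to a JSON header next to the
#' CSV (same path with extension `.json`).
#'
#' @param cal a `dcis_calibration`.
#' @param path CSV file path (its `.json` sibling is written too).
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  A <- cal$max_age
  fmt <- function(x) sprintf("%.17g", x)
  rows <- rbind(
    data.frame(parameter = "mortality", age = cal$ages, grade = NA_integer_,
               value = fmt(cal$mortality), stringsAsFactors = FALSE),
    do.call(rbind, lapply(.GRADES, function(g)
      data.frame(parameter = "onset", age = cal$ages, grade = g,
                 value = fmt(cal$onset[, g]), stringsAsFactors = FALSE))),
    do.call(rbind, lapply(.GRADES, function(g)
      data.frame(parameter = "progression", age = cal$ages, grade = g,
                 value = fmt(cal$progression[, g]), stringsAsFactors = FALSE)))
  )
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  header <- list(label = cal$label, max_age = cal$max_age,
                 scalars = cal$scalars,
                 intervals = cal$intervals)
  jsonlite::write_json(header, calibration_header_path(path),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

calibration_header_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a calibration set from disk
#'
#' Inverse of [write_calibration()]. The reader is strict: a missing
#' schedule block (e.g. no grade-3 onset rows), a gap or duplicate in an
#' age sequence, or a non-numeric cell raises a parse error naming the
#' offending column or row.
#'
#' @param path CSV file path written by [write_calibration()].
#' @return A `dcis_calibration` equal to the one written.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  hp <- calibration_header_path(path)
  if (!file.exists(hp)) stop("calibration header not found: ", hp)
  header <- jsonlite::read_json(hp, simplifyVector = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(parameter = "character", age = "integer",
                                 grade = "integer", value = "character"))
  val <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(val)) {
    i <- which(is.na(val))[1L]
    stop(sprintf("non-numeric value '%s' in row %d (%s, age %s)",
                 tab$value[i], i, tab$parameter[i], tab$age[i]))
  }
  tab$value <- val
  max_age <- as.integer(header$max_age)
  take <- function(parameter, grade = NULL) {
    sel <- tab$parameter == parameter &
      (if (is.null(grade)) is.na(tab$grade) else !is.na(tab$grade) & tab$grade == grade)
    block <- tab[sel, ]
    colname <- if (is.null(grade)) parameter else
      sprintf("%s grade %d", parameter, grade)
    if (nrow(block) == 0L)
      stop("missing column in calibration file: ", colname)
    block <- block[order(block$age), ]
    expected <- 0:max_age
    if (!identical(block$age, expected)) {
      gap <- setdiff(expected, block$age)
      if (length(gap))
        stop(sprintf("age gap in %s: missing age(s) %s", colname,
                     paste(utils::head(gap, 5L), collapse = ", ")))
      stop(sprintf("duplicated or out-of-range ages in %s", colname))
    }
    block$value
  }
  mortality <- take("mortality")
  onset <- vapply(.GRADES, function(g) take("onset", g),
                  numeric(max_age + 1L))
  progression <- vapply(.GRADES, function(g) take("progression", g),
                        numeric(max_age + 1L))
  intervals <- as.data.frame(header$intervals, stringsAsFactors = FALSE)
  dcis_calibration(mortality, onset, progression,
                   scalars = header$scalars, intervals = intervals,
                   label = header$label)
}

#' Apply a sensitivity-analysis value to a calibration
#'
#' Scalar parameters are replaced; schedule parameters (`mortality`,
#' `onset`, `progression`) are multiplied by `value` and clipped to
#' `[0, 1]`, with the horizon row of mortality kept absorbing if it was.
#'
#' @param cal a `dcis_calibration`.
#' @param parameter one of the names in `cal$intervals$parameter`.
#' @param value replacement value (scalar) or multiplicative factor
#'   (schedule).
#' @return The perturbed `dcis_calibration`.
#' @export
apply_parameter <- function(cal, parameter, value) {
  iv <- cal$intervals
  row <- match(parameter, iv$parameter)
  if (is.na(row)) stop("no interval defined for parameter: ", parameter)
  if (iv$kind[row] == "scalar") {
    cal$scalars[[parameter]] <- value
    # keep the stated interval covering the perturbed point value
    cal$intervals$low[row] <- min(iv$low[row], value)
    cal$intervals$high[row] <- max(iv$high[row], value)
  } else {
    horizon_absorbing <- cal$mortality[cal$max_age + 1L] == 1
    cal[[parameter]] <- pmin(pmax(cal[[parameter]] * value, 0), 1)
    if (parameter == "mortality" && horizon_absorbing)
      cal$mortality[cal$max_age + 1L] <- 1
  }
  cal$label <- sprintf("%s [%s = %g]", cal$label, parameter, value)
  cal
}
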