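.DETECT_MODES <- c("SCREEN", "CLINICAL", "IBC_PROGRESSION")
.PERSPECTIVES <- c("INDIVIDUAL", "POPULATION", "LIFETIME")

#' Overdiagnosis definition
#'
#' A definition fixes which detection modes count as "diagnosed DCIS" in
#' the numerator and denominator, and over which age window diagnoses are
#' counted. The conventional letters are A (screen-detected + clinically
#' detected + progressed to IBC), B (screen + clinical), C (screen only);
#' the perspectives are INDIVIDUAL (screening start to screening end),
#' POPULATION (screening start to the model horizon) and LIFETIME (birth
#' to horizon). The base definition is A from the population perspective.
#'
#' Numeric perspective aliases are accepted for convenience but with a
#' warning: the literature numbers them inconsistently, so the explicit
#' names are authoritative (1 = INDIVIDUAL, 2 = POPULATION, 3 = LIFETIME
#' here).
#'
#' @param numerator subset of `c("SCREEN", "CLINICAL", "IBC_PROGRESSION")`;
#'   must contain `"SCREEN"`.
#' @param denominator superset of `numerator` (defaults to it).
#' @param perspective `"INDIVIDUAL"`, `"POPULATION"` or `"LIFETIME"` (or a
#'   numeric alias).
#' @param label optional display label.
#' @return An object of class `dcis_definition`.
#' @export
definition_spec <- function(numerator = .DETECT_MODES,
                            denominator = numerator,
                            perspective = "POPULATION",
                            label = NULL) {
  perspective <- as_perspective(perspective)
  numerator <- match.arg(numerator, .DETECT_MODES, several.ok = TRUE)
  denominator <- match.arg(denominator, .DETECT_MODES, several.ok = TRUE)
  if (!"SCREEN" %in% numerator)
    stop("invalid definition: SCREEN must be in the numerator modes")
  if (!all(numerator %in% denominator))
    stop("invalid definition: denominator modes must contain the numerator modes")
  letter <- switch(paste(sort(numerator), collapse = "+"),
                   "CLINICAL+IBC_PROGRESSION+SCREEN" = "A",
                   "CLINICAL+SCREEN" = "B",
                   "SCREEN" = "C",
                   "custom")
  structure(list(numerator = numerator, denominator = denominator,
                 perspective = perspective,
                 label = label %||% sprintf("%s-%s", letter, perspective)),
            class = "dcis_definition")
}

as_perspective <- function(x) {
  if (is.numeric(x)) {
    warning("numeric perspective codes are ambiguous in the literature; ",
            "interpreting 1 = INDIVIDUAL, 2 = POPULATION, 3 = LIFETIME. ",
            "Prefer the explicit names.", call. = FALSE)
    x <- .PERSPECTIVES[x]
  }
  match.arg(toupper(x), .PERSPECTIVES)
}

#' The base definition: all modes, population perspective
#' @return A `dcis_definition`.
#' @export
base_definition <- function() definition_spec()

definition_modes <- function(letter) {
  switch(letter,
         A = .DETECT_MODES,
         B = c("SCREEN", "CLINICAL"),
         C = "SCREEN",
         stop("unknown definition letter: ", letter))
}

# Closed age window implied by a perspective.
perspective_window <- function(perspective, policy, max_age) {
  switch(perspective,
         INDIVIDUAL = c(policy$start_age, policy$end_age),
         POPULATION = c(policy$start_age, max_age),
         LIFETIME = c(0L, max_age))
}

#' Count diagnoses in an arm
#'
#' Counts diagnosis records whose mode is in `modes` and whose age lies in
#' the closed interval `window`. `NONE` records are never counted (they
#' carry no diagnosis).
#'
#' @param arm a `dcis_arm`.
#' @param modes non-empty subset of
#'   `c("SCREEN", "CLINICAL", "IBC_PROGRESSION")`. An empty set is
#'   rejected; use `character(0)` counts through
#'   [estimate_overdiagnosis()]'s internal handling instead.
#' @param window length-2 closed age interval.
#' @param by_grade if `TRUE`, return a length-3 vector of per-grade counts
#'   (summing to the total); otherwise the total.
#' @param per_cohort if `TRUE`, return a matrix with one row per cohort.
#' @return Count(s).
#' @export
count_diagnoses <- function(arm, modes, window, by_grade = FALSE,
                            per_cohort = FALSE) {
  if (length(modes) == 0L) stop("modes must be a non-empty set")
  modes <- match.arg(modes, .DETECT_MODES, several.ok = TRUE)
  cnt <- count_records(arm$records, modes, window,
                       cohorts = if (per_cohort) arm$cohorts else NULL)
  if (per_cohort) {
    if (by_grade) cnt[, 1:3, drop = FALSE] else cnt[, "total"]
  } else {
    tot <- as.integer(colSums(cnt))
    names(tot) <- colnames(cnt)
    if (by_grade) tot[1:3] else unname(tot["total"])
  }
}

# grade x cohort counting core; modes may be empty (returns zeros).
count_records <- function(records, modes, window, cohorts = NULL) {
  cohorts <- cohorts %||% sort(unique(records$cohort))
  sel <- records$mode %in% modes & !is.na(records$age) &
    records$age >= window[1] & records$age <= window[2]
  out <- matrix(0L, nrow = length(cohorts), ncol = 4L,
                dimnames = list(cohorts, c("1", "2", "3", "total")))
  if (any(sel)) {
    r <- records[sel, ]
    for (i in seq_along(cohorts)) {
      g <- r$grade[r$cohort == cohorts[i]]
      out[i, 1:3] <- tabulate(g, 3L)
    }
  }
  out[, "total"] <- rowSums(out[, 1:3, drop = FALSE])
  out
}

#' Overdiagnosis rate per 100,000 screened women
#'
#' @param number number of overdiagnosed DCIS.
#' @param n_screened number of women who attended at least one screen.
#' @return `number / n_screened * 100000`; `NA` (with a warning) when
#'   `n_screened` is zero.
#' @export
overdiagnosis_rate <- function(number, n_screened) {
  if (any(n_screened == 0)) {
    warning("rate undefined: no screened women in denominator")
    return(ifelse(n_screened == 0, NA_real_, number / n_screened * 1e5))
  }
  number / n_screened * 1e5
}

#' Estimate overdiagnosis from a paired run
#'
#' For each cohort, the overdiagnosed number is the count of
#' numerator-mode diagnoses in the screened arm inside the perspective
#' window, minus the count of the same modes excluding `SCREEN` in the
#' unscreened arm; the proportion divides by the denominator-mode count in
#' the screened arm; the rate is per 100,000 women attending at least one
#' screen. Per-grade estimates are computed identically within grade and
#' sum to the totals. A zero denominator yields an undefined (`NA`)
#' proportion, never zero.
#'
#' @param paired a `dcis_paired` from [simulate_paired()].
#' @param spec a `dcis_definition` (default: [base_definition()]).
#' @return `dcis_od_estimate`: list with `definition`, `window`,
#'   `per_cohort` (long data frame: cohort, grade `"all"`/`"1"`/`"2"`/
#'   `"3"`, number, denominator, rate, proportion) and `summary`
#'   (mean/min/max over cohorts per grade).
#' @export
estimate_overdiagnosis <- function(paired, spec = base_definition()) {
  stopifnot(inherits(paired, "dcis_paired"))
  window <- perspective_window(spec$perspective, paired$policy,
                               paired$max_age)

  num_s <- count_records(paired$screened$records, spec$numerator, window)
  num_u <- count_records(paired$unscreened$records,
                         setdiff(spec$numerator, "SCREEN"), window)
  den_s <- count_records(paired$screened$records, spec$denominator, window)
  number <- num_s - num_u
  nscr <- paired$screened$n_screened

  per <- do.call(rbind, lapply(seq_along(paired$cohorts), function(i) {
    data.frame(
      cohort = paired$cohorts[i],
      grade = c("all", "1", "2", "3"),
      number = number[i, c("total", "1", "2", "3")],
      denominator = den_s[i, c("total", "1", "2", "3")],
      rate = number[i, c("total", "1", "2", "3")] / nscr[i] * 1e5,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }))
  per$proportion <- ifelse(per$denominator == 0, NA_real_,
                           per$number / per$denominator)

  summ <- do.call(rbind, lapply(c("all", "1", "2", "3"), function(g) {
    sub <- per[per$grade == g, ]
    data.frame(
      grade = g,
      number = mean(sub$number), number_min = min(sub$number),
      number_max = max(sub$number),
      rate = mean(sub$rate), rate_min = min(sub$rate),
      rate_max = max(sub$rate),
      proportion = mean(sub$proportion),
      proportion_min = suppressWarnings(min(sub$proportion)),
      proportion_max = suppressWarnings(max(sub$proportion)),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(definition = spec, window = window,
                 per_cohort = per, summary = summ),
            class = "dcis_od_estimate")
}

#' @export
print.dcis_od_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<dcis_od_estimate> %s, ages %d-%d\n",
              x$definition$label, x$window[1], x$window[2]))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Overdiagnosis under every definition and perspective
#'
#' Computes all nine cells of the definition grid (A/B/C numerators x
#' INDIVIDUAL/POPULATION/LIFETIME perspectives) from the same paired run,
#' plus, per perspective, the labelled variant that uses the B numerator
#' (screen- and clinically detected DCIS only) over the A denominator
#' (all diagnosed DCIS including progression to IBC).
#'
#' @param paired a `dcis_paired`.
#' @param include_variants include the B-numerator/A-denominator variant
#'   rows (default `TRUE`).
#' @param by_grade include per-grade rows (default `FALSE`: totals only).
#' @return Tidy data frame: `definition`, `perspective`, `grade`, `number`
#'   (+ min/max), `rate` (+ min/max), `proportion` (+ min/max), means over
#'   cohorts.
#' @export
definition_grid <- function(paired, include_variants = TRUE,
                            by_grade = FALSE) {
  cells <- expand.grid(letter = c("A", "B", "C"),
                       perspective = .PERSPECTIVES,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    spec <- definition_spec(definition_modes(cells$letter[i]),
                            perspective = cells$perspective[i])
    grid_row(paired, spec, cells$letter[i], cells$perspective[i], by_grade)
  })
  if (include_variants) {
    rows <- c(rows, lapply(.PERSPECTIVES, function(p) {
      spec <- definition_spec(definition_modes("B"),
                              denominator = definition_modes("A"),
                              perspective = p,
                              label = paste0("B/A-", p))
      grid_row(paired, spec, "B/A", p, by_grade)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

grid_row <- function(paired, spec, letter, perspective, by_grade) {
  est <- estimate_overdiagnosis(paired, spec)
  s <- est$summary
  if (!by_grade) s <- s[s$grade == "all", ]
  cbind(data.frame(definition = letter, perspective = perspective,
                   stringsAsFactors = FALSE), s)
}
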