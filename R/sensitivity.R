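#' Univariate (tornado) sensitivity analysis
#'
#' Re-estimates the overdiagnosed proportion with each parameter moved to
#' the lower and upper bound of its interval in turn, all other parameters
#' held at their point values and the same run seed reused throughout
#' (common random numbers), so bar widths reflect parameter uncertainty
#' only. Schedule parameters are perturbed by their multiplicative factor
#' bounds. Results come back in tornado order (widest bar first).
#'
#' @param cal a valid `dcis_calibration`; every swept parameter must have
#'   a row in `cal$intervals`.
#' @param policy a `dcis_policy`.
#' @param spec a `dcis_definition` (default: [base_definition()]).
#' @param n,n_cohorts,seed simulation settings passed to
#'   [simulate_paired()].
#' @param parameters which parameters to sweep (default: all with
#'   intervals).
#' @return `dcis_tornado`: data frame with `parameter`, `low`, `high`
#'   (bound values), `proportion_low`, `proportion_high`, `width`, plus
#'   attribute `base` (the base-run proportion).
#' @export
univariate_sensitivity <- function(cal, policy = screening_policy(),
                                   spec = base_definition(),
                                   n = 100000L, n_cohorts = 1L, seed = 1L,
                                   parameters = NULL) {
  stop_if_invalid(cal)
  iv <- cal$intervals
  parameters <- parameters %||% iv$parameter
  missing_iv <- setdiff(parameters, iv$parameter)
  if (length(missing_iv))
    stop("no interval defined for parameter(s): ",
         paste(missing_iv, collapse = ", "))
  prop_of <- function(c2) {
    est <- estimate_overdiagnosis(
      simulate_paired(c2, policy, n = n, n_cohorts = n_cohorts, seed = seed),
      spec)
    est$summary$proportion[est$summary$grade == "all"]
  }
  base <- prop_of(cal)
  rows <- lapply(parameters, function(p) {
    row <- iv[iv$parameter == p, ]
    data.frame(parameter = p, low = row$low, high = row$high,
               proportion_low = prop_of(apply_parameter(cal, p, row$low)),
               proportion_high = prop_of(apply_parameter(cal, p, row$high)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$proportion_high - out$proportion_low)
  out <- out[order(-out$width, out$parameter), ]
  rownames(out) <- NULL
  attr(out, "base") <- base
  class(out) <- c("dcis_tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Repeats the paired simulation `n_runs` times (default 100), each run
#' drawing every parameter independently and uniformly within its
#' interval, then pairing a screened and an identically parameterised
#' unscreened cohort. Each run's cohort seed is a distinct sub-seed of
#' `seed` so parameter and sampling noise are both represented;
#' `use_base_seed = TRUE` pins every run to the base cohort seed, which
#' with zero-width intervals reproduces the base estimate run for run.
#'
#' @inheritParams univariate_sensitivity
#' @param n_runs number of Monte-Carlo parameter draws (default 100).
#' @param use_base_seed reuse the base cohort seed in every run.
#' @return `dcis_psa`: list with `runs` (one row per run: sampled
#'   parameter values and resulting proportion), `min`, `max`,
#'   `variation = max - min`.
#' @export
probabilistic_sensitivity <- function(cal, policy = screening_policy(),
                                      spec = base_definition(),
                                      n_runs = 100L, n = 100000L,
                                      n_cohorts = 1L, seed = 1L,
                                      use_base_seed = FALSE) {
  stop_if_invalid(cal)
  iv <- cal$intervals
  if (is.null(iv) || nrow(iv) == 0L)
    stop("no parameter intervals defined in the calibration")
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(run) {
    set.seed(mix_seed(seed, .STREAM_PSA_PAR, run))
    u <- runif(nrow(iv))
    vals <- iv$low + u * (iv$high - iv$low)
    if (any(vals < iv$low - 1e-12 | vals > iv$high + 1e-12))
      stop("internal error: PSA draw outside its interval")
    c2 <- cal
    for (j in seq_len(nrow(iv)))
      c2 <- apply_parameter(c2, iv$parameter[j], vals[j])
    run_seed <- if (use_base_seed) seed else
      mix_seed(seed, .STREAM_PSA_RUN, run)
    est <- estimate_overdiagnosis(
      simulate_paired(c2, policy, n = n, n_cohorts = n_cohorts,
                      seed = run_seed), spec)
    prop <- est$summary$proportion[est$summary$grade == "all"]
    as.data.frame(c(list(run = run),
                    setNames(as.list(vals), iv$parameter),
                    list(proportion = prop)),
                  stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, runs)
  structure(list(runs = runs,
                 min = min(runs$proportion), max = max(runs$proportion),
                 variation = max(runs$proportion) - min(runs$proportion),
                 seed = seed),
            class = "dcis_psa")
}

#' @export
print.dcis_psa <- function(x, ...) {
  cat(sprintf("<dcis_psa> %d runs: proportion in [%.4f, %.4f], variation %.4f\n",
              nrow(x$runs), x$min, x$max, x$variation))
  invisible(x)
}

#' Tornado plot of the univariate sensitivity analysis
#'
#' @param tornado a `dcis_tornado` from [univariate_sensitivity()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- as.data.frame(tornado)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = proportion_low, xend = proportion_high, yend = parameter),
      linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(tornado, "base"),
                        linetype = "dashed") +
    ggplot2::labs(x = "proportion of DCIS overdiagnosed", y = NULL)
}

#' Strip plot of the probabilistic sensitivity analysis
#'
#' @param psa a `dcis_psa` from [probabilistic_sensitivity()].
#' @return A ggplot object.
#' @export
plot_psa <- function(psa) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(psa$runs, ggplot2::aes(x = proportion)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "proportion of DCIS overdiagnosed", y = "runs")
}
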