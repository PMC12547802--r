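test_that("definition specs validate modes and perspectives", {
  expect_error(definition_spec(numerator = c("CLINICAL")), "SCREEN")
  expect_error(definition_spec(numerator = c("SCREEN", "CLINICAL"),
                               denominator = "SCREEN"),
               "denominator")
  expect_warning(spec <- definition_spec(perspective = 2), "ambiguous")
  expect_identical(spec$perspective, "POPULATION")
  expect_identical(base_definition()$label, "A-POPULATION")
})

test_that("diagnosis counting respects modes, window, and grade sums", {
  p <- fixture_paired()
  expect_identical(
    count_diagnoses(p$unscreened, "SCREEN", c(0, 60)), 0L)
  expect_identical(
    count_diagnoses(p$unscreened, c("CLINICAL", "IBC_PROGRESSION"),
                    c(0, 60)), 2L)
  by_g <- count_diagnoses(p$screened, c("SCREEN", "CLINICAL",
                                        "IBC_PROGRESSION"), c(0, 60),
                          by_grade = TRUE)
  expect_identical(sum(by_g), 3L)
  expect_identical(unname(by_g), c(1L, 1L, 1L))
  # a single-age window equals the per-age count at that age
  expect_identical(count_diagnoses(p$screened, "SCREEN", c(50, 50)), 1L)
  expect_identical(count_diagnoses(p$screened, "SCREEN", c(51, 60)), 0L)
  expect_error(count_diagnoses(p$screened, character(0), c(0, 60)),
               "non-empty")
})

test_that("rate arithmetic matches the published convention", {
  expect_equal(overdiagnosis_rate(0, 1000), 0)
  expect_equal(overdiagnosis_rate(2, 50000), 4.0)
  # 340 excess DCIS among 892,388 screened women -> 38.1 per 100,000
  expect_equal(round(overdiagnosis_rate(340, 892388), 1), 38.1)
  expect_warning(r <- overdiagnosis_rate(3, 0), "undefined")
  expect_true(is.na(r))
})

test_that("fixture overdiagnosis under the base definition is 1 of 3", {
  est <- estimate_overdiagnosis(fixture_paired())
  all_row <- est$summary[est$summary$grade == "all", ]
  expect_equal(all_row$number, 1)
  expect_equal(all_row$proportion, 1 / 3)
  expect_equal(all_row$rate, 1e5)              # one screened woman
  # grade decomposition: the excess case is the grade-1 interception
  expect_equal(est$summary$number[est$summary$grade == "1"], 1)
  expect_equal(est$summary$number[est$summary$grade == "2"], 0)
  expect_equal(est$summary$number[est$summary$grade == "3"], 0)
})

test_that("all nine fixture grid cells match hand enumeration", {
  grid <- definition_grid(fixture_paired())
  for (p in c("INDIVIDUAL", "POPULATION", "LIFETIME")) {
    row <- function(d) grid[grid$definition == d & grid$perspective == p, ]
    expect_equal(row("A")$number, 1)
    expect_equal(row("A")$proportion, 1 / 3)
    expect_equal(row("B")$number, 1)
    expect_equal(row("B")$proportion, 1 / 2)
    expect_equal(row("C")$number, 1)
    expect_equal(row("C")$proportion, 1)
    expect_equal(row("B/A")$number, 1)
    expect_equal(row("B/A")$proportion, 1 / 3)
  }
})

test_that("published-scale inputs reproduce the published point estimates", {
  # screened-arm diagnoses 1,700 vs 1,360 in the unscreened arm inside the
  # population window give 340 excess cases and a proportion of 0.20
  n <- 100000L
  scr_rec <- data.frame(
    cohort = 1L, id = 1:n,
    mode = c(rep("SCREEN", 1500L), rep("CLINICAL", 120L),
             rep("IBC_PROGRESSION", 80L), rep("NONE", n - 1700L)),
    age = c(rep(60L, 1700L), rep(NA, n - 1700L)),
    grade = c(rep(2L, 1700L), rep(NA, n - 1700L)))
  uns_rec <- data.frame(
    cohort = 1L, id = 1:n,
    mode = c(rep("CLINICAL", 900L), rep("IBC_PROGRESSION", 460L),
             rep("NONE", n - 1360L)),
    age = c(rep(60L, 1360L), rep(NA, n - 1360L)),
    grade = c(rep(2L, 1360L), rep(NA, n - 1360L)))
  paired <- paired_result(
    arm_result(scr_rec, n, n_screened = 89239L, arm = "screened"),
    arm_result(uns_rec, n, n_screened = 0L, arm = "unscreened"),
    policy = screening_policy(), max_age = 100L)
  est <- estimate_overdiagnosis(paired)
  all_row <- est$summary[est$summary$grade == "all", ]
  expect_equal(all_row$number, 340)
  expect_equal(all_row$proportion, 0.20)
  expect_equal(round(all_row$rate, 1), 381.0)  # 340 per 89,239 screened
})

test_that("grid orderings and perspective identities hold on simulated runs", {
  p <- simulate_paired(generate_synthetic_calibration(3),
                       screening_policy(), n = 20000, n_cohorts = 2,
                       seed = 3)
  grid <- definition_grid(p, include_variants = FALSE)
  for (persp in c("INDIVIDUAL", "POPULATION", "LIFETIME")) {
    g <- grid[grid$perspective == persp, ]
    expect_lte(g$proportion[g$definition == "A"],
               g$proportion[g$definition == "B"])
    expect_lte(g$proportion[g$definition == "B"],
               g$proportion[g$definition == "C"])
  }
  for (d in c("A", "B", "C")) {
    g <- grid[grid$definition == d, ]
    expect_equal(g$number[g$perspective == "POPULATION"],
                 g$number[g$perspective == "LIFETIME"])
    expect_lte(g$proportion[g$perspective == "LIFETIME"],
               g$proportion[g$perspective == "POPULATION"])
  }
})

test_that("per-grade numbers sum to the overall number in every grid cell", {
  p <- simulate_paired(toy_cal(1), toy_policy(), n = 10000, n_cohorts = 2,
                       seed = 5)
  grid <- definition_grid(p, by_grade = TRUE)
  cells <- unique(grid[c("definition", "perspective")])
  for (i in seq_len(nrow(cells))) {
    g <- grid[grid$definition == cells$definition[i] &
                grid$perspective == cells$perspective[i], ]
    expect_equal(sum(g$number[g$grade != "all"]),
                 g$number[g$grade == "all"])
  }
})

test_that("a zero denominator yields an undefined proportion, not zero", {
  rec <- data.frame(cohort = 1L, id = 1:10, mode = "NONE",
                    age = NA_integer_, grade = NA_integer_)
  paired <- paired_result(
    arm_result(rec, 10L, n_screened = 5L, arm = "screened"),
    arm_result(rec, 10L, n_screened = 0L, arm = "unscreened"),
    policy = screening_policy(), max_age = 100L)
  est <- estimate_overdiagnosis(paired)
  expect_true(is.na(est$summary$proportion[est$summary$grade == "all"]))
})
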