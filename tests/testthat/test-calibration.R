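test_that("validation reports violations naming field and index", {
  cal <- generate_synthetic_calibration(seed = 1)
  expect_identical(validate_calibration(cal), character(0))

  bad <- cal
  bad$mortality[61] <- 1.2                      # q(60)
  v <- validate_calibration(bad)
  expect_length(v, 1L)
  expect_match(v, "mortality")
  expect_match(v, "age 60")

  bad <- cal
  bad$progression[, 1] <- bad$progression[, 3] + 0.01  # grade order flipped
  v <- validate_calibration(bad)
  expect_true(any(grepl("monotonicity", v)))

  bad <- cal
  bad$onset[40, ] <- c(0.5, 0.4, 0.3)           # grade sum > 1
  expect_true(any(grepl("exceeds 1", validate_calibration(bad))))

  bad <- cal
  bad$scalars$participation <- -0.1
  expect_true(any(grepl("participation", validate_calibration(bad))))
})

test_that("synthetic generator embeds the default scalar parameters", {
  cal <- generate_synthetic_calibration(seed = 1)
  expect_equal(cal$scalars$regression, 0.05)
  expect_equal(cal$scalars$screen_sensitivity, 0.86)
  expect_equal(cal$scalars$clinical_detection, 0.05)
  expect_equal(cal$scalars$participation, 0.76)
})

test_that("synthetic generator is deterministic and seed-sensitive", {
  expect_identical(generate_synthetic_calibration(1),
                   generate_synthetic_calibration(1))
  a <- generate_synthetic_calibration(1)
  b <- generate_synthetic_calibration(2)
  expect_false(identical(a$onset, b$onset))
})

test_that("synthetic onset is unimodal, peaks in 55-70, zero before 25", {
  for (seed in c(1, 5, 23)) {
    cal <- generate_synthetic_calibration(seed)
    h <- rowSums(cal$onset)
    expect_true(all(h[1:25] == 0))
    peak <- which.max(h) - 1L
    expect_gte(peak, 55); expect_lte(peak, 70)
    expect_true(all(diff(h[26:(peak + 1L)]) >= 0))        # rising flank
    expect_true(all(diff(h[(peak + 1L):101]) <= 0))       # falling flank
  }
})

test_that("every generated calibration is valid, over many seeds", {
  for (seed in 0:119)
    expect_identical(validate_calibration(
      generate_synthetic_calibration(seed)), character(0))
})

test_that("generator overrides are applied and unknown names rejected", {
  cal <- generate_synthetic_calibration(1, overrides = list(
    regression = 0.1, onset_peak_age = 57))
  expect_equal(cal$scalars$regression, 0.1)
  expect_equal(which.max(rowSums(cal$onset)) - 1L, 57L)
  expect_error(generate_synthetic_calibration(1,
                                              overrides = list(bogus = 1)),
               "bogus")
})

test_that("calibration round-trips through disk bit-exactly", {
  cal <- generate_synthetic_calibration(seed = 7)
  path <- file.path(tempdir(), "cal.csv")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_identical(back$mortality, cal$mortality)
  expect_identical(back$onset, cal$onset)
  expect_identical(back$progression, cal$progression)
  expect_identical(back$scalars, cal$scalars)
  expect_equal(back$intervals, cal$intervals)
  expect_identical(back$label, cal$label)
})

test_that("reader rejects malformed tables, naming the defect", {
  cal <- toy_cal(1)
  path <- file.path(tempdir(), "cal2.csv")
  write_calibration(cal, path)

  tab <- read.csv(path, colClasses = "character")
  drop_g3 <- tab[!(tab$parameter == "onset" & tab$grade == "3"), ]
  p2 <- file.path(tempdir(), "cal3.csv")
  write.csv(drop_g3, p2, row.names = FALSE, quote = FALSE)
  file.copy(overdcis:::calibration_header_path(path),
            overdcis:::calibration_header_path(p2), overwrite = TRUE)
  expect_error(read_calibration(p2), "onset grade 3")

  gap <- tab[!(tab$parameter == "mortality" & tab$age == "5"), ]
  write.csv(gap, p2, row.names = FALSE, quote = FALSE)
  expect_error(read_calibration(p2), "age gap in mortality.*5")

  bad <- tab
  bad$value[3] <- "oops"
  write.csv(bad, p2, row.names = FALSE, quote = FALSE)
  expect_error(read_calibration(p2), "non-numeric.*row 3")
})

test_that("apply_parameter replaces scalars and scales schedules", {
  cal <- toy_cal(1)
  expect_equal(apply_parameter(cal, "regression", 0.15)$scalars$regression,
               0.15)
  up <- apply_parameter(cal, "progression", 1.2)
  expect_equal(up$progression, pmin(cal$progression * 1.2, 1))
  dn <- apply_parameter(cal, "mortality", 0.8)
  expect_equal(dn$mortality[9], 1)   # horizon stays absorbing
  expect_error(apply_parameter(cal, "nonexistent", 1), "nonexistent")
})
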