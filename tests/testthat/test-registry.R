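test_that("registry round-trips through delimited text", {
  reg <- make_registry(3)
  pf <- tempfile(fileext = ".csv")
  jf <- tempfile(fileext = ".csv")
  write_registry(reg, pf, injuries_path = jf)
  back <- read_registry(pf, injuries_path = jf)
  for (col in names(reg$patients)) {
    if (is.numeric(reg$patients[[col]])) {
      expect_equal(back$patients[[col]], reg$patients[[col]],
                   tolerance = 1e-9, info = col)
    } else {
      expect_equal(back$patients[[col]], reg$patients[[col]], info = col)
    }
  }
  expect_equal(back$injuries, reg$injuries)

  # packed-injury dialect round-trips too
  pf2 <- tempfile(fileext = ".csv")
  write_registry(reg, pf2)
  back2 <- read_registry(pf2)
  expect_equal(back2$injuries[order(back2$injuries$patient_id), ],
               reg$injuries[order(reg$injuries$patient_id), ],
               ignore_attr = TRUE)
})

test_that("not-measurable SpO2 is kept distinct from missing", {
  p <- make_patients(3)
  p$spo2_pct[1] <- NA; p$spo2_nm[1] <- TRUE     # not measurable
  p$spo2_pct[2] <- NA                            # truly missing
  reg <- trauma_registry(p, NULL)
  pf <- tempfile(fileext = ".csv")
  write_registry(reg, pf)
  txt <- readLines(pf)
  expect_true(any(grepl("NM", txt)))
  back <- read_registry(pf)
  expect_true(back$patients$spo2_nm[1])
  expect_false(back$patients$spo2_nm[2])
  expect_true(is.na(back$patients$spo2_pct[2]))
})

test_that("invalid rows and schemas are rejected with clear errors", {
  p <- make_patients(2)
  p$age_years[2] <- -3
  expect_error(trauma_registry(p), class = "ntriss_validation_error")
  p2 <- make_patients(2)
  p2$bmr[1] <- 6; p2$gcs_total[1] <- 7  # no valid GCS decomposition
  expect_error(trauma_registry(p2), class = "ntriss_validation_error")
  # missing required column
  f <- tempfile(fileext = ".csv")
  writeLines(c("name,age_years", "x,30"), f)
  expect_error(read_registry(f), class = "ntriss_schema_error")
  # column remapping through a schema
  writeLines(c("id,idade", "p1,30"), f)
  back <- read_registry(f, schema = c(patient_id = "id", age_years = "idade"))
  expect_equal(back$patients$age_years, 30)
  # empty file: empty registry with a warning
  writeLines("patient_id,age_years", f)
  expect_warning(empty <- read_registry(f), "no data rows")
  expect_equal(nrow(empty$patients), 0L)
})

test_that("eligibility filters count each exclusion once, in rule order", {
  p <- make_patients(5)
  p$age_years <- c(13, 14, 40, 70, 25)
  reg <- trauma_registry(p, NULL)
  res <- apply_eligibility(reg)
  expect_equal(res$report$n_excluded_age, 1L)
  expect_equal(res$report$n_retained, 4L)

  # a record failing several rules is counted under the first failing rule
  p$age_years[2] <- 10
  p$transferred[2] <- TRUE
  p$mechanism[3] <- "unknown"
  p$hours_from_event[4] <- 30
  reg <- trauma_registry(p, NULL)
  res <- apply_eligibility(reg)
  expect_equal(res$report$n_excluded_age, 2L)
  expect_equal(res$report$n_excluded_late, 1L)
  expect_equal(res$report$n_excluded_transfer, 0L)
  expect_equal(res$report$n_excluded_mechanism, 1L)
  expect_equal(res$report$n_retained, 1L)

  # empty input
  res0 <- apply_eligibility(trauma_registry(make_patients(0), NULL))
  expect_equal(res0$report$n_input, 0L)
  expect_equal(res0$report$n_retained, 0L)
})

test_that("missing hours_from_event is eligible by default, strict flag flips", {
  p <- make_patients(2)
  p$hours_from_event[1] <- NA
  reg <- trauma_registry(p, NULL)
  expect_equal(apply_eligibility(reg)$report$n_retained, 2L)
  expect_equal(apply_eligibility(reg, strict_hours = TRUE)$report$n_retained,
               1L)
})

test_that("eligibility counts reconcile on random record batches", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(1:60, 1)
    p <- make_patients(n)
    p$patient_id <- paste0("R", seq_len(n))
    p$age_years <- sample(c(NA, 5:90), n, replace = TRUE)
    p$hours_from_event <- sample(c(NA, 1, 50), n, replace = TRUE)
    p$transferred <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    p$mechanism <- sample(c("blunt", "penetrating", "unknown", NA), n,
                          replace = TRUE)
    rep_out <- apply_eligibility(trauma_registry(p, NULL))$report
    expect_equal(rep_out$n_retained + rep_out$n_excluded_age +
                   rep_out$n_excluded_late + rep_out$n_excluded_transfer +
                   rep_out$n_excluded_mechanism,
                 rep_out$n_input)
  }
})

test_that("missing-data policies resolve SpO2 as declared", {
  p <- make_patients(4)
  p$spo2_pct <- c(97, NA, NA, 0)
  p$spo2_nm <- c(FALSE, TRUE, FALSE, FALSE)
  reg <- trauma_registry(p, NULL)

  default <- resolve_missing(reg)
  expect_equal(default$spo2_code, c(4L, 0L, NA, 0L))
  expect_equal(default$spo2_flag,
               c("measured", "not_measurable", "missing", "measured"))
  expect_false(any(default$excluded_complete_case))

  zero <- resolve_missing(reg, policy = "spo2_zero_always")
  expect_equal(zero$spo2_code, c(4L, 0L, 0L, 0L))
  expect_equal(zero$spo2_flag[3], "missing_zeroed")

  cc <- resolve_missing(reg, policy = "complete_case")
  expect_equal(cc$excluded_complete_case, c(FALSE, FALSE, TRUE, FALSE))

  expect_error(resolve_missing(reg, policy = "impute"),
               class = "ntriss_config_error")
})

test_that("resolve_missing never invents a numeric SpO2", {
  set.seed(31)
  n <- 200
  p <- make_patients(n)
  p$patient_id <- paste0("S", seq_len(n))
  p$spo2_pct <- sample(c(NA, 0, 45, 85, 93, 99), n, replace = TRUE)
  p$spo2_nm <- is.na(p$spo2_pct) & runif(n) < 0.3
  reg <- trauma_registry(p, NULL)
  for (pol in c("spo2_zero_if_unmeasurable", "spo2_zero_always")) {
    out <- resolve_missing(reg, policy = pol)
    zero <- !is.na(out$spo2_code) & out$spo2_code == 0L
    legit <- p$spo2_nm | (!is.na(p$spo2_pct) & p$spo2_pct == 0) |
      (pol == "spo2_zero_always" & is.na(p$spo2_pct))
    expect_true(all(!zero | legit))
  }
})
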