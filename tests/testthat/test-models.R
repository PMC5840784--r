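test_that("linear predictor reproduces hand-evaluated dot products", {
  lib <- default_coefficients()
  # all-zero covariates return the intercept exactly
  expect_identical(
    linear_predictor(lib[["adjusted_triss.blunt"]],
                     list(rts = 0, iss = 0, age = 0)),
    -1.64790049)
  # hand-evaluated against the packaged blunt set
  expect_equal(
    linear_predictor(lib[["ntriss_like.blunt"]],
                     list(bmr = 6, sbp = 4, niss = 1, age = 0)),
    5.54935803, tolerance = 1e-12)
  # all slopes zero leaves only the intercept
  cs <- coefficient_set("ntriss_like", "blunt", 2.5, rep(0, 4))
  expect_identical(
    linear_predictor(cs, list(bmr = 3, sbp = 2, niss = 40, age = 1)), 2.5)
  expect_error(
    linear_predictor(lib[["ntriss_like.blunt"]],
                     list(bmr = 6, sbp = 4, age = 0)),
    "niss", class = "ntriss_model_input_error")
})

test_that("survival probability is a stable, strictly increasing logistic", {
  expect_identical(survival_probability(0), 0.5)
  # frozen from a high-precision independent evaluation
  expect_equal(survival_probability(-1.64790049), 0.161392906281518,
               tolerance = 1e-12)
  b <- seq(-700, 700, length.out = 4001)
  ps <- survival_probability(b)
  expect_true(all(diff(ps) >= 0))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(ps[abs(b) < 30] > 0 & ps[abs(b) < 30] < 1))
  expect_error(survival_probability(NaN), class = "ntriss_computation_error")
  # truncated-base replication mode differs by less than 2e-7
  grid <- seq(-10, 10, by = 0.05)
  expect_lt(max(abs(survival_probability(grid) -
                      survival_probability(grid, e_mode = "printed"))), 2e-7)
})

test_that("logistic of the linear predictor matches a direct oracle", {
  lib <- default_coefficients()
  set.seed(41)
  for (i in 1:200) {
    cs <- lib[[sample(length(lib), 1)]]
    x <- as.list(stats::setNames(round(runif(length(cs$covariates), 0, 8)),
                                 cs$covariates))
    b <- linear_predictor(cs, x)
    direct <- cs$intercept + sum(cs$slopes * unlist(x[cs$covariates]))
    expect_equal(b, direct, tolerance = 1e-15)
    expect_equal(survival_probability(b), 1 / (1 + exp(-b)),
                 tolerance = 1e-12)
  }
})

test_that("the packaged library passes sign and arity validation", {
  lib <- default_coefficients()
  expect_length(lib, 8)
  expect_s3_class(lib[["triss_spo2.penetrating"]], "coefficient_set")
  expect_identical(lib[["triss_spo2.penetrating"]]$slopes[["age"]],
                   -4.0353761)
  expect_error(coefficient_set("ntriss_like", "blunt", 0, c(1, 2)),
               class = "ntriss_schema_error")
  expect_error(coefficient_set("ntriss_like", "sharp", 0, rep(0, 4)),
               class = "ntriss_schema_error")
})

test_that("coefficient libraries round-trip through JSON", {
  lib <- default_coefficients()
  path <- tempfile(fileext = ".json")
  write_coefficients(lib, path)
  back <- load_coefficients(path)
  expect_equal(names(back), names(lib))
  for (key in names(lib)) {
    expect_identical(back[[key]]$intercept, lib[[key]]$intercept)
    expect_identical(back[[key]]$slopes, lib[[key]]$slopes)
  }
})

test_that("packaged models are monotone in each covariate", {
  lib <- default_coefficients()
  for (key in names(lib)) {
    cs <- lib[[key]]
    base <- stats::setNames(as.list(c(rts = 5, gcs = 3, sbp = 3, bmr = 4,
                                      spo2 = 3, iss = 16, niss = 16,
                                      age = 0)[cs$covariates]),
                            cs$covariates)
    ps0 <- survival_probability(linear_predictor(cs, base))
    for (cov in cs$covariates) {
      up <- base
      up[[cov]] <- up[[cov]] + 1
      ps1 <- survival_probability(linear_predictor(cs, up))
      if (cov %in% c("iss", "niss", "age")) {
        expect_lt(ps1, ps0)
      } else {
        expect_gt(ps1, ps0)
      }
    }
  }
})

test_that("scoring selects the mechanism-matched set and audits covariates", {
  p <- make_patients(2)
  p$mechanism <- c("blunt", "penetrating")
  p$age_years <- c(30, 30)
  p$sbp_mmhg <- c(120, 120)
  p$spo2_pct <- c(99, 99)
  reg <- trauma_registry(p, NULL)
  for (m in names(model_definitions())) {
    sc <- score_registry(reg, m)
    expect_true(all(is.na(sc$refusal)))
    expect_true(all(sc$ps > 0.97))  # healthy young uninjured
    # identical covariates, different mechanism set, different ps
    expect_false(sc$ps[1] == sc$ps[2])
  }
})

test_that("scoring refuses records it cannot code, naming the reason", {
  p <- make_patients(3)
  p$mechanism[1] <- "unknown"
  p$sbp_mmhg[2] <- NA
  reg <- trauma_registry(p, NULL)
  sc <- score_registry(reg, "adjusted_triss")
  expect_match(sc$refusal[1], "mechanism")
  expect_match(sc$refusal[2], "rts")
  expect_true(is.na(sc$refusal[3]))
  # SBP enters every model, directly or through RTS
  for (m in names(model_definitions())) {
    expect_false(is.na(score_registry(reg, m)$refusal[2]))
  }
  # unscoreable ISS refuses anatomical models
  inj <- data.frame(patient_id = "T3", body_region = "chest",
                    ais_severity = 9L)
  reg2 <- trauma_registry(make_patients(3), inj)
  expect_match(score_registry(reg2, "triss_spo2")$refusal[3], "ISS")
  expect_no_error(
    score_record(make_patients(1)[1, ], inj[0, ], model_id = "triss_spo2",
                 coefficients = default_coefficients()))
})

test_that("RTS scale switch changes the adjusted TRISS prediction only", {
  reg <- make_registry(2)
  w <- score_registry(reg, "adjusted_triss", rts_scale = "weighted")
  t <- score_registry(reg, "adjusted_triss", rts_scale = "trts")
  expect_false(any(w$b == t$b))
  expect_equal(w$x_rts, rep(7.8408, 2))
  expect_equal(t$x_rts, rep(12, 2))
  nw <- score_registry(reg, "ntriss_like", rts_scale = "weighted")
  nt <- score_registry(reg, "ntriss_like", rts_scale = "trts")
  expect_equal(nw$ps, nt$ps)
})

test_that("MTOS comparator sets are labelled as external and validate", {
  for (rev in c("1995", "1987")) {
    lib <- mtos_coefficients(rev)
    expect_length(lib, 2)
    expect_match(lib[["adjusted_triss.blunt"]]$provenance, "external")
    # age flip lowers survival for both mechanisms
    for (key in names(lib)) {
      cs <- lib[[key]]
      young <- linear_predictor(cs, list(rts = 7.8408, iss = 9, age = 0))
      old <- linear_predictor(cs, list(rts = 7.8408, iss = 9, age = 1))
      expect_lt(old, young)
    }
  }
})
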