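make_two_site_registry <- function(n_a, n_b, seed = 5) {
  n <- n_a + n_b
  p <- make_patients(n)
  p$patient_id <- paste0("D", seq_len(n))
  p$site <- c(rep("SPBRA", n_a), rep("SDEUA", n_b))
  trauma_registry(p, NULL)
}

test_that("test/derived split reproduces the published cohort arithmetic", {
  reg <- make_two_site_registry(2416, 8172)
  sp <- split_test_derived(reg, n_test_per_site = 300, seed = 9)
  expect_equal(nrow(sp$test$patients), 600L)
  derived_by_site <- table(sp$derived$patients$site)
  expect_equal(unname(derived_by_site[["SPBRA"]]), 2116L)
  expect_equal(unname(derived_by_site[["SDEUA"]]), 7872L)
})

test_that("the split is a reproducible, disjoint, exhaustive partition", {
  reg <- make_two_site_registry(400, 500)
  a <- split_test_derived(reg, n_test_per_site = 100, seed = 3)
  b <- split_test_derived(reg, n_test_per_site = 100, seed = 3)
  expect_identical(a$test$patients$patient_id, b$test$patients$patient_id)
  ids_test <- a$test$patients$patient_id
  ids_der <- a$derived$patients$patient_id
  expect_length(intersect(ids_test, ids_der), 0)
  expect_setequal(c(ids_test, ids_der), reg$patients$patient_id)
  # n = 0: everything derived
  z <- split_test_derived(reg, n_test_per_site = 0, seed = 3)
  expect_equal(nrow(z$test$patients), 0L)
  expect_equal(nrow(z$derived$patients), nrow(reg$patients))
  # too-small site errors, naming the site
  expect_error(split_test_derived(reg, n_test_per_site = 450, seed = 3),
               "SPBRA", class = "ntriss_validation_error")
})

test_that("site weights balance the minority site", {
  reg <- make_two_site_registry(2116, 7872)
  w_pub <- site_weights(reg, mode = "published")
  expect_equal(unique(w_pub[reg$patients$site == "SPBRA"]), 3.72)
  expect_equal(unique(w_pub[reg$patients$site == "SDEUA"]), 1)
  w_ex <- site_weights(reg, mode = "exact")
  expect_equal(unique(w_ex[reg$patients$site == "SPBRA"]), 7872 / 2116)
  # equal sites: all weights one
  eq <- make_two_site_registry(50, 50)
  expect_equal(site_weights(eq), rep(1, 100))
  # one site: warn; three sites: error
  one <- make_two_site_registry(10, 0)
  expect_warning(w1 <- site_weights(one), "single site")
  expect_equal(w1, rep(1, 10))
  three <- make_two_site_registry(10, 10)
  three$patients$site[1:3] <- "OTHER"
  expect_error(site_weights(three), class = "ntriss_validation_error")
})

sim_logistic_data <- function(n, beta, seed) {
  set.seed(seed)
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n, -2, 2))
  eta <- beta[1] + X %*% beta[-1]
  y <- rbinom(n, 1, stats::plogis(eta))
  list(X = X, y = y)
}

test_that("IRLS matches the glm oracle with arbitrary positive weights", {
  d <- sim_logistic_data(2000, c(-0.5, 0.8, -1.1, 0.4), seed = 51)
  set.seed(52)
  w <- runif(2000, 0.2, 4)
  fit <- fit_weighted_logistic(d$X, d$y, weights = w)
  expect_true(fit$converged)
  ref <- suppressWarnings(
    stats::glm(d$y ~ d$X, family = stats::binomial(), weights = w))
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-7)
  refse <- sqrt(diag(suppressWarnings(stats::vcov(ref))))
  expect_equal(unname(fit$standard_errors), unname(refse), tolerance = 1e-5)
})

test_that("integer weights equal physical row replication exactly", {
  d <- sim_logistic_data(300, c(0.2, 0.6, -0.9, 0.3), seed = 53)
  set.seed(54)
  k <- sample(1:3, 300, replace = TRUE)
  fit_w <- fit_weighted_logistic(d$X, d$y, weights = k)
  idx <- rep(seq_len(300), k)
  fit_r <- fit_weighted_logistic(d$X[idx, ], d$y[idx])
  expect_equal(fit_w$coefficients, fit_r$coefficients, tolerance = 1e-8)
  expect_equal(fit_w$log_likelihood, fit_r$log_likelihood, tolerance = 1e-6)
})

test_that("parameter recovery: estimates land within 3 SE of truth", {
  beta <- c(-0.4, 0.7, -1.2, 0.5)
  d <- sim_logistic_data(50000, beta, seed = 55)
  fit <- fit_weighted_logistic(d$X, d$y)
  expect_true(fit$converged)
  z <- (fit$coefficients - beta) / fit$standard_errors
  expect_true(all(abs(z) < 3))
})

test_that("degenerate and deficient designs are diagnosed, not fitted", {
  X <- cbind(x = rnorm(50))
  expect_error(fit_weighted_logistic(X, rep(2, 50)),
               class = "ntriss_validation_error")
  fit <- fit_weighted_logistic(X, rep(1, 50))
  expect_false(fit$converged)
  expect_equal(fit$diagnostic, "separation")
  # perfectly separated continuous predictor
  xs <- c(rnorm(25, -4), rnorm(25, 4))
  ys <- c(rep(0, 25), rep(1, 25))
  fit2 <- fit_weighted_logistic(cbind(x = xs), ys)
  expect_false(fit2$converged)
  expect_equal(fit2$diagnostic, "separation")
  # collinear columns named
  X2 <- cbind(a = rnorm(80), b = 0)
  X2 <- cbind(X2, c = X2[, "a"] * 2)
  expect_error(fit_weighted_logistic(X2, rbinom(80, 1, 0.5)),
               "collinear", class = "ntriss_validation_error")
})

test_that("derive_model recovers the generating coefficients end to end", {
  pp <- sim_params()
  pp$mech_blunt_prob <- 1
  sim <- simulate_registry(20000, seed = 57, params = pp)
  expect_warning(
    res <- derive_model(sim$registry, "ntriss_like", weights_mode = "exact"),
    "below minimum")
  expect_null(res$penetrating)
  fit <- res$blunt$fit
  expect_true(fit$converged)
  truth <- default_coefficients()[["ntriss_like.blunt"]]
  tv <- c(truth$intercept, truth$slopes)
  # robust SEs are the sampling SEs of the site-weighted estimator
  z <- (fit$coefficients - tv) / fit$robust_standard_errors
  expect_true(all(abs(z) < 3))
  cs <- res$blunt$coefficient_set
  expect_s3_class(cs, "coefficient_set")
  expect_match(cs$provenance, "derived")
})

test_that("published and exact weighting agree closely at scale", {
  sim <- simulate_registry(12000, seed = 58)
  fits <- lapply(c("exact", "published"), function(m) {
    derive_model(sim$registry, "adjusted_triss", weights_mode = m)
  })
  ce <- fits[[1]]$blunt$fit$coefficients
  cp <- fits[[2]]$blunt$fit$coefficients
  expect_lt(max(abs(ce - cp)), 1e-2)
})

test_that("mechanism strata below the minimum are refused with a warning", {
  p <- make_patients(80)
  p$patient_id <- paste0("M", 1:80)
  p$mechanism <- c(rep("blunt", 70), rep("penetrating", 10))
  p$survived <- rep(c(TRUE, TRUE, TRUE, FALSE), 20)
  set.seed(59)
  p$age_years <- runif(80, 15, 90)
  p$sbp_mmhg <- runif(80, 40, 180)
  inj <- data.frame(patient_id = p$patient_id,
                    body_region = sample(iss_body_regions, 80, replace = TRUE),
                    ais_severity = sample(1:5, 80, replace = TRUE))
  reg <- trauma_registry(p, inj)
  expect_warning(res <- derive_model(reg, "adjusted_triss",
                                     weights_mode = "none"),
                 "below minimum")
  expect_null(res$penetrating)
})
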