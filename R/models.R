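#' @title TRISS-family survival probability models
#' @description The four models share the logistic form
#'   Ps = 1 / (1 + exp(-b)) with a linear predictor b whose covariates differ:
#'   adjusted TRISS uses RTS, ISS and the age indicator; NTRISS-like replaces
#'   RTS with BMR + coded SBP and ISS with NISS; the two SpO2 variants add the
#'   banded SpO2 code (and TRISS SpO2 splits RTS into coded GCS + SBP).
#'   Separate coefficient sets apply to blunt and penetrating trauma.
#' @name survival_models
NULL

#' Model definitions: covariates per model
#'
#' Ordered covariate names for each model's linear predictor. `rts` denotes
#' the RTS total on the configured scale (weighted by default, see
#' [score_registry()]); `gcs`, `sbp` are RTS component codes (0-4), `spo2`
#' the SpO2 band code (0-4), `bmr` the best motor response (1-6), `age` the
#' dichotomous indicator.
#'
#' @return named list: model_id -> character vector of covariate names.
#' @export
model_definitions <- function() {
  list(
    adjusted_triss   = c("rts", "iss", "age"),
    ntriss_like      = c("bmr", "sbp", "niss", "age"),
    triss_spo2       = c("gcs", "sbp", "spo2", "iss", "age"),
    ntriss_like_spo2 = c("bmr", "sbp", "spo2", "niss", "age")
  )
}

ntriss_model_ids <- function() names(model_definitions())

# expected slope signs for published/packaged sets (physiology protective,
# anatomy and age harmful); asserted on load of the packaged library
covariate_signs <- c(rts = 1, gcs = 1, sbp = 1, bmr = 1, spo2 = 1,
                     iss = -1, niss = -1, age = -1)

#' Construct and validate a coefficient set
#'
#' @param model_id one of `adjusted_triss`, `ntriss_like`, `triss_spo2`,
#'   `ntriss_like_spo2`.
#' @param mechanism `"blunt"` or `"penetrating"`.
#' @param intercept intercept b0.
#' @param slopes numeric vector of slopes in the model's covariate order
#'   (named or unnamed; length must match the model's arity).
#' @param provenance free-text origin label (e.g. `"published table"`,
#'   `"derived 2026-01-01"`).
#' @return object of class `coefficient_set` with fields `model_id`,
#'   `mechanism`, `intercept`, `slopes` (named), `covariates`, `provenance`.
#' @export
coefficient_set <- function(model_id, mechanism, intercept, slopes,
                            provenance = "custom") {
  defs <- model_definitions()
  if (!model_id %in% names(defs)) {
    stop_ntriss("unknown model_id: ", model_id,
                class = "ntriss_schema_error")
  }
  if (!mechanism %in% c("blunt", "penetrating")) {
    stop_ntriss("mechanism must be blunt or penetrating",
                class = "ntriss_schema_error")
  }
  covs <- defs[[model_id]]
  if (length(slopes) != length(covs)) {
    stop_ntriss(model_id, " requires ", length(covs), " slopes (",
                paste(covs, collapse = ", "), "); got ", length(slopes),
                class = "ntriss_schema_error")
  }
  if (!is.null(names(slopes)) && any(nzchar(names(slopes))) &&
      !identical(names(slopes), covs)) {
    stop_ntriss("slope names must match the model covariate order exactly: ",
                paste(covs, collapse = ", "), class = "ntriss_schema_error")
  }
  if (!is_scalar_number(intercept) || !all(is.finite(slopes))) {
    stop_ntriss("coefficients must be finite numbers",
                class = "ntriss_schema_error")
  }
  slopes <- stats::setNames(as.numeric(slopes), covs)
  structure(list(model_id = model_id, mechanism = mechanism,
                 intercept = as.numeric(intercept), slopes = slopes,
                 covariates = covs, provenance = provenance),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("coefficient_set %s / %s  [%s]\n", x$model_id, x$mechanism,
              x$provenance))
  cat(sprintf("  b0 = %.8f\n", x$intercept))
  for (i in seq_along(x$slopes)) {
    cat(sprintf("  b%d(%s) = %.8f\n", i, names(x$slopes)[i], x$slopes[i]))
  }
  invisible(x)
}

lib_key <- function(model_id, mechanism) paste(model_id, mechanism, sep = ".")

#' Load a coefficient library from JSON
#'
#' The JSON document holds `schema_version` and a `sets` array; each entry
#' carries `model_id`, `mechanism`, `intercept`, `slopes` and `provenance`.
#' Every set is validated (known model, mechanism, arity) on load.
#'
#' @param path JSON file.
#' @param check_signs assert the published sign pattern (positive
#'   physiological slopes, negative anatomical/age slopes); used for the
#'   packaged library, where a violation indicates corruption.
#' @return named list of [coefficient_set] objects keyed
#'   `"<model_id>.<mechanism>"`, class `coefficient_library`.
#' @export
load_coefficients <- function(path, check_signs = FALSE) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$sets)) {
    stop_ntriss("coefficient document lacks a 'sets' array",
                class = "ntriss_schema_error")
  }
  sets <- lapply(doc$sets, function(s) {
    coefficient_set(s$model_id, s$mechanism, s$intercept,
                    unlist(s$slopes), s$provenance %||% "unlabelled")
  })
  names(sets) <- vapply(sets, function(s) lib_key(s$model_id, s$mechanism),
                        character(1))
  if (anyDuplicated(names(sets))) {
    stop_ntriss("duplicate (model_id, mechanism) pair in coefficient file",
                class = "ntriss_schema_error")
  }
  lib <- structure(sets, class = "coefficient_library")
  if (check_signs) {
    for (s in lib) {
      expected <- covariate_signs[s$covariates]
      if (any(sign(s$slopes) != expected)) {
        stop_ntriss("slope sign pattern violated in ", s$model_id, "/",
                    s$mechanism, class = "ntriss_schema_error")
      }
    }
  }
  lib
}

#' Write a coefficient library to JSON
#'
#' @param library a `coefficient_library` (or list of [coefficient_set]).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(library, path) {
  sets <- lapply(unname(library), function(s) {
    list(model_id = s$model_id, mechanism = s$mechanism,
         intercept = s$intercept, slopes = as.list(unname(s$slopes)),
         provenance = s$provenance)
  })
  jsonlite::write_json(list(schema_version = 1, sets = sets), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The packaged published coefficient library
#'
#' Blunt and penetrating coefficient sets for all four models, as published
#' for the two-hospital derivation cohort. Loaded from the JSON document
#' shipped in `inst/extdata/coefficients.json`; slope signs are asserted on
#' load.
#'
#' @return a `coefficient_library`.
#' @export
default_coefficients <- function() {
  path <- system.file("extdata", "coefficients.json", package = "ntriss",
                      mustWork = TRUE)
  load_coefficients(path, check_signs = TRUE)
}

#' Original MTOS TRISS coefficient sets (external literature)
#'
#' The original Major Trauma Outcome Study TRISS coefficients, shipped as an
#' optional comparator. These were not derived by this package and use the
#' weighted RTS scale. Two published revisions are available.
#'
#' @param revision `"1995"` (default) or `"1987"`.
#' @return a `coefficient_library` with blunt and penetrating
#'   `adjusted_triss`-shaped sets, provenance-labelled as external literature.
#' @export
mtos_coefficients <- function(revision = c("1995", "1987")) {
  revision <- match.arg(revision)
  vals <- switch(revision,
    "1995" = list(blunt = c(-0.4499, 0.8085, -0.0835, -1.7430),
                  penetrating = c(-2.5355, 0.9934, -0.0651, -1.1360)),
    "1987" = list(blunt = c(-1.2470, 0.9544, -0.0768, -1.9052),
                  penetrating = c(-0.6029, 1.1430, -0.1516, -2.6676)))
  prov <- paste0("external literature (MTOS ", revision,
                 "); weighted RTS scale")
  sets <- lapply(names(vals), function(mech) {
    coefficient_set("adjusted_triss", mech, vals[[mech]][1],
                    vals[[mech]][-1], provenance = prov)
  })
  names(sets) <- vapply(sets, function(s) lib_key(s$model_id, s$mechanism),
                        character(1))
  structure(sets, class = "coefficient_library")
}

#' Linear predictor b
#'
#' Exact dot product b0 + sum(b_i x_i) in the model's covariate order.
#'
#' @param coefs a [coefficient_set].
#' @param covariates named list or vector of covariate values; must contain
#'   every covariate the model names, all finite.
#' @return the linear predictor b.
#' @export
linear_predictor <- function(coefs, covariates) {
  stopifnot(inherits(coefs, "coefficient_set"))
  missing_cov <- setdiff(coefs$covariates, names(covariates))
  if (length(missing_cov)) {
    stop_ntriss("missing covariate for ", coefs$model_id, ": ",
                paste(missing_cov, collapse = ", "),
                class = "ntriss_model_input_error")
  }
  x <- as.numeric(unlist(covariates[coefs$covariates]))
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- coefs$covariates[is.na(x) | !is.finite(x)]
    stop_ntriss("covariate not finite for ", coefs$model_id, ": ",
                paste(bad, collapse = ", "),
                class = "ntriss_model_input_error")
  }
  coefs$intercept + sum(coefs$slopes * x)
}

#' Survival probability from the linear predictor
#'
#' Numerically stable logistic Ps = 1 / (1 + exp(-b)); no overflow for |b| up
#' to the largest representable exponent, strictly increasing in b, never
#' exactly 0 or 1 for finite b of moderate size.
#'
#' @param b linear predictor (vectorised, finite).
#' @param e_mode `"exact"` (default) uses the true Euler constant via
#'   `plogis`; `"printed"` uses the truncated base 2.718282 carried by the
#'   published equation, for byte-level replication experiments (differs by
#'   less than 2e-7 in Ps).
#' @return probability of survival in (0, 1).
#' @export
survival_probability <- function(b, e_mode = c("exact", "printed")) {
  e_mode <- match.arg(e_mode)
  if (anyNA(b) || any(!is.finite(b))) {
    stop_ntriss("linear predictor must be finite",
                class = "ntriss_computation_error")
  }
  if (e_mode == "exact") {
    stats::plogis(b)
  } else {
    1 / (1 + 2.718282^(-b))
  }
}

#' Score one patient record
#'
#' Codes the record's covariates, selects the mechanism-matched coefficient
#' set and evaluates the model. Returns a full audit trail; refusals (unknown
#' mechanism, unscoreable ISS/NISS, missing covariates) are explicit errors.
#'
#' @param record single-row patient data frame (see [trauma_registry]).
#' @param injuries injury rows for this patient (long format).
#' @param model_id model to evaluate.
#' @param coefficients a `coefficient_library` (default: packaged published
#'   sets).
#' @param policy missing-SpO2 policy, see [resolve_missing()].
#' @param rts_scale `"weighted"` (default) or `"trts"`: which RTS total
#'   enters the adjusted TRISS equation.
#' @param e_mode see [survival_probability()].
#' @return list of class `ntriss_prediction`: `model_id`, `mechanism`, `b`,
#'   `ps`, `covariates` (named values used), `flags` (character).
#' @export
score_record <- function(record, injuries = NULL, model_id,
                         coefficients = default_coefficients(),
                         policy = "spo2_zero_if_unmeasurable",
                         rts_scale = c("weighted", "trts"),
                         e_mode = c("exact", "printed")) {
  rts_scale <- match.arg(rts_scale)
  e_mode <- match.arg(e_mode)
  if (nrow(record) != 1L) {
    stop_ntriss("score_record expects a single patient row",
                class = "ntriss_model_input_error")
  }
  if (is.null(injuries)) {
    injuries <- data.frame(patient_id = character(), body_region = character(),
                           ais_severity = integer())
  }
  reg <- trauma_registry(record, injuries)
  scored <- score_registry(reg, model_id, coefficients = coefficients,
                           policy = policy, rts_scale = rts_scale,
                           e_mode = e_mode)
  row <- scored[1, ]
  if (!is.na(row$refusal)) {
    stop_ntriss("scoring refused: ", row$refusal,
                class = "ntriss_model_input_error")
  }
  defs <- model_definitions()[[model_id]]
  structure(list(model_id = model_id, mechanism = row$mechanism,
                 b = row$b, ps = row$ps,
                 covariates = stats::setNames(
                   as.numeric(row[paste0("x_", defs)]), defs),
                 flags = strsplit(row$flags, ";")[[1]] %||% character()),
            class = "ntriss_prediction")
}

#' @export
print.ntriss_prediction <- function(x, ...) {
  cat(sprintf("%s (%s): b = %.6f, Ps = %.6f\n", x$model_id, x$mechanism,
              x$b, x$ps))
  cat("  covariates:", paste(names(x$covariates), signif(x$covariates, 6),
                             sep = "=", collapse = " "), "\n")
  if (length(x$flags) && any(nzchar(x$flags))) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score every patient in a registry
#'
#' Vectorised scoring. Records that cannot be scored under `model_id` are
#' returned with `NA` predictions and a `refusal` reason rather than dropped,
#' so callers can audit exactly which rule fired.
#'
#' @inheritParams score_record
#' @param registry a [trauma_registry]; records should already have passed
#'   [apply_eligibility()].
#' @return data frame, one row per patient: `patient_id`, `model_id`,
#'   `mechanism`, covariate columns `x_<name>`, `b`, `ps`, `flags`
#'   (semicolon-joined), `refusal` (`NA` when scored).
#' @export
score_registry <- function(registry, model_id,
                           coefficients = default_coefficients(),
                           policy = "spo2_zero_if_unmeasurable",
                           rts_scale = c("weighted", "trts"),
                           e_mode = c("exact", "printed")) {
  stopifnot(inherits(registry, "trauma_registry"))
  rts_scale <- match.arg(rts_scale)
  e_mode <- match.arg(e_mode)
  defs <- model_definitions()
  if (!model_id %in% names(defs)) {
    stop_ntriss("unknown model_id: ", model_id, class = "ntriss_schema_error")
  }
  covs <- defs[[model_id]]
  p <- registry$patients
  coded <- resolve_missing(registry, policy = policy)
  sev <- severity_scores(registry$injuries, patient_ids = p$patient_id)
  X <- data.frame(
    rts = if (rts_scale == "weighted") coded$rts_weighted
          else as.numeric(coded$trts),
    gcs = as.numeric(coded$gcs_code),
    sbp = as.numeric(coded$sbp_code),
    bmr = as.numeric(coded$bmr),
    spo2 = as.numeric(coded$spo2_code),
    iss = as.numeric(sev$iss),
    niss = as.numeric(sev$niss),
    age = as.numeric(coded$age_ind)
  )
  refusal <- rep(NA_character_, nrow(p))
  bad_mech <- is.na(p$mechanism) | !p$mechanism %in% c("blunt", "penetrating")
  refusal[bad_mech] <- "mechanism unknown"
  if (any(covs %in% c("iss", "niss"))) {
    uns <- !sev$scoreable
    refusal[is.na(refusal) & uns] <- "ISS/NISS unscoreable"
  }
  for (cov in covs) {
    miss <- is.na(X[[cov]])
    refusal[is.na(refusal) & miss] <- paste0("missing covariate: ", cov)
  }
  refusal[is.na(refusal) & coded$excluded_complete_case] <-
    "excluded by complete-case policy"
  flags <- ifelse(coded$spo2_flag == "not_measurable" & "spo2" %in% covs,
                  "spo2_coded_zero_not_measurable", "")
  flags <- paste0(flags, ifelse(
    coded$spo2_flag == "missing_zeroed" & "spo2" %in% covs,
    "spo2_zero_by_policy", ""))
  b <- ps <- rep(NA_real_, nrow(p))
  for (mech in c("blunt", "penetrating")) {
    rows <- which(is.na(refusal) & p$mechanism == mech)
    if (!length(rows)) next
    key <- lib_key(model_id, mech)
    if (is.null(coefficients[[key]])) {
      stop_ntriss("no coefficient set for ", key, class = "ntriss_schema_error")
    }
    cs <- coefficients[[key]]
    xm <- as.matrix(X[rows, cs$covariates, drop = FALSE])
    # row-wise sum (not BLAS) so results are identical regardless of batch size
    b[rows] <- cs$intercept +
      rowSums(xm * matrix(cs$slopes, nrow(xm), ncol(xm), byrow = TRUE))
    ps[rows] <- survival_probability(b[rows], e_mode = e_mode)
  }
  out <- data.frame(patient_id = p$patient_id, model_id = model_id,
                    mechanism = p$mechanism, stringsAsFactors = FALSE)
  for (cov in covs) out[[paste0("x_", cov)]] <- X[[cov]]
  out$b <- b
  out$ps <- ps
  out$flags <- flags
  out$refusal <- refusal
  out
}
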