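#' @title Trauma registry container and I/O
#' @description A trauma registry is a pair of data frames: one row per
#'   patient (demographics, admission physiology, mechanism, outcome) and a
#'   long-format injury table (one row per AIS-coded lesion). Registries are
#'   read from and written to delimited text with configurable missing /
#'   not-measurable tokens.
#' @name registry
NULL

patient_columns <- c("patient_id", "site", "age_years", "mechanism",
                     "gcs_total", "bmr", "sbp_mmhg", "rr_bpm", "spo2_pct",
                     "spo2_nm", "hours_from_event", "transferred", "survived")

#' Construct a trauma registry
#'
#' Validates and bundles a patient table and an injury table. The patient
#' table carries, per row: `patient_id`, `site`, `age_years`, `mechanism`
#' ("blunt", "penetrating" or "unknown"), `gcs_total` (3-15), `bmr` (best
#' motor response, 1-6), `sbp_mmhg`, `rr_bpm`, `spo2_pct` (0-100), `spo2_nm`
#' (logical: SpO2 recorded as "not measurable", distinct from missing),
#' `hours_from_event`, `transferred`, `survived`. Any field other than
#' `patient_id` may be `NA`.
#'
#' @param patients data frame of patient rows; missing optional columns are
#'   added as `NA`.
#' @param injuries data frame with `patient_id`, `body_region`,
#'   `ais_severity`, or `NULL` for an injury-free registry.
#' @return object of class `trauma_registry`.
#' @export
trauma_registry <- function(patients, injuries = NULL) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  if (is.null(injuries)) {
    injuries <- data.frame(patient_id = character(), body_region = character(),
                           ais_severity = integer(), stringsAsFactors = FALSE)
  }
  injuries <- as.data.frame(injuries, stringsAsFactors = FALSE)
  for (col in setdiff(patient_columns, names(patients))) {
    patients[[col]] <- rep(if (col == "spo2_nm") FALSE else NA,
                           nrow(patients))
  }
  patients <- patients[patient_columns]
  patients$patient_id <- as.character(patients$patient_id)
  patients$spo2_nm[is.na(patients$spo2_nm)] <- FALSE
  validate_patients(patients)
  if (nrow(injuries)) {
    check_ais(injuries$ais_severity)
    orphans <- !injuries$patient_id %in% patients$patient_id
    if (any(orphans)) {
      stop_ntriss("injury rows reference unknown patient_id: ",
                  paste(unique(injuries$patient_id[orphans]), collapse = ", "),
                  class = "ntriss_validation_error")
    }
  }
  structure(list(patients = patients, injuries = injuries),
            class = "trauma_registry")
}

validate_patients <- function(p) {
  fail <- function(rows, msg) {
    stop_ntriss("invalid patient record (row ",
                paste(utils::head(rows, 5), collapse = ", "), "): ", msg,
                class = "ntriss_validation_error")
  }
  if (anyNA(p$patient_id) || any(p$patient_id == "")) {
    fail(which(is.na(p$patient_id) | p$patient_id == ""),
         "patient_id is required")
  }
  if (anyDuplicated(p$patient_id)) {
    fail(which(duplicated(p$patient_id)), "duplicate patient_id")
  }
  chk <- function(bad, msg) if (any(bad, na.rm = TRUE)) fail(which(bad), msg)
  chk(p$age_years < 0, "negative age")
  chk(!p$mechanism %in% c("blunt", "penetrating", "unknown") &
        !is.na(p$mechanism), "mechanism must be blunt/penetrating/unknown")
  chk(p$gcs_total < 3 | p$gcs_total > 15, "gcs_total outside 3-15")
  chk(p$bmr < 1 | p$bmr > 6, "bmr outside 1-6")
  chk(p$sbp_mmhg < 0, "negative sbp_mmhg")
  chk(p$rr_bpm < 0, "negative rr_bpm")
  chk(p$spo2_pct < 0 | p$spo2_pct > 100, "spo2_pct outside [0, 100]")
  chk(p$hours_from_event < 0, "negative hours_from_event")
  # GCS = eye(1-4) + verbal(1-5) + motor(1-6): a valid decomposition requires
  # motor <= total - 2
  chk(!is.na(p$bmr) & !is.na(p$gcs_total) & p$bmr > p$gcs_total - 2,
      "bmr exceeds gcs_total - 2 (no valid GCS decomposition)")
  invisible(TRUE)
}

#' @export
print.trauma_registry <- function(x, ...) {
  cat("trauma_registry:", nrow(x$patients), "patients,",
      nrow(x$injuries), "injuries\n")
  mech <- table(factor(x$patients$mechanism,
                       levels = c("blunt", "penetrating", "unknown")))
  cat("  mechanism:", paste(names(mech), mech, sep = "=", collapse = " "), "\n")
  if (any(!is.na(x$patients$survived))) {
    cat(sprintf("  mortality: %.1f%% (of %d with known outcome)\n",
                100 * mean(!x$patients$survived, na.rm = TRUE),
                sum(!is.na(x$patients$survived))))
  }
  invisible(x)
}

default_na_tokens <- c("", "NA")

#' Read a trauma registry from delimited text
#'
#' The patient file must carry a header; column names are remapped through
#' `schema` (canonical name -> file column name). Injuries arrive either as a
#' companion long-format file (`patient_id`, `body_region`, `ais_severity`)
#' or packed into an `injuries` column as `"region:ais;region:ais"`.
#'
#' @param path patient table file.
#' @param injuries_path optional companion injury file.
#' @param schema named character vector remapping canonical column names to
#'   the file's column names; defaults to identity.
#' @param delim field delimiter (default comma).
#' @param na_tokens tokens read as missing (default `""`, `"NA"`).
#' @param nm_token token in the SpO2 column meaning "not measurable"
#'   (default `"NM"`); kept distinct from missing.
#' @return a [trauma_registry].
#' @export
read_registry <- function(path, injuries_path = NULL, schema = NULL,
                          delim = ",", na_tokens = default_na_tokens,
                          nm_token = "NM") {
  if (!file.exists(path)) {
    stop_ntriss("registry file not found: ", path, class = "ntriss_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) {
    warning("registry file has a header but no data rows: ", path)
    return(trauma_registry(data.frame(patient_id = character())))
  }
  pick <- function(canonical) {
    col <- if (!is.null(schema) && canonical %in% names(schema)) {
      schema[[canonical]]
    } else {
      canonical
    }
    if (!col %in% names(raw)) return(NULL)
    raw[[col]]
  }
  need <- pick("patient_id")
  if (is.null(need)) {
    stop_ntriss("required column missing from registry file: patient_id",
                class = "ntriss_schema_error")
  }
  as_na <- function(x) {
    x[x %in% na_tokens] <- NA_character_
    x
  }
  num <- function(canonical) {
    x <- as_na(pick(canonical) %||% rep(NA_character_, nrow(raw)))
    suppressWarnings(as.numeric(x))
  }
  lgl <- function(canonical) {
    x <- tolower(as_na(pick(canonical) %||% rep(NA_character_, nrow(raw))))
    out <- rep(NA, nrow(raw))
    out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
    out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
    out
  }
  spo2_raw <- as_na(pick("spo2_pct") %||% rep(NA_character_, nrow(raw)))
  spo2_nm <- !is.na(spo2_raw) & spo2_raw == nm_token
  spo2 <- suppressWarnings(as.numeric(ifelse(spo2_nm, NA, spo2_raw)))
  patients <- data.frame(
    patient_id = as.character(need),
    site = as_na(pick("site") %||% rep(NA_character_, nrow(raw))),
    age_years = num("age_years"),
    mechanism = tolower(as_na(pick("mechanism") %||%
                                rep(NA_character_, nrow(raw)))),
    gcs_total = num("gcs_total"),
    bmr = num("bmr"),
    sbp_mmhg = num("sbp_mmhg"),
    rr_bpm = num("rr_bpm"),
    spo2_pct = spo2,
    spo2_nm = spo2_nm,
    hours_from_event = num("hours_from_event"),
    transferred = lgl("transferred"),
    survived = lgl("survived"),
    stringsAsFactors = FALSE
  )
  injuries <- NULL
  if (!is.null(injuries_path)) {
    inj <- utils::read.table(injuries_path, header = TRUE, sep = delim,
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    for (col in c("patient_id", "body_region", "ais_severity")) {
      if (!col %in% names(inj)) {
        stop_ntriss("required column missing from injury file: ", col,
                    class = "ntriss_schema_error")
      }
    }
    injuries <- data.frame(patient_id = as.character(inj$patient_id),
                           body_region = as.character(inj$body_region),
                           ais_severity = as.integer(inj$ais_severity),
                           stringsAsFactors = FALSE)
  } else if (!is.null(pick("injuries"))) {
    injuries <- unpack_injuries(patients$patient_id, as_na(pick("injuries")))
  }
  trauma_registry(patients, injuries)
}

unpack_injuries <- function(patient_id, packed) {
  keep <- !is.na(packed) & nzchar(packed)
  if (!any(keep)) return(NULL)
  parts <- strsplit(packed[keep], ";", fixed = TRUE)
  n_each <- lengths(parts)
  toks <- strsplit(unlist(parts), ":", fixed = TRUE)
  if (any(lengths(toks) != 2L)) {
    stop_ntriss("malformed packed injury token (expect region:ais)",
                class = "ntriss_schema_error")
  }
  m <- do.call(rbind, toks)
  data.frame(patient_id = rep(patient_id[keep], n_each),
             body_region = m[, 1],
             ais_severity = as.integer(m[, 2]),
             stringsAsFactors = FALSE)
}

pack_injuries <- function(registry) {
  inj <- registry$injuries
  packed <- vapply(registry$patients$patient_id, function(id) {
    i <- inj$patient_id == id
    paste(inj$body_region[i], inj$ais_severity[i], sep = ":", collapse = ";")
  }, character(1))
  unname(packed)
}

#' Write a trauma registry to delimited text
#'
#' Inverse of [read_registry()]: the written files round-trip back to an
#' identical registry. When `injuries_path` is `NULL` the injury list is
#' packed into an `injuries` column (`"region:ais;..."`).
#'
#' @param registry a [trauma_registry].
#' @param path output patient file.
#' @param injuries_path optional output injury file (long format).
#' @param delim field delimiter.
#' @param nm_token token written for not-measurable SpO2.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, injuries_path = NULL,
                           delim = ",", nm_token = "NM") {
  stopifnot(inherits(registry, "trauma_registry"))
  out <- registry$patients
  out$spo2_pct <- ifelse(out$spo2_nm, nm_token, as.character(out$spo2_pct))
  out$spo2_nm <- NULL
  if (is.null(injuries_path)) {
    out$injuries <- pack_injuries(registry)
  } else {
    utils::write.table(registry$injuries, injuries_path, sep = delim,
                       row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the cohort eligibility filters
#'
#' Retains patients aged >= 14 years, admitted within 24 h of the traumatic
#' event, not transferred from another hospital, and with a known blunt or
#' penetrating mechanism. Each excluded record is counted once, under the
#' first failing rule in the fixed order age, late admission, transfer,
#' mechanism, so the report is deterministic.
#'
#' @param registry a [trauma_registry].
#' @param min_age_years minimum age (default 14).
#' @param max_hours latest admission delay in hours (default 24).
#' @param strict_hours if `FALSE` (default) records with missing
#'   `hours_from_event` are retained (registry exports rarely carry it); if
#'   `TRUE` they are excluded under the late-admission rule.
#' @return list with `registry` (filtered, injuries subset to retained
#'   patients) and `report`, an `eligibility_report` with fields `n_input`,
#'   `n_excluded_age`, `n_excluded_late`, `n_excluded_transfer`,
#'   `n_excluded_mechanism`, `n_retained`.
#' @export
apply_eligibility <- function(registry, min_age_years = 14, max_hours = 24,
                              strict_hours = FALSE) {
  stopifnot(inherits(registry, "trauma_registry"))
  p <- registry$patients
  fail_age <- is.na(p$age_years) | p$age_years < min_age_years
  fail_late <- if (strict_hours) {
    is.na(p$hours_from_event) | p$hours_from_event > max_hours
  } else {
    !is.na(p$hours_from_event) & p$hours_from_event > max_hours
  }
  fail_transfer <- !is.na(p$transferred) & p$transferred
  fail_mech <- is.na(p$mechanism) | !p$mechanism %in% c("blunt", "penetrating")
  first_rule <- rep(0L, nrow(p))
  first_rule[fail_mech] <- 4L
  first_rule[fail_transfer] <- 3L
  first_rule[fail_late] <- 2L
  first_rule[fail_age] <- 1L
  keep <- first_rule == 0L
  report <- structure(list(
    n_input = nrow(p),
    n_excluded_age = sum(first_rule == 1L),
    n_excluded_late = sum(first_rule == 2L),
    n_excluded_transfer = sum(first_rule == 3L),
    n_excluded_mechanism = sum(first_rule == 4L),
    n_retained = sum(keep)
  ), class = "eligibility_report")
  kept <- trauma_registry(
    p[keep, , drop = FALSE],
    registry$injuries[registry$injuries$patient_id %in% p$patient_id[keep], ,
                      drop = FALSE]
  )
  list(registry = kept, report = report)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("eligibility:", x$n_retained, "of", x$n_input, "retained",
      sprintf("(excluded: age %d, late %d, transfer %d, mechanism %d)\n",
              x$n_excluded_age, x$n_excluded_late, x$n_excluded_transfer,
              x$n_excluded_mechanism))
  invisible(x)
}

missing_policies <- c("spo2_zero_if_unmeasurable", "complete_case",
                      "spo2_zero_always")

#' Code admission physiology under a missing-data policy
#'
#' Produces every physiological covariate the survival models consume: RTS
#' component codes and totals, BMR, SpO2 band code and the age indicator.
#' SpO2 recorded as "not measurable" always codes to 0; truly absent SpO2 is
#' governed by `policy`:
#' \describe{
#'   \item{`spo2_zero_if_unmeasurable` (default)}{missing SpO2 leaves
#'     `spo2_code` `NA`, making the record ineligible for the two SpO2 models
#'     only.}
#'   \item{`complete_case`}{missing SpO2 flags the whole record
#'     (`excluded_complete_case`); scoring refuses it for every model.}
#'   \item{`spo2_zero_always`}{missing SpO2 is coded 0.}
#' }
#' Absent GCS/BMR or SBP always leave the corresponding codes `NA`; models
#' that require them refuse the record at scoring time.
#'
#' @param registry a [trauma_registry] (or its patient data frame).
#' @param policy one of `"spo2_zero_if_unmeasurable"`, `"complete_case"`,
#'   `"spo2_zero_always"`.
#' @return data frame, one row per patient: `patient_id`, `gcs_code`,
#'   `sbp_code`, `rr_code`, `spo2_code`, `bmr`, `age_ind`, `rts_weighted`,
#'   `trts`, `spo2_flag` (one of measured / not_measurable / missing /
#'   missing_zeroed), `excluded_complete_case`.
#' @export
resolve_missing <- function(registry, policy = "spo2_zero_if_unmeasurable") {
  if (!policy %in% missing_policies) {
    stop_ntriss("unknown missing-data policy: ", policy, " (expected one of ",
                paste(missing_policies, collapse = ", "), ")",
                class = "ntriss_config_error")
  }
  p <- if (inherits(registry, "trauma_registry")) registry$patients
       else registry
  comp <- code_rts_components(p$gcs_total, p$sbp_mmhg, p$rr_bpm)
  tot <- rts_totals(comp$gcs_code, comp$sbp_code, comp$rr_code)
  spo2_missing <- is.na(p$spo2_pct) & !p$spo2_nm
  spo2_code <- code_spo2(p$spo2_pct, p$spo2_nm)
  spo2_flag <- ifelse(p$spo2_nm, "not_measurable",
               ifelse(spo2_missing, "missing", "measured"))
  if (policy == "spo2_zero_always") {
    spo2_code[spo2_missing] <- 0L
    spo2_flag[spo2_missing] <- "missing_zeroed"
  }
  data.frame(
    patient_id = p$patient_id,
    gcs_code = comp$gcs_code,
    sbp_code = comp$sbp_code,
    rr_code = comp$rr_code,
    spo2_code = spo2_code,
    bmr = as.integer(p$bmr),
    age_ind = age_indicator(p$age_years),
    rts_weighted = tot$rts_weighted,
    trts = tot$trts,
    spo2_flag = spo2_flag,
    excluded_complete_case = policy == "complete_case" & spo2_missing,
    stringsAsFactors = FALSE
  )
}
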