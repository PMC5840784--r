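#' @title Anatomical and physiological severity coding
#' @description Functions that turn raw admission data into the coded
#'   covariates the survival models consume: ISS and NISS from an AIS injury
#'   list, the Revised Trauma Score component codes and totals, the banded
#'   peripheral oxygen saturation code, and the dichotomous age indicator.
#' @name severity
NULL

#' The six ISS body regions
#'
#' Canonical region labels used throughout the package. ISS takes the highest
#' AIS severity in each of the three most severely injured distinct regions;
#' NISS ignores regions entirely.
#'
#' @export
iss_body_regions <- c("head_neck", "face", "chest", "abdomen",
                      "extremities", "external")

# Coefficients of the weighted Revised Trauma Score (Champion et al. coding,
# frozen here; any future edit must be deliberate and test-covered).
rts_weights <- c(gcs = 0.9368, sbp = 0.7326, rr = 0.2908)

check_ais <- function(ais_severity) {
  bad <- !is.na(ais_severity) &
    !(ais_severity %in% c(1, 2, 3, 4, 5, 6, 9))
  if (any(bad)) {
    stop_ntriss("AIS severity must be 1-6 (9/NA mark unknown severity); got ",
                paste(unique(ais_severity[bad]), collapse = ", "),
                class = "ntriss_validation_error")
  }
  invisible(TRUE)
}

#' Injury Severity Score
#'
#' Sum of squares of the highest AIS severity in each of the three most
#' severely injured distinct body regions. Any AIS 6 injury sets the score to
#' the ceiling of 75. An injury of unknown severity (AIS 9 or `NA`) makes the
#' patient unscoreable and `NA` is returned.
#'
#' @param body_region character vector of region labels (see
#'   [iss_body_regions]); one entry per injury.
#' @param ais_severity integer vector of AIS severities 1-6 per injury
#'   (9 or `NA` = unknown).
#' @return Integer ISS in 0-75, or `NA` when unscoreable. Empty input gives 0.
#' @seealso [compute_niss()], [severity_scores()]
#' @examples
#' compute_iss(c("head_neck", "head_neck", "chest", "extremities"),
#'             c(4, 3, 3, 2)) # 4^2 + 3^2 + 2^2 = 29
#' @export
compute_iss <- function(body_region, ais_severity) {
  if (length(body_region) != length(ais_severity)) {
    stop_ntriss("body_region and ais_severity lengths differ",
                class = "ntriss_validation_error")
  }
  if (length(ais_severity) == 0L) return(0L)
  check_ais(ais_severity)
  bad_region <- !body_region %in% iss_body_regions
  if (any(bad_region)) {
    stop_ntriss("unknown body region: ",
                paste(unique(body_region[bad_region]), collapse = ", "),
                class = "ntriss_validation_error")
  }
  if (any(is.na(ais_severity) | ais_severity == 9)) return(NA_integer_)
  if (any(ais_severity == 6)) return(75L)
  region_max <- tapply(ais_severity, body_region, max)
  top <- sort(as.integer(region_max), decreasing = TRUE)
  top <- top[seq_len(min(3L, length(top)))]
  as.integer(sum(top^2))
}

#' New Injury Severity Score
#'
#' Sum of squares of the three highest AIS severities regardless of body
#' region. Shares the AIS-6 ceiling and unknown-severity conventions of
#' [compute_iss()], and always satisfies NISS >= ISS.
#'
#' @param ais_severity integer vector of AIS severities 1-6 per injury
#'   (9 or `NA` = unknown).
#' @return Integer NISS in 0-75, or `NA` when unscoreable.
#' @export
compute_niss <- function(ais_severity) {
  if (length(ais_severity) == 0L) return(0L)
  check_ais(ais_severity)
  if (any(is.na(ais_severity) | ais_severity == 9)) return(NA_integer_)
  if (any(ais_severity == 6)) return(75L)
  top <- sort(as.integer(ais_severity), decreasing = TRUE)
  top <- top[seq_len(min(3L, length(top)))]
  as.integer(sum(top^2))
}

#' Per-patient ISS and NISS from a long-format injury table
#'
#' @param injuries data frame with columns `patient_id`, `body_region`,
#'   `ais_severity` (one row per injury).
#' @param patient_ids optional character vector of patients to score; patients
#'   absent from `injuries` receive ISS = NISS = 0 (no recorded injuries).
#' @return data frame with columns `patient_id`, `iss`, `niss`, `scoreable`.
#' @details Vectorised over patients; agrees exactly with applying
#'   [compute_iss()] / [compute_niss()] per patient.
#' @export
severity_scores <- function(injuries, patient_ids = NULL) {
  ids <- patient_ids %||% unique(injuries$patient_id)
  n <- length(ids)
  out <- data.frame(patient_id = ids, iss = 0L, niss = 0L,
                    scoreable = TRUE, stringsAsFactors = FALSE)
  if (nrow(injuries) == 0L || n == 0L) return(out)
  check_ais(injuries$ais_severity)
  bad_region <- !injuries$body_region %in% iss_body_regions
  if (any(bad_region)) {
    stop_ntriss("unknown body region: ",
                paste(unique(injuries$body_region[bad_region]), collapse = ", "),
                class = "ntriss_validation_error")
  }
  pid <- match(injuries$patient_id, ids)
  keep <- !is.na(pid)
  pid <- pid[keep]
  sev <- as.integer(injuries$ais_severity[keep])
  region <- injuries$body_region[keep]

  unknown <- is.na(sev) | sev == 9L
  not_scoreable <- tabulate(pid[unknown], nbins = n) > 0L
  cap75 <- tabulate(pid[!unknown & sev == 6L], nbins = n) > 0L

  ok <- !unknown
  top3_sq_sum <- function(p, s) {
    # sum of squares of the three largest s within each p (1..n)
    if (!length(p)) return(integer(n))
    o <- order(p, -s)
    ps <- p[o]
    within_rank <- sequence(tabulate(ps, nbins = n))
    sel <- within_rank <= 3L
    m <- rowsum(as.numeric(s[o][sel]^2), ps[sel])
    res <- integer(n)
    res[as.integer(rownames(m))] <- as.integer(m[, 1])
    res
  }
  niss <- top3_sq_sum(pid[ok], sev[ok])
  # region maxima, then the three most severely injured regions
  grp <- interaction(pid[ok], region[ok], drop = TRUE)
  rmax <- tapply(sev[ok], grp, max)
  rpid <- as.integer(sub("\\..*$", "", names(rmax)))
  iss <- top3_sq_sum(rpid, as.integer(rmax))

  iss[cap75] <- 75L
  niss[cap75] <- 75L
  iss[not_scoreable] <- NA_integer_
  niss[not_scoreable] <- NA_integer_
  out$iss <- iss
  out$niss <- niss
  out$scoreable <- !not_scoreable
  out
}

#' Revised Trauma Score component codes
#'
#' Codes the Glasgow Coma Scale total, systolic blood pressure and respiratory
#' rate into the standard 0-4 RTS bands: GCS 13-15 -> 4, 9-12 -> 3, 6-8 -> 2,
#' 4-5 -> 1, 3 -> 0; SBP > 89 -> 4, 76-89 -> 3, 50-75 -> 2, 1-49 -> 1,
#' 0 -> 0; RR 10-29 -> 4, > 29 -> 3, 6-9 -> 2, 1-5 -> 1, 0 -> 0. Missing
#' inputs give missing codes. All arguments are vectorised.
#'
#' @param gcs_total integer 3-15 or `NA`.
#' @param sbp_mmhg non-negative systolic blood pressure in mmHg, or `NA`.
#' @param rr_bpm non-negative respiratory rate in breaths per minute, or `NA`.
#' @return data frame with columns `gcs_code`, `sbp_code`, `rr_code`.
#' @export
code_rts_components <- function(gcs_total, sbp_mmhg, rr_bpm) {
  bad <- !is.na(gcs_total) & (gcs_total < 3 | gcs_total > 15)
  if (any(bad)) {
    stop_ntriss("GCS total outside 3-15: ",
                paste(unique(gcs_total[bad]), collapse = ", "),
                class = "ntriss_validation_error")
  }
  if (any(!is.na(sbp_mmhg) & sbp_mmhg < 0) ||
      any(!is.na(rr_bpm) & rr_bpm < 0)) {
    stop_ntriss("SBP and RR must be non-negative",
                class = "ntriss_validation_error")
  }
  gcs_code <- ifelse(is.na(gcs_total), NA_integer_,
              ifelse(gcs_total >= 13, 4L,
              ifelse(gcs_total >= 9, 3L,
              ifelse(gcs_total >= 6, 2L,
              ifelse(gcs_total >= 4, 1L, 0L)))))
  sbp_code <- ifelse(is.na(sbp_mmhg), NA_integer_,
              ifelse(sbp_mmhg > 89, 4L,
              ifelse(sbp_mmhg >= 76, 3L,
              ifelse(sbp_mmhg >= 50, 2L,
              ifelse(sbp_mmhg > 0, 1L, 0L)))))
  rr_code <- ifelse(is.na(rr_bpm), NA_integer_,
             ifelse(rr_bpm > 29, 3L,
             ifelse(rr_bpm >= 10, 4L,
             ifelse(rr_bpm >= 6, 2L,
             ifelse(rr_bpm > 0, 1L, 0L)))))
  data.frame(gcs_code = gcs_code, sbp_code = sbp_code, rr_code = rr_code)
}

#' RTS totals from component codes
#'
#' Returns both RTS scales in use: `trts`, the unweighted coded sum (triage
#' RTS, 0-12), and `rts_weighted`, the weighted sum
#' 0.9368 GCS + 0.7326 SBP + 0.2908 RR (0-7.8408). Which scale enters the
#' adjusted TRISS equation is a scoring-time configuration choice (see
#' [score_registry()]).
#'
#' @param gcs_code,sbp_code,rr_code integer codes 0-4 (vectorised); any `NA`
#'   component gives `NA` totals.
#' @return data frame with columns `rts_weighted`, `trts`.
#' @export
rts_totals <- function(gcs_code, sbp_code, rr_code) {
  data.frame(
    rts_weighted = rts_weights[["gcs"]] * gcs_code +
      rts_weights[["sbp"]] * sbp_code + rts_weights[["rr"]] * rr_code,
    trts = as.integer(gcs_code + sbp_code + rr_code)
  )
}

#' Peripheral oxygen saturation band code
#'
#' Bands SpO2 into five ordinal codes: 0 or not measurable = 0; 1 to 80 = 1;
#' 81 to 90 = 2; 91 to 95 = 3; 96 to 100 = 4. Real-valued saturations map by
#' interval membership with breaks at 80, 90 and 95 (so 80.5 -> 2); a measured
#' value of exactly 0 codes to 0.
#'
#' @param spo2_pct numeric saturation in percent (0-100), vectorised; `NA`
#'   yields `NA` (truly missing, see [resolve_missing()]).
#' @param not_measurable logical (recycled): `TRUE` marks a "not measurable"
#'   reading, which always codes to 0 regardless of `spo2_pct`.
#' @return integer vector of codes 0-4.
#' @examples
#' code_spo2(c(98, 85, 80, 81))           # 4 2 1 2
#' code_spo2(NA, not_measurable = TRUE)   # 0
#' @export
code_spo2 <- function(spo2_pct, not_measurable = FALSE) {
  n <- max(length(spo2_pct), length(not_measurable))
  spo2_pct <- rep_len(spo2_pct, n)
  not_measurable <- rep_len(not_measurable, n)
  bad <- !is.na(spo2_pct) & (spo2_pct < 0 | spo2_pct > 100)
  if (any(bad)) {
    stop_ntriss("SpO2 outside [0, 100]: ",
                paste(unique(spo2_pct[bad]), collapse = ", "),
                class = "ntriss_validation_error")
  }
  code <- ifelse(is.na(spo2_pct), NA_integer_,
          ifelse(spo2_pct <= 0, 0L,
          ifelse(spo2_pct <= 80, 1L,
          ifelse(spo2_pct <= 90, 2L,
          ifelse(spo2_pct <= 95, 3L, 4L)))))
  code[not_measurable] <- 0L
  as.integer(code)
}

#' Dichotomous age indicator
#'
#' 0 if age < 55 years, 1 if age >= 55 years.
#'
#' @param age_years non-negative age in years (vectorised).
#' @return integer vector of 0/1 (`NA` for missing age).
#' @export
age_indicator <- function(age_years) {
  bad <- !is.na(age_years) & age_years < 0
  if (any(bad)) {
    stop_ntriss("negative age", class = "ntriss_validation_error")
  }
  as.integer(ifelse(is.na(age_years), NA_integer_, age_years >= 55))
}

#' Machine-readable coding tables
#'
#' All banding rules used by the package (RTS component bands, SpO2 bands,
#' RTS weights, age threshold, ISS regions), as a list suitable for audit or
#' JSON export via [export_coding_tables()].
#'
#' @return named list of coding tables.
#' @export
coding_tables <- function() {
  list(
    schema_version = 1L,
    gcs_bands = list("13-15" = 4L, "9-12" = 3L, "6-8" = 2L, "4-5" = 1L,
                     "3" = 0L),
    sbp_bands = list(">89" = 4L, "76-89" = 3L, "50-75" = 2L, "1-49" = 1L,
                     "0" = 0L),
    rr_bands = list("10-29" = 4L, ">29" = 3L, "6-9" = 2L, "1-5" = 1L,
                    "0" = 0L),
    spo2_bands = list("0 or not measurable" = 0L, "1-80" = 1L, "81-90" = 2L,
                      "91-95" = 3L, "96-100" = 4L),
    rts_weights = as.list(rts_weights),
    age_threshold_years = 55,
    iss_body_regions = iss_body_regions
  )
}

#' Write the coding tables as JSON
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_coding_tables <- function(path) {
  jsonlite::write_json(coding_tables(), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
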