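# shared fixtures and independent oracles

# a small hand-built eligible patient table; all fields present
make_patients <- function(n = 3) {
  data.frame(
    patient_id = sprintf("T%d", seq_len(n)),
    site = rep(c("SPBRA", "SDEUA"), length.out = n),
    age_years = rep(c(30, 45, 62), length.out = n),
    mechanism = rep(c("blunt", "penetrating"), length.out = n),
    gcs_total = rep(15, n),
    bmr = rep(6, n),
    sbp_mmhg = rep(c(120, 135, 98), length.out = n),
    rr_bpm = rep(16, n),
    spo2_pct = rep(c(99, 97, 92), length.out = n),
    spo2_nm = rep(FALSE, n),
    hours_from_event = rep(1.5, n),
    transferred = rep(FALSE, n),
    survived = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

make_injuries <- function(ids) {
  data.frame(patient_id = rep(ids, each = 2),
             body_region = rep(c("head_neck", "chest"), length(ids)),
             ais_severity = rep(c(3L, 2L), length(ids)),
             stringsAsFactors = FALSE)
}

make_registry <- function(n = 3) {
  p <- make_patients(n)
  trauma_registry(p, make_injuries(p$patient_id))
}

# exhaustive ISS oracle: maximise the sum of squared region-maxima over all
# choices of up to three distinct regions (independent of the greedy path)
iss_oracle <- function(body_region, ais_severity) {
  if (length(ais_severity) == 0L) return(0L)
  if (any(is.na(ais_severity) | ais_severity == 9)) return(NA_integer_)
  if (any(ais_severity == 6)) return(75L)
  region_max <- tapply(ais_severity, body_region, max)
  regions <- names(region_max)
  best <- 0L
  for (k in seq_len(min(3L, length(regions)))) {
    combos <- utils::combn(regions, k, simplify = FALSE)
    for (cc in combos) {
      best <- max(best, sum(as.integer(region_max[cc])^2))
    }
  }
  as.integer(best)
}

# brute-force AUC: mean over all (positive, negative) pairs, ties one half
auc_oracle <- function(scores, outcome) {
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

random_injury_set <- function(max_lesions = 6, severities = 1:5) {
  m <- sample.int(max_lesions, 1)
  data.frame(body_region = sample(iss_body_regions, m, replace = TRUE),
             ais_severity = sample(severities, m, replace = TRUE),
             stringsAsFactors = FALSE)
}
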