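#' @title Coefficient derivation pipeline
#' @description Reproduces the derivation procedure behind the packaged
#'   coefficient sets: a seeded per-site test/derived split, site-balancing
#'   weights that give both hospitals equal importance, and a weighted
#'   logistic regression (IRLS) fitted per model and trauma mechanism.
#' @name derivation
NULL

#' Split a registry into test and derived databases
#'
#' Samples `n_test_per_site` patients uniformly without replacement from each
#' site into the test database; everyone else forms the derived database used
#' to fit coefficients. The partition is disjoint, exhaustive and reproducible
#' given the seed.
#'
#' @param registry a [trauma_registry].
#' @param n_test_per_site patients drawn per site (default 300).
#' @param seed integer RNG seed.
#' @return list with `test` and `derived`, both [trauma_registry] objects.
#' @export
split_test_derived <- function(registry, n_test_per_site = 300, seed = 1) {
  stopifnot(inherits(registry, "trauma_registry"))
  p <- registry$patients
  sites <- split(seq_len(nrow(p)), p$site)
  too_small <- vapply(sites, length, integer(1)) < n_test_per_site
  if (any(too_small)) {
    stop_ntriss("site smaller than n_test_per_site: ",
                paste(names(sites)[too_small], collapse = ", "),
                class = "ntriss_validation_error")
  }
  test_idx <- with_seed(seed, {
    # fixed site order so the draw is independent of input row order per site
    unlist(lapply(sites[order(names(sites))], function(i) {
      if (n_test_per_site == 0) integer() else sample(i, n_test_per_site)
    }), use.names = FALSE)
  })
  subset_reg <- function(idx) {
    ids <- p$patient_id[idx]
    trauma_registry(p[idx, , drop = FALSE],
                    registry$injuries[registry$injuries$patient_id %in% ids, ,
                                      drop = FALSE])
  }
  list(test = subset_reg(sort(test_idx)),
       derived = subset_reg(setdiff(seq_len(nrow(p)), test_idx)))
}

#' Site-balancing weights
#'
#' With two sites of unequal size, each minority-site patient receives weight
#' majority count / minority count so both sites contribute equally to the
#' fit; majority-site patients get weight 1. `mode = "published"` rounds the
#' ratio to 2 decimals, as carried by the published derivation (7872 / 2116
#' -> 3.72); `mode = "exact"` (default) keeps the full ratio.
#'
#' @param patients patient data frame (or [trauma_registry]).
#' @param mode `"exact"` or `"published"`.
#' @return numeric weight per patient row, in input order.
#' @export
site_weights <- function(patients, mode = c("exact", "published")) {
  mode <- match.arg(mode)
  if (inherits(patients, "trauma_registry")) patients <- patients$patients
  counts <- table(patients$site)
  if (length(counts) == 1L) {
    warning("single site: all weights 1")
    return(rep(1, nrow(patients)))
  }
  if (length(counts) > 2L) {
    stop_ntriss("site weighting is defined for two sites; got ",
                length(counts), class = "ntriss_validation_error")
  }
  minority <- names(counts)[which.min(counts)]
  ratio <- max(counts) / min(counts)
  if (mode == "published") ratio <- round(ratio, 2)
  ifelse(patients$site == minority, ratio, 1)
}

#' Weighted logistic regression by IRLS
#'
#' Maximises the weight-multiplied Bernoulli log-likelihood
#' sum(w * (y log mu + (1 - y) log(1 - mu))) by iteratively reweighted least
#' squares from beta = 0. Convergence when the maximum absolute score drops
#' below `tol_score` or the relative log-likelihood change below `tol_ll`;
#' at most `max_iter` iterations. Standard errors come from the inverse of
#' the weighted observed information; `robust_standard_errors` additionally
#' carry the sandwich variance, which is the appropriate sampling variance
#' when case weights are not all one (weighted pseudo-likelihood). Perfect
#' separation is reported as non-convergence with a named diagnostic, never
#' as silent giant coefficients.
#'
#' @param X design matrix (no intercept column; one is added first).
#' @param y 0/1 outcome vector.
#' @param weights positive case weights (default all 1).
#' @param tol_score,tol_ll,max_iter convergence controls.
#' @return list of class `ntriss_fit`: `coefficients` (named, `(Intercept)`
#'   first), `standard_errors`, `robust_standard_errors`, `n_used`,
#'   `converged`, `iterations`, `log_likelihood`, `diagnostic` (`NA` or e.g.
#'   `"separation"`).
#' @export
fit_weighted_logistic <- function(X, y, weights = NULL, tol_score = 1e-8,
                                  tol_ll = 1e-10, max_iter = 100) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) {
    stop_ntriss("X and y sizes differ", class = "ntriss_validation_error")
  }
  if (anyNA(X) || anyNA(y)) {
    stop_ntriss("design and outcome must be complete (no missing cells)",
                class = "ntriss_validation_error")
  }
  if (!all(y %in% c(0, 1))) {
    stop_ntriss("outcome must be 0/1", class = "ntriss_validation_error")
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0)) {
    stop_ntriss("weights must be positive and finite",
                class = "ntriss_validation_error")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  qrX <- qr(Xd)
  if (qrX$rank < p) {
    dropped <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):p]]
    stop_ntriss("rank-deficient design; collinear column(s): ",
                paste(dropped, collapse = ", "),
                class = "ntriss_validation_error")
  }
  beta <- rep(0, p)
  loglik <- function(eta) {
    # stable: log(1 + exp(-|eta|)) form
    sum(w * (y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))))
  }
  ll_old <- loglik(drop(Xd %*% beta))
  converged <- FALSE
  diagnostic <- NA_character_
  iter <- 0L
  H <- NULL
  repeat {
    iter <- iter + 1L
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(Xd, w * (y - mu)))
    wk <- w * mu * (1 - mu)
    H <- crossprod(Xd, Xd * wk)
    if (max(abs(score)) < tol_score) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) {
      diagnostic <- "singular_information"
      break
    }
    # step-halving keeps the likelihood non-decreasing
    ll_new <- -Inf
    for (h in 0:10) {
      cand <- beta + step / 2^h
      ll_new <- loglik(drop(Xd %*% cand))
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    beta <- cand
    if (abs(ll_new - ll_old) < tol_ll * (abs(ll_old) + 1e-12)) {
      eta <- drop(Xd %*% beta)
      mu <- stats::plogis(eta)
      score <- drop(crossprod(Xd, w * (y - mu)))
      wk <- w * mu * (1 - mu)
      H <- crossprod(Xd, Xd * wk)
      converged <- max(abs(score)) < sqrt(tol_score)
      if (!converged && max(abs(beta)) > 15) diagnostic <- "separation"
      break
    }
    ll_old <- ll_new
    if (iter >= max_iter) {
      if (max(abs(beta)) > 15) diagnostic <- "separation"
      else diagnostic <- "max_iterations"
      break
    }
  }
  # a vanishing score can also mean the data are perfectly classified; the
  # MLE then lies at infinity and the fit must be reported as separated
  if (converged) {
    mu_fin <- stats::plogis(drop(Xd %*% beta))
    if (max(abs(beta)) > 15 || all(abs(y - mu_fin) < 1e-4)) {
      converged <- FALSE
      diagnostic <- "separation"
    }
  }
  if (length(unique(y)) == 1L) {
    converged <- FALSE
    diagnostic <- "separation"
  }
  se <- tryCatch(sqrt(diag(solve(H))), error = function(e) rep(NA_real_, p))
  rse <- tryCatch({
    mu <- stats::plogis(drop(Xd %*% beta))
    meat <- crossprod(Xd * (w * (y - mu)))
    hinv <- solve(H)
    sqrt(diag(hinv %*% meat %*% hinv))
  }, error = function(e) rep(NA_real_, p))
  structure(list(coefficients = stats::setNames(beta, colnames(Xd)),
                 standard_errors = stats::setNames(se, colnames(Xd)),
                 robust_standard_errors = stats::setNames(rse, colnames(Xd)),
                 n_used = n, converged = converged, iterations = iter,
                 log_likelihood = loglik(drop(Xd %*% beta)),
                 diagnostic = diagnostic),
            class = "ntriss_fit")
}

#' @export
print.ntriss_fit <- function(x, ...) {
  cat(sprintf("weighted logistic fit: n = %d, %s in %d iterations\n",
              x$n_used,
              if (x$converged) "converged" else
                paste0("NOT converged (", x$diagnostic, ")"),
              x$iterations))
  print(round(rbind(estimate = x$coefficients, se = x$standard_errors), 6))
  invisible(x)
}

#' Build a model design matrix from a registry
#'
#' Assembles the covariate matrix for one model from coded physiology and
#' severity indices, complete cases only.
#'
#' @inheritParams score_registry
#' @return list: `X` (matrix, model covariate order), `y` (0/1 survived),
#'   `rows` (patient row indices used).
#' @export
build_design <- function(registry, model_id,
                         policy = "spo2_zero_if_unmeasurable",
                         rts_scale = c("weighted", "trts")) {
  scored <- score_registry(registry, model_id,
                           coefficients = default_coefficients(),
                           policy = policy, rts_scale = rts_scale)
  covs <- model_definitions()[[model_id]]
  ok <- is.na(scored$refusal) & !is.na(registry$patients$survived)
  X <- as.matrix(scored[ok, paste0("x_", covs), drop = FALSE])
  colnames(X) <- covs
  list(X = X, y = as.numeric(registry$patients$survived[ok]),
       rows = which(ok))
}

#' Derive mechanism-specific coefficient sets for one model
#'
#' Stratifies the derived database by trauma mechanism, applies
#' site-balancing weights (computed on the full derived set before
#' stratification by default), builds the model design via the coding
#' machinery and fits a weighted logistic regression per stratum.
#'
#' @inheritParams score_registry
#' @param registry the derived database, a [trauma_registry].
#' @param weights_mode `"exact"` or `"published"`, see [site_weights()]; or
#'   `"none"` for unweighted fits.
#' @param weights_scope `"global"` (default: site weights computed on the
#'   full derived set) or `"per_stratum"` (recomputed within each mechanism).
#' @param min_stratum smallest mechanism stratum that will be fitted
#'   (default 50); smaller strata are refused with a warning.
#' @return named list (`blunt`, `penetrating`); each entry is a list with the
#'   provenance-stamped `coefficient_set` and its `fit` (`ntriss_fit`), or
#'   `NULL` when that stratum was refused.
#' @export
derive_model <- function(registry, model_id, weights_mode = "exact",
                         weights_scope = c("global", "per_stratum"),
                         policy = "spo2_zero_if_unmeasurable",
                         rts_scale = c("weighted", "trts"),
                         min_stratum = 50) {
  stopifnot(inherits(registry, "trauma_registry"))
  weights_scope <- match.arg(weights_scope)
  p <- registry$patients
  w_all <- if (weights_mode == "none") rep(1, nrow(p))
           else site_weights(p, mode = weights_mode)
  out <- list(blunt = NULL, penetrating = NULL)
  for (mech in c("blunt", "penetrating")) {
    idx <- which(!is.na(p$mechanism) & p$mechanism == mech)
    if (length(idx) < min_stratum) {
      warning("mechanism stratum '", mech, "' below minimum (",
              length(idx), " < ", min_stratum, "); fit refused")
      next
    }
    sub <- trauma_registry(
      p[idx, , drop = FALSE],
      registry$injuries[registry$injuries$patient_id %in% p$patient_id[idx], ,
                        drop = FALSE])
    d <- build_design(sub, model_id, policy = policy, rts_scale = rts_scale)
    if (length(d$y) < min_stratum) {
      warning("complete-case rows for '", mech, "' below minimum; fit refused")
      next
    }
    w <- if (weights_scope == "global") w_all[idx][d$rows]
         else if (weights_mode == "none") rep(1, length(d$rows))
         else site_weights(sub$patients[d$rows, , drop = FALSE],
                           mode = weights_mode)
    fit <- fit_weighted_logistic(d$X, d$y, weights = w)
    cs <- coefficient_set(
      model_id, mech,
      intercept = fit$coefficients[["(Intercept)"]],
      slopes = fit$coefficients[-1],
      provenance = paste0("derived ", format(Sys.Date()), " (n=", fit$n_used,
                          ", weights=", weights_mode, ")"))
    out[[mech]] <- list(coefficient_set = cs, fit = fit)
  }
  out
}
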