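# Single-season occupancy model with imperfect detection. Likelihood for
# site i with history y_i over J surveys:
#   detected at least once:  L_i = psi_i * prod_j p_ij^y (1-p_ij)^(1-y)
#   never detected:          L_i = psi_i * prod_j (1-p_ij) + (1 - psi_i)
# with logit links on both psi (site covariates) and p (site or
# site-by-survey covariates). Maximised by BFGS with analytic gradients
# from several deterministic jittered starts.

PROB_CLIP <- 1e-10

#' Negative log-likelihood of the occupancy model
#'
#' @param params numeric vector: occupancy coefficients followed by
#'   detection coefficients.
#' @param y binary n x J detection matrix.
#' @param X_psi n x k_psi occupancy design matrix.
#' @param X_p list of J design matrices (n x k_p), one per survey.
#' @return Scalar negative log-likelihood.
#' @export
occu_nll <- function(params, y, X_psi, X_p) {
  if (any(!is.finite(params))) stop("non-finite parameter value")
  parts <- occu_lik_parts(params, y, X_psi, X_p)
  -sum(parts$loglik)
}

occu_lik_parts <- function(params, y, X_psi, X_p) {
  kp <- ncol(X_psi)
  beta <- params[seq_len(kp)]
  alpha <- params[-seq_len(kp)]
  J <- ncol(y)
  psi <- clip01(stats::plogis(drop(X_psi %*% beta)))
  p <- vapply(
    seq_len(J),
    function(j) clip01(stats::plogis(drop(X_p[[j]] %*% alpha))),
    numeric(nrow(y))
  )
  p <- matrix(p, nrow = nrow(y))
  detected <- rowSums(y) > 0
  cond <- rowSums(y * log(p) + (1 - y) * log(1 - p)) # log prod p^y (1-p)^(1-y)
  q <- exp(rowSums(log(1 - p))) # prob of all-zero history given occupied
  loglik <- ifelse(detected, log(psi) + cond, log(psi * q + (1 - psi)))
  list(psi = psi, p = p, q = q, detected = detected, loglik = loglik)
}

clip01 <- function(x) pmin(pmax(x, PROB_CLIP), 1 - PROB_CLIP)

# analytic gradient of occu_nll
occu_nll_grad <- function(params, y, X_psi, X_p) {
  kp <- ncol(X_psi)
  parts <- occu_lik_parts(params, y, X_psi, X_p)
  psi <- parts$psi; p <- parts$p; q <- parts$q; det <- parts$detected
  L0 <- psi * q + (1 - psi)
  # d loglik / d eta_psi
  dpsi <- ifelse(det, 1 - psi, psi * (1 - psi) * (q - 1) / L0)
  g_beta <- -drop(crossprod(X_psi, dpsi))
  # d loglik / d eta_p per survey
  g_alpha <- 0
  for (j in seq_len(ncol(y))) {
    dp <- ifelse(det, y[, j] - p[, j], -psi * q * p[, j] / L0)
    g_alpha <- g_alpha - drop(crossprod(X_p[[j]], dp))
  }
  c(g_beta, g_alpha)
}

# build standardized design matrices for a detection tibble
occu_design <- function(data, psi_covariates, p_covariates) {
  y_cols <- sort(grep("^y_[0-9]+$", names(data), value = TRUE))
  if (length(y_cols) < 2) stop("need y_1 ... y_J columns with J >= 2")
  J <- length(y_cols)
  y <- as.matrix(data[y_cols])
  if (!all(y %in% c(0, 1))) stop("detection histories must be binary")
  n <- nrow(y)

  get_site <- function(v) {
    if (!v %in% names(data)) stop("covariate '", v, "' not found in data")
    x <- data[[v]]
    if (any(!is.finite(x))) stop("covariate '", v, "' has non-finite values")
    x
  }
  scaling <- list()
  X_psi <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in psi_covariates) {
    x <- get_site(v)
    mu <- mean(x); sdv <- stats::sd(x)
    if (sdv == 0) sdv <- 1
    scaling[[v]] <- c(mean = mu, sd = sdv)
    X_psi <- cbind(X_psi, (x - mu) / sdv)
    colnames(X_psi)[ncol(X_psi)] <- v
  }

  X_p <- lapply(seq_len(J), function(j) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  })
  for (v in p_covariates) {
    survey_cols <- paste0(v, "_", seq_len(J))
    if (all(survey_cols %in% names(data))) {
      m <- as.matrix(data[survey_cols])
      if (any(!is.finite(m))) stop("covariate '", v, "' has non-finite values")
      mu <- mean(m); sdv <- stats::sd(as.vector(m))
      if (sdv == 0) sdv <- 1
      scaling[[v]] <- c(mean = mu, sd = sdv)
      m <- (m - mu) / sdv
      for (j in seq_len(J)) {
        X_p[[j]] <- cbind(X_p[[j]], m[, j])
        colnames(X_p[[j]])[ncol(X_p[[j]])] <- v
      }
    } else {
      x <- get_site(v)
      mu <- mean(x); sdv <- stats::sd(x)
      if (sdv == 0) sdv <- 1
      scaling[[v]] <- c(mean = mu, sd = sdv)
      xz <- (x - mu) / sdv
      for (j in seq_len(J)) {
        X_p[[j]] <- cbind(X_p[[j]], xz)
        colnames(X_p[[j]])[ncol(X_p[[j]])] <- v
      }
    }
  }
  list(y = y, X_psi = X_psi, X_p = X_p, scaling = scaling, J = J, n = n)
}

#' Fit a single-season occupancy model
#'
#' Maximum-likelihood fit with logit links on occupancy and detection.
#' Covariates are z-scored at fit time (coefficients are reported on the
#' standardized scale; the centring constants are stored for prediction).
#' Optimisation is BFGS with analytic gradients from `nstarts`
#' deterministic jittered starts; the best optimum is kept. A fit is
#' flagged `converged` when the gradient norm at the optimum is below
#' `gradtol`, and `boundary` when any coefficient exceeds 15 in absolute
#' value (logit-scale separation).
#'
#' @param data tibble with binary columns `y_1 ... y_J`, site covariate
#'   columns, and optionally survey covariate columns `name_1 ... name_J`.
#' @param psi_covariates character vector of occupancy covariate names.
#' @param p_covariates character vector of detection covariate names; a
#'   name with matching `name_1..name_J` columns is treated as
#'   survey-varying.
#' @param nstarts number of jittered starts.
#' @param gradtol gradient tolerance for the convergence flag.
#' @param null_fit optional pre-computed intercept-only fit on the same
#'   data (reused for the Nagelkerke R-squared); computed on the fly when
#'   `NULL`.
#' @param compute_rn2 compute Nagelkerke R-squared (needs the null fit).
#' @return An object of class `occu_fit`.
#' @export
fit_occupancy <- function(data, psi_covariates = character(),
                          p_covariates = character(),
                          nstarts = 5, gradtol = 1e-6,
                          null_fit = NULL, compute_rn2 = TRUE) {
  design <- occu_design(data, psi_covariates, p_covariates)
  k_psi <- ncol(design$X_psi)
  k_p <- ncol(design$X_p[[1]])
  n_params <- k_psi + k_p
  if (design$n <= n_params) {
    stop("need more sites (", design$n, ") than parameters (", n_params, ")")
  }

  naive <- mean(rowSums(design$y) > 0)
  det_rate <- sum(design$y) / max(1, sum(rowSums(design$y) > 0) * design$J)
  base <- c(
    stats::qlogis(min(max(naive, 0.1), 0.9)), rep(0, k_psi - 1),
    stats::qlogis(min(max(det_rate, 0.1), 0.9)), rep(0, k_p - 1)
  )
  # deterministic jitters: fixed alternating-sign offsets of growing size
  starts <- lapply(seq_len(nstarts), function(s) {
    if (s == 1) return(base)
    base + 0.4 * (s - 1) * (-1)^(seq_len(n_params) + s)
  })

  best <- NULL
  failures <- character()
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, occu_nll, occu_nll_grad,
        y = design$y, X_psi = design$X_psi, X_p = design$X_p,
        method = "BFGS", control = list(maxit = 500, reltol = 1e-14)
      ),
      error = function(e) e
    )
    if (inherits(opt, "error")) {
      failures <- c(failures, conditionMessage(opt))
      next
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop(
      "all optimisation starts failed: ",
      paste(unique(failures), collapse = "; ")
    )
  }

  grad <- occu_nll_grad(best$par, design$y, design$X_psi, design$X_p)
  hess <- tryCatch(
    stats::optimHess(best$par, occu_nll, occu_nll_grad,
      y = design$y, X_psi = design$X_psi, X_p = design$X_p
    ),
    error = function(e) NULL
  )
  vc <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL) else NULL

  beta <- stats::setNames(best$par[seq_len(k_psi)], colnames(design$X_psi))
  alpha <- stats::setNames(best$par[-seq_len(k_psi)], colnames(design$X_p[[1]]))
  parts <- occu_lik_parts(best$par, design$y, design$X_psi, design$X_p)
  loglik <- -best$value
  aic <- -2 * loglik + 2 * n_params
  aicc <- aic + 2 * n_params * (n_params + 1) / (design$n - n_params - 1)

  fit <- structure(
    list(
      beta_psi = beta, beta_p = alpha,
      psi_covariates = psi_covariates, p_covariates = p_covariates,
      loglik = loglik, n_params = n_params, n_sites = design$n,
      aic = aic, aicc = aicc, rn2 = NA_real_,
      converged = max(abs(grad)) < gradtol && best$convergence == 0,
      boundary = any(abs(best$par) > 15),
      psi_hat = parts$psi, p_hat = parts$p,
      vcov = vc, scaling = design$scaling,
      y = design$y, X_psi = design$X_psi, X_p = design$X_p
    ),
    class = "occu_fit"
  )
  if (compute_rn2) {
    if (length(psi_covariates) == 0 && length(p_covariates) == 0) {
      fit$rn2 <- 0
    } else {
      if (is.null(null_fit)) {
        null_fit <- fit_occupancy(data,
          character(), character(),
          nstarts = nstarts, gradtol = gradtol, compute_rn2 = FALSE
        )
      }
      fit$rn2 <- nagelkerke_r2(fit, null_fit)
    }
  }
  fit
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Single-season occupancy model fit\n")
  cat(sprintf(
    "  sites: %d  params: %d  logLik: %.3f  AIC: %.2f  AICc: %.2f\n",
    x$n_sites, x$n_params, x$loglik, x$aic, x$aicc
  ))
  if (!is.na(x$rn2)) cat(sprintf("  Nagelkerke R2: %.3f\n", x$rn2))
  cat("  psi:", paste(sprintf("%s=%.3f", names(x$beta_psi), x$beta_psi), collapse = " "), "\n")
  cat("  p:  ", paste(sprintf("%s=%.3f", names(x$beta_p), x$beta_p), collapse = " "), "\n")
  if (!x$converged) cat("  [not converged at gradient tolerance]\n")
  if (x$boundary) cat("  [boundary estimate: |logit| > 15]\n")
  invisible(x)
}

#' Nagelkerke R-squared of an occupancy fit
#'
#' `RN2 = (1 - exp((2/n) (l0 - l1))) / (1 - exp((2/n) l0))`, with `l0` the
#' log-likelihood of the intercept-only (constant psi, constant p) model,
#' `l1` the fitted model's, and `n` the number of sites.
#'
#' @param fit fitted `occu_fit`.
#' @param null_fit intercept-only `occu_fit` on the same data.
#' @param n sample size; defaults to the number of sites.
#' @return Scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit, null_fit, n = fit$n_sites) {
  l1 <- fit$loglik
  l0 <- null_fit$loglik
  if (l1 < l0 - 1e-6) {
    stop("fitted log-likelihood below the null model's: optimiser failure")
  }
  l1 <- max(l1, l0)
  r2 <- (1 - exp((2 / n) * (l0 - l1))) / (1 - exp((2 / n) * l0))
  min(max(r2, 0), 1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of an occupancy fit
#'
#' @param x an `occu_fit`.
#' @param ... unused.
#' @return Tibble with `component` ("psi"/"p"), `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value` (Wald).
#' @export
tidy.occu_fit <- function(x, ...) {
  est <- c(x$beta_psi, x$beta_p)
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, length(est))
  stat <- est / se
  tibble::tibble(
    component = rep(c("psi", "p"), c(length(x$beta_psi), length(x$beta_p))),
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
}

#' One-row model summary
#'
#' @param x an `occu_fit`.
#' @param ... unused.
#' @return Tibble with `logLik`, `AIC`, `AICc`, `rn2`, `n_sites`,
#'   `n_params`, `converged`, `boundary`.
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, AIC = x$aic, AICc = x$aicc, rn2 = x$rn2,
    n_sites = x$n_sites, n_params = x$n_params,
    converged = x$converged, boundary = x$boundary
  )
}

#' Predict occupancy probability for new covariate values
#'
#' New covariates are given in original (unstandardized) units and are
#' centred with the training means and SDs stored in the fit.
#'
#' @param object an `occu_fit`.
#' @param newdata data frame with one column per occupancy covariate;
#'   omitted covariates are held at their training mean.
#' @param ... unused.
#' @return Numeric vector of occupancy probabilities.
#' @export
predict.occu_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$psi_hat)
  vars <- object$psi_covariates
  unknown <- setdiff(names(newdata), vars)
  if (length(unknown) > 0) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  }
  n <- nrow(newdata)
  X <- matrix(1, n, 1)
  for (v in vars) {
    sc <- object$scaling[[v]]
    xz <- if (v %in% names(newdata)) (newdata[[v]] - sc["mean"]) / sc["sd"] else rep(0, n)
    X <- cbind(X, xz)
  }
  unname(stats::plogis(drop(X %*% object$beta_psi)))
}

#' Scan all detection-covariate structures
#'
#' Fits constant-occupancy models with every subset of the detection
#' covariates (2^k models, 8 for the standard three) and ranks them by
#' AICc.
#'
#' @param data detection tibble (see [fit_occupancy()]).
#' @param p_covariates detection covariates to scan over.
#' @param ... passed to [fit_occupancy()].
#' @return Tibble ranked by AICc with columns `p_terms` (label), `k`,
#'   `logLik`, `AICc`, `delta_aicc`, and `fit` (list column).
#' @export
detection_model_scan <- function(data, p_covariates = c("veg_str", "day", "area"),
                                 ...) {
  subsets <- all_subsets(p_covariates)
  null_fit <- fit_occupancy(data, character(), character(), compute_rn2 = FALSE, ...)
  fits <- purrr::map(subsets, function(terms) {
    fit_occupancy(data, character(), terms, null_fit = null_fit, ...)
  })
  out <- tibble::tibble(
    p_terms = vapply(
      subsets,
      function(s) if (length(s) == 0) "(constant)" else paste(s, collapse = "+"),
      character(1)
    ),
    k = vapply(fits, function(f) f$n_params, numeric(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    fit = fits
  ) |>
    dplyr::arrange(.data$AICc) |>
    dplyr::mutate(delta_aicc = .data$AICc - min(.data$AICc))
  dplyr::relocate(out, "delta_aicc", .after = "AICc")
}

all_subsets <- function(vars) {
  k <- length(vars)
  purrr::map(seq_len(2^k) - 1, function(mask) {
    vars[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
  })
}

#' Parametric-bootstrap goodness of fit
#'
#' Pearson chi-square over the 2^J detection-history cohorts, with expected
#' counts `E_h = sum_i Pr(h | fit, site i)`, compared to its distribution
#' under `B` datasets simulated from the fitted model and refitted. Returns
#' the bootstrap p-value `#(chi2_b >= chi2_obs) / B` and the overdispersion
#' ratio `c_hat = chi2_obs / mean(chi2_b)`.
#'
#' @param fit an `occu_fit`.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed for the simulation.
#' @return List of class `occu_gof`: `chi2_obs`, `p_value`, `c_hat`, `B`,
#'   `n_failed` (refits dropped), `chi2_boot`.
#' @export
gof_parametric_bootstrap <- function(fit, B = 200, seed = 1) {
  if (B < 1) stop("B must be at least 1")
  chi2_obs <- occu_history_chi2(fit$y, fit$psi_hat, fit$p_hat)$chi2
  n <- fit$n_sites
  J <- ncol(fit$y)
  par_hat <- c(fit$beta_psi, fit$beta_p)
  chi2_boot <- rep(NA_real_, B)
  with_local_seed(seed, for (b in seq_len(B)) {
    z <- stats::rbinom(n, 1, fit$psi_hat)
    yb <- matrix(
      stats::rbinom(n * J, 1, rep(z, J) * as.vector(fit$p_hat)),
      n, J
    )
    opt <- tryCatch(
      stats::optim(par_hat, occu_nll, occu_nll_grad,
        y = yb, X_psi = fit$X_psi, X_p = fit$X_p,
        method = "BFGS", control = list(maxit = 500, reltol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    parts <- occu_lik_parts(opt$par, yb, fit$X_psi, fit$X_p)
    chi2_boot[b] <- occu_history_chi2(yb, parts$psi, parts$p)$chi2
  })
  ok <- !is.na(chi2_boot)
  structure(
    list(
      chi2_obs = chi2_obs,
      p_value = sum(chi2_boot[ok] >= chi2_obs) / B,
      c_hat = chi2_obs / mean(chi2_boot[ok]),
      B = B, n_failed = sum(!ok), chi2_boot = chi2_boot[ok]
    ),
    class = "occu_gof"
  )
}

#' @export
print.occu_gof <- function(x, ...) {
  cat(sprintf(
    "Parametric-bootstrap GOF: chi2 = %.3f, p = %.3f, c-hat = %.3f (B = %d%s)\n",
    x$chi2_obs, x$p_value, x$c_hat, x$B,
    if (x$n_failed > 0) sprintf(", %d refits dropped", x$n_failed) else ""
  ))
  invisible(x)
}

# observed and expected counts over all 2^J histories
occu_history_chi2 <- function(y, psi, p) {
  n <- nrow(y); J <- ncol(y)
  hist_mat <- as.matrix(expand.grid(rep(list(0:1), J)))
  H <- nrow(hist_mat)
  obs_code <- drop(y %*% 2^(seq_len(J) - 1))
  codes <- drop(hist_mat %*% 2^(seq_len(J) - 1))
  O <- vapply(codes, function(cd) sum(obs_code == cd), numeric(1))
  E <- vapply(seq_len(H), function(h) {
    hh <- matrix(hist_mat[h, ], n, J, byrow = TRUE)
    pr_given_z1 <- exp(rowSums(hh * log(p) + (1 - hh) * log(1 - p)))
    pr <- psi * pr_given_z1 + if (sum(hist_mat[h, ]) == 0) (1 - psi) else 0
    sum(pr)
  }, numeric(1))
  chi2 <- sum((O - E)^2 / E)
  list(chi2 = chi2, observed = O, expected = E, histories = hist_mat)
}
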