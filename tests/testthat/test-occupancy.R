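test_that("likelihood matches closed forms for known probabilities", {
  # psi ~ 1 (clipped), p = 0.5, history "10": L = 0.5 * 0.5 = 0.25
  y <- matrix(c(1, 0), 1, 2)
  X_psi <- matrix(1, 1, 1)
  X_p <- list(matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(occu_nll(c(40, 0), y, X_psi, X_p), -log(0.25), tolerance = 1e-8)
  # psi = 0.6, p = 0.7, history "00": L = 0.6*0.09 + 0.4
  y0 <- matrix(c(0, 0), 1, 2)
  nll <- occu_nll(c(qlogis(0.6), qlogis(0.7)), y0, X_psi, X_p)
  expect_equal(nll, -log(0.6 * 0.3^2 + 0.4), tolerance = 1e-12)
  expect_error(occu_nll(c(NA, 0), y, X_psi, X_p), "non-finite")
})

test_that("likelihood equals latent-state enumeration on random small datasets", {
  set.seed(99)
  for (case in 1:100) {
    n <- sample(2:8, 1)
    J <- sample(2:3, 1)
    cs <- random_occu_case(n, J)
    expect_equal(
      occu_nll(cs$params, cs$y, cs$X_psi, cs$X_p),
      enum_nll(cs$psi, cs$p, cs$y),
      tolerance = 1e-12
    )
  }
})

test_that("analytic gradient agrees with numerical differentiation", {
  set.seed(17)
  cs <- random_occu_case(12, 2)
  g <- scaleocc:::occu_nll_grad(cs$params, cs$y, cs$X_psi, cs$X_p)
  eps <- 1e-6
  for (k in seq_along(cs$params)) {
    up <- cs$params; up[k] <- up[k] + eps
    dn <- cs$params; dn[k] <- dn[k] - eps
    num <- (occu_nll(up, cs$y, cs$X_psi, cs$X_p) -
      occu_nll(dn, cs$y, cs$X_psi, cs$X_p)) / (2 * eps)
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})

test_that("MLE recovers generating parameters on a large simulated dataset", {
  s <- simulate_occupancy_data(
    500,
    psi_coefs = c("(Intercept)" = qlogis(0.6)),
    p_coefs = c("(Intercept)" = qlogis(0.7)),
    seed = 12
  )
  fit <- fit_occupancy(s$data)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta_psi[1] - qlogis(0.6)), 3 * se[1])
  expect_lt(abs(fit$beta_p[1] - qlogis(0.7)), 3 * se[2])
})

test_that("complete separation is flagged as a boundary fit", {
  data <- counts_data(12, 0, 0) # every history "11"
  fit <- fit_occupancy(data)
  expect_true(fit$boundary)
  expect_gt(plogis(fit$beta_psi[1]), 0.999)
  expect_gt(plogis(fit$beta_p[1]), 0.999)
})

test_that("with effectively perfect detection psi_hat equals naive occupancy", {
  data <- counts_data(9, 0, 21) # only "11" and "00" histories
  fit <- fit_occupancy(data)
  expect_equal(unname(plogis(fit$beta_psi[1])), 9 / 30, tolerance = 1e-3)
})

test_that("information criteria satisfy their identities", {
  region <- small_region()
  fit <- fit_occupancy(region$detections, "habitat_150", c("veg_str", "day"))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  K <- fit$n_params
  expect_equal(
    fit$aicc,
    fit$aic + 2 * K * (K + 1) / (fit$n_sites - K - 1)
  )
  expect_gte(fit$aicc, fit$aic)
})

test_that("Nagelkerke R2 follows its formula and bounds", {
  region <- small_region()
  null_fit <- fit_occupancy(region$detections, compute_rn2 = FALSE)
  fit <- fit_occupancy(region$detections, "habitat_150", "veg_str",
    null_fit = null_fit
  )
  n <- fit$n_sites
  manual <- (1 - exp((2 / n) * (null_fit$loglik - fit$loglik))) /
    (1 - exp((2 / n) * null_fit$loglik))
  expect_equal(fit$rn2, manual)
  expect_gte(fit$rn2, 0)
  expect_lte(fit$rn2, 1)
  # null vs itself
  expect_equal(nagelkerke_r2(null_fit, null_fit), 0)
  # an optimiser failure (l1 < l0) is caught
  broken <- null_fit
  broken$loglik <- null_fit$loglik - 1
  expect_error(nagelkerke_r2(broken, null_fit), "below the null")
})

test_that("prediction applies the stored standardization", {
  s <- simulate_occupancy_data(
    300,
    psi_coefs = c("(Intercept)" = 0, x = 1),
    p_coefs = c("(Intercept)" = qlogis(0.7)),
    seed = 5
  )
  fit <- fit_occupancy(s$data, "x")
  sc <- fit$scaling[["x"]]
  # at the training mean the prediction is logistic(beta0)
  expect_equal(
    predict(fit, data.frame(x = sc["mean"])),
    unname(plogis(fit$beta_psi[1]))
  )
  # one SD above the mean adds exactly beta1 on the logit scale
  expect_equal(
    predict(fit, data.frame(x = sc["mean"] + sc["sd"])),
    unname(plogis(fit$beta_psi[1] + fit$beta_psi[2]))
  )
  expect_error(predict(fit, data.frame(bogus = 1)), "unknown covariate")
})

test_that("detection scan fits all eight structures and ranks them", {
  region <- small_region()
  scan <- detection_model_scan(region$detections)
  expect_equal(nrow(scan), 8)
  expect_equal(scan$delta_aicc[1], 0)
  expect_true("(constant)" %in% scan$p_terms)
  expect_true(all(diff(scan$AICc) >= 0))
  expect_setequal(
    scan$k,
    c(2, 3, 3, 3, 4, 4, 4, 5)
  )
})

test_that("history chi-square uses expected counts that sum to n", {
  data <- counts_data(17, 7, 18)
  fit <- fit_occupancy(data)
  hc <- scaleocc:::occu_history_chi2(fit$y, fit$psi_hat, fit$p_hat)
  expect_equal(sum(hc$expected), nrow(data))
  expect_equal(sum(hc$observed), nrow(data))
  # hand-computed expectation under given (psi, p)
  psi <- rep(0.5, 2); p <- matrix(0.6, 2, 2)
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  hc2 <- scaleocc:::occu_history_chi2(y, psi, p)
  # histories (00,10,01,11) expectations for each of 2 identical sites
  e00 <- 2 * (0.5 * 0.4^2 + 0.5)
  e10 <- 2 * 0.5 * 0.6 * 0.4
  e11 <- 2 * 0.5 * 0.36
  expect_equal(hc2$expected, c(e00, e10, e10, e11))
})

test_that("bootstrap GOF is seeded, reproducible and well-formed", {
  data <- counts_data(10, 6, 14)
  fit <- fit_occupancy(data)
  g1 <- gof_parametric_bootstrap(fit, B = 50, seed = 3)
  g2 <- gof_parametric_bootstrap(fit, B = 50, seed = 3)
  expect_identical(g1$chi2_boot, g2$chi2_boot)
  expect_gte(g1$p_value, 0)
  expect_lte(g1$p_value, 1)
  expect_gt(g1$c_hat, 0)
  expect_error(gof_parametric_bootstrap(fit, B = 0), "at least 1")
})

test_that("tidy and glance return the broom-style summaries", {
  region <- small_region()
  fit <- fit_occupancy(region$detections, "habitat_150", "veg_str")
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_equal(td$component, c("psi", "psi", "p", "p"))
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$AIC, fit$aic)
})
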