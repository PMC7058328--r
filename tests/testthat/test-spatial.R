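test_that("Moran's I matches the direct formula and ape's implementation", {
  set.seed(41)
  coords <- cbind(c(0, 3, 1, 7, 4, 6), c(0, 1, 5, 2, 6, 6))
  r <- c(0.3, -1.2, 0.5, 2.1, -0.4, 0.9)
  out <- global_morans_i(r, coords, n_permutations = 99, seed = 1)
  expect_equal(out$morans_i, morans_i_direct(r, coords), tolerance = 1e-12)
  expect_equal(out$expected_i, -1 / 5)
  # ape row-standardizes the weight matrix; feeding it pre-standardized
  # weights makes its statistic comparable with the direct formula, which
  # validates the oracle itself against an independent implementation
  w <- 1 / as.matrix(dist(coords))
  diag(w) <- 0
  w_std <- w / rowSums(w)
  ape_out <- ape::Moran.I(r, w_std, scaled = FALSE)
  n <- length(r)
  rc <- r - mean(r)
  direct_std <- (n / sum(w_std)) * drop(rc %*% w_std %*% rc) / sum(rc^2)
  expect_equal(direct_std, ape_out$observed, tolerance = 1e-12)
})

test_that("Moran permutation test rejects a spatial gradient and is calibrated under shuffling", {
  grid <- as.matrix(expand.grid(x = 1:7, y = 1:7))
  gradient <- grid[, 1] + grid[, 2] + rnorm(49, 0, 0.3)
  out <- global_morans_i(gradient, grid, n_permutations = 499, seed = 2)
  expect_lte(out$p_value, 0.05)
  expect_gt(out$morans_i, out$expected_i)
  # destroying the spatial structure brings I back near its null expectation
  set.seed(3)
  i_shuffled <- replicate(200, {
    global_morans_i(sample(gradient), grid, n_permutations = 0, seed = 1)$morans_i
  })
  expect_lt(abs(mean(i_shuffled) - (-1 / 48)), 3 * sd(i_shuffled) / sqrt(200))
})

test_that("Moran's I rejects degenerate inputs", {
  coords <- cbind(1:5, 1:5)
  expect_error(global_morans_i(rep(1, 5), coords), "constant")
  expect_error(global_morans_i(c(1, 2, 3), coords[1:3, ]), "at least 4")
  expect_error(
    global_morans_i(c(1, 2, 3, 4), rbind(coords[1:3, ], c(1, 1))),
    "coincident"
  )
})

test_that("PCNM axes match a dense eigen-decomposition oracle", {
  set.seed(44)
  coords <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  resid <- rnorm(12)
  out <- pcnm_autocovariate(coords, resid)
  # oracle: truncate at the longest MST edge, 4t replacement, Gower centre
  d <- as.matrix(dist(coords))
  t_mst <- max(vegan::spantree(dist(coords))$dist)
  expect_equal(out$threshold, t_mst, tolerance = 1e-9)
  dtr <- d
  dtr[dtr > t_mst] <- 4 * t_mst
  a <- -0.5 * dtr^2
  n <- nrow(a)
  cmat <- diag(n) - matrix(1 / n, n, n)
  g <- cmat %*% a %*% cmat
  ev <- eigen(g, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-9
  expect_equal(out$eigenvalues, ev$values[pos], tolerance = 1e-8)
  expect_true(all(diff(out$eigenvalues) <= 1e-9))
  expect_lte(ncol(out$vectors), n - 1)
  # eigenvectors agree up to sign/scale
  for (k in seq_len(ncol(out$vectors))) {
    expect_equal(abs(cor(out$vectors[, k], ev$vectors[, k])), 1, tolerance = 1e-6)
  }
  # retained axes mutually orthogonal
  cp <- crossprod(out$vectors)
  expect_equal(cp - diag(diag(cp)), matrix(0, ncol(cp), ncol(cp)),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  # the autocovariate is the max-|Spearman| axis
  cors <- apply(out$vectors, 2, function(v) abs(cor(v, resid, method = "spearman")))
  expect_equal(out$selected, unname(which.max(cors)))
})

test_that("collinear equidistant points give the analytic PCNM spectrum", {
  coords <- cbind(seq(0, 40, by = 10), rep(0, 5))
  out <- pcnm_autocovariate(coords, rnorm(5))
  expect_true(all(out$eigenvalues > 0))
  expect_lte(length(out$eigenvalues), 4)
})

test_that("conditional-occupancy residuals are zero-centred for detected sites", {
  data <- counts_data(8, 4, 12)
  fit <- fit_occupancy(data)
  res <- occupancy_residuals(fit)
  detected <- rowSums(fit$y) > 0
  expect_equal(res[detected], 1 - fit$psi_hat[detected])
  # never-detected residuals lie in (-psi, 1-psi)
  expect_true(all(res[!detected] > -fit$psi_hat[!detected]))
  expect_true(all(res[!detected] < 1 - fit$psi_hat[!detected]))
})

test_that("spatially unstructured residuals rarely change the model", {
  # with no spatial signal the Moran gate fires at ~alpha, so the spatial
  # stage leaves the model untouched (AIC unchanged) in the vast majority
  # of runs
  set.seed(51)
  changed <- replicate(50, {
    s <- simulate_occupancy_data(
      60,
      psi_coefs = c("(Intercept)" = 0),
      p_coefs = c("(Intercept)" = 1),
      seed = sample.int(1e6, 1)
    )
    coords <- cbind(runif(60, 0, 1000), runif(60, 0, 1000))
    fit <- fit_occupancy(s$data)
    sac <- spatial_autocorrelation_check(fit, coords,
      n_permutations = 199, seed = sample.int(1e6, 1)
    )
    if (!sac$significant) {
      0
    } else {
      dat <- s$data
      dat$auto <- sac$autocovariate
      abs(fit_occupancy(dat, "auto")$aic - fit$aic)
    }
  })
  expect_gte(mean(changed < 2), 0.8)
})

test_that("the spatial check attaches an autocovariate only when SAC is significant", {
  set.seed(52)
  s <- simulate_occupancy_data(
    49,
    psi_coefs = c("(Intercept)" = 0.5),
    p_coefs = c("(Intercept)" = 1.5),
    seed = 8
  )
  grid <- as.matrix(expand.grid(x = seq(0, 600, 100), y = seq(0, 600, 100)))
  fit <- fit_occupancy(s$data)
  diag_out <- spatial_autocorrelation_check(fit, grid, seed = 9)
  expect_identical(diag_out$significant, diag_out$p_value < 0.05)
  if (diag_out$significant) {
    expect_equal(length(diag_out$autocovariate), 49)
  } else {
    expect_null(diag_out$autocovariate)
  }
})
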