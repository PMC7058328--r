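# Shared fixtures and independent oracles, built in code at test time.

# small synthetic scenario used across tests (cached per session)
.fixture_env <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 11, ...) {
  sim_config(
    extent_m = c(800, 800), cell_size_m = 5, n_patches = 12,
    habitat_fraction_target = 0.12,
    scales = c(50, 150, 250, 500), true_scale_m = 150,
    seed = seed, ...
  )
}

small_region <- function() {
  if (is.null(.fixture_env$region)) {
    .fixture_env$region <- simulate_region(small_sim_config())
  }
  .fixture_env$region
}

# detection table realizing given history counts under a constant model
counts_data <- function(n_both, n_one, n_none) {
  tibble::tibble(
    patch_id = seq_len(n_both + n_one + n_none),
    y_1 = c(rep(1, n_both), rep(1, n_one), rep(0, n_none)),
    y_2 = c(rep(1, n_both), rep(0, n_one), rep(0, n_none))
  )
}

# independent likelihood oracle: full latent-state enumeration per site
enum_nll <- function(psi, p, y) {
  n <- nrow(y)
  ll <- 0
  for (i in seq_len(n)) {
    li <- 0
    for (z in 0:1) {
      pz <- if (z == 1) psi[i] else 1 - psi[i]
      cond <- 1
      for (j in seq_len(ncol(y))) {
        pd <- z * p[i, j]
        cond <- cond * ifelse(y[i, j] == 1, pd, 1 - pd)
      }
      li <- li + pz * cond
    }
    ll <- ll + log(li)
  }
  -ll
}

# random dataset + designs + params for likelihood fuzzing
random_occu_case <- function(n, J) {
  kpsi <- sample(1:3, 1)
  kp <- sample(1:2, 1)
  X_psi <- cbind(1, matrix(rnorm(n * (kpsi - 1)), n))
  X_p <- lapply(seq_len(J), function(j) cbind(1, matrix(rnorm(n * (kp - 1)), n)))
  params <- runif(kpsi + kp, -2, 2)
  psi <- plogis(drop(X_psi %*% params[1:kpsi]))
  p <- vapply(X_p, function(X) plogis(drop(X %*% params[-(1:kpsi)])), numeric(n))
  p <- matrix(p, nrow = n)
  y <- matrix(rbinom(n * J, 1, 0.5), n, J)
  list(params = params, X_psi = X_psi, X_p = X_p, y = y, psi = psi, p = p)
}

# brute-force AUC: pair enumeration with shared ties
auc_bruteforce <- function(obs, pred) {
  pos <- pred[obs == 1]
  neg <- pred[obs == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# direct double-loop Moran's I with inverse-distance weights
morans_i_direct <- function(r, coords) {
  n <- length(r)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) w[i, j] <- 1 / sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  rc <- r - mean(r)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * rc[i] * rc[j]
  (n / sum(w)) * num / sum(rc^2)
}

# axis-aligned rectangle polygon helper (open ring)
rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
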