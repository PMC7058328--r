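make_profile <- function(variable, scales, rn2) {
  out <- tibble::tibble(
    variable = variable, scale = scales, rn2 = rn2,
    sign = "+", aic = 0, converged = TRUE, ok = TRUE
  )
  attr(out, "scale_of_effect") <- scales[which.max(rn2)]
  class(out) <- c("scale_profile", class(out))
  out
}

test_that("scale profiles cover every scale and recover a strong true scale", {
  sim <- simulate_scale_data(200, true_scale = 250, beta1 = 2, seed = 21)
  prof <- scale_profile_scan(sim$data, "habitat")
  expect_equal(nrow(prof), 10)
  expect_equal(prof$scale, default_scales())
  expect_true(scale_of_effect(prof) %in% default_scales())
  expect_equal(scale_of_effect(prof), 250)
  expect_true(attr(prof, "complete"))
})

test_that("exact ties across scales resolve to the smallest scale", {
  sim <- simulate_scale_data(80, scales = c(50, 150, 250), true_scale = 150, seed = 4)
  data <- sim$data
  # make every scale carry the identical covariate: all fits tie exactly
  data$habitat_150 <- data$habitat_50
  data$habitat_250 <- data$habitat_50
  prof <- scale_profile_scan(data, "habitat", scales = c(50, 150, 250))
  expect_equal(scale_of_effect(prof), 50)
})

test_that("a failing scale leaves the profile incomplete but scanned", {
  sim <- simulate_scale_data(60, scales = c(50, 150), true_scale = 50, seed = 9)
  data <- sim$data
  data$habitat_150 <- NULL # missing column -> that scale fails
  prof <- scale_profile_scan(data, "habitat", scales = c(50, 150))
  expect_equal(nrow(prof), 2)
  expect_false(attr(prof, "complete"))
  expect_false(prof$ok[prof$scale == 150])
  expect_equal(scale_of_effect(prof), 50)
})

test_that("collinearity screening drops the weaker member of correlated pairs", {
  set.seed(10)
  n <- 200
  x1 <- rnorm(n)
  tbl <- tibble::tibble(
    a = x1,
    b = x1 + rnorm(n, 0, 0.05), # near-duplicate of a
    c = rnorm(n),
    d = rnorm(n)
  )
  out <- collinearity_filter(
    tbl, c("a", "b", "c", "d"),
    strengths = c(a = 0.5, b = 0.2, c = 0.3, d = 0.1)
  )
  expect_true("a" %in% out$retained)
  expect_false("b" %in% out$retained)
  expect_setequal(out$retained, c("a", "c", "d"))
  expect_true(all(out$vif$vif < 10))
  # an exactly duplicated column has |rs| = 1
  dup <- collinearity_filter(
    tibble::tibble(a = x1, b = x1, c = rnorm(n)),
    c("a", "b", "c"),
    strengths = c(a = 0.4, b = 0.1, c = 0.2)
  )
  expect_equal(abs(dup$correlated_pairs$rs[1]), 1)
  expect_false("b" %in% dup$retained)
})

test_that("flagged pairs are preserved for model sets instead of dropped", {
  set.seed(11)
  x <- rnorm(100)
  tbl <- tibble::tibble(np_dist = x, prox = x + rnorm(100, 0, 0.1), h = rnorm(100))
  out <- collinearity_filter(
    tbl, c("np_dist", "prox", "h"),
    strengths = c(np_dist = 0.3, prox = 0.2, h = 0.1),
    flagged_pairs = list(c("np_dist", "prox"))
  )
  expect_true(all(c("np_dist", "prox") %in% out$retained))
  expect_true(out$correlated_pairs$flagged[1])
})

test_that("Spearman matrix equals the rank-formula hand computation", {
  tbl <- tibble::tibble(
    u = c(3, 1, 4, 1.5, 9, 2.6),
    v = c(2, 7, 1, 8, 2.8, 1.8)
  )
  out <- suppressWarnings(collinearity_filter(
    tbl, c("u", "v"),
    strengths = c(u = 1, v = 0), rs_threshold = 0.99
  ))
  ru <- rank(tbl$u); rv <- rank(tbl$v)
  hand <- sum((ru - mean(ru)) * (rv - mean(rv))) /
    sqrt(sum((ru - mean(ru))^2) * sum((rv - mean(rv))^2))
  expect_equal(out$spearman["u", "v"], hand)
})

test_that("VIF is 1 for orthogonal columns and prunes aliased sets, matching car", {
  set.seed(12)
  q <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  tbl <- tibble::as_tibble(as.data.frame(q)) |>
    rlang::set_names(c("o1", "o2", "o3"))
  out <- collinearity_filter(tbl, c("o1", "o2", "o3"),
    strengths = c(o1 = 1, o2 = 1, o3 = 1)
  )
  expect_equal(out$vif$vif, rep(1, 3), tolerance = 1e-6)
  # cross-check against car::vif on an arbitrary response
  X <- tibble::tibble(
    a = rnorm(100), b = rnorm(100)
  ) |> dplyr::mutate(c = a + b + rnorm(100, 0, 0.5))
  ours <- scaleocc:::vif_from_cor(stats::cor(as.matrix(X)))
  y <- rnorm(100)
  theirs <- car::vif(stats::lm(y ~ a + b + c, data = X))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
  # zero-variance column is excluded with a warning
  expect_warning(
    collinearity_filter(
      dplyr::mutate(X, k = 1), c("a", "b", "k"),
      strengths = c(a = 1, b = 1, k = 1)
    ),
    "zero-variance"
  )
})

test_that("model sets enumerate one member per flagged pair", {
  roster <- c("dist_river", "area", "np_dist", "prox", "crop_pas", "urban")
  four <- build_model_sets(
    list(c("np_dist", "prox"), c("crop_pas", "urban")),
    roster
  )
  expect_equal(nrow(four), 4)
  for (i in 1:4) {
    m <- four$members[[i]]
    expect_equal(sum(c("np_dist", "prox") %in% m), 1)
    expect_equal(sum(c("crop_pas", "urban") %in% m), 1)
    expect_true(all(c("dist_river", "area") %in% m))
  }
  two <- build_model_sets(list(c("np_dist", "prox")), roster)
  expect_equal(nrow(two), 2)
  one <- build_model_sets(list(), roster)
  expect_equal(nrow(one), 1)
  expect_equal(one$members[[1]], roster)
  expect_error(build_model_sets(list(), character()), "empty")
  expect_error(
    build_model_sets(list(c("a", "b"), c("b", "c")), c("a", "b", "c")),
    "two flagged pairs"
  )
})

test_that("global models resolve composition terms by scale label", {
  members <- c("habitat", "urban", "np_dist", "veg_str")
  ss <- assemble_global_model(members, 150)
  expect_equal(ss, c("habitat_150", "urban_150", "np_dist", "veg_str"))
  profiles <- list(
    habitat = make_profile("habitat", c(500, 2000), c(0.1, 0.4)),
    urban = make_profile("urban", c(500, 2000), c(0.3, 0.2))
  )
  ms <- assemble_global_model(members, "ms", profiles)
  expect_equal(ms, c("habitat_2000", "urban_500", "np_dist", "veg_str"))
  expect_error(
    assemble_global_model(c("crop_pas"), "ms", profiles),
    "no scale profile"
  )
})

test_that("all-subsets selection fits 2^k x 2^kp models and flags the competitive set", {
  sim <- simulate_occupancy_data(
    120,
    psi_coefs = c("(Intercept)" = 0, x1 = 1.5, x2 = 0),
    p_coefs = c("(Intercept)" = 1, w = 0.5),
    seed = 31
  )
  res <- all_subsets_selection(sim$data, c("x1", "x2"), c("w"))
  expect_equal(nrow(res), 4 * 2)
  expect_equal(res$delta[1], 0)
  expect_true(res$selected[1])
  expect_true(all(res$delta >= 0))
  expect_true(all(res$selected == (res$delta < 2)))
  # cross-module consistency: the null subset reproduces the null fit's AIC
  null_fit <- fit_occupancy(sim$data)
  null_row <- res[res$psi_label == "(intercept)" & res$p_label == "(intercept)", ]
  expect_equal(null_row$AIC, null_fit$aic, tolerance = 1e-6)
  # a fixed term appears in every candidate
  fixed <- all_subsets_selection(sim$data, c("x1"), c("w"), fixed_psi = "x2")
  expect_true(all(vapply(fixed$psi_terms, function(t) "x2" %in% t, logical(1))))
  expect_equal(nrow(fixed), 2 * 2)
  expect_error(
    all_subsets_selection(sim$data, c("x1", "x2"), "w", guard = 3),
    "guard"
  )
  expect_error(
    all_subsets_selection(sim$data, "nope", "w"),
    "missing from data"
  )
})
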