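# Scale-of-effect scans, collinearity screening, single-scale/multi-scale
# model-set construction and all-subsets AIC selection.

#' Univariate scale-of-effect profile
#'
#' Fits one univariate occupancy model per buffer scale for a composition
#' (or proximity) variable, with the detection structure fixed to the
#' standard three covariates, and locates the scale of effect: the scale
#' with the highest Nagelkerke R-squared, ties broken to the smallest
#' scale.
#'
#' @param data detection tibble with `<variable>_<scale>` columns.
#' @param variable variable name stem (e.g. `"habitat"`).
#' @param scales buffer scale set (m).
#' @param p_covariates detection covariates held fixed during the scan.
#' @param ... passed to [fit_occupancy()].
#' @return Tibble of class `scale_profile` with one row per scale
#'   (`variable`, `scale`, `rn2`, `sign`, `aic`, `converged`, `ok`) and
#'   attribute `scale_of_effect`. Failed scales are kept as `ok = FALSE`
#'   rows and the profile is marked incomplete.
#' @export
scale_profile_scan <- function(data, variable, scales = default_scales(),
                               p_covariates = c("veg_str", "day", "area"), ...) {
  check_scales(scales)
  null_fit <- fit_occupancy(data, character(), character(), compute_rn2 = FALSE, ...)
  rows <- purrr::map(scales, function(s) {
    col <- paste0(variable, "_", s)
    fit <- tryCatch(
      fit_occupancy(data, col, p_covariates, null_fit = null_fit, ...),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(
        variable = variable, scale = s, rn2 = NA_real_, sign = NA_character_,
        aic = NA_real_, converged = NA, ok = FALSE
      ))
    }
    tibble::tibble(
      variable = variable, scale = s, rn2 = fit$rn2,
      sign = if (fit$beta_psi[col] >= 0) "+" else "-",
      aic = fit$aic, converged = fit$converged, ok = TRUE
    )
  })
  out <- dplyr::bind_rows(rows)
  soe <- if (any(out$ok)) out$scale[which.max(out$rn2)] else NA_real_
  attr(out, "scale_of_effect") <- soe
  attr(out, "complete") <- all(out$ok)
  class(out) <- c("scale_profile", class(out))
  out
}

#' @rdname scale_profile_scan
#' @param profile a `scale_profile`.
#' @export
scale_of_effect <- function(profile) attr(profile, "scale_of_effect")

#' Collinearity screening by Spearman correlation and VIF
#'
#' Identifies variable pairs with `|r_s|` above `rs_threshold`. Pairs
#' declared ecologically important (`flagged_pairs`) are kept for separate
#' model sets; in every other correlated pair the variable with the weaker
#' univariate effect (lower `strengths` value) is dropped, strongest
#' conflicts first. Remaining variables are then pruned iteratively by
#' variance inflation factor (computed from the inverse correlation
#' matrix) until all VIF are below `vif_threshold`. Zero-variance columns
#' are excluded with a warning.
#'
#' @param covariate_table tibble of candidate covariate columns.
#' @param candidate_vars names of the candidate variables.
#' @param strengths named numeric vector of univariate effect strengths
#'   (e.g. Nagelkerke R-squared at each variable's scale of effect).
#' @param rs_threshold Spearman threshold (default 0.60).
#' @param vif_threshold VIF threshold (default 10).
#' @param flagged_pairs list of length-2 character vectors naming pairs to
#'   keep via model sets rather than drop.
#' @return List: `retained`, `dropped` (tibble with reasons),
#'   `correlated_pairs` (tibble `var1`, `var2`, `rs`, `flagged`),
#'   `vif` (tibble for the retained set), `spearman` (full matrix).
#' @export
collinearity_filter <- function(covariate_table, candidate_vars, strengths,
                                rs_threshold = 0.60, vif_threshold = 10,
                                flagged_pairs = list()) {
  if (length(candidate_vars) < 2) stop("need at least two candidate variables")
  X <- as.matrix(covariate_table[candidate_vars])
  sds <- apply(X, 2, stats::sd)
  dropped <- tibble::tibble(variable = character(), reason = character())
  if (any(sds == 0)) {
    warning(
      "excluding zero-variance variable(s): ",
      paste(candidate_vars[sds == 0], collapse = ", ")
    )
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      variable = candidate_vars[sds == 0], reason = "zero variance"
    ))
    candidate_vars <- candidate_vars[sds > 0]
    X <- X[, candidate_vars, drop = FALSE]
  }
  rs <- stats::cor(X, method = "spearman")

  is_flagged <- function(a, b) {
    any(vapply(
      flagged_pairs,
      function(pr) setequal(pr, c(a, b)),
      logical(1)
    ))
  }
  idx <- which(upper.tri(rs) & abs(rs) > rs_threshold, arr.ind = TRUE)
  pair_v1 <- rownames(rs)[idx[, 1]]
  pair_v2 <- colnames(rs)[idx[, 2]]
  pairs <- tibble::tibble(
    var1 = pair_v1,
    var2 = pair_v2,
    rs = rs[idx],
    flagged = purrr::map2_lgl(pair_v1, pair_v2, is_flagged)
  ) |> dplyr::arrange(dplyr::desc(abs(.data$rs)))

  retained <- candidate_vars
  active <- pairs[!pairs$flagged, ]
  while (nrow(active) > 0) {
    pr <- active[1, ]
    weaker <- if ((strengths[pr$var1] %||% 0) >= (strengths[pr$var2] %||% 0)) {
      pr$var2
    } else {
      pr$var1
    }
    retained <- setdiff(retained, weaker)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      variable = weaker,
      reason = sprintf("spearman |rs|=%.2f with %s", abs(pr$rs),
        setdiff(c(pr$var1, pr$var2), weaker))
    ))
    active <- active[active$var1 %in% retained & active$var2 %in% retained, ]
  }

  # iterative VIF pruning on the retained roster. Flagged-pair members are
  # alternates that never co-occur in a model, so only one member per pair
  # enters the VIF computation and neither can be VIF-dropped — their
  # collinearity is what the model sets exist to handle.
  protected <- intersect(unique(unlist(flagged_pairs)), retained)
  vif_roster <- function(vars) {
    for (pr in flagged_pairs) {
      if (all(pr %in% vars)) vars <- setdiff(vars, pr[2])
    }
    vars
  }
  repeat {
    vv <- vif_roster(retained)
    if (length(vv) < 2) break
    v <- vif_values(X[, vv, drop = FALSE])
    removable <- v[setdiff(names(v), protected)]
    if (length(removable) == 0 || max(removable) < vif_threshold) break
    worst <- names(which.max(removable))
    retained <- setdiff(retained, worst)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      variable = worst, reason = sprintf("vif=%.1f", max(removable))
    ))
  }
  vv <- vif_roster(retained)
  vif_tbl <- if (length(vv) >= 2) {
    v <- vif_values(X[, vv, drop = FALSE])
    tibble::tibble(variable = names(v), vif = unname(v))
  } else {
    tibble::tibble(variable = vv, vif = rep(1, length(vv)))
  }
  list(
    retained = retained, dropped = dropped,
    correlated_pairs = pairs, vif = vif_tbl, spearman = rs
  )
}

vif_from_cor <- function(R) diag(solve(R))

# VIF per column as 1/(1 - R^2) from regressing each column on the others;
# robust to exact collinearity (returns Inf instead of failing)
vif_values <- function(X) {
  vapply(stats::setNames(seq_len(ncol(X)), colnames(X)), function(i) {
    yv <- X[, i]
    fit <- stats::lm.fit(cbind(1, X[, -i, drop = FALSE]), yv)
    r2 <- 1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Build candidate model sets from ecologically-flagged correlated pairs
#'
#' One set per combination choosing exactly one member of each flagged
#' pair, keeping all other roster variables — the Cartesian product over
#' pairs: two flagged pairs give four sets, one gives two, none gives the
#' single global set.
#'
#' @param flagged_pairs list of length-2 character vectors.
#' @param roster all variables available for the global model (including
#'   the pair members).
#' @return Tibble with `set_id`, `choice` (label), `members` (list column
#'   of variable rosters).
#' @export
build_model_sets <- function(flagged_pairs, roster) {
  if (length(roster) == 0) stop("empty variable roster")
  all_members <- unlist(flagged_pairs)
  if (anyDuplicated(all_members)) stop("a variable appears in two flagged pairs")
  members <- unique(all_members)
  base <- setdiff(roster, members)
  if (length(flagged_pairs) == 0) {
    return(tibble::tibble(set_id = 1L, choice = "(all)", members = list(roster)))
  }
  combos <- do.call(
    expand.grid,
    c(lapply(flagged_pairs, function(pr) pr), list(stringsAsFactors = FALSE))
  )
  tibble::tibble(
    set_id = seq_len(nrow(combos)),
    choice = apply(combos, 1, paste, collapse = " & "),
    members = purrr::map(seq_len(nrow(combos)), function(i) {
      c(base, unlist(combos[i, ], use.names = FALSE))
    })
  )
}

#' Occupancy terms of a single-scale or multi-scale global model
#'
#' Single-scale (`scale_label` numeric or numeric-string): every
#' composition-type variable in the roster carries that scale's suffix.
#' Multi-scale (`scale_label = "ms"`): each composition-type variable is
#' taken at its own scale of effect, looked up in `profiles`.
#' Configuration, geometry and quality variables pass through unchanged.
#'
#' @param members variable roster of the model set.
#' @param scale_label one of the scales (numeric) or `"ms"`.
#' @param profiles named list of `scale_profile` objects (needed for
#'   `"ms"`), one per scale-dependent variable.
#' @param scaled_vars variables that exist at multiple scales.
#' @return Character vector of occupancy term (column) names.
#' @export
assemble_global_model <- function(members, scale_label, profiles = NULL,
                                  scaled_vars = c("habitat", "crop_pas", "urban", "prox")) {
  vapply(members, function(v) {
    if (!v %in% scaled_vars) return(v)
    if (identical(scale_label, "ms")) {
      if (is.null(profiles[[v]])) {
        stop("no scale profile available for variable '", v, "'")
      }
      paste0(v, "_", scale_of_effect(profiles[[v]]))
    } else {
      paste0(v, "_", scale_label)
    }
  }, character(1), USE.NAMES = FALSE)
}

#' All-subsets occupancy model selection
#'
#' Fits every subset of the occupancy terms crossed with every subset of
#' the detection covariates (2^k_psi x 2^k_p models), computes the AIC
#' difference to the best model, and flags candidates with
#' `delta < delta_threshold` as selected.
#'
#' @param data detection tibble.
#' @param psi_terms occupancy term (column) names of the global model.
#' @param p_terms detection covariates (subsets of these are scanned too).
#' @param delta_threshold retention threshold on the AIC difference
#'   (default 2).
#' @param use_aicc rank by AICc instead of AIC.
#' @param fixed_psi occupancy terms forced into every candidate (e.g. a
#'   spatial autocovariate).
#' @param null_fit optional pre-computed intercept-only fit, reused for
#'   every candidate's Nagelkerke R-squared.
#' @param guard refuse to fit more than this many models.
#' @param ... passed to [fit_occupancy()].
#' @return Tibble with `model_id`, `psi_terms`/`p_terms` (list columns),
#'   labels, `k`, `logLik`, `AIC`, `AICc`, `rn2`, `delta`, `selected`,
#'   `fit` (list column), ordered by `delta`.
#' @export
all_subsets_selection <- function(data, psi_terms,
                                  p_terms = c("veg_str", "day", "area"),
                                  delta_threshold = 2, use_aicc = FALSE,
                                  fixed_psi = character(),
                                  null_fit = NULL, guard = 50000, ...) {
  missing <- setdiff(c(psi_terms, fixed_psi), names(data))
  if (length(missing) > 0) {
    stop("term column(s) missing from data: ", paste(missing, collapse = ", "))
  }
  psi_sets <- lapply(all_subsets(setdiff(psi_terms, fixed_psi)), function(s) {
    c(fixed_psi, s)
  })
  p_sets <- all_subsets(p_terms)
  n_models <- length(psi_sets) * length(p_sets)
  if (n_models > guard) {
    stop(
      n_models, " candidate models exceed the guard (", guard,
      "); reduce the variable roster"
    )
  }
  if (is.null(null_fit)) {
    null_fit <- fit_occupancy(data, character(), character(),
      compute_rn2 = FALSE, ...
    )
  }
  grid <- tidyr::expand_grid(psi = psi_sets, p = p_sets)
  fits <- purrr::map2(grid$psi, grid$p, function(ps, pp) {
    fit_occupancy(data, ps, pp, null_fit = null_fit, ...)
  })
  lbl <- function(terms) {
    vapply(
      terms,
      function(t) if (length(t) == 0) "(intercept)" else paste(t, collapse = "+"),
      character(1)
    )
  }
  crit <- vapply(fits, function(f) if (use_aicc) f$aicc else f$aic, numeric(1))
  out <- tibble::tibble(
    model_id = seq_len(nrow(grid)),
    psi_terms = grid$psi, p_terms = grid$p,
    psi_label = lbl(grid$psi), p_label = lbl(grid$p),
    k = vapply(fits, function(f) f$n_params, numeric(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    AIC = vapply(fits, function(f) f$aic, numeric(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    rn2 = vapply(fits, function(f) f$rn2, numeric(1)),
    delta = crit - min(crit),
    fit = fits
  ) |>
    dplyr::mutate(selected = .data$delta < delta_threshold) |>
    dplyr::arrange(.data$delta)
  out
}
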