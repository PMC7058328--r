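# Confusion-matrix evaluation of selected models: PCC, AUC, Cohen's kappa
# at 0.5 and at the kappa-optimal threshold. "Observed presence" is naive
# occupancy (detected in at least one survey); "predicted" is the
# unconditional occupancy probability psi_hat.

#' Confusion matrix, PCC and kappa at one threshold
#'
#' Predicted presence is `psi >= threshold`. PCC is `(TP + TN)/n`; kappa
#' is `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the
#' marginal products. If both marginals are degenerate (`p_e = 1`), kappa
#' is 1 for perfect agreement and an error otherwise.
#'
#' @param observed binary vector of observed presence/absence.
#' @param predicted_psi occupancy probabilities, same length.
#' @param threshold classification threshold in \[0, 1\].
#' @return One-row tibble: `threshold`, `tp`, `fp`, `fn`, `tn`, `pcc`,
#'   `kappa`.
#' @export
classification_indices <- function(observed, predicted_psi, threshold = 0.5) {
  stopifnot(
    length(observed) == length(predicted_psi),
    threshold >= 0, threshold <= 1,
    all(observed %in% c(0, 1))
  )
  pred <- as.integer(predicted_psi >= threshold)
  tp <- sum(pred == 1 & observed == 1)
  fp <- sum(pred == 1 & observed == 0)
  fn <- sum(pred == 0 & observed == 1)
  tn <- sum(pred == 0 & observed == 0)
  n <- length(observed)
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  kappa <- if (abs(1 - pe) < 1e-12) {
    if (po == 1) 1 else stop("degenerate marginals with imperfect agreement: kappa undefined")
  } else {
    (po - pe) / (1 - pe)
  }
  tibble::tibble(
    threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn,
    pcc = po, kappa = kappa
  )
}

#' Rank-based AUC
#'
#' Area under the ROC curve by the Mann-Whitney statistic: the probability
#' that a randomly chosen presence site outranks a randomly chosen absence
#' site, with ties shared.
#'
#' @inheritParams classification_indices
#' @return Scalar AUC in `[0, 1]`.
#' @export
auc_rank <- function(observed, predicted_psi) {
  stopifnot(length(observed) == length(predicted_psi))
  n1 <- sum(observed == 1)
  n0 <- sum(observed == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both presence and absence sites")
  r <- rank(predicted_psi)
  (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kappa-optimal classification threshold
#'
#' Evaluates Cohen's kappa at each of the 101 thresholds 0, 0.01, ..., 1
#' and returns the maximum and the smallest threshold attaining it.
#'
#' @inheritParams classification_indices
#' @return List: `kappa_opt`, `opt_threshold`, `grid` (101-row tibble of
#'   per-threshold indices).
#' @export
optimize_kappa_threshold <- function(observed, predicted_psi) {
  thresholds <- seq(0, 1, by = 0.01)
  grid <- purrr::map(
    thresholds,
    function(t) classification_indices(observed, predicted_psi, t)
  ) |> dplyr::bind_rows()
  best <- max(grid$kappa)
  list(
    kappa_opt = best,
    opt_threshold = grid$threshold[which(grid$kappa >= best - 1e-12)[1]],
    grid = grid
  )
}

#' Evaluation report for a fitted occupancy model
#'
#' Computes PCC and kappa at threshold 0.5, the rank-based AUC, and the
#' kappa-optimal threshold, using naive occupancy (detected at least once)
#' as the observed state and the fitted unconditional `psi_hat` as the
#' prediction.
#'
#' @param fit an `occu_fit`.
#' @return One-row tibble: `pcc`, `auc`, `kappa_05`, `kappa_opt`,
#'   `opt_threshold`.
#' @export
evaluate_model <- function(fit) {
  obs <- as.integer(rowSums(fit$y) > 0)
  psi <- fit$psi_hat
  at05 <- classification_indices(obs, psi, 0.5)
  opt <- optimize_kappa_threshold(obs, psi)
  tibble::tibble(
    pcc = at05$pcc,
    auc = auc_rank(obs, psi),
    kappa_05 = at05$kappa,
    kappa_opt = opt$kappa_opt,
    opt_threshold = opt$opt_threshold
  )
}

#' Predicted-occupancy curve along one covariate
#'
#' Varies one occupancy covariate over a grid (original units) with every
#' other covariate held at its training mean, and returns the predicted
#' occupancy probability.
#'
#' @param fit an `occu_fit`.
#' @param variable occupancy covariate name.
#' @param grid numeric grid in original units; defaults to 100 points over
#'   the training range.
#' @return Tibble of class `psi_curve` with columns `variable` (name),
#'   `value`, `psi`.
#' @export
prediction_curve <- function(fit, variable, grid = NULL) {
  if (!variable %in% fit$psi_covariates) {
    stop("'", variable, "' is not an occupancy covariate of this fit")
  }
  sc <- fit$scaling[[variable]]
  if (is.null(grid)) {
    # training range in original units, recovered from the stored scaling
    xz <- fit$X_psi[, variable]
    x <- xz * sc["sd"] + sc["mean"]
    grid <- seq(min(x), max(x), length.out = 100)
  }
  nd <- stats::setNames(data.frame(grid), variable)
  out <- tibble::tibble(
    variable = variable, value = grid,
    psi = predict(fit, nd)
  )
  class(out) <- c("psi_curve", class(out))
  out
}
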