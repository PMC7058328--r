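# Residual spatial autocorrelation diagnostics and the PCNM autocovariate.

# run seeded code without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Conditional-occupancy residuals of a fit
#'
#' Residual for site i is `z*_i - psi_hat_i`, where `z*_i` is the
#' conditional occupancy estimate: 1 for sites with at least one
#' detection, and otherwise the posterior probability of occupancy given
#' an all-zero history, `psi q / (psi q + 1 - psi)` with
#' `q = prod_j (1 - p_ij)`.
#'
#' @param fit an `occu_fit`.
#' @return Numeric residual vector.
#' @export
occupancy_residuals <- function(fit) {
  q <- exp(rowSums(log(1 - fit$p_hat)))
  zstar <- ifelse(
    rowSums(fit$y) > 0, 1,
    fit$psi_hat * q / (fit$psi_hat * q + 1 - fit$psi_hat)
  )
  zstar - fit$psi_hat
}

#' Global Moran's I with a permutation test
#'
#' `I = (n / S0) * sum_ij w_ij (r_i - rbar)(r_j - rbar) / sum_i (r_i -
#' rbar)^2` with inverse-Euclidean-distance weights between patch
#' centroids and a zero diagonal. The p-value is two-sided against the
#' permutation distribution of I under random relabelling of the
#' residuals, centred on the null expectation `-1/(n-1)`.
#'
#' @param residuals numeric vector (finite, not constant).
#' @param centroids n x 2 coordinate matrix (m).
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return List: `morans_i`, `expected_i`, `p_value`, `n_permutations`.
#' @export
global_morans_i <- function(residuals, centroids, n_permutations = 999, seed = 1) {
  n <- length(residuals)
  if (n < 4) stop("need at least 4 sites for Moran's I")
  if (any(!is.finite(residuals))) stop("non-finite residuals")
  if (stats::sd(residuals) == 0) stop("constant residuals: Moran's I undefined")
  d <- as.matrix(stats::dist(centroids))
  if (any(d[upper.tri(d)] == 0)) stop("coincident centroids give infinite weights")
  w <- 1 / d
  diag(w) <- 0
  s0 <- sum(w)
  stat <- function(r) {
    rc <- r - mean(r)
    (n / s0) * drop(rc %*% w %*% rc) / sum(rc^2)
  }
  i_obs <- stat(residuals)
  e_i <- -1 / (n - 1)
  i_perm <- with_local_seed(seed, vapply(
    seq_len(n_permutations),
    function(b) stat(residuals[sample.int(n)]),
    numeric(1)
  ))
  p <- (1 + sum(abs(i_perm - e_i) >= abs(i_obs - e_i))) / (n_permutations + 1)
  list(
    morans_i = i_obs, expected_i = e_i, p_value = p,
    n_permutations = n_permutations
  )
}

#' PCNM spatial autocovariate
#'
#' Principal coordinates of neighbour matrices: the intersite distance
#' matrix is truncated at the longest edge of its minimum spanning tree
#' (larger distances replaced by four times the truncation distance), the
#' doubly-centred `-D^2/2` matrix is eigen-decomposed, and the
#' eigenvectors with positive eigenvalues are the spatial axes (computed
#' with `vegan::pcnm`). The autocovariate returned is the retained
#' eigenvector with the largest absolute Spearman correlation with the
#' residuals.
#'
#' @param centroids n x 2 coordinate matrix (m).
#' @param residuals numeric residual vector (see [occupancy_residuals()]).
#' @return List: `autocovariate` (numeric vector), `eigenvalues`
#'   (descending), `vectors` (matrix of retained axes), `selected` (index
#'   of the chosen axis), `correlation` (its Spearman correlation),
#'   `threshold` (truncation distance).
#' @export
pcnm_autocovariate <- function(centroids, residuals) {
  n <- nrow(centroids)
  if (n < 4) stop("need at least 4 sites for PCNM")
  d <- stats::dist(centroids)
  if (max(d) == 0) stop("all pairwise distances are zero")
  pc <- vegan::pcnm(d)
  vecs <- as.matrix(pc$vectors)
  vals <- pc$values[seq_len(ncol(vecs))]
  if (ncol(vecs) == 0) stop("no positive PCNM eigenvalue")
  cors <- apply(vecs, 2, function(v) {
    suppressWarnings(stats::cor(v, residuals, method = "spearman"))
  })
  sel <- unname(which.max(abs(cors)))
  list(
    autocovariate = unname(vecs[, sel]), eigenvalues = unname(vals), vectors = vecs,
    selected = sel, correlation = cors[sel], threshold = pc$threshold
  )
}

#' Spatial autocorrelation check for a fitted model
#'
#' Computes conditional-occupancy residuals, tests them with
#' [global_morans_i()], and — when the test is significant at `alpha` —
#' attaches the [pcnm_autocovariate()].
#'
#' @param fit an `occu_fit`.
#' @param centroids n x 2 patch centroid matrix (m).
#' @param alpha significance level for adding the autocovariate.
#' @param n_permutations,seed passed to [global_morans_i()].
#' @return List of class `spatial_diagnostics`: `morans_i`, `expected_i`,
#'   `p_value`, `significant`, `autocovariate` (or `NULL`),
#'   `pcnm_eigenvalues` (or `NULL`).
#' @export
spatial_autocorrelation_check <- function(fit, centroids, alpha = 0.05,
                                          n_permutations = 999, seed = 1) {
  res <- occupancy_residuals(fit)
  mi <- global_morans_i(res, centroids, n_permutations = n_permutations, seed = seed)
  sig <- mi$p_value < alpha
  pc <- if (sig) pcnm_autocovariate(centroids, res) else NULL
  structure(
    list(
      morans_i = mi$morans_i, expected_i = mi$expected_i,
      p_value = mi$p_value, significant = sig,
      autocovariate = pc$autocovariate,
      pcnm_eigenvalues = pc$eigenvalues
    ),
    class = "spatial_diagnostics"
  )
}

#' @export
print.spatial_diagnostics <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (E[I] = %.4f), permutation p = %.4f — %s\n",
    x$morans_i, x$expected_i, x$p_value,
    if (x$significant) "significant; PCNM autocovariate built" else "not significant"
  ))
  invisible(x)
}
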