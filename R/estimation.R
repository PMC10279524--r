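#' Default tuning-parameter grid
#'
#' The conventional grid for Storey-type tail estimators,
#' `0.05, 0.10, ..., 0.95`. Any strictly increasing vector in `(0, 1)`
#' may be supplied instead wherever a grid is accepted.
#'
#' @return numeric vector of lambda values.
#' @export
lambda_grid <- function() seq(0.05, 0.95, by = 0.05)

check_lambda <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam <= 0 || lam >= 1) {
    stop("`lambda` must be a single value in (0, 1)", call. = FALSE)
  }
  lam
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || !length(grid) ||
      any(grid <= 0 | grid >= 1) || is.unsorted(grid, strictly = TRUE)) {
    stop("lambda grid must be strictly increasing with values in (0, 1)",
         call. = FALSE)
  }
  grid
}

#' Storey tail estimator of the null proportion
#'
#' Raw estimate \eqn{\hat\pi_0(\lambda) = \#\{p_i \ge \lambda\} /
#' (m(1-\lambda))} of the proportion of null hypotheses in one p-value
#' sequence. The raw value can exceed 1; clipping is applied downstream.
#'
#' @param p numeric vector of p-values.
#' @param lam tuning parameter lambda in `(0, 1)`.
#' @return raw (unclipped) estimate.
#' @export
storey_pi0 <- function(p, lam) {
  check_lambda(lam)
  stopifnot(is.numeric(p), length(p) >= 1L)
  sum(p >= lam) / (length(p) * (1 - lam))
}

#' Joint-tail estimator of the double-null proportion
#'
#' Raw estimate \eqn{\hat\xi_{00}(\lambda) = \#\{p_{1i} \ge \lambda,
#' p_{2i} \ge \lambda\} / (m(1-\lambda)^2)} of the probability that a
#' feature is null in both studies.
#'
#' @param pairs a [paired_pvalues] object.
#' @param lam tuning parameter lambda in `(0, 1)`.
#' @return raw (unclipped) estimate.
#' @export
estimate_xi00 <- function(pairs, lam) {
  check_lambda(lam)
  stopifnot(inherits(pairs, "paired_pvalues"))
  m <- length(pairs$p1)
  sum(pairs$p1 >= lam & pairs$p2 >= lam) / (m * (1 - lam)^2)
}

#' Smoothing-spline selection over the lambda grid
#'
#' Fits a cubic smoothing spline with 3 effective degrees of freedom to
#' raw estimates computed over a lambda grid and returns the fitted value
#' at the largest lambda, clipped to `[0, 1]`. With fewer than 4 grid
#' points the spline cannot be fit and the raw estimate at the largest
#' lambda is returned with a warning.
#'
#' @param estimates numeric vector of raw estimates, one per grid point.
#' @param grid lambda grid (same length as `estimates`).
#' @return selected estimate in `[0, 1]`.
#' @export
smooth_select <- function(estimates, grid) {
  check_grid(grid)
  stopifnot(length(estimates) == length(grid))
  if (length(grid) < 4L) {
    warning("fewer than 4 lambda grid points; using the estimate at max(lambda)",
            call. = FALSE)
    est <- estimates[length(estimates)]
  } else {
    fit <- stats::smooth.spline(grid, estimates, df = 3)
    est <- stats::predict(fit, x = max(grid))$y
  }
  min(max(est, 0), 1)
}

#' Estimate the four-group proportions from paired p-values
#'
#' Computes smoothed Storey estimates of the per-study null proportions
#' \eqn{\hat\pi_0^{(1)}, \hat\pi_0^{(2)}} and of the double-null
#' proportion \eqn{\hat\xi_{00}}, then derives
#' \eqn{\hat\xi_{01} = \hat\pi_0^{(1)} - \hat\xi_{00}},
#' \eqn{\hat\xi_{10} = \hat\pi_0^{(2)} - \hat\xi_{00}} and
#' \eqn{\hat\xi_{11}} as the remainder. \eqn{\hat\xi_{00}} is clipped into
#' the Frechet–Hoeffding interval
#' \eqn{[\max(0, \hat\pi_0^{(1)} + \hat\pi_0^{(2)} - 1),
#'       \min(\hat\pi_0^{(1)}, \hat\pi_0^{(2)})]}
#' so that all four components are valid probabilities.
#'
#' @param pairs a [paired_pvalues] object.
#' @param grid lambda grid for the smoother; default [lambda_grid()].
#' @param fixed_lambda optional single lambda in `(0, 1)`; when given,
#'   smoothing is bypassed and raw estimates at this lambda are used.
#' @param smoothing logical; set `FALSE` to use the raw estimate at the
#'   largest grid value instead of the spline fit.
#' @return An object of class `proportion_estimates`: list with
#'   `pi0_study1`, `pi0_study2`, `joint` (a [four_group_proportions]),
#'   and `lambdas_used`.
#' @examples
#' set.seed(1)
#' pp <- paired_pvalues(1:2000, runif(2000), runif(2000))
#' estimate_proportions(pp)
#' @export
estimate_proportions <- function(pairs, grid = lambda_grid(),
                                 fixed_lambda = NULL, smoothing = TRUE) {
  stopifnot(inherits(pairs, "paired_pvalues"))
  if (!is.null(fixed_lambda)) {
    check_lambda(fixed_lambda)
    pi0_1 <- storey_pi0(pairs$p1, fixed_lambda)
    pi0_2 <- storey_pi0(pairs$p2, fixed_lambda)
    xi00 <- estimate_xi00(pairs, fixed_lambda)
    lambdas <- c(lambda1 = fixed_lambda, lambda2 = fixed_lambda,
                 lambda3 = fixed_lambda)
  } else {
    check_grid(grid)
    raw1 <- vapply(grid, function(l) storey_pi0(pairs$p1, l), numeric(1))
    raw2 <- vapply(grid, function(l) storey_pi0(pairs$p2, l), numeric(1))
    raw00 <- vapply(grid, function(l) estimate_xi00(pairs, l), numeric(1))
    if (smoothing) {
      pi0_1 <- smooth_select(raw1, grid)
      pi0_2 <- smooth_select(raw2, grid)
      xi00 <- smooth_select(raw00, grid)
    } else {
      pi0_1 <- raw1[length(grid)]
      pi0_2 <- raw2[length(grid)]
      xi00 <- raw00[length(grid)]
    }
    lmax <- max(grid)
    lambdas <- c(lambda1 = lmax, lambda2 = lmax, lambda3 = lmax)
  }
  pi0_1 <- min(max(pi0_1, 0), 1)
  pi0_2 <- min(max(pi0_2, 0), 1)
  lo <- max(0, pi0_1 + pi0_2 - 1)
  hi <- min(pi0_1, pi0_2)
  xi00 <- min(max(xi00, lo), hi)
  xi01 <- pi0_1 - xi00
  xi10 <- pi0_2 - xi00
  xi11 <- max(0, 1 - xi00 - xi01 - xi10)
  # renormalise away accumulated floating-point drift
  tot <- xi00 + xi01 + xi10 + xi11
  joint <- four_group_proportions(xi00 / tot, xi01 / tot, xi10 / tot,
                                  xi11 / tot)
  structure(
    list(
      pi0_study1 = pi0_1,
      pi0_study2 = pi0_2,
      joint = joint,
      lambdas_used = lambdas
    ),
    class = "proportion_estimates"
  )
}

#' @export
print.proportion_estimates <- function(x, ...) {
  cat("Estimated null proportions\n")
  cat(sprintf("  pi0 study 1: %.4f   pi0 study 2: %.4f\n",
              x$pi0_study1, x$pi0_study2))
  print(x$joint)
  cat(sprintf("  lambdas used: %s\n",
              paste(format(x$lambdas_used), collapse = ", ")))
  invisible(x)
}
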