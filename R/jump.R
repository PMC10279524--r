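#' Maximum p-value statistic
#'
#' The per-feature test statistic for replicability: the larger of the two
#' study p-values, \eqn{q_i = \max(p_{1i}, p_{2i})}. A feature can only be
#' replicable if it is significant in both studies, so a small \eqn{q_i}
#' is evidence against the composite null.
#'
#' @param pairs a [paired_pvalues] object.
#' @return numeric vector of length `m` with values in `[0, 1]`.
#' @export
max_p <- function(pairs) {
  stopifnot(inherits(pairs, "paired_pvalues"))
  pmax(pairs$p1, pairs$p2)
}

#' Composite-null CDF bound for the maximum p-value
#'
#' Upper bound `G(t)` on the conditional CDF of the max-p statistic given
#' the replicability null, derived from the four-group model under
#' standard-uniform null p-values and conditional independence:
#' \deqn{G(t) = \frac{\xi_{00} t^2 + (\xi_{01} + \xi_{10}) t}
#'              {\xi_{00} + \xi_{01} + \xi_{10}}.}
#' `G(t) <= t` always (super-uniformity), with
#' `G(t) - t = xi00 t (t - 1) / (xi00 + xi01 + xi10)`.
#'
#' @param t numeric vector of thresholds in `[0, 1]`.
#' @param props a [four_group_proportions] object; its replicability-null
#'   mass `xi00 + xi01 + xi10` must be positive.
#' @return `G(t)`, same length as `t`.
#' @export
composite_null_cdf <- function(t, props) {
  stopifnot(is.numeric(t), all(t >= 0 & t <= 1))
  nm <- null_mass(props)
  if (nm <= 0) {
    stop("replicability null is empty: xi00 + xi01 + xi10 = 0", call. = FALSE)
  }
  (props[["xi00"]] * t^2 + (props[["xi01"]] + props[["xi10"]]) * t) / nm
}

#' Conservative plug-in FDR estimate at threshold t
#'
#' Estimates the false discovery rate of rejecting all features with
#' `q <= t` by bounding the expected number of composite-null rejections:
#' \deqn{\widehat{FDR}^*(t) = \frac{m(\hat\xi_{00} t^2 + \hat\xi_{01} t +
#'   \hat\xi_{10} t)}{R(t) \vee 1},}
#' where `R(t)` is the observed number of max-p statistics at or below `t`.
#'
#' @param t numeric vector of thresholds in `[0, 1]`.
#' @param q numeric vector of max-p statistics (length `m`).
#' @param props a [four_group_proportions] object (estimated or oracle).
#' @return the FDR estimate for each `t`.
#' @export
fdr_star <- function(t, q, props) {
  stopifnot(is.numeric(t), all(t >= 0 & t <= 1), is.numeric(q))
  m <- length(q)
  qs <- sort(q)
  r <- findInterval(t, qs)  # number of q <= t
  m * (props[["xi00"]] * t^2 +
         (props[["xi01"]] + props[["xi10"]]) * t) / pmax(r, 1)
}

#' Data-adaptive rejection threshold
#'
#' The largest threshold `t` at which the plug-in FDR estimate stays at or
#' below `alpha`. The supremum is attained at an observed order statistic
#' of `q`, so the search is restricted to those values (the step-up form);
#' if no order statistic qualifies, the threshold is 0 and nothing is
#' rejected.
#'
#' @inheritParams fdr_star
#' @param alpha nominal FDR level in `(0, 1)`.
#' @return scalar threshold `t_m` in `[0, 1]`.
#' @seealso [jump_test()] for the full step-up procedure.
#' @export
find_threshold <- function(q, props, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  qs <- sort(q)
  fdr <- fdr_star(qs, q, props)
  ok <- which(fdr <= alpha)
  if (!length(ok)) return(0)
  qs[max(ok)]
}

#' Replicability analysis by the step-up max-p procedure
#'
#' Runs the full decision rule: orders the max-p statistics
#' \eqn{q_{(1)} \le \dots \le q_{(m)}}, finds the largest rank
#' \eqn{\hat k = \max\{i : \widehat{FDR}^*(q_{(i)}) \le \alpha\}}, and
#' rejects every feature with \eqn{q_i \le q_{(\hat k)}} (ties included).
#' Per-feature adjusted replicability values are the running minimum, from
#' the largest `q` downward, of the plug-in FDR estimate at each order
#' statistic, capped at 1 — analogous to BH adjusted p-values, so that a
#' feature is rejected at level `alpha` iff its adjusted value is
#' `<= alpha`.
#'
#' @param pairs a [paired_pvalues] object. Alternatively supply `q`
#'   directly and leave `pairs` missing.
#' @param props a [four_group_proportions] object, typically from
#'   [estimate_proportions()]; supply the true proportions for the oracle
#'   procedure.
#' @param alpha nominal FDR level in `(0, 1)`; default 0.05.
#' @param q optional numeric vector of max-p statistics, used instead of
#'   `max_p(pairs)` when given.
#' @return An object of class `jump_result`: list with `feature_ids`, `q`,
#'   `adjusted`, `rejected`, `threshold`, `alpha`, `proportions`,
#'   `n_rejected`.
#' @examples
#' pp <- paired_pvalues(paste0("g", 1:3), c(0.01, 0.2, 0.5), c(0.005, 0.1, 0.4))
#' jump_test(pp, four_group_proportions(1, 0, 0, 0), alpha = 0.05)
#' @export
jump_test <- function(pairs = NULL, props, alpha = 0.05, q = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (is.null(q)) {
    q <- max_p(pairs)
    ids <- pairs$feature_ids
  } else {
    ids <- if (!is.null(pairs)) pairs$feature_ids else as.character(seq_along(q))
  }
  m <- length(q)
  ord <- order(q)
  qs <- q[ord]
  fdr_at_orderstats <- fdr_star(qs, q, props)
  adj_sorted <- rev(cummin(rev(pmin(fdr_at_orderstats, 1))))
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  ok <- which(fdr_at_orderstats <= alpha)
  threshold <- if (length(ok)) qs[max(ok)] else 0
  rejected <- if (length(ok)) q <= threshold else rep(FALSE, m)
  structure(
    list(
      feature_ids = ids,
      q = q,
      adjusted = adjusted,
      rejected = rejected,
      threshold = threshold,
      alpha = alpha,
      proportions = props,
      n_rejected = sum(rejected)
    ),
    class = "jump_result"
  )
}

#' @export
print.jump_result <- function(x, ...) {
  cat("Replicability analysis (max-p step-up procedure)\n")
  cat(sprintf("  features: %d   alpha: %g\n", length(x$q), x$alpha))
  cat(sprintf("  estimated null mass: %.4f (xi00 = %.4f)\n",
              null_mass(x$proportions), x$proportions[["xi00"]]))
  cat(sprintf("  threshold t_m: %.6g   rejections: %d\n",
              x$threshold, x$n_rejected))
  invisible(x)
}
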