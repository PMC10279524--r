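baseline_result <- function(method_name, rejected, adjusted = NULL) {
  structure(
    list(method_name = method_name, rejected = rejected, adjusted = adjusted),
    class = "baseline_result"
  )
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("%s: %d of %d features rejected\n",
              x$method_name, sum(x$rejected), length(x$rejected)))
  invisible(x)
}

#' Benjamini–Hochberg step-up procedure
#'
#' Standard BH: with ordered p-values \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' find the largest rank `i0` with \eqn{p_{(i_0)} \le \alpha i_0 / m} and
#' reject all hypotheses with p-value at or below \eqn{p_{(i_0)}}.
#' Adjusted values are the usual running minimum of `m p_(i) / i`, capped
#' at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha nominal FDR level in `(0, 1)`.
#' @return a `baseline_result` with `rejected` and `adjusted`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  m <- length(p)
  ord <- order(p)
  adj_sorted <- rev(cummin(rev(pmin(m * p[ord] / seq_len(m), 1))))
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  baseline_result("bh", adjusted <= alpha, adjusted)
}

#' Ad hoc intersection of per-study BH discoveries
#'
#' Runs BH at level `alpha` separately within each study and declares
#' replicable the features rejected in both. Popular in practice, but it
#' does not control the FDR of the composite replicability null.
#'
#' @param pairs a [paired_pvalues] object.
#' @param alpha nominal FDR level in `(0, 1)`.
#' @return a `baseline_result` (no adjusted values: the rule is a set
#'   intersection, not a per-feature score).
#' @export
adhoc_bh <- function(pairs, alpha = 0.05) {
  r1 <- bh_adjust(pairs$p1, alpha)$rejected
  r2 <- bh_adjust(pairs$p2, alpha)$rejected
  baseline_result("adhoc_bh", r1 & r2)
}

#' BH on the maximum p-value (partial conjunction)
#'
#' Applies BH at level `alpha` to the max-p statistics
#' `q_i = max(p1i, p2i)`. Valid (the max-p statistic is super-uniform
#' under the composite null) but conservative, because it ignores the
#' hidden-state structure.
#'
#' @inheritParams adhoc_bh
#' @return a `baseline_result` with `rejected` and `adjusted`.
#' @export
maxp_bh <- function(pairs, alpha = 0.05) {
  res <- bh_adjust(max_p(pairs), alpha)
  res$method_name <- "maxp"
  res
}

#' Sidak combination of two p-values
#'
#' Per feature, `pc = 1 - (1 - min(p1, p2))^2`: the p-value of the
#' minimum under independent uniforms. A meta-analysis combination —
#' sensitive to a signal in either study, hence invalid for replicability.
#'
#' @param p1,p2 numeric vectors of p-values.
#' @return combined p-value vector.
#' @export
sidak_combine <- function(p1, p2) {
  1 - (1 - pmin(p1, p2))^2
}

#' Lancaster (weighted chi-square) combination of two p-values
#'
#' Per feature, transforms each p-value to an upper-tail chi-square
#' quantile with its study's degrees of freedom, sums, and refers the sum
#' to chi-square with the total degrees of freedom. With the default
#' `df = c(2, 2)` this is exactly Fisher's method,
#' `-2(log p1 + log p2) ~ chi^2_4`.
#'
#' @param p1,p2 numeric vectors of p-values.
#' @param df degrees of freedom per study, length-2 numeric; default
#'   `c(2, 2)`.
#' @return combined p-value vector.
#' @export
lancaster_combine <- function(p1, p2, df = c(2, 2)) {
  stopifnot(length(df) == 2L, all(df > 0))
  stat <- stats::qchisq(p1, df[1], lower.tail = FALSE) +
    stats::qchisq(p2, df[2], lower.tail = FALSE)
  stats::pchisq(stat, sum(df), lower.tail = FALSE)
}

#' Registry of replicability-analysis methods
#'
#' Named list of method functions with common signature
#' `function(pairs, alpha)` returning an object with a logical `rejected`
#' element — the plug-in interface used by the simulation harness
#' ([run_scenario()]). Built-ins: `jump` (estimated proportions), `maxp`,
#' `adhoc_bh`, `sidak_bh`, `lancaster_bh`, `fisher_bh` (alias of
#' `lancaster_bh` at equal weights). External methods can be added to the
#' list before passing it to the harness.
#'
#' @param methods character vector of registry keys; default all.
#' @return named list of functions.
#' @export
replicability_methods <- function(methods = NULL) {
  registry <- list(
    jump = function(pairs, alpha) {
      props <- estimate_proportions(pairs)
      jump_test(pairs, props$joint, alpha)
    },
    maxp = function(pairs, alpha) maxp_bh(pairs, alpha),
    adhoc_bh = function(pairs, alpha) adhoc_bh(pairs, alpha),
    sidak_bh = function(pairs, alpha) {
      res <- bh_adjust(sidak_combine(pairs$p1, pairs$p2), alpha)
      res$method_name <- "sidak_bh"
      res
    },
    lancaster_bh = function(pairs, alpha) {
      res <- bh_adjust(lancaster_combine(pairs$p1, pairs$p2), alpha)
      res$method_name <- "lancaster_bh"
      res
    }
  )
  registry$fisher_bh <- registry$lancaster_bh
  if (is.null(methods)) return(registry)
  unknown <- setdiff(methods, names(registry))
  if (length(unknown)) {
    stop("unknown method(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  registry[methods]
}
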