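#' Two-study Gaussian simulation scenario
#'
#' Generative model for evaluating replicability procedures. Hidden states
#' `(theta1, theta2)` are drawn i.i.d. from the four-group multinomial
#' with proportions `props`; the summary statistic of feature `i` in study
#' `j` is `X_ji ~ N(mu_j * theta_ji, sigma_j^2)`, and the one-sided
#' p-value is `p_ji = 1 - Phi(X_ji / sigma_j)`. A feature is truly
#' replicable iff its state is `(1, 1)`.
#'
#' @param m number of features per replication.
#' @param props true [four_group_proportions].
#' @param mu1,mu2 non-null means (on the raw statistic scale; the
#'   effective z-shift is `mu_j / sigma_j`).
#' @param sigma1,sigma2 standard deviations, positive; default 1.
#' @param alpha nominal FDR level; default 0.05.
#' @param n_reps number of Monte-Carlo replications; default 100.
#' @param seed master integer seed; replication `r` uses a child seed
#'   derived deterministically from `(seed, r)`.
#' @return an object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(m, props, mu1, mu2, sigma1 = 1, sigma2 = 1,
                                alpha = 0.05, n_reps = 100, seed = 1) {
  stopifnot(
    m >= 1, inherits(props, "four_group_proportions"),
    sigma1 > 0, sigma2 > 0, alpha > 0, alpha < 1, n_reps >= 1
  )
  structure(
    list(m = as.integer(m), props = props, mu1 = mu1, mu2 = mu2,
         sigma1 = sigma1, sigma2 = sigma2, alpha = alpha,
         n_reps = as.integer(n_reps), seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

# deterministic child seed for replication r; stays below 2^31
child_seed <- function(seed, rep_index) {
  (as.double(seed) * 48271 + as.double(rep_index) * 16807) %% 2147483647
}

#' Draw hidden states for one replication
#'
#' @param scenario a [simulation_scenario].
#' @param rep_index replication number (>= 1); together with the
#'   scenario's master seed it fixes the RNG state, so states and the
#'   subsequent p-values of a replication are reproducible.
#' @return integer matrix `m x 2` with columns `theta1`, `theta2`.
#' @export
gen_states <- function(scenario, rep_index = 1) {
  set.seed(child_seed(scenario$seed, rep_index))
  xi <- scenario$props
  state <- sample.int(4L, scenario$m, replace = TRUE,
                      prob = c(xi[["xi00"]], xi[["xi01"]],
                               xi[["xi10"]], xi[["xi11"]]))
  cbind(theta1 = as.integer(state %in% c(2L, 4L)),
        theta2 = as.integer(state %in% c(3L, 4L)))
}

#' Generate paired p-values given hidden states
#'
#' Continues the RNG stream set by [gen_states()]; do not reseed between
#' the two calls if reproducibility of the replication is wanted.
#'
#' @param states matrix from [gen_states()].
#' @param scenario a [simulation_scenario].
#' @return list with `pairs` (a [paired_pvalues]) and `h` (logical truth:
#'   `TRUE` iff the state is `(1, 1)`).
#' @export
gen_pvalues <- function(states, scenario) {
  m <- nrow(states)
  x1 <- stats::rnorm(m, scenario$mu1 * states[, "theta1"], scenario$sigma1)
  x2 <- stats::rnorm(m, scenario$mu2 * states[, "theta2"], scenario$sigma2)
  p1 <- stats::pnorm(x1 / scenario$sigma1, lower.tail = FALSE)
  p2 <- stats::pnorm(x2 / scenario$sigma2, lower.tail = FALSE)
  list(
    pairs = paired_pvalues(seq_len(m), p1, p2),
    h = states[, "theta1"] == 1L & states[, "theta2"] == 1L
  )
}

#' False discovery proportion and power of one replication
#'
#' For each method, the false discovery proportion is
#' `#(rejected & !h) / max(1, #rejected)` and the power contribution is
#' `#(rejected & h) / #h`; power is `NA` when the replication contains no
#' truly replicable feature.
#'
#' @param pairs a [paired_pvalues] object.
#' @param truth logical vector, `TRUE` for truly replicable features.
#' @param methods named list of method functions as in
#'   [replicability_methods()].
#' @param alpha nominal FDR level.
#' @return data.frame with columns `method`, `fdp`, `power`.
#' @export
evaluate_replication <- function(pairs, truth, methods, alpha = 0.05) {
  stopifnot(is.logical(truth), length(truth) == length(pairs$p1))
  n_true <- sum(truth)
  rows <- lapply(names(methods), function(nm) {
    rej <- methods[[nm]](pairs, alpha)$rejected
    data.frame(
      method = nm,
      fdp = sum(rej & !truth) / max(1L, sum(rej)),
      power = if (n_true > 0L) sum(rej & truth) / n_true else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Run a simulation scenario
#'
#' Repeats state generation, p-value generation and method evaluation
#' `n_reps` times and averages the per-replication false discovery
#' proportion and power. Deterministic given the scenario seed.
#'
#' @param scenario a [simulation_scenario].
#' @param methods named list of method functions; default the full
#'   registry from [replicability_methods()].
#' @param mc_se logical; also report Monte-Carlo standard errors of the
#'   mean FDR and power (default `TRUE`).
#' @return data.frame, one row per method: `method`, `empirical_fdr`,
#'   `empirical_power`, `n_reps` (and `fdr_se`, `power_se` if requested).
#' @examples
#' sc <- simulation_scenario(
#'   m = 500, props = four_group_proportions(0.9, 0.025, 0.025, 0.05),
#'   mu1 = 3, mu2 = 3, n_reps = 5, seed = 7
#' )
#' run_scenario(sc, replicability_methods(c("jump", "maxp")))
#' @export
run_scenario <- function(scenario, methods = replicability_methods(),
                         mc_se = TRUE) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  per_rep <- vector("list", scenario$n_reps)
  for (r in seq_len(scenario$n_reps)) {
    states <- gen_states(scenario, r)
    sim <- gen_pvalues(states, scenario)
    per_rep[[r]] <- evaluate_replication(sim$pairs, sim$h, methods,
                                         scenario$alpha)
  }
  all_reps <- do.call(rbind, per_rep)
  out <- do.call(rbind, lapply(names(methods), function(nm) {
    sub <- all_reps[all_reps$method == nm, , drop = FALSE]
    n <- nrow(sub)
    res <- data.frame(
      method = nm,
      empirical_fdr = mean(sub$fdp),
      empirical_power = if (all(is.na(sub$power))) NA_real_
                        else mean(sub$power, na.rm = TRUE),
      n_reps = n
    )
    if (mc_se) {
      res$fdr_se <- stats::sd(sub$fdp) / sqrt(n)
      res$power_se <- if (all(is.na(sub$power))) NA_real_
                      else stats::sd(sub$power, na.rm = TRUE) / sqrt(n)
    }
    res
  }))
  rownames(out) <- NULL
  out
}
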