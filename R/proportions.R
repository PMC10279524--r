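#' Four-group hidden-state proportions
#'
#' Proportions of the joint hidden states of a feature across two studies.
#' State `(k, l)` means the feature is non-null in study 1 iff `k = 1` and
#' in study 2 iff `l = 1`; `xi_kl` is the probability of that state. The
#' replicability null is the union of states `(0,0)`, `(0,1)` and `(1,0)`.
#'
#' @param xi00,xi01,xi10,xi11 state probabilities; each in `[0, 1]` and
#'   summing to 1 (tolerance `1e-9`).
#'
#' @return An object of class `four_group_proportions`, a named numeric
#'   vector with elements `xi00`, `xi01`, `xi10`, `xi11`.
#' @examples
#' four_group_proportions(0.9, 0.025, 0.025, 0.05)
#' @export
four_group_proportions <- function(xi00, xi01, xi10, xi11) {
  xi <- c(xi00 = xi00, xi01 = xi01, xi10 = xi10, xi11 = xi11)
  if (anyNA(xi) || !is.numeric(xi)) {
    stop("proportions must be numeric and non-missing", call. = FALSE)
  }
  if (any(xi < 0) || any(xi > 1)) {
    stop("each proportion must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(xi) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", format(sum(xi), digits = 12), ")",
         call. = FALSE)
  }
  structure(xi, class = "four_group_proportions")
}

#' @export
print.four_group_proportions <- function(x, ...) {
  cat("Four-group state proportions (study1, study2):\n")
  cat(sprintf("  (0,0): %.4f  (0,1): %.4f  (1,0): %.4f  (1,1): %.4f\n",
              x[["xi00"]], x[["xi01"]], x[["xi10"]], x[["xi11"]]))
  cat(sprintf("  replicability-null mass: %.4f\n",
              x[["xi00"]] + x[["xi01"]] + x[["xi10"]]))
  invisible(x)
}

# total mass of the composite replicability null
null_mass <- function(props) {
  props[["xi00"]] + props[["xi01"]] + props[["xi10"]]
}
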