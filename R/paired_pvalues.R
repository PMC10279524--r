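#' Paired p-values from two studies
#'
#' Container for the input of a two-study replicability analysis: one
#' p-value per feature and study, matched on a shared feature identifier.
#'
#' @param feature_ids character or integer vector of unique feature
#'   identifiers (e.g. gene names), length `m`.
#' @param p1,p2 numeric vectors of p-values in `[0, 1]` from study 1 and
#'   study 2, each of length `m`. Values exactly 0 or 1 are accepted as-is.
#'
#' @return An object of class `paired_pvalues`: a list with elements
#'   `feature_ids`, `p1`, `p2` and attribute `m` (number of features).
#' @examples
#' pp <- paired_pvalues(c("g1", "g2"), c(0.01, 0.4), c(0.03, 0.9))
#' max_p(pp)
#' @export
paired_pvalues <- function(feature_ids, p1, p2) {
  feature_ids <- as.character(feature_ids)
  p1 <- as.numeric(p1)
  p2 <- as.numeric(p2)
  m <- length(feature_ids)
  if (m < 1L) {
    stop("at least one feature is required", call. = FALSE)
  }
  if (length(p1) != m || length(p2) != m) {
    stop("`feature_ids`, `p1` and `p2` must have identical length", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    dup <- feature_ids[duplicated(feature_ids)][1L]
    stop("duplicate feature identifier: ", dup, call. = FALSE)
  }
  for (nm in c("p1", "p2")) {
    p <- if (nm == "p1") p1 else p2
    if (anyNA(p)) {
      stop("missing values in `", nm, "` (feature ",
           feature_ids[which(is.na(p))[1L]], ")", call. = FALSE)
    }
    bad <- which(p < 0 | p > 1)
    if (length(bad)) {
      stop("p-value outside [0, 1] in `", nm, "` for feature ",
           feature_ids[bad[1L]], " (value ", p[bad[1L]], ")", call. = FALSE)
    }
  }
  structure(
    list(feature_ids = feature_ids, p1 = p1, p2 = p2),
    m = m,
    class = "paired_pvalues"
  )
}

#' @export
print.paired_pvalues <- function(x, ...) {
  m <- attr(x, "m")
  cat("Paired p-values for", m, "features from two studies\n")
  k <- min(m, 5L)
  print(data.frame(
    feature_id = x$feature_ids[seq_len(k)],
    p1 = x$p1[seq_len(k)],
    p2 = x$p2[seq_len(k)]
  ), row.names = FALSE)
  if (m > k) cat("... and", m - k, "more features\n")
  invisible(x)
}

#' @export
length.paired_pvalues <- function(x) attr(x, "m")
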