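#' Read paired p-values from delimited text
#'
#' Accepts either one table with columns `(feature_id, p1, p2)` or two
#' tables with columns `(feature_id, p)` which are matched on the
#' intersection of their feature identifiers. Delimiter is auto-detected
#' (`.csv` / `.tsv` and friends); a header row is required. Rows with
#' missing or non-numeric p-values are dropped with a message; duplicate
#' identifiers within a table are an error, as is any p-value outside
#' `[0, 1]`.
#'
#' @param path path to the merged table, or to the study-1 table when
#'   `path2` is given.
#' @param path2 optional path to the study-2 table.
#' @param feature_col name of the identifier column; default
#'   `"feature_id"`.
#' @param p_cols names of the p-value columns: `c("p1", "p2")` for the
#'   merged layout, or a single name (default `"p"`) shared by the two
#'   per-study tables.
#' @return a [paired_pvalues] object; features are in study-1 input order
#'   (merged layout: input order).
#' @export
read_paired_pvalues <- function(path, path2 = NULL,
                                feature_col = "feature_id",
                                p_cols = NULL) {
  if (is.null(path2)) {
    if (is.null(p_cols)) p_cols <- c("p1", "p2")
    tab <- read_pvalue_table(path, feature_col, p_cols)
    ids <- tab[[feature_col]]
    p1 <- tab[[p_cols[1]]]
    p2 <- tab[[p_cols[2]]]
  } else {
    if (is.null(p_cols)) p_cols <- "p"
    t1 <- read_pvalue_table(path, feature_col, p_cols[1])
    t2 <- read_pvalue_table(path2, feature_col, p_cols[1])
    ids <- intersect(t1[[feature_col]], t2[[feature_col]])
    if (!length(ids)) {
      stop("no feature identifiers common to ", path, " and ", path2,
           call. = FALSE)
    }
    p1 <- t1[[p_cols[1]]][match(ids, t1[[feature_col]])]
    p2 <- t2[[p_cols[1]]][match(ids, t2[[feature_col]])]
  }
  paired_pvalues(ids, p1, p2)
}

read_pvalue_table <- function(path, feature_col, p_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = list(character = feature_col))
  missing_cols <- setdiff(c(feature_col, p_cols), names(tab))
  if (length(missing_cols)) {
    stop(path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (pc in p_cols) tab[[pc]] <- suppressWarnings(as.numeric(tab[[pc]]))
  keep <- stats::complete.cases(tab[, c(feature_col, p_cols), drop = FALSE])
  if (any(!keep)) {
    message("dropping ", sum(!keep),
            " row(s) with missing or non-numeric p-values from ", path)
    tab <- tab[keep, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no usable rows in ", path, call. = FALSE)
  if (anyDuplicated(tab[[feature_col]])) {
    dup <- tab[[feature_col]][duplicated(tab[[feature_col]])][1L]
    stop("duplicate feature identifier in ", path, ": ", dup, call. = FALSE)
  }
  for (pc in p_cols) {
    bad <- which(tab[[pc]] < 0 | tab[[pc]] > 1)
    if (length(bad)) {
      stop("p-value outside [0, 1] in ", path, " for feature ",
           tab[[feature_col]][bad[1L]], " (column ", pc, ", value ",
           tab[[pc]][bad[1L]], ")", call. = FALSE)
    }
  }
  tab
}

#' Write per-feature results to a delimited table
#'
#' One row per feature, in input order: `feature_id`, `p1`, `p2`, `q`,
#' `jump_adjusted`, `jump_rejected`, plus `<method>_adjusted` (where the
#' method defines one) and `<method>_rejected` per supplied baseline.
#'
#' @param result a `jump_result` from [jump_test()].
#' @param path output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @param pairs the [paired_pvalues] the result was computed from.
#' @param baselines optional named list of `baseline_result` objects.
#' @return the output `data.frame`, invisibly.
#' @export
write_results <- function(result, path, pairs, baselines = list()) {
  stopifnot(inherits(result, "jump_result"), inherits(pairs, "paired_pvalues"))
  out <- data.frame(
    feature_id = pairs$feature_ids,
    p1 = pairs$p1,
    p2 = pairs$p2,
    q = result$q,
    jump_adjusted = result$adjusted,
    jump_rejected = result$rejected,
    stringsAsFactors = FALSE
  )
  for (nm in names(baselines)) {
    b <- baselines[[nm]]
    if (!is.null(b$adjusted)) out[[paste0(nm, "_adjusted")]] <- b$adjusted
    out[[paste0(nm, "_rejected")]] <- b$rejected
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data.table::fwrite(out, path, sep = sep)
  invisible(out)
}

#' Read a simulation scenario from a JSON configuration file
#'
#' Expected keys: `m`, `xi00`, `xi01`, `xi10`, `xi11`, `mu1`, `mu2`,
#' `sigma1`, `sigma2`, `alpha`, `n_reps`, `seed` (the last five optional,
#' with [simulation_scenario()] defaults; a `seed` given on the command
#' line overrides the file).
#'
#' @param path path to a JSON file.
#' @param seed optional seed overriding the file's.
#' @return a [simulation_scenario].
#' @export
read_scenario_config <- function(path, seed = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("m", "xi00", "xi01", "xi10", "xi11", "mu1", "mu2")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys)) {
    stop("scenario config lacks key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  simulation_scenario(
    m = cfg$m,
    props = four_group_proportions(cfg$xi00, cfg$xi01, cfg$xi10, cfg$xi11),
    mu1 = cfg$mu1, mu2 = cfg$mu2,
    sigma1 = cfg$sigma1 %||% 1, sigma2 = cfg$sigma2 %||% 1,
    alpha = cfg$alpha %||% 0.05,
    n_reps = cfg$n_reps %||% 100,
    seed = seed %||% cfg$seed %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
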