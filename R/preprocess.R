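#' Autoscale a feature table
#'
#' Centers every variable to mean zero and scales it to unit sample standard
#' deviation (n - 1 denominator), the standard chemometric pretreatment
#' applied before every model fit in this pipeline. The returned scaling
#' state reproduces the transform on new data and supports the exact inverse.
#'
#' @param table a [feature_table] or numeric matrix (samples in rows).
#' @return list with `table` (the autoscaled [feature_table]) and `scaling`
#'   (a `scaling_state` with per-variable `center` and `scale`).
#' @export
autoscale <- function(table) {
  m <- if (is_feature_table(table)) ft_values(table) else as.matrix(table)
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  zero <- which(scale == 0)
  if (length(zero)) {
    stop("zero variance: ",
         (colnames(m) %||% as.character(seq_len(ncol(m))))[zero[1]])
  }
  out <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  st <- scaling_state(center = center, scale = scale)
  list(table = feature_table(out,
                             variable_class = attr(table, "variable_class")),
       scaling = st)
}

scaling_state <- function(center = NULL, scale = NULL, frobenius = NULL) {
  structure(list(center = center, scale = scale, frobenius = frobenius),
            class = "scaling_state")
}

#' Apply or invert a stored scaling
#'
#' @param scaling a `scaling_state` from [autoscale()] or [block_scale()].
#' @param m numeric matrix with the same variables as at fit time.
#' @return the transformed matrix.
#' @export
apply_scaling <- function(scaling, m) {
  m <- as.matrix(m)
  if (!is.null(scaling$center)) m <- sweep(m, 2, scaling$center, "-")
  if (!is.null(scaling$scale)) m <- sweep(m, 2, scaling$scale, "/")
  if (!is.null(scaling$frobenius)) m <- m / scaling$frobenius
  m
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(scaling, m) {
  m <- as.matrix(m)
  if (!is.null(scaling$frobenius)) m <- m * scaling$frobenius
  if (!is.null(scaling$scale)) m <- sweep(m, 2, scaling$scale, "*")
  if (!is.null(scaling$center)) m <- sweep(m, 2, scaling$center, "+")
  m
}

#' Scale a block by its Frobenius norm
#'
#' Divides the whole matrix by the square root of its summed squared entries
#' so that each data block contributes equal total variance before
#' concatenation — the "equalizing" step of low-level multi-block fusion.
#' The output always has Frobenius norm 1.
#'
#' @param table a [feature_table] or numeric matrix.
#' @return list with `table` (scaled) and `scaling` (state holding the norm).
#' @export
block_scale <- function(table) {
  m <- if (is_feature_table(table)) ft_values(table) else as.matrix(table)
  fro <- sqrt(sum(m^2))
  if (fro == 0) stop("cannot block-scale an all-zero matrix")
  list(table = feature_table(m / fro,
                             variable_class = attr(table, "variable_class")),
       scaling = scaling_state(frobenius = fro))
}

#' Filter OTUs by relative abundance
#'
#' Retains OTUs whose relative abundance strictly exceeds `threshold_pct` in
#' at least one sample (`mode = "any"`, the default) or on average across
#' samples (`mode = "mean"`). Retained values are left unchanged: rows are
#' NOT re-closed to 100 after filtering.
#'
#' @param table a compositional [feature_table] (rows sum to 100).
#' @param threshold_pct abundance threshold in percent, default 1.
#' @param mode `"any"` or `"mean"`.
#' @return the filtered [feature_table]; a warning is emitted (and a
#'   zero-column table returned) when nothing passes.
#' @export
filter_otus <- function(table, threshold_pct = 1.0,
                        mode = c("any", "mean")) {
  mode <- match.arg(mode)
  if (threshold_pct < 0 || threshold_pct >= 100)
    stop("threshold_pct must be in [0, 100)")
  m <- ft_values(table)
  keep <- if (mode == "any") {
    apply(m, 2, max) > threshold_pct
  } else {
    colMeans(m) > threshold_pct
  }
  if (!any(keep)) {
    warning("no OTU exceeds ", threshold_pct, "% abundance; empty table")
  }
  cls <- attr(table, "variable_class")
  feature_table(m[, keep, drop = FALSE],
                variable_class = if (!is.null(cls)) cls[keep])
}

#' Close a composition to percentages
#'
#' Rescales every row of a nonnegative table to sum to 100, the convention
#' used for OTU relative-abundance tables. Idempotent on already-closed
#' input.
#'
#' @param table a [feature_table] of nonnegative counts or proportions.
#' @return the closed [feature_table].
#' @export
close_composition <- function(table) {
  m <- ft_values(table)
  if (any(m < 0)) stop("composition values must be nonnegative")
  rs <- rowSums(m)
  zero <- which(rs == 0)
  if (length(zero)) stop("all-zero sample row: ", rownames(m)[zero[1]])
  feature_table(100 * m / rs,
                variable_class = attr(table, "variable_class"))
}
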