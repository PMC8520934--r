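#' Thresholded Pearson correlation network
#'
#' Pairwise Pearson correlations with two-tailed p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and a
#' significance mask `|r| > r_threshold AND p < p_threshold` (diagonal and
#' within-pair self-correlations excluded). With one table the network is
#' square over its variables; with two tables sharing no variable ids it is
#' bipartite — the full symmetric matrix over the union of variables is
#' returned with the mask restricted to cross-table pairs.
#'
#' @param A a [feature_table].
#' @param B optional second [feature_table]; samples are aligned by
#'   intersection when the two differ.
#' @param r_threshold absolute correlation threshold (default 0.6).
#' @param p_threshold p-value threshold (default 0.05).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching the plain threshold rule; `"BH"` available).
#' @return a `correlation_network`: `r`, `p`, `mask` (logical), `n` samples
#'   used, `block` (which input each variable came from).
#' @export
pearson_network <- function(A, B = NULL, r_threshold = 0.6,
                            p_threshold = 0.05, adjust = "none") {
  a <- if (is_feature_table(A)) ft_values(A) else as.matrix(A)
  bipartite <- !is.null(B)
  if (bipartite) {
    b <- if (is_feature_table(B)) ft_values(B) else as.matrix(B)
    common <- intersect(rownames(a), rownames(b))
    if (length(common) < 3) stop("need at least 3 shared samples")
    if (length(intersect(colnames(a), colnames(b))))
      stop("tables share variable ids; bipartite mode needs disjoint sets")
    m <- cbind(a[common, , drop = FALSE], b[common, , drop = FALSE])
    block <- c(rep("A", ncol(a)), rep("B", ncol(b)))
  } else {
    if (nrow(a) < 3) stop("need at least 3 samples")
    m <- a
    block <- rep("A", ncol(a))
  }
  n <- nrow(m)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero variance: ", colnames(m)[which(sds == 0)[1]])
  r <- stats::cor(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  off <- upper.tri(p)
  if (adjust != "none") {
    padj <- p
    padj[off] <- stats::p.adjust(p[off], method = adjust)
    padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
    p <- padj
  }
  mask <- abs(r) > r_threshold & p < p_threshold
  diag(mask) <- FALSE
  if (bipartite) {
    same <- outer(block, block, "==")
    mask[same] <- FALSE
  }
  names(block) <- colnames(m)
  structure(list(r = r, p = p, mask = mask, n = n, block = block,
                 r_threshold = r_threshold, p_threshold = p_threshold),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "correlation_network: %d variables, n = %d, %d significant edges (|r| > %g & p < %g)\n",
    ncol(x$r), x$n, sum(x$mask[upper.tri(x$mask)]), x$r_threshold,
    x$p_threshold))
  invisible(x)
}

#' Edge list of the significant correlations
#'
#' @param network a `correlation_network`.
#' @return data.frame with `from`, `to`, `r`, `p` for each masked pair.
#' @export
network_edges <- function(network) {
  idx <- which(network$mask & upper.tri(network$mask), arr.ind = TRUE)
  data.frame(from = colnames(network$r)[idx[, 1]],
             to = colnames(network$r)[idx[, 2]],
             r = network$r[idx], p = network$p[idx],
             stringsAsFactors = FALSE)
}

#' Paired two-tailed t-test
#'
#' Classical paired Student t on the differences `x_end - x_start`. When
#' every pair differs by exactly the same nonzero constant (zero difference
#' variance) the shift is reported as exact: `t = Inf`, `p = 0`, flagged via
#' `exact_shift = TRUE`.
#'
#' @param x_start,x_end paired measurement vectors (n >= 2).
#' @return list with `t`, `p`, `mean_difference` (end minus start), `df`,
#'   `exact_shift`.
#' @export
paired_t_test <- function(x_start, x_end) {
  if (length(x_start) != length(x_end)) stop("vectors must be paired")
  n <- length(x_start)
  if (n < 2) stop("need at least 2 pairs")
  d <- x_end - x_start
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) stop("zero difference variance and zero mean difference")
    return(list(t = sign(md) * Inf, p = 0, mean_difference = md,
                df = n - 1, exact_shift = TRUE))
  }
  tstat <- md / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  list(t = tstat, p = p, mean_difference = md, df = n - 1,
       exact_shift = FALSE)
}

#' PLS trend analysis of milk composition against lactation day
#'
#' Regresses the autoscaled milk metabolite matrix on the centered day
#' after birth by PLS. The latent-variable count is chosen by maximizing
#' cross-validated Q2Y; per-variable coefficient confidence intervals come
#' from percentile bootstrap over samples (2.5-97.5%), and a variable is
#' called trending (direction = coefficient sign) only when its interval
#' excludes zero.
#'
#' @param milk a [feature_table] of milk metabolite concentrations.
#' @param meta [sample_metadata] rows for the milk samples (a `suction`
#'   column, when present, restricts the fit to end-of-suction samples).
#' @param cfg a [dcv_config()]; `max_lv`, `inner_folds` and `seed` are used.
#' @param n_boot bootstrap resamples (default 500).
#' @return a `trend_model` with the chosen `n_lv`, `q2y` per LV count,
#'   `r2y`, `coefficients`, `ci` (2 x p), and a `trends` table (variable,
#'   coefficient, lower, upper, direction in {-1, 0, +1}).
#' @export
milk_trend <- function(milk, meta, cfg = dcv_config(), n_boot = 500) {
  m <- if (is_feature_table(milk)) ft_values(milk) else as.matrix(milk)
  meta <- match_metadata(feature_table(m), meta)
  if (!is.null(meta$suction)) {
    keep <- meta$suction == "end"
    m <- m[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 6) stop("need at least 6 milk samples with day metadata")
  day <- meta$day_after_birth
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  a_max <- min(cfg$max_lv, n - 2, ncol(m))
  # CV Q2Y per LV count selects the model dimensionality
  folds <- .make_folds(rep("x", n), min(cfg$inner_folds, n), FALSE)
  yhat <- matrix(NA_real_, n, a_max)
  for (f in unique(folds)) {
    te <- folds == f
    st <- .std_fit(m[!te, , drop = FALSE])
    ym <- mean(day[!te])
    fit <- .pls_coef(st$x, day[!te] - ym, a_max)
    pr <- .std_apply(st, m[te, , drop = FALSE]) %*% fit$B_per_lv + ym
    for (a in seq_len(a_max)) yhat[te, a] <- pr[, min(a, max(fit$n_lv, 1))]
  }
  q2y <- apply(yhat, 2, function(v) q2(day, v, mean(day)))
  n_lv <- which.max(q2y)
  sc <- autoscale(m)
  full <- pls_fit(ft_values(sc$table), day - mean(day), n_lv)
  boot <- matrix(NA_real_, n_boot, ncol(m))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    if (stats::sd(day[idx]) == 0) next
    st <- try(.std_fit(m[idx, , drop = FALSE]), silent = TRUE)
    if (inherits(st, "try-error")) next
    fit <- .pls_coef(st$x, day[idx] - mean(day[idx]),
                     min(n_lv, length(idx) - 2))
    boot[b, ] <- fit$B_per_lv[, min(n_lv, max(fit$n_lv, 1))]
  }
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  colnames(ci) <- colnames(m)
  direction <- ifelse(ci[1, ] > 0, 1L, ifelse(ci[2, ] < 0, -1L, 0L))
  trends <- data.frame(variable = colnames(m),
                       coefficient = unname(full$B),
                       lower = unname(ci[1, ]), upper = unname(ci[2, ]),
                       direction = unname(direction),
                       stringsAsFactors = FALSE)
  structure(list(n_lv = n_lv, q2y = q2y, r2y = full$r2y,
                 coefficients = stats::setNames(full$B, colnames(m)),
                 ci = ci, trends = trends, pls = full,
                 n_boot = n_boot),
            class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf(
    "trend_model: %d LV(s), R2Y = %.3f, Q2Y = %.3f; %d increasing, %d decreasing variables\n",
    x$n_lv, x$r2y[length(x$r2y)], x$q2y[x$n_lv],
    sum(x$trends$direction == 1), sum(x$trends$direction == -1)))
  invisible(x)
}

#' @export
result_tables.correlation_network <- function(x) {
  list(r = x$r, p = x$p,
       edges = network_edges(x))
}

#' @export
result_parameters.correlation_network <- function(x)
  list(r_threshold = x$r_threshold, p_threshold = x$p_threshold, n = x$n)

#' @export
result_tables.trend_model <- function(x) {
  list(trends = x$trends,
       q2y = data.frame(n_lv = seq_along(x$q2y), q2y = x$q2y))
}

#' @export
result_parameters.trend_model <- function(x)
  list(n_lv = x$n_lv, n_boot = x$n_boot)
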