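#' Configuration for repeated double cross-validation
#'
#' @param n_repetitions number of repeated random splits (study default 50).
#' @param outer_folds outer-loop folds estimating prediction (default 5).
#' @param inner_folds inner-loop folds selecting the LV count (default 5).
#' @param max_lv largest latent-variable count considered (default 10).
#' @param stratified stratify folds by class (default TRUE).
#' @param seed integer seed; NULL leaves the RNG stream untouched.
#' @return a `dcv_config` list.
#' @export
dcv_config <- function(n_repetitions = 50, outer_folds = 5, inner_folds = 5,
                       max_lv = 10, stratified = TRUE, seed = NULL) {
  if (n_repetitions < 1) stop("n_repetitions must be at least 1")
  structure(list(n_repetitions = as.integer(n_repetitions),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 max_lv = as.integer(max_lv),
                 stratified = isTRUE(stratified),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "dcv_config")
}

# ---- fast internal kernels (hot path of rDCV and permutation nulls) ----

# column-standardize; returns scaled x plus center/sd for reuse on test
# rows. `colw` are optional post-standardization column weights (used by
# multi-block PLS-DA to equalize block Frobenius norms inside each fold);
# they are folded into the stored sd.
.std_fit <- function(m, colw = NULL) {
  n <- nrow(m)
  cm <- colMeans(m)
  xc <- m - rep(cm, each = n)
  sd <- sqrt(colSums(xc^2) / (n - 1))
  if (any(sd == 0)) {
    stop("zero variance: ",
         (colnames(m) %||% as.character(seq_len(ncol(m))))[which(sd == 0)[1]],
         " (within a cross-validation training set)")
  }
  if (!is.null(colw)) sd <- sd / colw
  list(x = xc / rep(sd, each = n), center = cm, sd = sd)
}

.std_apply <- function(st, m) {
  n <- nrow(m)
  (m - rep(st$center, each = n)) / rep(st$sd, each = n)
}

# minimal NIPALS PLS1 returning coefficients for every LV count 1..A;
# silently returns fewer LVs when no covariance remains
.pls_coef <- function(X, y, A) {
  p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  Xd <- X; yd <- y
  eps <- 1e-12 * max(1, sum(y^2))
  a <- 0
  for (k in seq_len(A)) {
    wv <- crossprod(Xd, yd)
    nw <- sqrt(sum(wv^2))
    if (nw < sqrt(eps) || sum(yd^2) < eps) break
    wv <- wv / nw
    tv <- Xd %*% wv
    tt <- sum(tv^2)
    pv <- crossprod(Xd, tv) / tt
    qv <- sum(yd * tv) / tt
    Xd <- Xd - tcrossprod(tv, pv)
    yd <- yd - tv * qv
    a <- k
    W[, k] <- wv; P[, k] <- pv; q[k] <- qv
  }
  if (a == 0) return(list(B_per_lv = matrix(0, p, 1), n_lv = 0L))
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  PtW <- crossprod(P, W)
  B <- matrix(0, p, a)
  for (k in seq_len(a)) {
    B[, k] <- W[, seq_len(k), drop = FALSE] %*%
      solve(PtW[seq_len(k), seq_len(k), drop = FALSE],
            q[seq_len(k)])
  }
  list(B_per_lv = B, n_lv = a)
}

# stratified (or plain) random fold assignment; returns integer fold id
.make_folds <- function(labels, k, stratified) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

# one outer fold: inner CV picks the LV count (min mean NMC, fewest-LV tie
# break), refit on the outer-training set, predict the held-out fold
.outer_fold <- function(m, yenc, tr, te, cfg, colw = NULL) {
  xtr <- m[tr, , drop = FALSE]
  ytr <- yenc[tr]
  a_cap <- min(cfg$max_lv, ncol(m), length(tr) - 2L)
  inner <- .make_folds(ytr, cfg$inner_folds, cfg$stratified)
  miss <- numeric(a_cap)
  for (f in unique(inner)) {
    it <- inner != f
    xi <- xtr[it, , drop = FALSE]
    yi <- ytr[it]
    if (length(unique(yi)) < 2) next  # degenerate inner split: skip
    st <- .std_fit(xi, colw)
    ym <- mean(yi)
    fit <- .pls_coef(st$x, yi - ym, a_cap)
    xs <- .std_apply(st, xtr[!it, , drop = FALSE])
    yh <- xs %*% fit$B_per_lv + ym                  # n_test x n_lv achieved
    # saturated models keep their last coefficients for larger LV counts
    cols <- pmin(seq_len(a_cap), max(fit$n_lv, 1L))
    miss <- miss + colSums((yh[, cols, drop = FALSE] >= 0) !=
                             (ytr[!it] == 1))
  }
  a_sel <- which.min(miss)                          # ties -> fewer LVs
  st <- .std_fit(xtr, colw)
  ym <- mean(ytr)
  fit <- .pls_coef(st$x, ytr - ym, a_sel)
  a_used <- max(fit$n_lv, 1L)
  B <- fit$B_per_lv[, min(a_sel, a_used)]
  xs <- .std_apply(st, m[te, , drop = FALSE])
  score <- drop(xs %*% B) + ym
  list(score = score, n_lv = min(a_sel, a_used), B = B)
}

# assembled figures of merit for one repetition's outer predictions
.rep_foms <- function(yenc, score) {
  pred <- ifelse(score >= 0, 1, -1)
  n_mis <- sum(pred != yenc)
  pos <- yenc == 1
  r <- rank(score)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  e <- yenc - score
  e[yenc == 1 & score > 1] <- 0
  e[yenc == -1 & score < -1] <- 0
  dq <- 1 - sum(e^2) / sum((yenc - mean(yenc))^2)
  c(nmc = n_mis, auroc = auc, dq2 = dq, ccr = 1 - n_mis / length(yenc))
}

# core engine shared by rdcv() and the permutation null: runs n_rep
# repetitions of double CV, returns per-repetition foms and (optionally)
# rank/score bookkeeping
.dcv_engine <- function(m, yenc, cfg, n_rep, keep_detail = TRUE,
                        colw = NULL) {
  n <- nrow(m); p <- ncol(m)
  foms <- matrix(NA_real_, n_rep, 4,
                 dimnames = list(NULL, c("nmc", "auroc", "dq2", "ccr")))
  ranks <- if (keep_detail) matrix(NA_integer_, p, n_rep * cfg$outer_folds)
  scores <- if (keep_detail) matrix(NA_real_, n_rep, n)
  lv <- if (keep_detail) matrix(NA_integer_, n_rep, cfg$outer_folds)
  fold_id <- if (keep_detail) matrix(NA_integer_, n_rep, n)
  coef_sum <- numeric(p)
  it <- 0L
  for (r in seq_len(n_rep)) {
    fold <- .make_folds(yenc, cfg$outer_folds, cfg$stratified)
    if (keep_detail) fold_id[r, ] <- fold
    score <- numeric(n)
    for (f in seq_len(cfg$outer_folds)) {
      te <- which(fold == f)
      if (!length(te)) next
      res <- .outer_fold(m, yenc, which(fold != f), te, cfg, colw)
      score[te] <- res$score
      it <- it + 1L
      if (keep_detail) {
        ranks[, it] <- rank(-abs(res$B), ties.method = "first")
        lv[r, f] <- res$n_lv
      }
      coef_sum <- coef_sum + res$B
    }
    foms[r, ] <- .rep_foms(yenc, score)
    if (keep_detail) scores[r, ] <- score
  }
  if (keep_detail && it < ncol(ranks))
    ranks <- ranks[, seq_len(it), drop = FALSE]
  list(foms = foms, ranks = ranks, scores = scores, lv = lv,
       folds = fold_id, coef_mean = coef_sum / max(it, 1L))
}

# ---- exported operations ----

#' Repeated double cross-validation of a binary PLS-DA model
#'
#' For each repetition, samples are split into stratified outer folds; for
#' each outer fold an inner cross-validation on the outer-training set
#' selects the latent-variable count minimizing mean inner misclassification
#' (ties broken toward fewer LVs); a PLS-DA model with that count — with
#' autoscaling re-estimated inside the fold, so the held-out fold never
#' leaks into scaling, LV selection or fitting — predicts the outer test
#' fold. Per outer fit, variables are ranked by |coefficient| (largest =
#' rank 1, ties broken by variable order); the geometric mean of these ranks
#' over all iterations is each variable's rank product, and variables with
#' rank product below the mean are flagged as candidate markers.
#'
#' @param X raw matrix or [feature_table] (autoscaling happens per fold).
#' @param labels binary class label per sample.
#' @param cfg a [dcv_config()].
#' @param classes length-2 character giving the positive class first;
#'   defaults to order of first appearance in `labels`.
#' @param col_weights optional per-variable weights applied after the
#'   within-fold autoscaling (multi-block fusion uses `1/sqrt(p_block)` to
#'   equalize block Frobenius norms inside every training fold).
#' @return a `dcv_result` with per-repetition figures of merit (`foms`),
#'   their `summary` (mean and sd of NMC, AUROC, DQ2, ccr), per-repetition
#'   outer `scores` and predicted classes, chosen LV counts, the rank matrix,
#'   `rank_product`, `coef_mean` and the `markers` table.
#' @export
rdcv <- function(X, labels, cfg = dcv_config(), classes = NULL,
                 col_weights = NULL) {
  m <- if (is_feature_table(X)) ft_values(X) else as.matrix(X)
  labels <- as.character(labels)
  if (is.null(classes)) classes <- unique(labels)
  if (length(classes) != 2 || !all(labels %in% classes))
    stop("rdcv requires exactly two classes covering all labels")
  counts <- table(factor(labels, classes))
  if (cfg$stratified && cfg$outer_folds > min(counts))
    stop("smallest class has ", min(counts), " samples; reduce outer_folds")
  yenc <- ifelse(labels == classes[1], 1, -1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  eng <- .dcv_engine(m, yenc, cfg, cfg$n_repetitions, keep_detail = TRUE,
                     colw = col_weights)
  rp <- rank_product(eng$ranks)
  names(rp) <- colnames(m)
  names(eng$coef_mean) <- colnames(m)
  markers <- select_markers(rp, eng$coef_mean, classes)
  summary <- rbind(mean = colMeans(eng$foms),
                   sd = apply(eng$foms, 2, stats::sd))
  pred_class <- matrix(ifelse(eng$scores >= 0, classes[1], classes[2]),
                       nrow(eng$scores),
                       dimnames = list(NULL, rownames(m)))
  colnames(eng$scores) <- rownames(m)
  structure(list(foms = eng$foms, summary = summary,
                 scores = eng$scores, predicted = pred_class,
                 n_lv = eng$lv, folds = eng$folds,
                 rank_matrix = eng$ranks,
                 rank_product = rp, coef_mean = eng$coef_mean,
                 markers = markers, classes = classes, labels = labels,
                 config = cfg),
            class = "dcv_result")
}

#' @export
print.dcv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "dcv_result (%s vs %s): %d repetitions\n  ccr %.3f +/- %.3f | NMC %.2f | AUROC %.3f | DQ2 %.3f\n  %d candidate markers (RP < mean RP)\n",
    x$classes[1], x$classes[2], nrow(x$foms),
    s["mean", "ccr"], s["sd", "ccr"], s["mean", "nmc"],
    s["mean", "auroc"], s["mean", "dq2"], nrow(x$markers)))
  invisible(x)
}

#' Rank product of a rank matrix
#'
#' Geometric mean of each variable's rank across iterations, computed in
#' log space for numerical safety. Every column must be a permutation of
#' `1..p`.
#'
#' @param rank_matrix integer matrix, variables x iterations.
#' @return numeric vector of rank products, one per variable.
#' @export
rank_product <- function(rank_matrix) {
  rm <- as.matrix(rank_matrix)
  p <- nrow(rm)
  for (k in seq_len(ncol(rm))) {
    if (!identical(sort(as.integer(rm[, k])), seq_len(p)))
      stop("column ", k, " of the rank matrix is not a permutation of 1..",
           p)
  }
  rp <- exp(rowMeans(log(rm)))
  names(rp) <- rownames(rm)
  rp
}

#' Select candidate markers by the rank-product rule
#'
#' Variables whose rank product lies strictly below the arithmetic mean rank
#' product, sorted ascending by RP. When the mean coefficient is supplied,
#' each marker is annotated with the class in which it is higher (positive
#' coefficient = higher in the first-listed class).
#'
#' @param rp named rank-product vector from [rank_product()].
#' @param coef_mean optional mean coefficient per variable (same order).
#' @param classes optional length-2 class labels for direction annotation.
#' @return data.frame with `variable`, `rank_product` and, when available,
#'   `direction` (the class the variable is higher in).
#' @export
select_markers <- function(rp, coef_mean = NULL, classes = c("A", "B")) {
  if (any(!is.finite(rp))) stop("rank products must be finite")
  sel <- which(rp < mean(rp))
  sel <- sel[order(rp[sel])]
  out <- data.frame(variable = names(rp)[sel] %||% as.character(sel),
                    rank_product = unname(rp[sel]),
                    stringsAsFactors = FALSE)
  if (!is.null(coef_mean) && nrow(out)) {
    out$direction <- ifelse(coef_mean[sel] >= 0, classes[1], classes[2])
  } else if (!is.null(coef_mean)) {
    out$direction <- character(0)
  }
  out
}

#' Permutation test of the rDCV figures of merit
#'
#' The observed statistic for each figure of merit is its mean over the
#' rDCV repetitions. For each of `n_perm` randomizations the class labels
#' are shuffled once and a single double-CV pass (one repetition) yields a
#' null NMC, AUROC and DQ2. p-values use the add-one convention
#' `p = (1 + #{null at least as extreme}) / (n_perm + 1)`, where "extreme"
#' is <= for NMC and >= for AUROC and DQ2, so the smallest attainable p is
#' `1/(n_perm + 1)`.
#'
#' @param X raw matrix or [feature_table].
#' @param labels binary class labels.
#' @param cfg a [dcv_config()]; its seed governs the whole procedure.
#' @param n_perm number of randomizations (study default 1000).
#' @param observed optionally a precomputed [rdcv()] result for the same
#'   data and config, to avoid refitting.
#' @param col_weights optional per-variable post-autoscaling weights, as in
#'   [rdcv()].
#' @return a `permutation_result` with `observed`, `null` (n_perm x 3
#'   matrix) and `p_value` per figure of merit.
#' @export
permutation_test <- function(X, labels, cfg = dcv_config(), n_perm = 1000,
                             observed = NULL, col_weights = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  m <- if (is_feature_table(X)) ft_values(X) else as.matrix(X)
  labels <- as.character(labels)
  if (is.null(observed)) {
    observed <- rdcv(m, labels, cfg, col_weights = col_weights)
  } else {
    stopifnot(inherits(observed, "dcv_result"))
    if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  }
  obs <- observed$summary["mean", c("nmc", "auroc", "dq2")]
  classes <- observed$classes
  null <- matrix(NA_real_, n_perm, 3,
                 dimnames = list(NULL, c("nmc", "auroc", "dq2")))
  for (b in seq_len(n_perm)) {
    yp <- ifelse(sample(labels) == classes[1], 1, -1)
    eng <- .dcv_engine(m, yp, cfg, 1L, keep_detail = FALSE,
                       colw = col_weights)
    null[b, ] <- eng$foms[1, c("nmc", "auroc", "dq2")]
  }
  p <- c(nmc = (1 + sum(null[, "nmc"] <= obs["nmc"])) / (n_perm + 1),
         auroc = (1 + sum(null[, "auroc"] >= obs["auroc"])) / (n_perm + 1),
         dq2 = (1 + sum(null[, "dq2"] >= obs["dq2"])) / (n_perm + 1))
  structure(list(observed = obs, null = null, p_value = p,
                 n_perm = as.integer(n_perm), config = cfg),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: %d randomizations\n  p(NMC) = %.4g, p(AUROC) = %.4g, p(DQ2) = %.4g\n",
    x$n_perm, x$p_value["nmc"], x$p_value["auroc"], x$p_value["dq2"]))
  invisible(x)
}

#' @export
result_tables.dcv_result <- function(x) {
  list(predictions = x$scores,
       foms = cbind(repetition = seq_len(nrow(x$foms)), x$foms),
       rank_products = data.frame(variable = names(x$rank_product),
                                  rank_product = unname(x$rank_product),
                                  coef_mean = unname(x$coef_mean)),
       markers = x$markers)
}

#' @export
result_parameters.dcv_result <- function(x) unclass(x$config)

#' @export
result_tables.permutation_result <- function(x) {
  list(fom_null = x$null,
       p_values = data.frame(fom = names(x$p_value),
                             observed = unname(x$observed[names(x$p_value)]),
                             p_value = unname(x$p_value)))
}

#' @export
result_parameters.permutation_result <- function(x)
  c(unclass(x$config), list(n_perm = x$n_perm))
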