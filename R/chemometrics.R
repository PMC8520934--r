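# Sign convention shared by PCA, PLS and ComDim: each component's loading
# vector is flipped so its largest-magnitude element is positive, making
# outputs reproducible across BLAS implementations.
fix_sign <- function(loading, ...) {
  i <- which.max(abs(loading))
  if (loading[i] < 0) -1 else 1
}

#' Principal component analysis by singular value decomposition
#'
#' Fits PCA on the column-centered matrix (input is normally already
#' autoscaled). Explained variance fractions are eigenvalue shares over all
#' `min(n - 1, p)` components, so they sum to 1 when K is maximal.
#'
#' @param X autoscaled [feature_table] or numeric matrix, samples in rows.
#' @param K number of components to keep.
#' @return object of class `pca_model` with `scores` (n x K), `loadings`
#'   (p x K), `explained` (fraction per component) and `center`.
#' @export
pca_fit <- function(X, K) {
  m <- if (is_feature_table(X)) ft_values(X) else as.matrix(X)
  n <- nrow(m); p <- ncol(m)
  kmax <- min(n - 1, p)
  if (K > kmax) stop("K must be at most min(n-1, p) = ", kmax)
  center <- colMeans(m)
  mc <- sweep(m, 2, center, "-")
  sv <- svd(mc)
  ev <- sv$d^2            # proportional to eigenvalues of the covariance
  explained <- (ev / sum(ev))[seq_len(K)]
  loadings <- sv$v[, seq_len(K), drop = FALSE]
  scores <- sv$u[, seq_len(K), drop = FALSE] %*%
    diag(sv$d[seq_len(K)], K, K)
  sg <- apply(loadings, 2, fix_sign)
  loadings <- sweep(loadings, 2, sg, "*")
  scores <- sweep(scores, 2, sg, "*")
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(K)))
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(K)))
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, center = center),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components, explained variance %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @export
result_tables.pca_model <- function(x) {
  list(scores = x$scores, loadings = x$loadings,
       explained = data.frame(component = seq_along(x$explained),
                              fraction = x$explained))
}

#' @export
result_parameters.pca_model <- function(x) list(K = ncol(x$scores))

#' Fit a PLS1 regression model by NIPALS
#'
#' Univariate-response partial least squares with y-deflation. Per
#' component: `w = X'y / ||X'y||`, `t = Xw`, `p = X't / t't`,
#' `q = y't / t't`, then `X <- X - t p'`, `y <- y - t q`. After A rounds the
#' regression vector is `B = W (P'W)^{-1} q`; coefficient vectors for every
#' intermediate number of latent variables are also returned, which lets
#' cross-validation score all LV counts from a single fit. Extraction stops
#' early (with a warning) when no covariance between X and y remains.
#'
#' X and y are taken as already preprocessed (autoscaled X, centered y);
#' scaling state can be attached afterwards for prediction via
#' [plsda_predict()].
#'
#' @param X numeric matrix, samples in rows, autoscaled.
#' @param y numeric response vector, centered.
#' @param A number of latent variables, at most `min(n - 1, p)`.
#' @return object of class `pls_model`: weights `W`, loadings `P`, scores
#'   `T`, y-loadings `q`, coefficients `B` (for the full model) and
#'   `B_per_lv` (p x A, column a = coefficients using a LVs), cumulative
#'   `r2y` per LV, and the achieved `n_lv`.
#' @export
pls_fit <- function(X, y, A) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y length must match rows of X")
  if (A < 1 || A > min(n - 1, p))
    stop("A must be in 1..min(n-1, p) = ", min(n - 1, p))
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A); r2y <- numeric(A)
  ss_y0 <- sum(y^2)
  Xd <- X; yd <- y
  a <- 0
  eps <- 1e-12 * max(1, ss_y0)
  for (k in seq_len(A)) {
    wv <- crossprod(Xd, yd)
    nw <- sqrt(sum(wv^2))
    if (nw < sqrt(eps) || sum(yd^2) < eps) {
      warning("no covariance left after ", a,
              " latent variable(s); stopping early")
      break
    }
    wv <- wv / nw
    tv <- Xd %*% wv
    tt <- sum(tv^2)
    pv <- crossprod(Xd, tv) / tt
    qv <- sum(yd * tv) / tt
    Xd <- Xd - tcrossprod(tv, pv)
    yd <- yd - tv * qv
    a <- k
    W[, k] <- wv; P[, k] <- pv; Tm[, k] <- tv; q[k] <- qv
    r2y[k] <- 1 - sum(yd^2) / ss_y0
  }
  if (a == 0) {
    return(structure(list(n_lv = 0L, W = W[, 0, drop = FALSE],
                          P = P[, 0, drop = FALSE],
                          T = Tm[, 0, drop = FALSE], q = numeric(0),
                          B = rep(0, p), B_per_lv = matrix(0, p, 0),
                          r2y = numeric(0),
                          variable_ids = colnames(X)),
                     class = "pls_model"))
  }
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  r2y <- r2y[seq_len(a)]
  lv <- paste0("LV", seq_len(a))
  dimnames(W) <- list(colnames(X), lv)
  dimnames(P) <- list(colnames(X), lv)
  dimnames(Tm) <- list(rownames(X), lv)
  # B for every LV count in one pass: R = W (P'W)^-1 is triangular-solvable
  PtW <- crossprod(P, W)
  B_per_lv <- matrix(0, p, a)
  for (k in seq_len(a)) {
    Rk <- W[, seq_len(k), drop = FALSE] %*%
      solve(PtW[seq_len(k), seq_len(k), drop = FALSE], diag(k))
    B_per_lv[, k] <- Rk %*% q[seq_len(k)]
  }
  rownames(B_per_lv) <- colnames(X)
  structure(list(n_lv = a, W = W, P = P, T = Tm, q = q,
                 B = B_per_lv[, a], B_per_lv = B_per_lv, r2y = r2y,
                 variable_ids = colnames(X)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variable(s), cumulative R2Y %s\n",
              x$n_lv, paste(sprintf("%.3f", x$r2y), collapse = ", ")))
  invisible(x)
}

#' Fit a binary PLS-DA classifier
#'
#' Encodes the two classes as +1 (first of `classes`) and -1, autoscales X,
#' centers the encoded response, and fits [pls_fit()]. The stored scaling
#' state is reapplied to new data at prediction time.
#'
#' @param X raw (unscaled) matrix or [feature_table].
#' @param labels class label per sample.
#' @param classes length-2 character: the positive class first.
#' @param A number of latent variables.
#' @return a `plsda_model`: the underlying `pls_model` plus scaling state,
#'   class encoding and training-response mean.
#' @export
plsda_fit <- function(X, labels, classes = NULL, A = 2) {
  m <- if (is_feature_table(X)) ft_values(X) else as.matrix(X)
  labels <- as.character(labels)
  if (is.null(classes)) classes <- unique(labels)
  if (length(classes) != 2) stop("PLS-DA here is strictly binary")
  if (!all(labels %in% classes))
    stop("unknown label: ", setdiff(labels, classes)[1])
  y <- ifelse(labels == classes[1], 1, -1)
  sc <- autoscale(m)
  y_mean <- mean(y)
  fit <- pls_fit(ft_values(sc$table), y - y_mean, A)
  structure(list(pls = fit, scaling = sc$scaling, classes = classes,
                 y_mean = y_mean, variable_ids = colnames(m)),
            class = "plsda_model")
}

#' Predict classes from a fitted PLS-DA model
#'
#' New samples are transformed with the model's stored scaling, scored as
#' `yhat = X B + y_mean`, and assigned by sign: positive scores go to the
#' first-listed class, negative to the second; an exact zero goes to the
#' first-listed class, deterministically.
#'
#' @param model a `plsda_model` from [plsda_fit()].
#' @param X_new raw matrix with the model's variables.
#' @param n_lv optionally score with fewer latent variables than fitted.
#' @return list with `score` (continuous) and `class` (labels).
#' @export
plsda_predict <- function(model, X_new, n_lv = NULL) {
  m <- if (is_feature_table(X_new)) ft_values(X_new) else as.matrix(X_new)
  if (ncol(m) != length(model$variable_ids))
    stop("variable mismatch: model has ", length(model$variable_ids),
         " variables, new data has ", ncol(m))
  if (!is.null(colnames(m)) && !is.null(model$variable_ids) &&
      !identical(colnames(m), model$variable_ids))
    stop("variable mismatch: ids differ from training data")
  xs <- apply_scaling(model$scaling, m)
  B <- if (is.null(n_lv)) model$pls$B else {
    if (n_lv < 1 || n_lv > model$pls$n_lv) stop("invalid n_lv")
    model$pls$B_per_lv[, n_lv]
  }
  score <- drop(xs %*% B) + model$y_mean
  cls <- ifelse(score >= 0, model$classes[1], model$classes[2])
  list(score = score, class = cls)
}

#' Number of misclassifications
#'
#' @param labels true labels.
#' @param predicted predicted labels drawn from the same label set.
#' @return integer count of mismatches.
#' @export
nmc <- function(labels, predicted) {
  if (length(labels) != length(predicted))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(predicted), unique(labels))
  if (length(bad)) stop("unknown label: ", bad[1])
  sum(labels != predicted)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive sample outscores a
#' randomly chosen negative one, with ties counted one half — computed from
#' midranks, which is exactly the pairwise count.
#'
#' @param labels class labels; `positive` marks the positive class.
#' @param score continuous classifier score, higher = more positive.
#' @param positive the positive class label (default: first label level
#'   encountered).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, score, positive = NULL) {
  labels <- as.character(labels)
  if (is.null(positive)) positive <- labels[1]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(score)           # midranks handle ties as half-wins
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discriminant Q2
#'
#' Q2 with residuals clipped for predictions that overshoot their own class
#' label in the correct direction: for `y = +1`, `yhat > 1` contributes no
#' residual, and symmetrically for `y = -1`. Always at least the classical
#' Q2 on the same predictions.
#'
#' @param y encoded labels, strictly +1 / -1.
#' @param yhat continuous predictions.
#' @param y_train_mean mean of the (encoded) training response, used in the
#'   total sum of squares.
#' @return DQ2 value (at most 1).
#' @export
dq2 <- function(y, yhat, y_train_mean = mean(y)) {
  if (!all(y %in% c(-1, 1))) stop("labels must be encoded +1/-1")
  e <- y - yhat
  e[y == 1 & yhat > 1] <- 0
  e[y == -1 & yhat < -1] <- 0
  tss <- sum((y - y_train_mean)^2)
  if (tss == 0) stop("zero total sum of squares")
  1 - sum(e^2) / tss
}

#' Cross-validated Q2
#'
#' `1 - PRESS/TSS` with the total sum of squares taken about the training
#' mean.
#'
#' @param y_true observed response.
#' @param yhat_cv cross-validated predictions.
#' @param y_train_mean training-set response mean.
#' @return Q2 value (at most 1).
#' @export
q2 <- function(y_true, yhat_cv, y_train_mean = mean(y_true)) {
  tss <- sum((y_true - y_train_mean)^2)
  if (tss == 0) stop("zero total sum of squares")
  1 - sum((y_true - yhat_cv)^2) / tss
}

#' Correct classification rate
#'
#' @param labels true labels.
#' @param predicted predicted labels.
#' @return `1 - NMC/n`.
#' @export
ccr <- function(labels, predicted) {
  1 - nmc(labels, predicted) / length(labels)
}
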