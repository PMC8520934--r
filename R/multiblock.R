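#' Fit a ComDim (CCSWA) common-components model
#'
#' Common components and specific weights analysis extracts components
#' explaining as much joint variability across data blocks as possible.
#' Blocks should already be autoscaled and Frobenius-norm scaled (see
#' [preprocess_blocks()]). Per component, starting from unit saliences, the
#' algorithm iterates: form the salience-weighted association matrix
#' `W = sum_j lambda_j X_j X_j'`, take its dominant unit eigenvector as the
#' global score `t`, and update each salience `lambda_j = t' X_j X_j' t`;
#' convergence is declared when the saliences move by less than `tol`.
#' Every block is then deflated by the extracted score
#' (`X_j <- X_j - t t' X_j`) and the next component extracted. Working on
#' the n x n association matrices keeps the fit cheap at the study's sample
#' sizes.
#'
#' Scores are kept unit-norm; the saliences carry the block-variance
#' magnitude. Component signs follow the largest-|loading| convention of
#' the concatenated block loadings.
#'
#' @param blocks a `block_set` from [align_blocks()], or list of matrices
#'   with identical rows.
#' @param K number of common components (default 2).
#' @param tol convergence tolerance on the saliences (default 1e-10).
#' @param max_iter maximum iterations per component (default 100).
#' @return a `comdim_model`: unit-norm global `scores` (n x K), `saliences`
#'   (K x n_blocks, nonnegative), per-block `loadings` (p_j x K), and
#'   per-block explained variance per component.
#' @export
comdim_fit <- function(blocks, K = 2, tol = 1e-10, max_iter = 100) {
  Xs <- .block_list(blocks)
  n <- nrow(Xs[[1]])
  if (any(vapply(Xs, nrow, integer(1)) != n))
    stop("blocks are not aligned: row counts differ")
  J <- length(Xs)
  bn <- names(Xs)
  tot_var <- vapply(Xs, function(x) sum(x^2), numeric(1))
  scores <- matrix(0, n, K, dimnames = list(rownames(Xs[[1]]),
                                            paste0("CC", seq_len(K))))
  saliences <- matrix(0, K, J, dimnames = list(paste0("CC", seq_len(K)), bn))
  loadings <- lapply(Xs, function(x)
    matrix(0, ncol(x), K, dimnames = list(colnames(x),
                                          paste0("CC", seq_len(K)))))
  expl <- matrix(0, K, J, dimnames = dimnames(saliences))
  assoc <- lapply(Xs, tcrossprod)
  for (k in seq_len(K)) {
    lambda <- rep(1, J)
    t_vec <- NULL
    for (iter in seq_len(max_iter)) {
      Wm <- Reduce(`+`, Map(`*`, assoc, lambda))
      eg <- eigen(Wm, symmetric = TRUE)
      t_vec <- eg$vectors[, 1]
      lambda_new <- vapply(assoc, function(a) drop(crossprod(t_vec, a %*%
                                                               t_vec)),
                           numeric(1))
      if (max(abs(lambda_new - lambda)) < tol) {
        lambda <- lambda_new
        break
      }
      lambda <- lambda_new
      if (iter == max_iter)
        warning("ComDim component ", k, " did not converge in ",
                max_iter, " iterations")
    }
    # shared sign convention: largest |loading| over the concatenated blocks
    load_k <- unlist(lapply(Xs, function(x) drop(crossprod(x, t_vec))))
    if (load_k[which.max(abs(load_k))] < 0) t_vec <- -t_vec
    scores[, k] <- t_vec
    saliences[k, ] <- lambda
    for (j in seq_len(J)) {
      loadings[[j]][, k] <- crossprod(Xs[[j]], t_vec)
      expl[k, j] <- sum(loadings[[j]][, k]^2) / tot_var[j]
      Xs[[j]] <- Xs[[j]] - tcrossprod(t_vec, drop(crossprod(Xs[[j]], t_vec)))
    }
    assoc <- lapply(Xs, tcrossprod)
  }
  structure(list(scores = scores, saliences = saliences,
                 loadings = loadings, explained = expl,
                 block_names = bn, n_cc = K,
                 residual = Xs, tot_var = tot_var),
            class = "comdim_model")
}

.block_list <- function(blocks) {
  Xs <- if (inherits(blocks, "block_set")) blocks$blocks else blocks
  if (!is.list(Xs) || !length(Xs)) stop("blocks must be a non-empty list")
  Xs <- lapply(Xs, function(x)
    if (is_feature_table(x)) ft_values(x) else as.matrix(x))
  if (is.null(names(Xs))) names(Xs) <- paste0("block", seq_along(Xs))
  Xs
}

#' @export
print.comdim_model <- function(x, ...) {
  cat(sprintf("comdim_model: %d common components over %d blocks\n",
              x$n_cc, length(x$block_names)))
  print(round(x$saliences, 4))
  invisible(x)
}

#' Project samples onto a ComDim model
#'
#' Reconstructs global scores for new (identically preprocessed) blocks by
#' sequentially projecting onto the stored loadings with the same deflation
#' as at fit time, and reports per-block score contributions.
#'
#' @param model a `comdim_model`.
#' @param blocks blocks with the same variables as at fit.
#' @return list with `scores` (global) and `block_scores` (per block).
#' @export
comdim_project <- function(model, blocks) {
  Xs <- .block_list(blocks)
  if (length(Xs) != length(model$block_names))
    stop("block count mismatch with the fitted model")
  for (j in seq_along(Xs)) {
    if (ncol(Xs[[j]]) != nrow(model$loadings[[j]]))
      stop("variable mismatch in block ", model$block_names[j])
  }
  n <- nrow(Xs[[1]])
  K <- model$n_cc
  # normalization: projecting the training blocks must reproduce stored T
  scale_k <- numeric(K)
  scores <- matrix(0, n, K, dimnames = list(rownames(Xs[[1]]),
                                            colnames(model$scores)))
  block_scores <- lapply(model$block_names, function(b)
    matrix(0, n, K, dimnames = list(rownames(Xs[[1]]),
                                    colnames(model$scores))))
  names(block_scores) <- model$block_names
  for (k in seq_len(K)) {
    contrib <- matrix(0, n, length(Xs))
    for (j in seq_along(Xs)) {
      pk <- model$loadings[[j]][, k]
      contrib[, j] <- model$saliences[k, j] * (Xs[[j]] %*% pk)
    }
    raw <- rowSums(contrib)
    # the training scores satisfy t = (sum_j lambda_j X_j p_jk) / nu_k with
    # nu_k = sum_j lambda_j ||p_jk||^2 (since p_jk = X_j' t, X_j deflated)
    nu <- sum(vapply(seq_along(Xs), function(j)
      model$saliences[k, j] * sum(model$loadings[[j]][, k]^2), numeric(1)))
    if (nu > 0) {
      raw <- raw / nu
      contrib <- contrib / nu
    }
    scores[, k] <- raw
    for (j in seq_along(Xs)) block_scores[[j]][, k] <- contrib[, j]
    # deflate new data exactly as at fit: remove the stored component
    for (j in seq_along(Xs)) {
      Xs[[j]] <- Xs[[j]] - tcrossprod(raw, model$loadings[[j]][, k])
    }
  }
  list(scores = scores, block_scores = block_scores)
}

#' Autoscale then Frobenius-scale each block
#'
#' The standard multi-block pretreatment: individual autoscaling of each
#' data matrix followed by division by its Frobenius norm, so every block
#' enters the joint model with equal total variance.
#'
#' @param blocks a `block_set` or list of feature tables (aligned rows).
#' @return list with `blocks` (preprocessed matrices) and `scalings`.
#' @export
preprocess_blocks <- function(blocks) {
  Xs <- .block_list(blocks)
  out <- lapply(Xs, function(x) {
    a <- autoscale(x)
    b <- block_scale(a$table)
    list(x = ft_values(b$table),
         scaling = scaling_state(center = a$scaling$center,
                                 scale = a$scaling$scale,
                                 frobenius = b$scaling$frobenius))
  })
  list(blocks = lapply(out, `[[`, "x"),
       scalings = lapply(out, `[[`, "scaling"))
}

#' Multi-block PLS-DA with rDCV validation
#'
#' Low-level data fusion: each block is autoscaled, divided by its
#' Frobenius norm and the blocks concatenated row-wise; the concatenated
#' matrix is then validated exactly like a single-block PLS-DA — repeated
#' double cross-validation, rank-product marker selection (markers annotated
#' with their block of origin) and, optionally, a permutation test.
#'
#' Inside the cross-validation, autoscaling and Frobenius norms are
#' re-estimated on each training fold via per-block variable bookkeeping,
#' by scaling the concatenated training matrix per variable and per block.
#'
#' @param blocks a `block_set` from [align_blocks()].
#' @param labels binary class labels for the common samples.
#' @param cfg a [dcv_config()].
#' @param classes length-2 character, positive class first.
#' @param n_perm permutation count; 0 skips the permutation test.
#' @return list of class `mbplsda_result`: `model` (PLS-DA on the
#'   concatenated matrix, full data), `dcv` (a `dcv_result`), `permutation`
#'   (or NULL), `block_membership`, per-block `block_share` of each LV, and
#'   `markers` with block annotation.
#' @export
mbplsda_fit <- function(blocks, labels, cfg = dcv_config(), classes = NULL,
                        n_perm = 0) {
  stopifnot(inherits(blocks, "block_set"))
  pp <- preprocess_blocks(blocks)
  concat <- do.call(cbind, pp$blocks)
  membership <- rep(names(pp$blocks), vapply(pp$blocks, ncol, integer(1)))
  colnames(concat) <- unlist(lapply(pp$blocks, colnames))
  labels <- as.character(labels)
  if (is.null(classes)) classes <- unique(labels)
  # full-data reference model on the preprocessed concatenation (already
  # scaled, so fit the PLS core directly on it)
  yenc <- ifelse(labels == classes[1], 1, -1)
  A <- min(cfg$max_lv, nrow(concat) - 1, ncol(concat))
  model <- pls_fit(concat, yenc - mean(yenc), A)
  share <- t(apply(model$W^2, 2, function(w)
    tapply(w, membership, sum) / sum(w)))
  # rDCV on the raw concatenation: per-fold autoscaling is re-estimated by
  # the engine; Frobenius equalization reduces to 1/sqrt(p_block) column
  # weights, because an autoscaled block's Frobenius norm is
  # sqrt(p_block * (n - 1)) and the common (n - 1) scalar cannot change
  # PLS-DA predictions
  raw <- do.call(cbind, .block_list(blocks))
  colnames(raw) <- colnames(concat)
  p_j <- vapply(pp$blocks, ncol, integer(1))
  colw <- rep(1 / sqrt(p_j), p_j)
  dcvres <- rdcv(raw, labels, cfg, classes, col_weights = colw)
  dcvres$markers$block <- membership[match(dcvres$markers$variable,
                                           colnames(concat))]
  perm <- NULL
  if (n_perm > 0) {
    perm <- permutation_test(raw, labels, cfg, n_perm, observed = dcvres,
                             col_weights = colw)
  }
  structure(list(model = model, dcv = dcvres, permutation = perm,
                 block_membership = stats::setNames(membership,
                                                    colnames(concat)),
                 block_share = share, markers = dcvres$markers,
                 classes = classes),
            class = "mbplsda_result")
}

#' @export
print.mbplsda_result <- function(x, ...) {
  cat("mbplsda_result\n")
  print(x$dcv)
  if (!is.null(x$permutation)) print(x$permutation)
  tab <- table(x$markers$block)
  if (length(tab))
    cat("markers per block:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
result_tables.comdim_model <- function(x) {
  c(list(scores = x$scores, saliences = x$saliences,
         explained = x$explained),
    stats::setNames(x$loadings, paste0("loadings_", names(x$loadings))))
}

#' @export
result_parameters.comdim_model <- function(x)
  list(n_cc = x$n_cc, blocks = x$block_names)
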