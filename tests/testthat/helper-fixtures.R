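# shared fixtures and independent oracles used across the suite

# plain numeric matrix from a feature_table
ft_vals <- function(x) {
  y <- unclass(x)
  attr(y, "variable_class") <- NULL
  y
}

tiny_table <- function(values = matrix(c(1, 2, 3, 4, 6, 8), 3, 2),
                       samples = c("s1", "s2", "s3"),
                       vars = c("lactate", "acetate")) {
  feature_table(values, sample_ids = samples, variable_ids = vars)
}

# O(n^2) pair-counting AUROC, independent of the midrank implementation
auroc_pairs <- function(labels, score, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  wins <- 0
  for (i in pos) for (j in neg) {
    wins <- wins + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  }
  wins / (length(pos) * length(neg))
}

# pseudoinverse least squares via SVD, independent of NIPALS
pinv_solve <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
}

# a small well-separated two-class dataset for classifier checks
separated_data <- function(n_per_class = 10, p = 8, shift = 4, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  X[seq_len(n_per_class), seq_len(3)] <-
    X[seq_len(n_per_class), seq_len(3)] + shift
  rownames(X) <- sprintf("s%02d", seq_len(2 * n_per_class))
  colnames(X) <- sprintf("v%d", seq_len(p))
  list(X = X, labels = rep(c("A", "B"), each = n_per_class))
}
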