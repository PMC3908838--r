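#' @title Fuzzy linear-programming SVM
#' @name kernel_svm
#' @description
#' The instance-weighted (fuzzy) linear-programming SVM: an RBF kernel, the
#' LP assembly and solve, discriminant evaluation, and the reduced-column
#' variant for large PSM collections, where only a random subset of kernel
#' columns enters the model.
NULL

#' Kernel / LP configuration
#'
#' @param sigma RBF bandwidth \eqn{\sigma > 0} in
#'   \eqn{k(x_1,x_2) = \exp(-\|x_1-x_2\|^2 / (2\sigma^2))}; default 2.0.
#' @param c Slack penalty \eqn{c > 0}; default 1.0.
#' @param column_fraction Fraction of kernel columns used by the model, in
#'   (0, 1]. 1 solves the full problem; smaller values activate the
#'   reduced-column mode.
#' @param seed Integer seed for column sampling.
#' @return A list of class `"kernel_config"`.
#' @export
kernel_config <- function(sigma = 2.0, c = 1.0, column_fraction = 1.0,
                          seed = 1L) {
  stopifnot(sigma > 0, c > 0,
            column_fraction > 0, column_fraction <= 1)
  structure(list(kernel = "rbf", sigma = sigma, c = c,
                 column_fraction = column_fraction, seed = as.integer(seed)),
            class = "kernel_config")
}

#' Gaussian (RBF) kernel between two feature vectors
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param sigma Bandwidth, > 0.
#' @return \eqn{\exp(-\|x_1-x_2\|^2/(2\sigma^2))}, in (0, 1].
#' @export
rbf_kernel <- function(x1, x2, sigma = 2.0) {
  if (length(x1) != length(x2)) stop("dimension mismatch in rbf_kernel")
  stopifnot(sigma > 0)
  exp(-sum((x1 - x2)^2) / (2 * sigma^2))
}

#' Kernel matrix between row and column index sets
#'
#' @param X Feature matrix (rows = PSMs).
#' @param rows,cols Integer index vectors into the rows of `X`; `cols`
#'   defaults to `rows`.
#' @param cfg A [kernel_config()].
#' @return The `length(rows)` x `length(cols)` RBF kernel matrix.
#' @export
kernel_matrix <- function(X, rows = seq_len(nrow(X)), cols = rows,
                          cfg = kernel_config()) {
  if (length(cols) == 0L) stop("empty column index set")
  A <- X[rows, , drop = FALSE]
  B <- X[cols, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical guard
  exp(-d2 / (2 * cfg$sigma^2))
}

#' Sample a reduced kernel-column index set
#'
#' Uniform sample without replacement of `max(1, round(fraction * n))`
#' indices, deterministic given the seed. `fraction = 1` returns the set
#' unchanged.
#'
#' @param omega Integer index set.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Sorted integer subset of `omega`.
#' @export
sample_columns <- function(omega, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(omega)
  k <- max(1L, round(fraction * length(omega)))
  sort(.with_local_seed(seed, sample(omega, k)))
}

#' Fit the fuzzy linear-programming SVM
#'
#' Solves
#' \deqn{\min_{\alpha, b, r, \xi} \; -r + c \sum_i \theta_i \xi_i}
#' subject to \eqn{y_i(\sum_{j} \alpha_j y'_j K_{ij} + b) \ge r - \xi_i}
#' for every training row, \eqn{-1 \le \alpha_j \le 1}, \eqn{\xi_i \ge 0},
#' \eqn{r \ge 0} and free offset \eqn{b}. With \eqn{\theta \equiv 1} this is
#' the plain linear-programming SVM; general \eqn{\theta \in [0,1]}
#' down-weights the slack cost of untrusted target rows. In reduced-column
#' mode `K` has one column per sampled index and the sum runs over those
#' columns only.
#'
#' @param K Kernel matrix, training rows by model columns.
#' @param y Labels in \{-1, +1\} for the rows of `K`.
#' @param yprime Labels for the columns of `K` (equal to `y` in full mode).
#' @param theta Instance weights in [0, 1] for the rows (decoys must be 1).
#' @param cfg A [kernel_config()] (supplies `c`).
#' @param column_indices Optional integer identity of the columns, stored in
#'   the model for alignment checks.
#' @return An object of class `"fcr_svm"`: list with `alpha`, `b`, `r`,
#'   `xi`, `column_indices`, `objective`, `solver_status`.
#' @export
fit_fuzzy_lp_svm <- function(K, y, yprime = y, theta = rep(1, length(y)),
                             cfg = kernel_config(),
                             column_indices = seq_len(ncol(K))) {
  K <- as.matrix(K)
  l <- nrow(K); lp <- ncol(K)
  stopifnot(length(y) == l, length(yprime) == lp, length(theta) == l,
            all(y %in% c(-1, 1)), all(yprime %in% c(-1, 1)),
            all(theta >= 0), all(theta <= 1), lp <= l,
            length(column_indices) == lp)
  Hm <- (y * K) * rep(yprime, each = l)    # Diag(y) K Diag(y')
  sol <- .lpsvm_ipm(Hm, y, cost_xi = cfg$c * theta)
  structure(list(alpha = sol$alpha, b = sol$b, r = sol$r, xi = sol$xi,
                 column_indices = column_indices, objective = sol$objective,
                 solver_status = sol$status, iterations = sol$iterations),
            class = "fcr_svm")
}

#' @export
print.fcr_svm <- function(x, ...) {
  cat(sprintf(
    "fuzzy LP-SVM: %d columns, r = %.6g, objective = %.6g (%s, %d IPM iters)\n",
    length(x$alpha), x$r, x$objective, x$solver_status, x$iterations))
  invisible(x)
}

#' Evaluate the SVM discriminant
#'
#' \eqn{f(x) = \sum_j \alpha_j y'_j k(x_j, x) + b} over the model columns.
#'
#' @param model An `"fcr_svm"`.
#' @param K_eval Kernel matrix, evaluation rows by model columns.
#' @param yprime Column labels, aligned with `model$column_indices`.
#' @return Numeric discriminant value per evaluation row.
#' @export
discriminant <- function(model, K_eval, yprime) {
  K_eval <- as.matrix(K_eval)
  if (ncol(K_eval) != length(model$alpha) ||
      length(yprime) != length(model$alpha))
    stop("kernel columns misaligned with model columns")
  drop(K_eval %*% (model$alpha * yprime)) + model$b
}

# Evaluate an expression with a temporary RNG state; restores .Random.seed.
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
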