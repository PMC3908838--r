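#' @title Silhouette and fuzzy silhouette indices
#' @name fuzzy_clustering
#' @description
#' The classic silhouette cluster-validity index (reference form), its
#' \eqn{\theta}-weighted fuzzy generalization over the good-target and
#' decoy sets, the class-average silhouettes and the separation statistic
#' `sep`, plus a row-subsampled variant for large collections.
NULL

#' Silhouette configuration
#'
#' @param distance Distance metric; only `"euclidean"` is supported.
#' @param rho Sample rate \eqn{\rho \in (0, 1]}: with \eqn{\rho < 1} the
#'   weighted averages run over a seeded \eqn{\rho}-subsample of each class.
#' @param seed Integer seed for the subsample.
#' @return A list of class `"silhouette_config"`.
#' @export
silhouette_config <- function(distance = "euclidean", rho = 1.0, seed = 1L) {
  stopifnot(identical(distance, "euclidean"), rho > 0, rho <= 1)
  structure(list(distance = distance, rho = rho, seed = as.integer(seed)),
            class = "silhouette_config")
}

# Full Euclidean distance matrix, computed termwise (no quadratic
# expansion): silhouette identities are asserted to 1e-12, which the
# crossprod shortcut cannot deliver.
.dist_matrix <- function(X) {
  unname(as.matrix(stats::dist(X)))
}

#' Classic silhouette values
#'
#' For point \eqn{i} in cluster \eqn{C_k},
#' \eqn{s_i = (b_i - a_i)/\max\{a_i, b_i\}} with \eqn{a_i} the mean
#' within-cluster distance and \eqn{b_i} the minimum mean distance to any
#' other cluster. Points in singleton clusters get 0, the conventional
#' neutral value.
#'
#' @param points Numeric matrix, one row per point.
#' @param clusters Cluster assignment vector (any type; coerced to factor).
#' @param orient_toward Optional cluster label (two-cluster case only).
#'   When given, values for members of the other cluster are sign-flipped,
#'   so positive always means "sits with `orient_toward`". This oriented
#'   two-group form is the deterministic reference that the fuzzy
#'   silhouette reduces to at unit weights: the fuzzy index is oriented
#'   toward the good-target group for every sample, decoys included.
#' @return Silhouette value per point, in [-1, 1].
#' @export
classic_silhouette <- function(points, clusters, orient_toward = NULL) {
  points <- as.matrix(points)
  fac <- factor(clusters)
  cl <- as.integer(fac)
  n <- nrow(points)
  stopifnot(length(cl) == n)
  K <- max(cl)
  if (K < 2L) stop("at least two clusters are required")
  if (!is.null(orient_toward) && K != 2L)
    stop("orient_toward requires exactly two clusters")
  D <- .dist_matrix(points)
  sizes <- tabulate(cl, K)
  # mean distance from each point to each cluster (including own, incl. self)
  sums <- sapply(seq_len(K), function(k) rowSums(D[, cl == k, drop = FALSE]))
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- cl[i]
    if (sizes[k] < 2L) { s[i] <- 0; next }
    a <- sums[i, k] / (sizes[k] - 1L)          # self distance is 0
    b <- min(sums[i, -k] / sizes[-k])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  if (!is.null(orient_toward)) {
    ref <- which(levels(fac) == as.character(orient_toward))
    if (length(ref) != 1L) stop("orient_toward is not a cluster label")
    s[cl != ref] <- -s[cl != ref]
  }
  s
}

#' Fuzzy (weighted) silhouette over the good-target and decoy sets
#'
#' For every row \eqn{i} of `X`, the weighted average distance to each of
#' the two reference sets is
#' \deqn{\beta_i^k = \frac{\sum_{j \in \Omega_k, j \ne i} \theta_j d(x_i, x_j)}
#'                        {\sum_{j \in \Omega_k, j \ne i} \theta_j}, \quad
#'        k \in \{1, -1\},}
#' and the fuzzy silhouette is
#' \eqn{s_i = (\beta_i^{-1} - \beta_i^{1}) / \max\{\beta_i^{-1}, \beta_i^{1}\}}.
#' Values are computed for every row, including rows outside both sets
#' (the `j != i` exclusion only applies inside the row's own set). With
#' `cfg$rho < 1` each reference set is replaced by a seeded
#' \eqn{\rho}-subsample of itself.
#'
#' @param X Feature matrix (rows = PSMs).
#' @param theta Weights in [0, 1] per row; decoys should be 1.
#' @param omega1 Indices of the good-target set \eqn{\Omega_1}.
#' @param omega_neg Indices of the decoy set \eqn{\Omega_{-1}}.
#' @param cfg A [silhouette_config()].
#' @return A list of class `"silhouette_state"`: `s`, `beta_pos`,
#'   `beta_neg` per row.
#' @export
fuzzy_silhouette <- function(X, theta, omega1, omega_neg,
                             cfg = silhouette_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(theta) == n, all(theta >= 0), all(theta <= 1))
  if (length(omega1) == 0L || length(omega_neg) == 0L)
    stop("both reference sets must be nonempty")
  if (length(intersect(omega1, omega_neg)) > 0L)
    stop("omega1 and omega_neg must be disjoint")

  s1 <- omega1; s2 <- omega_neg
  if (cfg$rho < 1) {
    s1 <- .with_local_seed(cfg$seed,
      sort(sample(omega1, max(1L, round(cfg$rho * length(omega1))))))
    s2 <- .with_local_seed(cfg$seed + 1L,
      sort(sample(omega_neg, max(1L, round(cfg$rho * length(omega_neg))))))
  }

  D_full <- .dist_matrix(X)
  beta_class <- function(sub, class_name) {
    D <- D_full[, sub, drop = FALSE]
    num <- drop(D %*% theta[sub])
    den <- rep(sum(theta[sub]), n)
    # self exclusion: d(i,i) = 0 leaves the numerator untouched
    den[sub] <- den[sub] - theta[sub]
    own_zero <- den <= 0 & seq_len(n) %in% sub
    if (any(den <= 0 & !own_zero))
      stop("class ", class_name, " has zero weight mass")
    beta <- num / den
    beta[own_zero] <- NA_real_   # singleton convention resolved below
    beta
  }
  beta_pos <- beta_class(s1, "omega1")
  beta_neg <- beta_class(s2, "omega_neg")

  s <- numeric(n)
  ok <- !is.na(beta_pos) & !is.na(beta_neg)
  mx <- pmax(beta_pos[ok], beta_neg[ok])
  s[ok] <- ifelse(mx > 0, (beta_neg[ok] - beta_pos[ok]) / mx, 0)
  if (any(!ok)) {
    warning("singleton/zero-mass own set: silhouette set to 0 for ",
            sum(!ok), " point(s)")
    s[!ok] <- 0
  }
  structure(list(s = s, beta_pos = beta_pos, beta_neg = beta_neg,
                 sampled_pos = s1, sampled_neg = s2),
            class = "silhouette_state")
}

#' Class-average silhouettes and the separation statistic
#'
#' \eqn{\bar s_k} is the plain average of \eqn{s_i} over each index set and
#' \eqn{sep = (\bar s_1 - \bar s_{-1})/2} measures how far the good-target
#' set has moved away from the decoys; it is also the mixing weight between
#' classifier and clustering evidence in the PSM score.
#'
#' @param state A `"silhouette_state"` (or any list with element `s`).
#' @param omega1,omega_neg,omega0 Index sets (good targets, decoys, bad
#'   targets; `omega0` may be empty).
#' @return List with `s_bar_pos`, `s_bar_neg`, `s_bar_zero` (NA when
#'   `omega0` is empty) and `sep`.
#' @export
separation <- function(state, omega1, omega_neg, omega0 = integer(0)) {
  s <- state$s
  if (length(omega1) == 0L)
    stop("omega1 is empty: the good-target set has degenerated")
  if (length(omega_neg) == 0L) stop("omega_neg is empty")
  s_bar_pos <- mean(s[omega1])
  s_bar_neg <- mean(s[omega_neg])
  s_bar_zero <- if (length(omega0) > 0L) mean(s[omega0]) else NA_real_
  list(s_bar_pos = s_bar_pos, s_bar_neg = s_bar_neg,
       s_bar_zero = s_bar_zero, sep = (s_bar_pos - s_bar_neg) / 2)
}
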