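#' @title The iterative ranker
#' @name ranker
#' @description
#' The main loop: fit the fuzzy LP-SVM with the current instance weights,
#' cut the good-target set by discriminant rank, compute fuzzy silhouettes,
#' cut again by silhouette rank, rescore, reweight, promote strong leftovers
#' back, and stop when the good set separates from the decoys (or
#' degenerates).
NULL

#' Ranker configuration
#'
#' @param n_percent Retention percentage for each ranking cut, in (0, 100);
#'   default 70 (each iteration keeps the top 70\% by discriminant, then the
#'   top 70\% of those by silhouette).
#' @param p_hat_fraction Collapse threshold as a fraction of the target
#'   count: the run stops when \eqn{|\Omega_1| \le \hat p =}
#'   `p_hat_fraction * |targets|`. Default 0.03.
#' @param sep_hat Separation threshold \eqn{\widehat{sep}} for successful
#'   termination; default 0.25.
#' @param max_iterations Safety cap on iterations; default 100.
#' @param kernel A [kernel_config()].
#' @param silhouette A [silhouette_config()].
#' @param scoring A [scoring_config()].
#' @param seed Master seed; all per-iteration sampling seeds derive from it.
#' @param verbose Log one line per iteration.
#' @return A list of class `"ranker_config"`.
#' @export
ranker_config <- function(n_percent = 70, p_hat_fraction = 0.03,
                          sep_hat = 0.25, max_iterations = 100L,
                          kernel = kernel_config(),
                          silhouette = silhouette_config(),
                          scoring = scoring_config(),
                          seed = 1L, verbose = FALSE) {
  stopifnot(n_percent > 0, n_percent < 100,
            p_hat_fraction > 0, p_hat_fraction < 1, max_iterations >= 1)
  structure(list(n_percent = n_percent, p_hat_fraction = p_hat_fraction,
                 sep_hat = sep_hat, max_iterations = as.integer(max_iterations),
                 kernel = kernel, silhouette = silhouette, scoring = scoring,
                 seed = as.integer(seed), verbose = verbose),
            class = "ranker_config")
}

#' Initial iteration state
#'
#' All target PSMs start in the good set \eqn{\Omega_1} and every instance
#' weight is 1: before any evidence, every target is taken at face value.
#'
#' @param coll A `psm_collection` with at least one target and one decoy.
#' @return List with `omega1`, `omega0`, `theta`, `k = 0`.
#' @export
init_state <- function(coll) {
  tg <- target_indices(coll)
  dc <- decoy_indices(coll)
  if (length(tg) == 0L) stop("collection has no target PSMs")
  if (length(dc) == 0L) stop("collection has no decoy PSMs")
  list(k = 0L, omega1 = tg, omega0 = integer(0), theta = rep(1, nrow(coll)))
}

#' Top-fraction selection by value rank
#'
#' Keeps the \eqn{\lceil n/100 \cdot |pool| \rceil} pool indices with the
#' largest values (ceiling, so the selection is never empty); ties are
#' broken by ascending original index.
#'
#' @param values Numeric vector indexed by original position.
#' @param pool Integer index set to select from.
#' @param n_percent Percentage in (0, 100).
#' @return Sorted integer subset of `pool`.
#' @export
top_fraction <- function(values, pool, n_percent) {
  if (length(pool) == 0L) stop("pool is empty")
  k <- ceiling(n_percent / 100 * length(pool))
  ranked <- pool[order(-values[pool], pool)]
  sort(ranked[seq_len(k)])
}

#' Two-stage refinement of the good-target set
#'
#' First cut: top `n_percent` of \eqn{\Omega_1} by discriminant value;
#' second cut: top `n_percent` of the survivors by silhouette. The partial
#' bad set is everything else in \eqn{\Omega_+}.
#'
#' @param omega1 Current good-target index set.
#' @param targets All target indices \eqn{\Omega_+}.
#' @param f Discriminant value per PSM.
#' @param s Silhouette value per PSM.
#' @param n_percent Retention percentage.
#' @return List with `omega1_two_thirds` and `omega0_partial`.
#' @export
refine_sets <- function(omega1, targets, f, s, n_percent = 70) {
  if (length(omega1) == 0L) stop("omega1 is empty: the run should have stopped")
  third <- top_fraction(f, omega1, n_percent)
  two_thirds <- top_fraction(s, third, n_percent)
  list(omega1_two_thirds = two_thirds,
       omega0_partial = setdiff(targets, two_thirds))
}

#' Promote strong bad-set members back into the good set
#'
#' Any member of the partial bad set whose discriminant value reaches the
#' mean discriminant of the surviving good set is promoted back (inclusive
#' comparison).
#'
#' @param omega1_two_thirds Surviving good set after both cuts.
#' @param omega0_partial Partial bad set.
#' @param f Discriminant value per PSM.
#' @param targets All target indices.
#' @return List with `omega1` and `omega0` for the next iteration.
#' @export
promote_by_mean <- function(omega1_two_thirds, omega0_partial, f, targets) {
  if (length(omega1_two_thirds) == 0L) stop("empty good set before promotion")
  f_bar <- mean(f[omega1_two_thirds])
  promoted <- omega0_partial[f[omega0_partial] >= f_bar]
  omega1 <- sort(union(omega1_two_thirds, promoted))
  list(omega1 = omega1, omega0 = setdiff(targets, omega1))
}

#' Termination decision
#'
#' Stops when the separation statistic reaches `sep_hat` (`"sep_reached"`),
#' when the good set collapses to at most \eqn{\hat p} members
#' (`"omega1_collapsed"`), or when the iteration cap is hit
#' (`"max_iterations"`).
#'
#' @param omega1_size Size of the next good set.
#' @param sep Current separation value.
#' @param cfg A [ranker_config()].
#' @param k Current iteration counter (0-based).
#' @param n_targets Number of target PSMs (defines \eqn{\hat p}).
#' @return `NULL` to continue, otherwise the termination label.
#' @export
check_stop <- function(omega1_size, sep, cfg, k, n_targets) {
  p_hat <- cfg$p_hat_fraction * n_targets
  if (sep >= cfg$sep_hat) return("sep_reached")
  if (omega1_size <= p_hat) return("omega1_collapsed")
  if (k + 1L >= cfg$max_iterations) return("max_iterations")
  NULL
}

#' Run the full iterative ranker
#'
#' Executes the complete loop over a PSM collection. Within one iteration
#' the order is: fit the weighted LP-SVM, evaluate the discriminant `f`,
#' cut \eqn{\Omega_1} by `f`, compute fuzzy silhouettes `s` against the cut
#' set, cut again by `s`, compute the class-average silhouettes and `sep`,
#' compute scores \eqn{(1-sep)\varphi + sep\,\psi} and the next weights
#' \eqn{\theta}, promote strong bad-set members back by mean discriminant,
#' then test the stopping rule. Deterministic given the master seed.
#'
#' @param coll A `psm_collection`.
#' @param X Optional precomputed [build_feature_matrix()] result; built
#'   with default preprocessing when omitted.
#' @param cfg A [ranker_config()].
#' @return An object of class `"fcr_result"`: per-PSM `final_scores`,
#'   `theta`, `f`, `silhouette`, `final_omega1`, an iteration `trace`
#'   data frame and the `termination` label.
#' @export
run_fc_ranker <- function(coll, X = NULL, cfg = ranker_config()) {
  stopifnot(inherits(coll, "psm_collection"))
  if (is.null(X)) X <- build_feature_matrix(coll)
  n <- nrow(coll)
  stopifnot(nrow(X) == n)
  targets <- target_indices(coll)
  decoys <- decoy_indices(coll)
  y <- psm_labels(coll)

  state <- init_state(coll)
  omega1 <- state$omega1
  theta <- state$theta
  full_cols <- cfg$kernel$column_fraction >= 1
  K_full <- if (full_cols) kernel_matrix(X, seq_len(n), seq_len(n), cfg$kernel)

  trace <- list()
  termination <- "max_iterations"
  f <- s <- score <- numeric(n)
  final_omega1 <- omega1

  for (k in seq_len(cfg$max_iterations) - 1L) {
    # classification
    if (full_cols) {
      omega_prime <- seq_len(n)
      K <- K_full
    } else {
      omega_prime <- sample_columns(seq_len(n), cfg$kernel$column_fraction,
                                    seed = cfg$seed + 7919L * k)
      K <- kernel_matrix(X, seq_len(n), omega_prime, cfg$kernel)
    }
    model <- fit_fuzzy_lp_svm(K, y, y[omega_prime], theta, cfg$kernel,
                              column_indices = omega_prime)
    f <- discriminant(model, K, y[omega_prime])
    omega1_third <- top_fraction(f, omega1, cfg$n_percent)

    # clustering
    sil_cfg <- cfg$silhouette
    sil_cfg$seed <- cfg$seed + 104729L + 2L * k
    st <- fuzzy_silhouette(X, theta, omega1_third, decoys, sil_cfg)
    s <- st$s
    omega1_two_thirds <- top_fraction(s, omega1_third, cfg$n_percent)
    omega0_partial <- setdiff(targets, omega1_two_thirds)
    sep_info <- separation(st, omega1_two_thirds, decoys, omega0_partial)

    # scores and weights
    phi <- phi_scale(f, targets, cfg$scoring)
    psi <- psi_scale(s, targets, cfg$scoring)
    score <- combine_scores(phi, psi, clamp_sep(sep_info$sep))
    theta <- update_weights(score, coll)

    nxt <- promote_by_mean(omega1_two_thirds, omega0_partial, f, targets)
    trace[[k + 1L]] <- data.frame(
      iter = k, n_omega1 = length(nxt$omega1),
      s_bar_pos = sep_info$s_bar_pos, s_bar_neg = sep_info$s_bar_neg,
      s_bar_zero = sep_info$s_bar_zero, sep = sep_info$sep,
      objective = model$objective)
    if (cfg$verbose)
      message(sprintf("iter %d: |omega1| = %d, sep = %.4f, objective = %.5g",
                      k, length(nxt$omega1), sep_info$sep, model$objective))

    final_omega1 <- nxt$omega1
    stop_label <- check_stop(length(nxt$omega1), sep_info$sep, cfg, k,
                             length(targets))
    if (!is.null(stop_label)) { termination <- stop_label; break }
    omega1 <- nxt$omega1
  }

  structure(list(final_scores = score, theta = theta, f = f, silhouette = s,
                 final_omega1 = final_omega1,
                 trace = do.call(rbind, trace), termination = termination,
                 config = cfg),
            class = "fcr_result")
}

#' @export
print.fcr_result <- function(x, ...) {
  cat(sprintf(
    "ranker result: %d iteration(s), termination = %s, final sep = %.4f\n",
    nrow(x$trace), x$termination, x$trace$sep[nrow(x$trace)]))
  cat(sprintf("final good-target set: %d PSMs\n", length(x$final_omega1)))
  invisible(x)
}

#' Attach ranker outputs to the PSM table
#'
#' @param coll A `psm_collection`.
#' @param result An `"fcr_result"` from [run_fc_ranker()].
#' @return The collection data frame with columns `score`, `theta`, `f`,
#'   `silhouette`, `in_omega1` appended.
#' @export
annotate_scores <- function(coll, result) {
  out <- as.data.frame(coll)
  out$score <- result$final_scores
  out$theta <- result$theta
  out$f <- result$f
  out$silhouette <- result$silhouette
  out$in_omega1 <- as.integer(seq_len(nrow(out)) %in% result$final_omega1)
  out
}
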