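# In-code fixtures shared across test files.

# Minimal PSM collection: xcorr carries the structure, everything else is
# constant unless overridden.
make_coll <- function(xcorr, is_decoy, truth = NULL, digest_type = NULL) {
  n <- length(xcorr)
  df <- data.frame(
    psm_id = sprintf("p%03d", seq_len(n)),
    spectrum_ref = sprintf("s%03d", seq_len(n)),
    peptide = NA_character_,
    is_decoy = is_decoy,
    xcorr = xcorr, delta_cn = 0.1, ions = 10, sprank = 1,
    calc_neutral_pep_mass = 1000,
    digest_type = if (is.null(digest_type)) 2 else digest_type,
    stringsAsFactors = FALSE)
  if (!is.null(truth)) df$truth <- truth
  psm_collection(df)
}

# Random small LP-SVM instance on an RBF kernel. Target weights are kept
# away from zero so that each class carries enough slack-cost mass for the
# LP to be bounded (with c = 1 the objective is unbounded below as soon as
# one class's theta-mass drops under 1/2).
rand_lp_instance <- function(l_max = 20, q_max = 4) {
  l <- sample(6:l_max, 1)
  q <- sample(1:q_max, 1)
  X <- matrix(rnorm(l * q), l, q)
  y <- sample(c(-1, 1), l, replace = TRUE)
  while (sum(y > 0) < 3 || sum(y < 0) < 2)
    y <- sample(c(-1, 1), l, replace = TRUE)
  theta <- ifelse(y < 0, 1, runif(l, 0.3, 1))
  K <- kernel_matrix(X, seq_len(l), seq_len(l), kernel_config())
  list(X = X, y = y, theta = theta, K = K, l = l, q = q)
}

# Cache for the expensive shared scenario runs used by several
# acceptance-style checks.
.fcr_test_cache <- new.env(parent = emptyenv())

cached_default_run <- function(seed, reduced = FALSE) {
  key <- paste0(if (reduced) "red" else "exact", seed)
  if (is.null(.fcr_test_cache[[key]])) {
    coll <- generate_psms(scenario("default", seed = seed))
    cfg <- if (reduced) {
      ranker_config(seed = seed,
                    kernel = kernel_config(column_fraction = 0.2),
                    silhouette = silhouette_config(rho = 0.2))
    } else {
      ranker_config(seed = seed)
    }
    res <- suppressWarnings(run_fc_ranker(coll, cfg = cfg))
    tg <- target_indices(coll)
    .fcr_test_cache[[key]] <- list(
      coll = coll, res = res,
      pos = which(coll$truth), neg = tg[!coll$truth[tg]])
  }
  .fcr_test_cache[[key]]
}
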