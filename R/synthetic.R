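#' @title Synthetic PSM generator
#' @name synthetic
#' @description
#' Generates PSM collections with the statistical structure the ranker
#' assumes: a compact cluster of correct target PSMs, incorrect targets
#' drawn from the same distribution as the decoys (the core premise of
#' target-decoy validation), and decoys — all with ground-truth labels, so
#' every stage of the method is testable without mass-spectrometry data.
NULL

# Direction of the class-mean shift across the five continuous attributes.
# X-correlation carries most of the planted signal, mirroring its dominant
# discriminating role among SEQUEST attributes.
.fcr_shift_direction <- c(3, 1, 1, 1, 1) / sqrt(13)

# Monotone affine maps from standard-normal latents onto plausible
# SEQUEST attribute ranges (intercept, slope).
.fcr_attr_maps <- list(
  xcorr = c(1.8, 0.9), delta_cn = c(0.12, 0.07), ions = c(12, 5),
  sprank = c(5, 3), calc_neutral_pep_mass = c(1500, 300))

#' Synthetic-data configuration
#'
#' @param n_targets,n_decoys Record counts (each >= 1).
#' @param good_fraction Fraction of targets that are planted-correct,
#'   in (0, 1).
#' @param q Feature count (default 6: five continuous attributes plus the
#'   digest type).
#' @param mean_shift Euclidean distance between the good-target mean and
#'   the incorrect/decoy mean in the continuous latent space, in units of
#'   the within-group standard deviation. Default 3.0.
#' @param noise_sd Within-group standard deviation per coordinate;
#'   default 1.0.
#' @param digest_type_probs List with elements `good` and `bad`: probability
#'   triples over (full, half, none) for planted-correct targets and for
#'   incorrect targets/decoys respectively.
#' @param seed Integer seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_targets = 300L, n_decoys = 300L,
                             good_fraction = 1 / 3, q = 6L,
                             mean_shift = 3.0, noise_sd = 1.0,
                             digest_type_probs = list(
                               good = c(full = 0.65, half = 0.25, none = 0.10),
                               bad = c(full = 0.02, half = 0.18, none = 0.80)),
                             seed = 1L) {
  stopifnot(n_targets >= 1L, n_decoys >= 1L,
            good_fraction > 0, good_fraction < 1,
            mean_shift >= 0, noise_sd > 0, q >= 2L)
  for (p in digest_type_probs) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("digest_type_probs must be two probability triples summing to 1")
  }
  structure(list(n_targets = as.integer(n_targets),
                 n_decoys = as.integer(n_decoys),
                 good_fraction = good_fraction, q = as.integer(q),
                 mean_shift = mean_shift, noise_sd = noise_sd,
                 digest_type_probs = digest_type_probs,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Named study scenarios
#'
#' `default`: 300 targets, 300 decoys, a third of targets planted-correct,
#' class-mean shift 3.0 — a clearly separable collection. `null`: shift 0
#' and identical digest-type distributions for both classes, so
#' planted-true and planted-false records are exchangeable (no signal to
#' find). `hard`: shift 1.0 — heavy overlap.
#'
#' @param name One of `"default"`, `"null"`, `"hard"`.
#' @param seed Integer seed passed through to the config.
#' @return A [synthetic_config()].
#' @export
scenario <- function(name = c("default", "null", "hard"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    default = synthetic_config(seed = seed),
    null = synthetic_config(
      mean_shift = 0,
      digest_type_probs = list(
        good = c(full = 0.02, half = 0.18, none = 0.80),
        bad = c(full = 0.02, half = 0.18, none = 0.80)),
      seed = seed),
    hard = synthetic_config(mean_shift = 1.0, seed = seed))
}

#' Generate a synthetic PSM collection
#'
#' Planted-correct targets are drawn from a spherical Gaussian at the good
#' mean; incorrect targets and decoys share a spherical Gaussian at the bad
#' mean, `mean_shift * noise_sd` away. Latent coordinates are mapped onto
#' plausible attribute ranges by monotone affine maps, and the digest type
#' is drawn from the class-conditional triples. Deterministic given the
#' seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A [psm_collection()] with a `truth` column (TRUE for
#'   planted-correct targets).
#' @export
generate_psms <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_good <- round(cfg$good_fraction * cfg$n_targets)
  n_bad_t <- cfg$n_targets - n_good
  n <- cfg$n_targets + cfg$n_decoys
  q_cont <- length(.fcr_attr_maps)

  .with_local_seed(cfg$seed, {
    mu_good <- cfg$mean_shift * cfg$noise_sd * .fcr_shift_direction
    lat <- matrix(stats::rnorm(n * q_cont, sd = cfg$noise_sd), n, q_cont)
    good_rows <- seq_len(n_good)
    lat[good_rows, ] <- sweep(lat[good_rows, , drop = FALSE], 2L, mu_good, `+`)

    df <- data.frame(
      psm_id = sprintf("psm_%05d", seq_len(n)),
      spectrum_ref = sprintf("spec_%05d", seq_len(n)),
      peptide = NA_character_,
      is_decoy = rep(c(FALSE, TRUE), c(cfg$n_targets, cfg$n_decoys)),
      stringsAsFactors = FALSE)
    for (j in seq_len(q_cont)) {
      m <- .fcr_attr_maps[[j]]
      df[[names(.fcr_attr_maps)[j]]] <- m[1] + m[2] * lat[, j]
    }
    cls_good <- rep(c(TRUE, FALSE), c(n_good, n - n_good))
    codes <- c(full = 2, half = 1, none = 0)
    dt <- numeric(n)
    dt[cls_good] <- sample(codes, n_good, replace = TRUE,
                           prob = cfg$digest_type_probs$good)
    dt[!cls_good] <- sample(codes, n - n_good, replace = TRUE,
                            prob = cfg$digest_type_probs$bad)
    df$digest_type <- dt
    df$truth <- cls_good & !df$is_decoy
    psm_collection(df)
  })
}
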