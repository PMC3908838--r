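#' @title Score scaling, combination and weight update
#' @name scoring
#' @description
#' Scales the SVM discriminant values (\eqn{\varphi}) and fuzzy silhouette
#' values (\eqn{\psi}) onto comparable ranges, mixes them into a per-PSM
#' score using the separation statistic `sep`, and turns target scores into
#' the fuzzy instance weights \eqn{\theta}.
NULL

#' Scoring configuration
#'
#' @param f0 Discriminant threshold \eqn{f_0}: the "uncertain" point of the
#'   discriminant scale (default 0, the decision boundary).
#' @param s0 Silhouette threshold \eqn{s_0} (default 0, the neutral
#'   silhouette).
#' @return A list of class `"scoring_config"`.
#' @export
scoring_config <- function(f0 = 0, s0 = 0) {
  stopifnot(is.finite(f0), is.finite(s0))
  structure(list(f0 = f0, s0 = s0), class = "scoring_config")
}

#' Scale discriminant values
#'
#' \deqn{\varphi(f) = \frac{2}{\pi}\,\mathrm{sign}(f - f_0)\,
#'   \arctan\!\Big(\big(|f - f_0| / f_{\max}\big)^{1/4}\Big)}
#' with \eqn{f_{\max} = \max_{i \in \Omega_+} |f(x_i) - f_0|} taken over the
#' target PSMs. The 1/4 power flattens the scale so that moderately and
#' strongly separated targets contribute similar weight. Degenerate
#' \eqn{f_{\max} = 0} yields \eqn{\varphi \equiv 0}.
#'
#' @param f Discriminant value per PSM.
#' @param targets Indices of the target PSMs \eqn{\Omega_+}.
#' @param cfg A [scoring_config()].
#' @return \eqn{\varphi} per PSM, in (-1, 1).
#' @export
phi_scale <- function(f, targets, cfg = scoring_config()) {
  if (length(targets) == 0L) stop("target set is empty")
  dev <- f - cfg$f0
  f_max <- max(abs(dev[targets]))
  if (f_max == 0) return(numeric(length(f)))
  (2 / pi) * sign(dev) * atan((abs(dev) / f_max)^(1 / 4))
}

#' Scale silhouette values
#'
#' \eqn{\psi(s) = (s - s_0)/s_{\max}} with
#' \eqn{s_{\max} = \max_{i \in \Omega_+} |s_i - s_0|} over the targets.
#' Degenerate \eqn{s_{\max} = 0} yields \eqn{\psi \equiv 0}.
#'
#' @param s Fuzzy silhouette per PSM.
#' @param targets Indices of the target PSMs.
#' @param cfg A [scoring_config()].
#' @return \eqn{\psi} per PSM (bounded by 1 in absolute value over the
#'   targets; decoys may exceed it and are reported unclamped).
#' @export
psi_scale <- function(s, targets, cfg = scoring_config()) {
  if (length(targets) == 0L) stop("target set is empty")
  dev <- s - cfg$s0
  s_max <- max(abs(dev[targets]))
  if (s_max == 0) return(numeric(length(s)))
  dev / s_max
}

#' Combine classifier and clustering evidence into PSM scores
#'
#' \eqn{score(i) = (1 - sep)\,\varphi_i + sep\,\psi_i}. As the good-target
#' set separates from the decoys (`sep` grows), the silhouette evidence
#' gains influence over the classifier evidence.
#'
#' @param phi,psi Scaled values per PSM.
#' @param sep Mixing weight; clamp to [0, 1] with [clamp_sep()] before use.
#' @return Score per PSM.
#' @export
combine_scores <- function(phi, psi, sep) {
  stopifnot(is.finite(sep), length(phi) == length(psi))
  (1 - sep) * phi + sep * psi
}

#' Clamp the separation statistic to [0, 1]
#'
#' Early iterations can yield slightly negative `sep`; a negative mixing
#' weight would invert the meaning of the silhouette contribution, so the
#' value entering the score combination is clamped.
#'
#' @param sep Raw separation value.
#' @return `min(max(sep, 0), 1)`.
#' @export
clamp_sep <- function(sep) min(max(sep, 0), 1)

#' Update the fuzzy instance weights
#'
#' \eqn{\theta_i = \max\{score(i), 0\}} for targets; decoys are certainly
#' incorrect, so their weights stay fixed at 1.
#'
#' @param score Score per PSM.
#' @param coll The `psm_collection` (supplies the target/decoy split).
#' @return \eqn{\theta} per PSM, in [0, 1] whenever `sep` was in [0, 1].
#' @export
update_weights <- function(score, coll) {
  stopifnot(length(score) == nrow(coll))
  theta <- pmax(score, 0)
  theta[decoy_indices(coll)] <- 1
  theta
}
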