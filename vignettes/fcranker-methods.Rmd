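---
title: "Rescoring PSMs with a fuzzy LP-SVM and a fuzzy silhouette"
author: "fcranker authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring PSMs with a fuzzy LP-SVM and a fuzzy silhouette}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcranker)
```

## The problem

A database search engine matches each MS/MS spectrum against candidate
peptides and reports the best peptide-spectrum match (PSM) with quality
attributes (for SEQUEST: x-correlation, delta-cn, ions, sprank,
calc-neutral-pep-mass). Well over half of the reported target PSMs are
typically wrong, and the search also reports decoy PSMs — matches against a
reversed/shuffled database that are incorrect by construction and calibrate
error rates. The rescoring task is semi-supervised with noisy positives:
decoy labels are trustworthy, target labels are not. This package scores
each target PSM by the possibility of it being correct, by iterating a
classifier that tolerates unreliable positive labels against a clustering
index that measures whether a PSM sits with the putative good targets or
with the decoys.

## Feature representation

Each PSM is a vector of the five continuous search-engine attributes plus
the encoded digest type (2 = both termini tryptic, 1 = one, 0 = neither).
Every column is standardized to zero mean and unit variance over all PSMs —
targets and decoys jointly, with population (1/N) variance — and then
multiplied by an attribute weight: 2.0 for x-correlation, delta-cn and
digest type, 1.0 for the rest. Joint scaling keeps the geometry symmetric
in class treatment; the same weighted representation feeds both the kernel
and the distance computations, so classifier and clustering evidence live
in one geometry. Constant columns map to zero rather than erroring, so
degenerate inputs cannot crash preprocessing. The normalization population
(targets + decoys rather than targets only) was a genuinely open choice;
the joint convention is the default and the recorded column means/sds make
the alternative easy to audit.

## The instance-weighted LP-SVM

Labels are $y_i = +1$ for targets and $-1$ for decoys. Each target carries
a weight $\theta_i \in [0,1]$ — its current possibility of being correct —
while decoys are pinned at $\theta_i = 1$. The classifier is a
linear-programming SVM on an RBF kernel
$k(x_1,x_2) = \exp(-\|x_1-x_2\|^2/(2\sigma^2))$ with $\sigma = 2$:

$$
\min_{\alpha, b, r, \xi}\; -r + c \sum_i \theta_i \xi_i
\quad \text{s.t.}\quad
y_i\Big(\sum_j \alpha_j y_j k(x_j, x_i) + b\Big) \ge r - \xi_i,\;
-1 \le \alpha_j \le 1,\; \xi_i \ge 0,\; r \ge 0,
$$

with $c = 1$. The margin variable $r$ is maximized while weighted slacks
are penalized; a target with small $\theta_i$ can sit on the wrong side
almost for free, so unreliable positives stop distorting the fit. With
$\theta \equiv 1$ this is the plain LP-SVM. The discriminant is
$f(x) = \sum_j \alpha_j y_j k(x_j, x) + b$.

Two properties worth knowing:

* **Feasibility** — $\alpha = 0, b = 0, r = 0, \xi = 0$ is always feasible
  with objective 0, so the optimum is never positive and infeasibility can
  only signal an assembly bug.
* **Boundedness** — along the ray $(r + t,\, b \mp t)$ only one class pays
  for slack, at rate $2c\sum_{\text{class}} \theta_i$ per unit of margin.
  The LP is therefore unbounded below as soon as one class's
  $\theta$-mass falls under $1/(2c)$. Decoys always contribute mass
  $\ge 1$; the target mass can in principle collapse in pathological runs.
  The solver detects this and raises a hard error carrying the status.

### Solving the LP

No LP solver package is available to this package, so it ships its own:
a Mehrotra predictor-corrector interior-point method specialized to this
LP's structure. The slack block of the normal matrix is diagonal, so each
Newton step reduces analytically to an $(l' + 2)$-dimensional dense
Cholesky solve plus an $O(l\,l'^2)$ assembly, where $l$ is the number of
training rows and $l'$ the number of kernel columns. Convergence is
declared at relative complementarity and residuals below $10^{-9}$; a
late-stage numerical breakdown with duality gap already below $10^{-6}$ is
accepted as near-optimal. The returned iterate is polished onto the
feasible set: $\alpha$ clamped to $[-1,1]$, $r$ to $[0,\infty)$, and
$\xi_i = \max(0, r - y_i f(x_i))$ recomputed as the minimal feasible
slacks, so the model invariants hold exactly. The test suite cross-checks
objectives against an independent assembly of the same LP solved by an
external simplex/IPM code, on dozens of random small instances, to
$10^{-6}$.

### Reduced columns for large collections

The kernel matrix is dense, and storing $l \times l$ entries is the
binding constraint at scale. The reduced mode samples
$l' = \lceil \text{fraction} \cdot l \rceil$ columns uniformly without
replacement (seeded, redrawn each iteration) and restricts the expansion
$f(x) = \sum_{j \in \Omega'} \alpha_j y_j k(x_j, x) + b$ to those columns;
all $l$ rows keep their constraints and slacks. At fraction 1 the reduced
path is exactly the full path.

## The fuzzy silhouette and the separation statistic

For every PSM $i$, the weighted average distance to the good-target set
$\Omega_1$ and to the decoy set $\Omega_{-1}$ is

$$
\beta_i^k = \frac{\sum_{j \in \Omega_k,\, j \ne i} \theta_j\, d(x_i, x_j)}
                 {\sum_{j \in \Omega_k,\, j \ne i} \theta_j},
\qquad k \in \{1, -1\},
$$

with Euclidean $d$ on the weighted feature matrix, and the fuzzy
silhouette is $s_i = (\beta_i^{-1} - \beta_i^{1}) / \max(\beta_i^{-1},
\beta_i^{1}) \in [-1, 1]$.

One orientation subtlety matters. The classic silhouette is positive when
a point sits well inside *its own* cluster, whichever that is. The fuzzy
index instead is oriented toward the good-target set for *every* PSM:
a decoy deep inside the decoy cluster gets a strongly *negative* value.
That is what makes the class averages move apart — $\bar s_1$ rises and
$\bar s_{-1}$ falls as the good set purifies — and the separation
statistic

$$ sep = (\bar s_1 - \bar s_{-1})/2 $$

grow from about 0 toward its maximum. With the own-cluster-positive
convention, both averages would rise together and $sep$ would hover near
zero, and the stopping rule below could never fire. At unit weights the
fuzzy index coincides with the classic silhouette computed in its oriented
two-group form (`classic_silhouette(..., orient_toward = )`), which the
tests assert to $10^{-12}$; against the plain classic form the magnitudes
coincide and only the decoy-side sign differs.

Degenerate cases: a singleton own-set makes $\beta$ undefined; the value
falls back to the neutral 0 with a warning (the classical singleton
convention). A reference class whose $\theta$-mass is zero for some other
point is a hard error naming the class — the run has degenerated.

For large collections, each reference set can be replaced by a seeded
$\rho$-subsample of itself, redrawn each iteration ($\rho = 0.2$ is the
reference choice at real-data scale; 1.0, the exact computation, is the
default here).

## Scores and weights

Discriminant and silhouette evidence are scaled onto comparable ranges
with thresholds $f_0 = s_0 = 0$ (the decision boundary and the neutral
silhouette — the natural "uncertain" points, both configurable):

$$
\varphi(f) = \tfrac{2}{\pi}\,\mathrm{sign}(f - f_0)
  \arctan\big((|f - f_0|/f_{\max})^{1/4}\big),
\qquad
\psi(s) = (s - s_0)/s_{\max},
$$

where $f_{\max}$ and $s_{\max}$ are the largest deviations over the
targets, recomputed each iteration. The fixed 1/4 power flattens
$\varphi$ so that moderately and strongly separated targets contribute
similar weight; the extreme target lands exactly at $\varphi = 0.5$.
Decoys can exceed the target maxima and are reported unclamped. The score
mixes the two with the current separation:

$$ score(i) = (1 - sep)\,\varphi(f(x_i)) + sep\,\psi(s_i), $$

with $sep$ clamped to $[0,1]$ before mixing (early iterations can produce
slightly negative values, and a negative mixing weight would invert the
meaning of the silhouette term; the raw value is kept for the trace and
the stopping rule). Early on, when nothing has separated, the classifier
dominates; as the good set tightens, clustering evidence takes over. New
weights are $\theta_i = \max(score(i), 0)$ for targets, 1 for decoys.

## The iteration

Starting from $\Omega_1 = $ all targets and $\theta \equiv 1$, each
iteration:

1. fits the weighted LP-SVM and evaluates $f$ for every PSM;
2. keeps the top $n\% = 70\%$ of $\Omega_1$ by $f$ (ceiling count, ties to
   the lower index, never empty);
3. computes fuzzy silhouettes against the cut set and the decoys, then
   keeps the top 70% of the survivors by $s$ — a net 49% retention before
   promotion;
4. computes $\bar s_1$, $\bar s_{-1}$, $sep$, then scores and new weights;
5. promotes back any discarded target whose $f$ reaches the mean $f$ of
   the surviving good set (inclusive comparison);
6. stops when $sep \ge \widehat{sep} = 0.25$ (success), when
   $|\Omega_1| \le \hat p = 0.03\,|\Omega_+|$ (the good set collapsed),
   or at a safety cap of `max_iterations` (default 100; the cap is this
   package's addition and carries its own termination label, so the other
   two causes stay interpretable).

All randomness (column sampling, silhouette subsampling) derives from one
master seed, so a run is bit-reproducible. The final scores are the last
computed scores for all PSMs, decoys included.

## What the synthetic generator does and does not emulate

The generator plants the mixture structure the method assumes: correct
targets form one compact spherical Gaussian cluster; incorrect targets and
decoys share a second one — sharing a distribution is exactly the premise
that makes decoys useful for error calibration, so the generator encodes
it explicitly. The class-mean distance is `mean_shift` (default 3.0)
within-group standard deviations, directed proportionally to
$(3, 1, 1, 1, 1)$ across the five continuous attributes: x-correlation
carries most of the planted signal, mirroring its dominant discriminating
role among real SEQUEST attributes, and strong enough that x-correlation
alone separates planted-correct targets from decoys with AUC about 0.96.
Latents map onto plausible attribute ranges by monotone affine maps, and
the digest type is drawn class-conditionally: mostly full-digested for
correct targets, mostly none-digested for the incorrect/decoy class — the
composition pattern real decoy sets show.

Three named scenarios fix the study conditions: `default` (300 targets,
300 decoys, a third of targets correct, shift 3.0), `null` (shift 0 *and*
identical digest-type distributions in both classes, so planted-true and
planted-false records are fully exchangeable — otherwise digest type would
leak signal into the "no signal" scenario), and `hard` (shift 1.0).

What the generator does not emulate: heavy-tailed and correlated attribute
distributions, score-dependent decoy composition, charge-state and
peptide-length structure, or any spectrum-level realism. Passing tests on
these scenarios therefore show that the algorithm finds planted structure
of the assumed shape and hallucinates none when there is none — not that
it matches any particular instrument's output.

## Validation choices

The packaged validation runs at 600 PSMs per collection over five seeds:
large enough that the silhouette averages and the target-decoy accounting
are stable, small enough that the whole suite (including the
interior-point solves) completes in well under a minute of compute. On
the `default` scenario the run terminates by `sep_reached` within a few
iterations with final-score AUC above 0.9 for planted-true versus
planted-false targets; on `null` it never reaches the separation
threshold and the final AUC stays near 0.5; the reduced mode
(fraction 0.2, $\rho$ 0.2) reproduces the exact run's ranking with
Spearman correlation above 0.85. FDR accounting follows the target-decoy
convention $FDR = 2\,FP/(FP+TP)$ with $FP$ the accepted-decoy count and
$FP + TP$ the accepted-target count; the selection at a level scans all
distinct observed scores and requires at least one accepted target (the
empty acceptance trivially has FDR 0 and would make the "level
unreachable" warning path dead code).

## Known limitations

* The LP is unbounded when a class's weight mass drops under $1/(2c)$;
  the solver reports it rather than repairing it. A run whose target
  weights collapse that far has already degenerated past the
  $\hat p$ stopping rule in every scenario we generate.
* Scores are not calibrated probabilities; no posterior-probability claim
  is made, and no protein-level inference is attempted.
* The two nested 70% cuts retain 49% per iteration before promotion;
  aggressive shrinkage is intentional (promotion refills the set), but on
  very small collections the ceiling rule and the promotion step dominate
  and the trace should be inspected.
* Only the RBF kernel and Euclidean silhouette distance are implemented;
  the configuration objects leave room for alternatives.
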