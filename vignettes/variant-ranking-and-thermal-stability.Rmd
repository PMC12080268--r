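---
title: "Ranking enzyme variants by evolutionary statistical energy and quantifying thermal resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking enzyme variants by evolutionary statistical energy and quantifying thermal resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evstab)
```

## The model

Protein families accumulate correlated substitution patterns over
evolution. Direct coupling analysis (DCA) captures them with a pairwise
Potts model over aligned sequences $\sigma = (\sigma_1, \dots, \sigma_L)$:

$$ E(\sigma) = \sum_i h_i(\sigma_i) + \sum_{i<j} J_{ij}(\sigma_i, \sigma_j), $$

where $h_i$ is the local bias of position $i$ and $J_{ij}$ the direct
coupling between positions $i$ and $j$. The model is the least-constrained
(maximum-entropy) distribution $p(\sigma) \propto e^{E(\sigma)}$
reproducing the empirical single- and pair-site frequencies $f_i$,
$f_{ij}$ of the alignment. A variant is scored by its statistical-energy
difference from the wild type,

$$ \Delta E(\sigma, \sigma^{wt}) = E(\sigma) - E(\sigma^{wt}), $$

with the convention that positive $\Delta E$ marks evolutionarily favored
substitutions. $\Delta E$ needs only the terms touching substituted
positions, so exhaustive enumeration of all single and double
substitutions is cheap once the model is inferred; the package ranks them
and decomposes every double into its two single effects plus a coupling
gap — the model-level epistasis

$$ \Delta E_{ab} - \Delta E_a - \Delta E_b
   = J_{ij}(a',b') - J_{ij}(a',b) - J_{ij}(a,b') + J_{ij}(a,b). $$

The structure-based arm of a campaign arrives as tabulated
$\Delta\Delta G$ predictions (several independent runs per variant); the
package aggregates them to mean ± SEM and ranks ascending, keeping the
stabilizing ($\Delta\Delta G < 0$) candidates. Computing
$\Delta\Delta G$ from structure is out of scope: those values are
upstream inputs.

## Alignment processing

`read_alignment()` reads FASTA, A2M or Stockholm, removes insert states
(lowercase and `"."`), and drops columns where the focus sequence is
gapped, so every retained column maps to a 1-based position of the
ungapped target protein. `filter_alignment()` removes sequences with more
than 50% gaps first and then columns with gaps in more than 30% of the
surviving sequences — that order matters and is fixed. Sequences are
down-weighted by identity clustering: sequence $s$ gets weight
$1/|\{t : \mathrm{id}(s,t) \ge 1-\theta\}|$ with $\theta = 0.2$ (80%
identity), the standard DCA convention; the alignment's effective size
$n_\mathrm{eff}$ is the sum of weights. The alphabet has $q = 21$ states
(20 amino acids plus gap): gaps occur in retained columns of non-focus
rows and are modeled, but never proposed as substitutions. Non-canonical
residues (B, Z, X, U, O, J) are mapped to gap with a logged count —
deterministic and conservative.

## Inference

Parameters are inferred by regularized pseudo-likelihood maximization:
each site's conditional likelihood
$p(\sigma_i \mid \sigma_{\setminus i})$ is maximized over
$(h_i, J_{i\cdot})$ with L2 penalties, by L-BFGS-B with analytic
gradients from a zero start (deterministic; the seed argument is retained
for future stochastic initializations). The asymmetric per-site coupling
estimates are symmetrized by averaging $J_{ij}$ and $J_{ji}$, and the
model is returned in the zero-sum gauge ($\sum_a h_i(a) = 0$,
$\sum_a J_{ij}(a,b) = 0$), which fixes the reparameterization freedom
while preserving every energy difference — $\Delta E$ is checked
gauge-invariant to $10^{-8}$ in the tests.

Defaults: $\lambda_h = 0.01$ and $\lambda_e = 0.2\,(L-1)$, the plmc-style
scaling in which the coupling penalty grows with the number of modeled
sites. The penalties act on the *weight-normalized* (mean) pseudo-
log-likelihood, so the fit is invariant to rescaling all sequence weights
and hence to duplicating the alignment when weights are recomputed; this
convention is recorded in the fit report. Convergence uses a projected-
gradient tolerance of $10^{-5}$ and at most 500 iterations per site;
non-convergence is reported, not hidden. With the normalized objective
the same $\lambda$ values regularize more strongly than when penalties
are added to a summed likelihood — comparisons across conventions should
rescale by $n_\mathrm{eff}$.

Whether pseudocounts belong at the frequency stage or only as inference
regularization is left open by common practice; the package exposes a
frequency-stage pseudocount (`pseudocount_lambda`, default 0) and relies
on the L2 penalties during inference, which is what pseudo-likelihood
pipelines typically do.

## Thermal-resistance analyses

* **Activity plates.** Replicate absorbances are background-subtracted
  (mean of empty-vector wells per condition) and divided by the wild
  type's net mean under the same condition. The reported SEM reflects the
  variant's replicate variation only, matching the field's convention of
  error bars from biological replicates of the variant; an option
  propagates the wild type's relative SEM in quadrature, and the recovery
  analyses use it because their comparison target involves the noisy wild
  type estimate. A variant whose replicates never exceed background is
  flagged inactive with fold 0.
* **Melting curves.** Thermal unfolding traces (20–95 °C at 1 °C/min) are
  analyzed by the smoothed first-derivative maximum, the scanning-
  fluorimetry convention. The smoother is a fixed-df smoothing spline
  (df = 12 on the 76-point scan): one two-state transition needs roughly
  that flexibility, while generalized cross-validation under-smooths the
  derivative and destabilizes the peak. The derivative is evaluated on a
  0.01 °C grid, so the estimate is not quantized to the scan step. A
  two-state sigmoid with linear pre-/post-transition baselines is fitted
  as a cross-check (agreement within 0.5 °C on clean curves) and supplies
  a standard error. Curves whose derivative peaks at a scan boundary, or
  with no peak above three times the median absolute derivative, are
  flagged as transition-free.
* **Deactivation.** Residual activity after incubation at 75 °C is fitted
  as first-order decay $A(t) = A_0 e^{-kt}$ on replicate means, the
  standard pairing with a reported half-life: $t_{1/2} = \ln 2 / k$, with
  a delta-method standard error. Series with no decreasing trend are
  flagged rather than fitted.
* **Classification and hit rates.** A variant is `improved`/`reduced`
  versus the wild type when
  $|value - wt| \ge z \sqrt{\mathrm{sem}^2 + \mathrm{sem}_{wt}^2}$ with
  $z = 2$, else `similar`. The threshold is explicit because published
  reports rarely state theirs; the packaged melting-temperature tables
  are *not* asserted to reproduce any particular published class count
  under this rule — the analysis scripts print the counts the rule
  yields. Hit rate is simply $100\,n_\mathrm{improved}/n_\mathrm{tested}$.
* **Correlation and epistasis.** Stability–activity association uses
  Spearman's $\rho$ with average ranks and the t-approximation p-value on
  $n-2$ df. Experimental epistasis of a double variant is reported
  additively for energies and temperatures and multiplicatively for fold
  changes ($\mathrm{double} - a \times b$).

## Synthetic data and what the tests show

Every input the pipeline reads can be generated with known ground truth:
alignments Gibbs-sampled from a Potts model (single-site heat-bath
updates — exact conditionals are available, so no proposal tuning),
two-state melting curves with additive instrument noise, first-order
decay series and replicated plates with multiplicative (CV-style) assay
noise. Generators are bit-reproducible given a seed and attach their
truth parameters; analysis stages never read the truth.

Recovery tests run at the study's reference conditions: half-lives of 40
and 104 minutes sampled every 15 minutes over 0–150 minutes with 3
replicates and 5% noise; a melting temperature of 82.2 °C on the 20–95 °C
grid with noise at 1% of the unfolding amplitude; a 3.6-fold activity
gain on a 3-replicate plate at 5% noise. Inference tests use
Gibbs-sampled alignments of 2000 sequences over 5 sites (spurious-
coupling and coupled-pair recovery) and 5000 sequences over 3 sites
(agreement with exhaustive Boltzmann enumeration within 0.02). These
sizes keep the full suite under a minute while leaving comfortable
statistical margins.

The generators emulate noise structure, not biology: no phylogenetic
correlation beyond the Potts dependencies, no plate positional effects,
no substrate-depletion kinetics, and the fixture model over the study's
16 positions is a *synthetic construction* that reproduces the printed
score tables, not a model inferred from the family's alignment (which
would require the homolog database). Passing tests therefore demonstrate
correctness of the computational pipeline, not predictive accuracy on new
enzymes.

## Numerical choices and edge cases

* Ranking ties are broken by position then mutant residue, making the
  order total and permutation-stable; double enumeration materializes
  per-pair score matrices (the largest fixture case is
  $120 \times 19 \times 19 \approx 43$k doubles, far below any memory
  concern at this scale).
* With 3 replicates a SEM estimate has 2 degrees of freedom, so
  "within 2 SEM" holds with roughly 85–90% probability, not 95%; the
  panel round-trip test checks coverage across repeated panels instead of
  demanding every draw succeed.
* Model files are JSON with a format/version header; doubles are written
  with 17 significant digits so round trips are bit-exact, and truncated
  or mislabeled files raise explicit format errors.
* Variants touching positions dropped by column filtering raise an
  "unmodeled position" error naming the position, rather than being
  silently skipped.
* The decay fitter treats a log-linear slope above $-10^{-8}$/min, or a
  fitted rate below $10^{-6}$/min, as "no measurable decay".
* Reported temperatures are rounded to one decimal and half-lives to
  whole minutes, the customary reporting precision for these assays.

## A worked example

```{r example}
model <- build_fixture_model()
head(enumerate_and_rank(model, "single", top_k = 5))
head(enumerate_and_rank(model, "double", top_k = 5))
epistasis_decompose(model, "S180T/Q289G")
```

```{r recovery}
series <- make_decay_series(t_half = 104, noise_frac = 0.05, seed = 2)
fit_decay(series)
curve <- make_melting_curve(tm = 82.2, noise_sd = 0.002, seed = 3)
fit_melting(curve)
```

## Limitations

The pseudo-likelihood fit is dense in $L^2 q^2$ parameters and intended
for the moderate alignment sizes used here and in the analysis scripts;
inferring a full-length protein model (hundreds of sites against a
large homolog set) would want compiled inner loops. Half-life standard
errors come from the fit covariance on replicate means and ignore
between-replicate correlation. The melting-curve sigmoid assumes
two-state unfolding; multi-domain transitions will be mis-summarized by a
single midpoint and should be caught by inspecting the fitted RMSE.
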