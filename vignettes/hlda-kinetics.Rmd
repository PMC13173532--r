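---
title: "HLDA collective variables and rare-event kinetics: methods and design"
author: "hldaKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HLDA collective variables and rare-event kinetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hldaKinetics)
```

## Scope and model

`hldaKinetics` addresses a screening question: given a two-state molecular
system (folded/unfolded, bound/unbound, ...), which discrete perturbations
of the system — point mutations, in the motivating application — speed up
or slow down the rare transition between the states, and by how much? The
package's premise is that this can be answered, to useful accuracy, from
*within-basin fluctuations alone*, without ever simulating a spontaneous
transition.

Three ingredients implement that premise.

**1. A linear CV from harmonic LDA.** Descriptors are pairwise
residue–residue distances $d_{pq}$ ($p<q$). From the two state-restricted
ensembles, with means $\mu_F,\mu_U$ and covariances $\Sigma_F,\Sigma_U$,
the between-class scatter is $S_b=\tfrac12\,\Delta\mu\,\Delta\mu^\top$
($\Delta\mu=\mu_F-\mu_U$) and the within-class scatter is the *harmonic*
average $S_w=(\Sigma_F^{-1}+\Sigma_U^{-1})^{-1}$ — the harmonic mean
penalises directions that are stiff in *either* basin, which is what makes
the resulting coordinate kinetically meaningful rather than merely
discriminative. The two-state problem is rank-1, so we use the closed form
$W\propto S_w^{-1}\Delta\mu$, $\lambda=\tfrac12\Delta\mu^\top
S_w^{-1}\Delta\mu$ (`solveHLDA()`), keeping a dense generalized
eigensolver as a cross-checked fallback (`method = "eigen"`). $\lambda$ is
affine-invariant in descriptor space and serves as the scalar separation
score; $W$ is reported unit-norm with the sign fixed so the CV increases
from folded to unfolded (neither normalization is canonical, but both are
needed for cross-system comparison).

**2. Residue-level importance.** $I_r$ is the mean of $|W_{rq}|$ over kept
pairs touching residue $r$ (`residueImportance()`). It is computed over
*post-pruning* pairs because those are the pairs that define $W$; residues
absent from all kept pairs are reported unscored (NA), never as zero —
an unmeasured residue is not a measured-unimportant residue. Normalized
scores divide by the maximum, giving a $[0,1]$ profile whose top residue
is exactly 1. Mutant screening (`screenMutants()`) compares each mutant's
$\lambda$ with the reference inside a relative neutral band (default 5%,
a reporting choice: eigenvalue differences below typical estimation noise
should not be read as direction calls).

**3. Kinetics from accelerated escapes.** Gaussian hills deposited along
the CV accelerate escape; the biased first-passage time $\tau$ is mapped
to physical time by the acceleration integral
$t^*=\sum_{t<\tau}\Delta t\,e^{V(t)/kT}$ (left Riemann sum;
`rescaleFPT()`). The rate is estimated by progressive exponential survival
fitting (`fitMFPT()`): for each cutoff $m$, the $m$ fastest rescaled times
get empirical survival $S(t_{(i)})=1-i/n_{\mathrm{total}}$ — uncrossed and
slower runs remain in the denominator as right-censored observations,
because discarding them biases the rate upward — and $S(t)=e^{-kt}$ is fit
by least squares. The $(k,m)$ with maximal $R^2$ is selected; MFPT $=1/k$.
The censored maximum-likelihood rate
$\hat k=m/(\sum_{i\le m}t_{(i)}+(n-m)t_{(m)})$ is always reported
alongside as an independent estimator of the same quantity. Exponentiality
is validated by a KS test against the fitted rate (conventional pass
$p>0.2$) and a Lilliefors-style test whose null distribution — rate
re-estimated from each sample — is generated by seeded parametric
bootstrap (default 1000 replicates), since no convenient closed form
exists for the exponential case (pass $p>0.05$).

## The synthetic testbed

The generator (`twoStateSpec()` and friends) is a latent overdamped
Langevin particle in $U(x)=\Delta U\,((x/a)^2-1)^2$, integrated by
Euler–Maruyama, mapped onto descriptors by
$d_j=\mathrm{offset}_j+b_j x+\varepsilon_j$,
$\varepsilon_j\sim N(0,\sigma_j^2)$. It reproduces the *statistical*
structure the method relies on — two unimodal basins in descriptor space,
a single dominant slow mode, Poissonian escapes — and nothing else.
Defaults (chosen once as the package's study conditions):

| parameter | default | rationale |
|---|---|---|
| barrier $\Delta U$ | 5 kT | rare on simulation timescales, reachable by brute force for validation |
| minima $\pm a$ | $a = 1$ | sets the latent length unit |
| friction $\gamma$, $kT$ | 1, 1 | reduced units throughout the toy |
| residues / pairs | 10, all 36 with $|p-q|\ge 2$ | matches a ten-residue hairpin's descriptor count |
| loadings $b_j$ | 0.3 | within-well descriptor signal comparable to noise |
| offsets, noise $\sigma_j$ | 1, 0.2 | distance-like baselines; realistic fluctuation-to-separation ratio |
| hill height / width | 0.5 kT / $0.2\,a\,\lVert b\rVert$ | gentle hills, several per barrier height, a fraction of the basin width |
| deposition pace | 1 per time unit | many well-relaxation times ($\approx\gamma a^2/8\Delta U$) between hills |

A "mutation" is an additive change to $\Delta U$, $a$ or entries of $b$
(`makeMutant()`); increasing $a$ increases both the separation score
($\lambda\propto$ growing in $a$) and, through the longer diffusive path,
the true MFPT — giving an end-to-end family in which the screening logic
must hold if the implementation is right.

`basinTrainingData()` emulates the state-restricted sampling protocol: one
run started in each minimum, frames labelled by the latent progress
coordinate with an exclusion band at $\pm 0.4a$ (unbiased runs make
occasional partial barrier excursions, and the band prevents exactly the
cross-contamination it prevents in real RMSD-based labelling), and a
recording stride of ~one well correlation time so that the per-state
moments are estimated from roughly independent frames.

What the testbed does **not** emulate: multimodal basins, anharmonic or
multi-pathway barriers, descriptor nonlinearity, hidden slow modes
orthogonal to the latent coordinate, and bias-deposition artifacts near
the transition state. A green test suite therefore certifies the
statistical machinery, not the adequacy of linear CVs for any particular
molecule.

## Numerical choices and degenerate inputs

* **Integration stability.** The step must satisfy
  $\Delta t\,\max|U''|/\gamma<0.1$ with the bound taken at the stiffest
  equilibrium point ($U''(\pm a)=8\Delta U/a^2$); the default step uses an
  0.08 safety factor, and a trajectory exceeding $10a$ aborts with an
  error naming the step and the spec.
* **Superposition RMSD.** Kabsch via SVD with the determinant correction:
  proper rotations only, so a mirror image is *not* distance zero.
  Collinear references (rank < 2) are refused. Labelling thresholds follow
  the inclusive convention (folded at $\le t_F$, unfolded at $\ge t_U$);
  first-passage times stamp the first satisfying frame with frame 0 at
  time 0.
* **Pruning determinism.** The worst-offending pair (largest Spearman
  $|\rho|$ above the cutoff, absolute value because an anti-correlated
  duplicate is equally redundant) is resolved by discarding the member
  with the larger mean $|\rho|$ to all other remaining descriptors; exact
  ties discard the lexicographically later pair label. This makes the
  result invariant to input column order, which is asserted in tests, and
  the postcondition (no kept pair above the cutoff) is audited on every
  run. Zero-variance columns are dropped first with a warning.
* **Covariance conditioning.** When a state covariance has condition
  number above $10^{10}$ (or fewer frames than descriptors), inversion
  adds a ridge $10^{-6}\,\mathrm{tr}(\Sigma)/p\cdot I$. Pruning is the
  first line of defense; the ridge keeps the solver defined on arbitrary
  inputs.
* **Survival-fit optimization.** The least-squares objective in $k$ is
  optimized in the dimensionless variable $u=k\,\bar t$, bracketed on a
  log-spaced grid before local refinement. The grid rules out the flat
  large-$k$ plateau (where predicted survival is uniformly ~0), and the
  dimensionless parameterization makes the estimate exactly equivariant
  under rescaling of the time axis. $R^2$ is computed on survival values
  by default; log-survival and CDF scales are exposed as options since the
  convention is not canonical.
* **Marcus barriers.** The crossing of the two parabolas is solved by the
  quadratic formula, restricted to the open interval between the minima;
  if both roots fall inside (unequal curvatures), the lower-energy
  crossing — the physical saddle — is returned, and a non-crossing
  configuration is an error rather than an extrapolation.

## Design decisions that were genuinely open

* Overdamped (position) Langevin suffices: the testbed validates
  statistics, not inertial dynamics.
* Standard (non-tempered) hills by default with an optional well-tempered
  bias factor.
* Unbiased ($n-1$) covariances.
* The importance average runs over kept pairs only (they define $W$), and
  the kept-pair set is recorded in the pruning report so a wild-type
  pruning can be reused for mutants (`--reuse-pruning` in the CLI);
  per-system pruning is the default.
* The MFPT ratio uses the natural log.
* Backbone definition for real structures: C$\alpha$ per residue by
  default, with an N/CA/C/O-centroid option, since distance descriptors
  and RMSD only need one representative point per residue.

## Problem sizes

The shipped tests and the acceptance study use: 20 000 decorrelated frames
per basin for eigenvalue estimation (ESS-limited, not wall-time-limited:
$\lambda$ gaps of ~5% across adjacent mutants need ~1% estimator noise);
200 biased escapes per system for wild-type kinetics and 60 per mutant for
the five-member family; 100 brute-force escape events for the reference
MFPT; 50 replicates of $n=200$ exponential samples for estimator
calibration; 1000 bootstrap replicates for Lilliefors p-values. These
sizes were chosen so each quantity's sampling error is small relative to
the effect it must resolve.

## Known limitations

* Linear CVs: a system whose folded/unfolded separation is not expressible
  as one linear combination of pair distances will yield a weak $\lambda$
  and unreliable importance scores; the `noSeparation` flag marks the
  degenerate end of that spectrum, not the marginal one.
* $\lambda$ is a *surrogate* for barrier change. In the toy family the
  monotone link to MFPT is built in; for real systems the package can only
  report the correlation (`thresholdScan()`, `correlateMetric()`), not
  guarantee it.
* Uniform state thresholds across mutants add variance when perturbations
  shift basin boundaries; thresholds are exposed everywhere rather than
  hard-coded.
* The rescaled-time estimator assumes hills are deposited slowly relative
  to basin relaxation and contribute negligible bias at the transition
  state; the default pace honours this in the toy, but the package does
  not verify it for user-supplied bias logs beyond $V\ge 0$.
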