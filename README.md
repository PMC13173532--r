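# hldaKinetics

Predicting how discrete perturbations ("mutations") of a two-state
molecular system reshape its free-energy barrier and unfolding kinetics —
from *within-basin sampling only*.

Exhaustively measuring mutant transition rates by simulation is
prohibitively expensive: rare barrier crossings in even a small two-state
folder (a ten-residue β-hairpin peptide is the canonical case) take
microseconds, and mutation space is combinatorially large. This package
implements a screening strategy for computational biophysicists working on
peptide/protein kinetics engineering: build an interpretable linear
collective variable (CV) from short simulations *restricted to the folded
and unfolded basins*, read residue-level kinetic importance off its
weights, score each mutant by how strongly it separates the two ensembles,
and — when rates are wanted — infer mean first-passage times (MFPTs) from
bias-accelerated trajectories.

## The model

**Harmonic linear discriminant analysis (HLDA).** Descriptors are
residue-pair backbone distances d<sub>pq</sub>, pruned so that no kept
pair has Spearman |ρ| > 0.93. From state-restricted ensembles with means
μ<sub>F</sub>, μ<sub>U</sub> and covariances Σ<sub>F</sub>, Σ<sub>U</sub>,
the CV direction **W** maximizes the ratio of between-class scatter
S<sub>b</sub> = ½ Δμ Δμᵀ (Δμ = μ<sub>F</sub> − μ<sub>U</sub>) to the
*harmonic* within-class scatter
S<sub>w</sub> = (Σ<sub>F</sub>⁻¹ + Σ<sub>U</sub>⁻¹)⁻¹. For two states the
leading eigenpair has the closed form

&nbsp;&nbsp;**W** ∝ S<sub>w</sub>⁻¹ Δμ,  λ = ½ Δμᵀ S<sub>w</sub>⁻¹ Δμ,

and the CV is s(R) = Σ<sub>p&lt;q</sub> W<sub>pq</sub> d<sub>pq</sub>(R).
λ measures the one-dimensional statistical separation of the two
ensembles; in a Marcus picture of two parabolic basins, greater separation
raises the crossing point and hence the barrier ΔF<sup>‡</sup>, so λ is a
surrogate for barrier-controlled kinetics.

**Residue importance.** I<sub>r</sub> = mean |W<sub>rq</sub>| over kept
pairs touching residue r flags kinetic "hot spots" whose mutation most
strongly perturbs the folded/unfolded separation.

**Kinetics (ST-iMetaD).** Escapes are accelerated by depositing Gaussian
hills along the CV; each biased first-passage time τ is rescaled to
physical time t\* = ∫₀^τ e^{V(t)/kT} dt. The rate k comes from
progressively fitting the empirical survival of the m fastest rescaled
times to S(t) = e^{−kt} (censored records stay in the denominator),
keeping the fit with maximal R²; MFPT = 1/k. The Poisson-escape assumption
is validated by a Kolmogorov–Smirnov test (pass: p > 0.2) and a
bootstrap Lilliefors test (pass: p > 0.05).

A built-in synthetic generator — an overdamped Langevin particle in the
double well U(x) = ΔU((x/a)² − 1)², mapped linearly (plus noise) onto
distance-like descriptors — provides a fully controlled testbed in which
every step of the pipeline can be checked against brute-force simulation
and closed-form results.

## Worked example

```r
library(hldaKinetics)

wt <- twoStateSpec()                                  # 5 kT barrier, 10 residues
train <- basinTrainingData(wt, nFramesPerState = 10000, seed = 1)
model <- fitHLDA(train)                               # prune at 0.93, then solve
model
#> HLDAModel (two-state harmonic LDA)
#>   lambda = 83.8372 over 36 descriptors; CV increases folded -> unfolded (W'muU > W'muF)
#>   top |W|:  d_5_8 = 0.19, d_1_4 = 0.186, d_8_10 = 0.182

rankHotspots(residueImportance(model), 3)
#> [1] 4 8 6

runs <- lapply(1:200, function(i)
  runBiasedEscape(wt, cvWeights(model), seed = i, recordStride = 10))
rec <- fptRecords(runs)
fitMFPT(rec)
#> MFPTEstimate: k = 0.04913, MFPT = 20.35 (R^2 = 0.9947 at m = 200 of 200 crossed / 200 total)
#>   censored-MLE cross-check: k = 0.04377

et <- exponentialityTests(rec$rescaledFPT[rec$crossed],
                          kHat = 0.04913, seed = 2)
round(unlist(et[c("ks.p", "lilliefors.p")]), 3)
#>         ks.p lilliefors.p
#>        0.628        0.097
```

λ = 83.8 is the wild-type separation score (its absolute scale depends on
the descriptor set; only comparisons across systems matter). Residues 4, 8
and 6 carry the largest mean CV weight, i.e. mutations there are predicted
to perturb unfolding kinetics most. The fitted escape rate k ≈ 0.049
(MFPT ≈ 20 reduced time units) agrees with the censored-MLE cross-check,
and both exponentiality tests pass, so the rescaled first-passage sample
is consistent with Poisson escape statistics. A brute-force unbiased
estimate of the same MFPT (`bruteForceFPT(wt, 100, seed = 2)`) lands
within a factor of ~1.2.

Mutants are derived with `makeMutant()`, screened with `screenMutants()`,
and threshold robustness is checked with `thresholdScan()`. A thin CLI
over these functions is installed at `inst/scripts/hldakin.R`
(`simulate`, `label`, `fpt`, `descriptors`, `prune`, `hlda`, `project`,
`importance`, `screen`, `mfpt`, `correlate`, `scan`).

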