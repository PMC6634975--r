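---
title: "Models and methods behind wmpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wmpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmpop)
```

`wmpop` analyzes trial-structured olfactory working-memory experiments:
behavioral event tables (one row per trial) and single-unit spike times
aligned to sample-odor onset. This vignette explains the models the package
implements, the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Trial structure and conventions

Time zero is sample-odor onset in every trial. The canonical trial is: 1 s
sample odor, a delay of `delay_s` seconds, 1 s test odor, a 1 s
pre-response delay and a 0.5 s response window; in dual-task trials the inner
Go/No-go cue starts 3 s into the delay and lasts 0.5 s. All windows are
half-open `[start, end)` — a lick exactly at the window start counts, one at
the end does not — and spike bins follow the same convention with
`n = floor((t1 - t0 - width)/step) + 1` bins, overlapping bins allowed.
Recording is assumed from 1 s before sample onset through the response-window
end; all provided pre-sample spikes are retained.

Outcomes are a pure function of licking and the trial relation: a lick inside
the response window is a *hit* on rewarded-type trials (non-match, paired,
Go) and a *false alarm* on unrewarded-type ones; the no-lick counterparts are
*miss* and *correct rejection*. `d_prime()` clamps rates of 0 or 1 to
`1/(2n)` and `1 - 1/(2n)` per group before the inverse-normal transform — a
standard correction the clamping-free definition leaves infinite; the choice
matters only for small groups at ceiling.

## The memory-decay model and its asymptote

Correct rate versus delay is fit as `C(d) = asymptote + A exp(-d / tau)` by
weighted least squares (`minpack.lm`). The asymptote convention was open: a
free asymptote looks more agnostic, but for a two-alternative task the curve
must decay to chance, and profiling shows the tau–asymptote trade-off is
severe — the Cramér–Rao bound at five delays (5–40 s) and 100 trials/delay
puts the relative error of tau near 80 % of its value with a free asymptote
versus ~29 % with the asymptote known, and simulation of the bounded
estimators reproduces exactly that ordering (~30 % vs ~19 % median at those
sample sizes, ~16 % vs ~5 % at tenfold pooling). The default therefore
anchors the asymptote at the chance level (0.5); `asymptote = "free"`
(bounded to [0.45, 0.6], initialized at 0.5) remains available, and every
fit records its convention. Flat curves return `amplitude_A = 0` with
`unidentifiable = TRUE` rather than a meaningless tau. Parameter-recovery
experiments in the acceptance suite use 10-subject cohorts at 100
trials/delay per subject, the scale of the behavioral cohorts the package
targets.

## Resampling statistics

Permutation tests use the absolute difference of means (two-sided by
construction); the paired variant flips signs of paired differences. Both
enumerate the null exhaustively whenever the number of distinct regroupings
(`choose(n, nx)` or `2^n`) fits in the repeat budget, reporting exact
p-values; Monte-Carlo p-values carry the `(count + 1)/(n_rep + 1)` correction
and can never be 0. The causal criterion for an optognetic effect is the
genotype × laser interaction of a split-plot ANOVA (`aov` with an
`Error(subject/within)` stratum); its type-I error is exact under normality
and is verified by simulation in the test suite. Outlier screens implement
the 1.5 IQR rule (quartiles by R's default type-7 quantiles) and iterative
two-sided Grubbs at α = 0.05 (the α the source left unstated). The 2×2
chi-square uses no continuity correction, matching large-count usage;
`bonferroni_adjust()` is `p.adjust`'s Bonferroni.

## GLM comparison

Candidate models explain the mean correct rate of trial groups sharing a
covariate combination, μ = Xᵀb, fit by weighted least squares (Gaussian
identity; weights = group sizes, respecting unequal group occupancy) with
`AIC = 2k − 2 logL`, `k` = design rank + 1 for the residual variance; no
small-sample correction. Two choices deserve note. First, `compare_models()`
evaluates all candidates on the *shared* grouping by the union of candidate
covariates: under per-model grouping a saturated candidate — the
intercept-only null most of all (one group, one parameter) — has zero
residual and unbounded likelihood, making cross-model AIC meaningless.
`build_design()` still offers per-model grouping for single-model use.
Second, the decay covariate `exp(-delay/tau)` uses the tau from the point
memory-decay fit, held fixed across bootstrap replicates (recorded in the
result as `tau_policy`); refitting tau per replicate would couple two
estimators without changing the comparison materially. Bootstrap replicates
resample trial outcomes with replacement within groups — sizes are preserved,
so no replicate can empty a group. The shipped seven-candidate family
(`default_model_specs()`) grades from the null model through sensory cues,
memory decay, perturbation main effects and their interactions to the
compact suppression model (#6: the delay-period-suppression indicator, the
trial relation, the decay value and their interactions) and an
over-parameterized superset; all are editable `model_spec()` objects. The
suppression indicator is `laser_on & perturb_epoch == "delay" & genotype ==
"ChR2"` — laser light in a ChR2-negative control is not suppression.

## Single-unit analyses

Quality control passes units with at most 0.15 % of inter-spike intervals
under 2 ms and a mean rate above 2 Hz, the mean computed over the union of
per-trial recording windows (not wall-clock time, which a trial-cut data file
cannot know). Z-scoring uses the per-trial baseline rate vector (mean rate
over the 1 s pre-sample window, one value per trial): its mean and SD
standardize all of a unit's rates, are stored for exact inversion, and a
zero-SD unit gets SD 1 plus a flag rather than infinities.

The selectivity index `(FR_S1 - FR_S2)/(FR_S1 + FR_S2)` is 0 when both means
are 0. auROC is computed from the threshold-swept ROC curve with trapezoidal
tie handling, which equals the Mann–Whitney `U/(n1 n2)` rank statistic (the
test suite asserts agreement to 1e-12). The selective-fraction time course
calls a unit selective in a bin when a label-permutation test on the mean
rate difference gives p < 0.05 (the significance criterion was unstated; a
permutation test matches the module's other machinery and is assumption
free), and compares each bin's fraction to the pre-sample baseline bin by
chi-square. Persistence counts *total* significant time (> 0.5 s transient,
> 5 s persistent), not the longest run — the alternative reading; the choice
is visible in the function's documentation and matters only for units with
fragmented significance.

## Mutual information

Per unit and time window (canonically 500 ms stepped by 100 ms), firing
rates are fit per sample label as Gaussians — means, SDs (floored at
`max(1e-3, 1e-6 |mean|)` to avoid singular densities) and empirical priors —
and `MI = Σ_s P[s] ∫ dr P[r|s] log2(P[r|s]/P[r])` is integrated over each
component's mean ± 8 SD by fixed 200-node Gauss–Legendre quadrature: the
integrand is smooth there, the omitted tails carry < 1e-14 of each
component's mass, the result agrees with adaptive quadrature to ~1e-5, and
the fixed rule is fast enough for the 10^5–10^6 evaluations a
permutation-masked time course needs. The Gaussians are supported on all
reals, exactly as fit — no truncation at zero rate — which is a known
(inherited) approximation for low-rate units. MI is clamped to
`[0, log2 K]` after a 1e-6 tolerance check.

The permutation mask deserves care. MI is a nonnegative divergence, so the
informative tail is the upper one; moreover a doubled two-tailed p-value with
1000 permutations is floored at 2/1001 ≈ 0.002 and *cannot* cross the
canonical 0.001 mask. The default is therefore the one-tailed
`(count + 1)/(n_perm + 1)` p-value; a `tails = "two"` mode exists and the
mode used is recorded in the profile. Masking at 0.001 refuses permutation
budgets that cannot resolve it. Dual-task units are classed as
exclusive/mixed by whether their masks fire for the outer-task sample, the
inner-task cue, both, or neither.

## Population decoding

Decoding uses an RBF-kernel SVM (`e1071`/libsvm) on pseudopopulation
vectors: per repeat, one held-out trial per class, and 30 bootstrap
pseudotrials per class assembled by sampling, independently per neuron, one
same-class trial with replacement — the central modelling assumption that
makes units from different sessions combinable, at the cost of erasing
trial-by-trial noise correlations. Only units with strictly more than 30
trials per class enter; rates are min–max scaled to [0, 1] per unit
(constant units map to 0). Hyperparameters are grid-searched once per time
bin (c ∈ 2^[−5,5], γ ∈ 2^[−10,0]) by 5-fold cross-validation on the
training pseudotrials only, ties broken toward the smallest c then γ.
Accuracy averages 500 repeats; with the training and testing sets disjoint in
every repeat (asserted inside the loop) this is resampled leave-one-trial-out
cross-validation. The shuffle null re-runs the procedure on label
permutations at the observed hyperparameters with 200 repeats per
permutation — a recorded reduction that leaves the null mean unbiased — and
per-bin significance is `(count + 1)/(n_shuffles + 1)`.

Seeding is hierarchical: a master seed derives independent per-bin streams,
and within a bin the grid search and the repeat loop consume separate derived
streams; partition and bootstrap draws are trial *indices*, independent of
which bin's rates are read. Cross-temporal decoding therefore reuses the
identical partitions when training on bin i and testing on bin j, its
hyperparameters are the training bin's, and its diagonal equals the
time-resolved accuracy exactly — an equality the tests assert rather than
approximate.

## The synthetic-data generator

The generator is the package's test bed and defines its study conditions.
Behavior: per-trial correct probability
`p(d) = chance + A exp(-d / tau)` with defaults A = 0.45, tau = 20 s,
chance = 0.5, a 2 % lapse rate mixing in chance-level guessing, 10 subjects ×
200 trials; four balanced sample–test combinations shuffled within every
4-trial block; laser either interleaved one-trial-on/one-trial-off (starting
off) or in alternating 24-trial blocks. Delay-period suppression in ChR2
subjects lowers p linearly in laser duration and onset phase
(`slope_per_s = 0.012`, phase gain 1 — i.e. a full 12 s delay suppression
costs ~14 points, the magnitude scale of the optogenetic experiments the
package targets), floored at chance: a destroyed memory yields guessing, not
below-chance performance. Dual-task distractors subtract configurable
amounts (Go worst by default). Outcomes are drawn first, then spikes are
generated conditioned on outcome, matching the analysis direction
(condition on correct/error).

Spikes: inhomogeneous Poisson with piecewise rate — baseline; odor epochs
scaled multiplicatively (optionally per-odor for sensory selectivity); the
delay epoch adds ± half the delay selectivity with exponential decay from
delay onset, attenuated in error trials; dual-task distractor responses with
optional Go/No-go-specific gain and a short exponential tail. Sampling is
exact per 10 ms piecewise-constant segment (Poisson counts then uniform
times) rather than thinning — the two are distributionally equivalent at
this resolution and the segment form is cheaper and exactly reproducible —
and an absolute refractory period (3 ms default) then thins the train as in
a well-isolated single unit, without which Poisson trains at realistic
rates would fail the 0.15 % ISI criterion that real sorted units meet.
Identical specs and seeds give byte-identical tables.

What the generator does *not* emulate: noise correlations between
simultaneously recorded units, non-Poisson spiking statistics (bursting,
adaptation beyond the refractory period), drift across a session, lick
artifacts, and any biophysical circuit mechanism. Passing tests on synthetic
data therefore validate the *pipeline* — estimator correctness, calibration,
leakage-freedom, reproducibility — not claims about cortical data.

## Problem sizes and numerical choices

The test and acceptance suites run simulations at deliberately chosen sizes:
2000 null simulations for permutation/ANOVA calibration, 1000 for bootstrap
coverage, 200 cohorts for tau recovery, 100 cohorts for GLM model recovery
(bootstrap 100), decoding with reduced grids (3 × 3) and 30–500 repeats on
populations of 5–10 units, and MI masks over ~250 unit-bins at 1000
permutations — large enough for the stated statistical bands, small enough
to run on a single CPU in minutes. Degenerate inputs follow explicit rules
rather than erroring where a flagged result is more useful: zero baseline SD
(SD := 1 + flag), both-zero selectivity index (0), constant units in
normalization (0 + warning), flat decay curves (amplitude 0, tau flagged).

## Known limitations

AIC comparability rests on the shared grouping; models outside the shipped
family with covariates of very different granularity should be compared on a
common covariate table. The Gaussian MI model can misstate information for
strongly non-Gaussian rate distributions. The pseudopopulation assumption
overstates decodable information when noise correlations are limiting. And
the behavioral generator's linear laser-effect parameterization is a
qualitative stand-in — its magnitudes are configuration, not measurement.
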