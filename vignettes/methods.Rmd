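---
title: "Methods: from single cells to stable outcome predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single cells to stable outcome predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cytoscreen implements a complete mechanistic-analysis pipeline for mass
cytometry immunophenotyping cohorts with a dichotomous clinical outcome —
the motivating setting is an oral immunotherapy trial in which participants
who tolerated an allergen challenge after a period of avoidance (sustained
unresponsiveness, SU) are contrasted with those who reacted (desensitized,
DS). This vignette is the package's own account of each method, its
assumptions, the parameters that matter, and the design choices made where
the design was genuinely open.

## Preprocessing

**Arcsinh transform.** Raw ion counts are variance-stabilized with
`asinh(x / cofactor)`; the cofactor defaults to 5, the mass-cytometry
convention (for fluorescence data 150 would be typical). The transform is
odd and strictly increasing, so gates and ranks are unambiguous across
scales. CD127 is excluded from the lineage-marker set by default (it is
retained in the matrix but not used for alignment or clustering) because it
is a marker prone to batch-dependent staining drift.

**Landmark alignment.** Staining intensity drifts between acquisition
batches; aligning the high-density modes ("landmarks") of each sample's
marker distribution removes location drift without distorting within-sample
ordering. The procedure: (1) landmarks are the local maxima of a Gaussian
KDE, Silverman's rule-of-thumb bandwidth, retaining peaks above 5% of the
maximum density and at most `max_peaks` of them — both choices are
conventional and configurable, since nothing in the problem pins them down;
(2) peaks are matched across samples by 1-D k-means on the pooled peak
positions with k equal to the modal per-sample peak count (deterministic
quantile initialization, so no RNG is involved); (3) each sample is warped
by a monotone piecewise-linear map taking its matched peaks onto the
consensus (mean) position of their group, with constant-offset
extrapolation beyond the outermost knots. Monotone piecewise-linear warps
preserve rank order exactly and compose/invert to machine precision, which
the tests assert. Samples in which no landmark is found get an identity
warp and a log message rather than an error.

**Subsampling and outliers.** Clustering operates on a uniform random
subsample of live cells (50,000 by default, the scale typical for one
sample; capped at what is available, with a warning). Participant-level
readouts are screened for extreme outliers with Tukey fences at
`coef = 3.0` times the interquartile range; the quartile convention is
fixed to linear interpolation (R's type 7) and recorded, because fence
positions depend on it and conventions differ across ecosystems.

## Gating

Subset definitions are a declarative tree of marker-threshold predicates
(YAML or list), applied top-down so a child population is always a subset
of its parent. Three relations cover practice: at/above threshold, below
threshold, and a half-open band `[lo, hi)` for graded phenotypes. Grade
gates such as CD25^hi^ (Treg) or CD56^dim^ (NK) are encoded as a second,
higher threshold key or a band — published gating figures never quantify
"hi"/"dim", so these thresholds are explicit, configurable inputs. The
shipped default tree encodes 26 standard PBMC populations (peanut-reactive
CD69^+^CD40L^+^CD4^+^ and CD69^+^CD8^+^ T cells, the CD45RA×CCR7
differentiation quadrants, Treg, NKT, γδ T, plasmablasts, memory B,
classical/intermediate monocytes, mDC1/mDC2, CD56^dim^CD16^+^ NK). TEMRA is
encoded as CD45RA^+^CCR7^−^. Per population the pipeline emits both
denominators — frequency among the parent and among all live cells — since
published readouts use either; downstream analyses must select explicitly.
Functional markers are summarized as the median transformed intensity (MSI)
over member cells.

Data-driven thresholds are available (`auto_threshold()`): the density
valley between the two largest modes, falling back to a high quantile with
a warning when the distribution is not bimodal.

## Clustering

Unsupervised structure discovery follows the self-organizing-map +
metaclustering design that dominates cytometry practice: an online SOM on
a 10×10 grid (codebook initialized from a seeded sample of cells; each cell
presented once per epoch for 10 epochs in seeded random order; learning
rate decaying 0.05 → 0.01). The Gaussian neighbourhood radius decays from
half the grid dimension down to 0.3. The end radius matters: at end radius
1 adjacent nodes retain ≈ 0.6 coupling indefinitely and a small grid can
never commit its nodes to distinct populations; shrinking the neighbourhood
to effectively the best-matching node lets the codebook settle on the
mixture components, which the blob-recovery tests verify against a k-means
oracle. Nodes are then metaclustered by hierarchical agglomerative
clustering (average linkage, Euclidean) cut at a fixed number of clusters
(30 by default). The consensus-resampling step some implementations use for
metaclustering is deliberately replaced by this deterministic cut:
reproducibility is prioritized over the marginal robustness of consensus
clustering, and the choice is visible in the metadata. Per sample the
pipeline reports metacluster frequencies (% of live, summing to 100) and
the pooled cluster × marker median matrix used for manual annotation.
Cluster annotation itself is out of scope — in practice it is done by
inspecting that matrix.

## Differential testing

Each feature is tested for a group difference with a likelihood-ratio test
between nested linear mixed models fitted by maximum likelihood: intercept
+ random batch intercept, versus the same plus the group fixed effect. ML
(not REML) is required for likelihood ratios across fixed-effect
structures. The statistic `2Δlogℓ`, truncated at zero, is referred to
χ²(1). When only one batch is present, or the batch variance collapses to
zero (singular fit), the test degenerates to the ordinary linear-model LRT
and the result is flagged — common practice for boundary cases in the mixed
modelling stack, in preference to mixture-χ² reference distributions.
Extreme outliers are removed per feature per stratum before fitting.
P values are Benjamini–Hochberg adjusted within the family of all features
of one stratum (timepoint × stimulation × grouping), matching how q values
are reported per analysis panel; a readout is significant only when
`p < 0.05` **and** `q < 0.1`. Wilcoxon rank-sum (Mann–Whitney) and
signed-rank paths are provided for analyte and clinical comparisons, with
exact small-sample p values where tie structure allows and tie-corrected
normal approximation otherwise. The response is fitted untransformed by
default, with optional log/logit transforms exposed, since the original
analysis does not state one.

Null calibration is a tested property, not an assumption: with simulated
batch effects and no group effect, the LRT p-value distribution is
approximately uniform (Kolmogorov–Smirnov distance < 0.05 at 2,000 null
fits) and empirical type-I error at α = 0.05 lies near nominal.

## Stability selection

The centrepiece statistic: the baseline feature table is re-simulated many
times (300 in the original design; the tests and acceptance script use 50,
which this package's power analysis shows is enough for features with
standardized shift ≥ 1.5 to surface reliably), an elastic-net logistic
regression is fitted to each replicate with penalty strength and L1/L2
mixing chosen jointly by k-fold cross-validated deviance (mixing grid
0.1–0.9 in steps of 0.2; 5 folds, class-balanced, seeded), features are
scored 0–100, and the **cumulative importance** of a feature is

> 100 × (number of iterations in which its score strictly exceeded 80) /
> (number of iterations).

The printed definition of the per-iteration indicator is self-contradictory
in its second branch; the implementation follows the accompanying text:
indicator = 1 iff score > 80, else 0, with 80 an arbitrary but fixed
threshold on the 0–100 scale.

Two deliberately distinct resampling modes are shipped because the
moment-preserving description ("same mean and variance per participant")
admits two readings:

* `per_participant_moments` (default; the literal reading) redraws each
  participant's entire feature vector i.i.d. from N(μ_p, σ_p²), where μ_p
  and σ_p² are the mean and variance across that participant's observed
  features. Under this reading the features of a participant become
  exchangeable, so no feature-level signal can survive the simulation —
  which is why the package's recovery properties are stated under the
  second mode.
* `per_feature_jitter` perturbs each observed value with noise scaled to
  half the feature's within-group standard deviation, preserving
  feature-level signal while still probing sampling variability.

Neither mode is asserted to be the original study's exact procedure; the
ambiguity is documented rather than hidden.

Feature scores are max-scaled absolute coefficients **on the standardized
scale** (|β_j|·sd(x_j), then scaled so the largest equals 100). The
standardization matters: coefficients on the original scale are inversely
proportional to the feature's units, and ranking them raw systematically
favours low-variance features regardless of signal. An all-zero model
scores every feature 0. Performance (AUC by the rank formula;
sensitivity/specificity at probability 0.5, second factor level positive)
is computed from out-of-fold pre-validated predictions rather than a
held-out split — at n = 46 a fixed split is too unstable. Because the
hyperparameter is itself selected on those folds, null performance centres
slightly above 0.5 (selection optimism); the null property is therefore
evaluated as the mean over fresh label permutations, each run through its
own small ensemble. Per-iteration seeds derive deterministically from the
master seed, failed iterations are excluded from all denominators, and more
than 10% failures aborts the run.

## Serology screening

Cytometry features are screened against serology variables (peanut-specific
IgE, Ara h 2-specific IgE, IgG4/IgE ratio) by Spearman rank correlation
with midrank ties, exact p values for small tie-free samples and the t
approximation otherwise. A pair passes the screen when `|ρ| > 0.4` and
`p < 0.001` — on the **raw** p value. This gate is intentionally not
multiplicity-adjusted: the conservative p-cut plays that role in the
original design, and the package documents rather than silently "fixes" it.
For passing pairs the ordinary least-squares line is reported; the 95%
pointwise confidence band drawn by `plot_correlation()` is a reporting
artifact, not an inferential claim.

## The synthetic cohort: what it emulates, and what it does not

Every stage is exercised end-to-end on a generator with known ground truth,
because the primary data (deposited FCS files) are not required at desk
scale. The generator emulates: two outcome arms (21 SU vs 30 DS by default,
mirroring the trial; 20 vs 26 reproduces the 46-sample baseline), batch
structure with additive latent batch intercepts, 123 participant-level
features (alternating subset-frequency and MSI kinds), a configurable set
of truly discriminative features, per-participant immune-subset
compositions that feed the single-cell event generator (18 populations
matching the default gating tree's leaves, with generous marker
separation), and serology variables rank-coupled to designated features by
a Gaussian copula (target Spearman ρ ≈ 0.45–0.47, the magnitude of the
published naive-CD8/IgE correlations; the latent copula noise is
orthogonalized against the feature's normal scores in-sample so the
realized coupling stays within ±0.15 of the target at n = 46).

Two generator choices deserve emphasis. First, frequencies are generated on
the logit scale (mapped to 0–100) and expressions on the log scale, so
values respect their natural ranges; `effect_size` is the **standardized
mean difference on the observed feature scale**, and the injected latent
shift is calibrated per feature (deterministic quadrature plus root
finding) to deliver exactly that — a fixed latent shift would be attenuated
by a feature-dependent amount through the nonlinear output maps. Bounded
and skewed features have a finite attainable standardized difference (a
subset near 0% cannot fall much further); the default base-mean ranges keep
all shifts up to ≈ 1.7 attainable in both directions, and an unattainable
request errors informatively. Second, all generation flows from a single
mandatory seed through arithmetic (non-RNG-consuming) child-seed
derivation, so every table, event matrix and ensemble is bit-reproducible.

What the generator does **not** emulate: spillover/compensation, doublets
and debris, non-Gaussian population shapes, marker correlations within
populations beyond the mixture structure, informative missingness, and any
attempt to fit generative parameters to the real deposited data. Passing
tests therefore demonstrate that the *methods* behave correctly under
controlled conditions — recovery of planted effects, calibrated nulls,
proportion recovery within binomial error — not that real data would yield
any particular biological result.

## Numerical choices and degenerate inputs

* Quartiles: type 7 (linear interpolation) everywhere, recorded in the
  outlier rule.
* KDE: Silverman bandwidth, 512-point grid; constant vectors short-circuit
  to a single landmark.
* Warps: strictly increasing knots enforced; identity for landmark-free
  samples; single-knot warps are pure shifts.
* Zero-variance responses: LRT returns statistic 0, p = 1 rather than a
  degenerate likelihood.
* Zero-variance participants in moments-mode simulation reproduce their
  mean exactly.
* Gating bands are half-open `[lo, hi)` so a grade gate and its
  complementary band partition the parent exactly.
* Problem sizes in the test-suite and acceptance script — 50-iteration
  ensembles, 20 master seeds for recovery, 2,000 null LRT fits, 10,000-cell
  clustering mixtures — are the package's chosen desk-scale study
  conditions; the power analysis behind them is the recovery test itself.

## Known limitations

* The moments-mode simulation, read literally, destroys feature identity;
  it is kept as the default because it is the literal printed procedure,
  but stability conclusions should be drawn under `per_feature_jitter`.
* FCS support covers float list-mode FCS 3.0 (read/write) — sufficient for
  interchange of synthetic and exported data, not for every instrument
  vendor extension; CSV is the robust path.
* The mixed-model LRT relies on the χ²(1) reference; for very small batch
  counts the random-intercept variance is weakly identified and the
  plain-regression fallback will engage often (it is flagged per feature).
* No longitudinal modelling, no multi-arm contrasts, no automated cluster
  annotation, no UMAP-based inference (embedding is display-only in the
  motivating analysis and is not a tested surface here).
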