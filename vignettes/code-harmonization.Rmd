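---
title: "Detecting and harmonizing cross-site medical-code heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and harmonizing cross-site medical-code heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codeharmony)
library(data.table)
```

## The problem

Two healthcare systems that share a common data model and coding standard
can still *use* the shared codes differently. Typical channels are coding
granularity (one site records laterality-specific diagnosis codes where the
other records an "unspecified" variant), code substitution (two
interchangeable codes of the same clinical group endorsed at very different
rates), site-local codes, and per-code frequency inflation. These are
differences in coding practice, not in patients, and they corrupt any
analysis that pools or transfers models across sites. The package provides
three stages — detection, mitigation, validation — all designed so that the
sites only ever need to exchange summary-level aggregates.

This vignette explains the models, their assumptions, the tunable
parameters, and the design choices made where more than one reasonable
construction existed.

## Detection

### Descriptive ratio

For code $j$ with endorsement counts $f_A, f_B$ and site person-time totals
$PT_A, PT_B$ (years), the smoothed frequency ratio is

$$\rho_j = \frac{(f_A + \kappa)/PT_A}{(f_B + \kappa)/PT_B}, \qquad \kappa = 10 .$$

The smoothing count keeps ratios finite for codes absent at one site and
shrinks ratios of rare codes toward the person-time ratio; it is purely
descriptive and never enters the formal tests. Swapping sites maps
$\rho \to 1/\rho$.

The installed example table (`cataract_frequency_example()`) carries the
published frequencies and ratios of the cataract-group codes from two
integrated healthcare systems. The person-time totals behind it were not
published, but the ratio formula factorizes as $\rho_j = c \cdot
(f_{A,j}+\kappa)/(f_{B,j}+\kappa)$ with a common $c = PT_B/PT_A$, so $c$ is
recoverable as a median over rows; `reconstructed_ratio()` does this
leave-one-out, so a code's own printed value never enters its
reconstruction:

```{r}
tbl <- cataract_frequency_example()
sapply(c("Z98.41", "H26.499"), function(cd) round(reconstructed_ratio(tbl, cd), 2))
```

### Code-level test

The comparison of a single code is operationalized as weighted least
squares of the per-patient endorsement *rate* (count / person-time) on a
site indicator plus baseline covariates, with person-time weights and an
HC0 sandwich variance for the site coefficient. Per-patient rates are
zero-inflated and heavily skewed, so the robust variance is essential; the
person-time weights give patients with longer follow-up (more precisely
estimated rates) more influence. An exact weighting/variance construction
was a genuinely open choice; this one is stated in full so it can be
replicated, and the test suite pins it to a brute-force normal-equations
oracle at 1e-10.

### Group-level score tests

Group tests work against the logistic null model of the site indicator on
covariates $Z$ (age, sex, insulin use, Elixhauser score), fitted by IRLS to
gradient norm $\le 10^{-10}$. With $\mu$ the fitted probabilities,
$D = \mathrm{diag}(\mu(1-\mu))$, $r = y - \mu$, and $G$ the patient-by-code
count matrix of one group:

* burden: $S = r'Gw$, $v = w'Aw$, $S^2/v \sim \chi^2_1$, where
  $A = G'DG - G'DZ (Z'DZ)^{-1} Z'DG$;
* SKAT: $Q = r'GW^2G'r$, $Q \sim \sum_k \lambda_k \chi^2_{1,k}$ with
  $\lambda_k$ the eigenvalues of $WAW$.

The burden test aggregates the group with a common sign and so has power
only when member codes shift in one direction; SKAT is a variance-component
test and detects substitution, where members move in opposite directions
and the group total is flat. Weights default to flat $w = 1$: the
minor-allele-frequency weighting familiar from genomics has no natural
analog for code frequencies, and a hook is provided rather than a guess.
Counts (not binary endorsements) are the default feature, to preserve the
frequency signal; a binary transform is available through
`patient_code_matrix()`. Bonferroni correction uses the number of tests
actually performed per family, with codes and groups as separate families.

The SKAT reference distribution is evaluated by Ruben's expansion of the
weighted chi-square sum into a mixture of central chi-squares — an exact
series with monotone coefficients whose truncation error is bounded by the
unallocated mixture mass — with the Liu et al. moment-matching
approximation as fallback when the series cannot converge or the upper tail
is below the expansion's cancellation floor (~1e-12). The test suite checks
the series against a $10^6$-draw Monte-Carlo estimate and against the Liu
approximation.

### Federated computation

Every quantity above is a sum of per-site cross-products. `site_view()`
wraps one site's data behind an interface that only ever emits aggregates:
per IRLS iteration $X'DX$ and $X'Dz$ (working response), and at the
converged null $G'r$, $G'DG$, $G'DZ$, $Z'DZ$. `federated_fit_null()` and
`federated_group_tests()` assemble the pooled Newton step and the pooled
test statistics from these sums, so the federated results equal the pooled
individual-level results to numerical precision — an exact identity, not an
approximation — and an audit log records the shape of every exchanged
payload. The federation is simulated in-process; network transport is out
of scope.

## Mitigation

### Embeddings

The premise of embedding-based mapping is that codes are surface views of a
shared clinical "language": if the two sites' patients undergo the same
latent clinical processes, the *co-occurrence geometry* of their codes is
shared even when the code choices differ. Per site, over the non-rare
vocabulary (site frequency ≥ 10), `count_cooccurrence()` counts unordered
pairs of same-patient events of distinct codes within a `window` (default
30 days — the convention of the co-occurrence embedding literature; the
choice matters little at desk scale and is exposed). Each qualifying event
pair counts once, preserving frequency information. The PMI matrix

$$\mathrm{PMI}_{ij} = \log\frac{C_{ij}/N}{(n_i/N)(n_j/N)}$$

is factorized by symmetric eigendecomposition, keeping the $d$
largest-magnitude eigenvalues ($V = U_d\,\mathrm{diag}\sqrt{|\sigma_d|}$,
default $d = 20$; column signs fixed so the largest-magnitude entry is
positive, making the factorization bit-reproducible). The SPPMI variant
$\max(\mathrm{PMI} - \log s, 0)$ is retained behind a flag, and the number
of codes it zeroes out entirely is reported — but PMI is the default:
unlike NLP stop words, high-frequency medical codes designate common
conditions and must not be discarded.

### Alignment

Anchors are the vocabulary intersection, in lexicographic order (a
top-N-by-frequency restriction is available). Anchor rows are
unit-normalized before fitting, and the reference site is never
transformed. Rotation alignment solves the orthogonal Procrustes problem
$\min_{T'T=I} \|X_A T - X_B\|_F$ in closed form via the SVD of $X_A'X_B$;
orthogonality keeps predictions at a common length, making the method
robust to scale differences between the sites' embeddings, and preserves
all within-site cosines. Projection alignment is the unconstrained ridge
regression $\min_T \|X_A T - X_B\|_F^2 + \lambda\|T\|_F^2$ — its anchor
residual can never exceed the rotation's.

`within_group_similarity()` is the alignment diagnostic: the mean cosine
over cross-site code pairs sharing a clinical group, averaged within group
first and then across groups (averaging group-wise keeps large groups from
dominating; the diagnostic is used comparatively, so either convention
would serve).

### Similarity, selection, operator

Mapping candidates for a source code are the reference codes of the same
clinical category; ungrouped codes are candidates only for their own name.
Directional similarity is the cosine of aligned vectors; regression
similarity regresses a source vector on all its candidates jointly (ridge),
so each coefficient is adjusted for the other candidates. The regression is
run per *source* code on candidate targets; the transposed construction
(per target on sources) is equally defensible and was not implemented.

Frequency refinement multiplies the similarity by
$\exp(-\gamma\,|\log(r_{A,i}/r_{B,j})|)$ with smoothed rates
$r = (f+\kappa)/PT$ and default $\gamma = 0.5$; it never changes sign, is
monotone in rate disagreement, and $\gamma = 0$ is the identity. The
exponential kernel was chosen for exactly those three properties; it
matters when two candidates are *directionally* indistinguishable — e.g. a
rarely used twin of the code at the reference site versus the code the
reference site actually uses — and the observed usage rates are the only
information that can break the tie.

Selection is top-K (ties broken by higher reference frequency, then
lexicographically) or all candidates above a threshold chosen by
cross-validation: the CV objective is $|AUC - 0.5|$ of the site classifier
on the harmonized data, directly instantiating the validation criterion.
The harmonization operator normalizes the positive part of the selected
similarities into a row-stochastic matrix $M$, so $X M$ conserves each
mapped code's count mass. How harmonized data should be *constructed* from
a mapping was an open design point; mass-conserving redistribution is the
minimal choice that keeps totals interpretable. Unmapped source codes
either carry to their identically named reference code or are dropped,
logged either way. Mapping is directional (source into reference);
the reverse direction is a separate run.

## Validation

`site_auc()` stacks the reference matrix and the harmonized source matrix,
fits an L2-penalized logistic regression (fixed penalty 1.0 on the
unstandardized log-likelihood, intercept unpenalized) in each stratified
training fold, and pools held-out scores into one cross-validated AUC with
a DeLong 95% interval. The penalty is fixed rather than tuned so that AUC
differences reflect harmonization, not hyperparameter search; features
default to log1p counts (binary endorsement available). The baseline
comparator is the same protocol on the codes present at both sites, with no
harmonization. The pipeline restricts both classifiers to codes inside the
mapped clinical categories: the mapping cannot move codes outside its
candidate scope (e.g. ungrouped site-local codes), so including them would
measure a difference the method never claimed to remove.

## The synthetic generator

`generate_cohort()` draws, per site, patient covariates (age ~ N(63, 10²),
sex ~ Bern(0.49), insulin ~ Bern(0.21), Elixhauser ~ Pois(3.6) — calibrated
to a published diabetic cohort's baseline table) and person-time uniform on
(0.5, 5] years; latent condition episodes arrive as Poisson processes with
log-linear covariate effects *shared across sites*; each episode emits
codes through a site-specific channel, dated within a 7-day co-emission
window. Coding differences therefore live entirely in the channels — the
clinical processes are identical by construction — and each condition
co-emits a diagnosis code and a shared CPT marker (per condition and site,
emission probabilities sum to at most 1). Scenario presets:

* `scenario_null()` — identical channels; identity ground truth; the
  type-I-error and domain-confusion null harness;
* `scenario_substitution()` — one group with a specific/unspecified pair
  per condition emitted at mirrored probabilities (0.55/0.05 vs 0.05/0.55),
  so the group-level intensity is exactly balanced while member ratios are
  11; five null groups; two site-B-only local codes;
* `scenario_granularity()` — one site splits a condition across three
  laterality codes (0.20/0.20/0.15) where the other emits one unspecified
  code (0.55), totals matched.

`expected_code_rates()` gives the closed-form expected endorsement rate per
code (condition rate × covariate moment factor × emission probability ×
multiplicity), so planted ratio structure is verified analytically, not by
simulation.

Ground truth is generative: a source code's support set is the reference
channel's emission distribution of its emitting condition, restricted to
the code's clinical category and renormalized. Sibling codes of one
condition within one group are content-equivalent views of the same
clinical event and are statistically exchangeable in co-occurrence, so no
co-occurrence method can direct a mapping *between* them — the support set
is the honest resolution limit of the method. `mapping_recovery()` scores a
top-1 selection against these supports. For the null preset the channels
are identical and the recorded truth is the identity map, matching its role
as a strict null harness.

What the generator does *not* emulate: real marginal frequency
distributions (tens of thousands of codes with power-law frequencies),
covariate missingness, enrollment churn, temporal drift within a site, and
correlated condition onsets. Passing tests therefore demonstrate that each
stage does what it claims under its own assumptions — shared latent
processes, channel-only differences — not that mapping quality observed
here transfers to any particular real network.

## Numerical choices and degenerate inputs

* IRLS convergence at gradient norm ≤ 1e-10; linear predictors beyond ±30
  raise a complete-separation error rather than returning drifting
  coefficients.
* Degenerate burden variance (v ≤ 0) and all-zero group matrices return
  p = 1 with a warning; collinear covariates are an error naming the column.
* Eigenvalues below 1e-10 of the largest are dropped from the SKAT mixture.
* Embedding sign convention (largest-magnitude entry positive) plus closed
  forms everywhere make detect → embed → align → map → validate
  deterministic given one seed, which also drives the generator and all CV
  fold assignments; repeated pipeline runs produce identical artifact
  checksums.
* Exact similarity ties in selection are broken by higher reference-code
  frequency, then lexicographic order.

## Scale of the shipped checks

The package's statistical guarantees are exercised at desk scale, chosen so
the full suite runs in about a minute: type-I error from 1000 replicates of
the null scenario at 500 patients/site; substitution sensitivity (SKAT
power ≥ 0.9, burden ≤ 0.2) from 100 replicates at 1000/site; federated ≡
pooled equality over 20 seeds; mapping recovery and AUC movement over 20
seeds at 1000/site with d = 10 embeddings. These sizes are statements about
the synthetic design, not about real-data performance.

## Known limitations

* Two sites only; multi-site consensus alignment is out of scope.
* Mapping is one-directional; reference-site codes can remain unmapped.
* The CV threshold optimizes the same criterion later used for validation;
  when the threshold path is chosen, the confusion AUC is an optimistic
  diagnostic and should be read comparatively.
* Domain confusion measures *residual site signal*, not mapping
  correctness: population differences not removed by covariate adjustment
  also keep the AUC above 0.5.
* The regression-similarity estimator is one of two defensible
  orientations (per-source on candidates), and the within-group similarity
  averages group-wise; both are documented conventions rather than the only
  possible readings.
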