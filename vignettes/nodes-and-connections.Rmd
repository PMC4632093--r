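---
title: "Nodes-and-connections screening: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nodes-and-connections screening: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodeconnect)
```

# The problem

Genome-scale RNAi knockdown screens identify genes required for a cellular
phenotype — here, drug-induced apoptosis of estrogen-dependent breast cancer
cells under the estrogen-receptor degrader fulvestrant — but they return flat
gene lists whose mutual relationships are opaque. The *nodes-and-connections*
strategy instead alternates two steps: a small screen establishes *primary
node* genes, then known physical/functional interactors of the current
frontier are predicted from an interaction catalog and only those candidates
are tested by knockdown. Validated candidates enter the map at the current
*generation* (discovery round) and become the next frontier. Iterating until
no new candidates validate yields a connected, generation-annotated
interaction map. Downstream, the map's nodes are evaluated as prognostic
biomarkers: by median-split survival analysis of expression cohorts, and by
ordinal immunohistochemistry (IHC) scoring summarized in a per-patient
Prognosis Marker Expression (PME) score whose synchronization across antigens
is tested against a permutation null.

`nodeconnect` implements each stage as ordinary R functions over plain data
frames, plus synthetic-data generators that emulate every input, so the whole
pipeline is exercisable and testable without any external download.

# Hit calling from clone-level viability

Each target gene is covered by several independent shRNA clones; each clone
is assayed in replicate in a drug arm and a vehicle arm, alongside
empty-vector (pLKO.1) control infections.

* **Per-clone test** (`test_clone`): a two-group one-way ANOVA (F test) of
  drug-arm viability, clone versus control. Because the F test is
  direction-blind, a clone is *positive* only when `p < alpha` **and** its
  drug-arm mean lies strictly above the control mean — resistance, not
  sensitization. With zero pooled variance the test degenerates: equal means
  report `p = 1` (direction `none`), distinct means report `p = 0`; this
  makes the noiseless simulation limit exact rather than `NaN`.
* **Per-target call** (`call_target`): a target is a hit when at least
  `min_positive` clones (default 2) are each positive. Distinct clones have
  different off-target spectra, so the two-clone rule is the screen's
  off-target filter; no multiplicity correction is applied across clones or
  targets, and the calibration suite checks the resulting family-wise rate
  against its closed form instead. Under the null the per-clone positive
  rate is `alpha/2` exactly (significance is symmetric and the direction
  gate keeps one tail), so the expected null hit rate for five clones is
  `1 - pbinom(1, 5, alpha/2)`, about 0.6% at `alpha = 0.05`.
* **Toxicity** (`flag_toxicity`): a knockdown whose pooled vehicle-arm mean
  falls below `threshold` (default 0.5) times the control vehicle mean kills
  cells regardless of drug. Such targets are *untestable*: `is_hit` is
  reported as `NA`, never `FALSE`, because downstream map assembly treats
  them differently from negatives. The 0.5 default is a configurable
  operationalization of a "strong" viability loss; the underlying reports
  are qualitative.

Whether the original analysis pooled all clones of a target into one ANOVA
or tested clone-by-clone is not documented; clone-by-clone is implemented
because the ≥2-clone rule is defined over individual clone outcomes.

# Map assembly semantics

`assemble_from_ledger` deterministically replays a campaign recorded as
`validation_record` rows (gene, round, source genes, outcome, corroboration
flag). The semantics were chosen to reproduce the shipped fulvestrant
campaign fixture exactly:

* **Generation = discovery round**, not graph distance. A gene that
  neighbors a generation-2 node but was only predicted and validated in
  round 4 is a fourth-generation node. Rounds are recorded data: curated
  campaigns re-run their predictions as the catalog grows, so a candidate's
  round is not derivable from its sources' generations.
* **Predicted-only admission rule.** A candidate whose knockdown was
  untestable (nonspecific toxicity, failed knockdown) is admitted at
  finalization as a `predicted_only` node iff (a) a later-validated node was
  discovered via it, or (b) its external-corroboration flag is set. Rule (a)
  admits the myosin light chains (their kinase MYLK3 validated downstream)
  and STAT3 (PAG1 validated via it); rule (b) admits STAT5A. Orphan
  untestables and all negatives stay in the provenance ledger only.
* **Alias groups** collapse several gene symbols into one displayed node
  (MYL2 + MYL9 become "Myosin light chains"), with generation equal to the
  earliest member round. This is what reconciles the gene-level ledger with
  the 19-node count of the displayed map.
* **Edges** are the admitted candidate–source pairs plus any catalog edges
  whose both endpoints are admitted; every non-primary node therefore keeps
  at least one neighbor of strictly lower generation (its provenance), an
  invariant the test suite checks.
* **Saturation** (`check_saturation`): `TRUE` when the last `k` rounds
  (default 2) each validated zero candidates. In simulated campaigns
  (`run_campaign`) the engine keeps proposing from the whole map after the
  frontier empties — without retesting negatives — so saturation is observed
  rather than inferred from an empty frontier.

`run_campaign` couples proposal, simulated screening and iteration against a
planted-subnetwork catalog from `generate_network`; with a noiseless assay
its recall of planted genes reachable from the seeds is exactly 1 at
saturation, which the tests use as a simulation oracle.

# PME scoring and the synchronization test

Ten antigens are scored 0–4 by two independent examiners on each of 18
tumors; the examiner mean (steps of 0.5) is the working score and the PME
score is its sum over the panel, bounded by `[0, 4 × n_antigens]`. The panel
size is configurable and the score is deliberately not rescaled when the
panel differs from 10 — the bounds adapt instead, keeping the score an
interpretable sum.

**Marginal-resampling null** (`simulate_null`): under the hypothesis that
antigens are expressed independently, a theoretical PME score draws one
observed mean score per antigen, independently and uniformly *with
replacement* from that antigen's per-patient values, and sums. Sampling with
replacement is required for the 50 000 independent sums the null comprises.
Two-tail cutoffs are the empirical 2.5/97.5 (5%) and 0.5/99.5 (1%)
percentiles with linear interpolation (R quantile type 7), splitting each
`alpha` symmetrically; tail membership is *strict* inequality beyond the
cutoffs, so values exactly at a cutoff are not extreme.

**Tail chi-square** (`tail_chi2`): Pearson chi-square without continuity
correction on the pooled 2-cell table (in-tail versus out-of-tail, 1 df)
against expectation `(n·alpha, n·(1−alpha))`; a 3-cell layout keeping the
lower and upper tails separate (2 df) is available via `cells = "split"`.
At `n = 18` the expected tail counts (0.9 and 0.18) violate the chi-square
sampling assumptions and make the nominal test anticonservative, so an
exact binomial p-value is always reported alongside; the calibration suite
quantifies the actual size under independent antigens with a binomial
oracle that uses the realized (discrete) tail mass of the resampled null
rather than the nominal `alpha`.

**Recurrence comparison** (`compare_groups`): the test behind the
recurrence-group contrast is not named in the source material, so the
two-sided Wilcoxon rank-sum is used (ordinal-sum data, n = 18) with a Welch
t-test reported alongside; subgroup analyses restrict to patients with or
without endocrine therapy.

# Median-split survival screen

For each gene and cohort, patients strictly above the gene's median
expression form the high-expresser group and the rest the low group — ties
go low, so every non-tied high value exceeds every low value, matching the
description of the published split. The one-sided log-rank test
(`logrank_one_sided`) uses the standard hypergeometric variance; `z` carries
the sign of observed-minus-expected events in the high group and the
one-sided p is `pnorm(z)`, so *fewer* events among high expressers (better
survival) gives small p. Benjamini–Hochberg runs once over the full
gene × cohort family (the published description corrects after testing every
gene in every data set), skipped records excluded; calls are significant at
adjusted values below 0.25. Real-cohort ingestion is a documented TSV schema
(`read_cohort`); reproducing any particular published cohort panel is out of
scope since those data are external.

# Expression-response classification

`classify_response` consumes already-normalized relative expression
(vehicle ≡ 1.00 after renormalization, which also makes calls invariant to
global rescaling). An omnibus one-way ANOVA across vehicle plus treatment
conditions gates significance at `alpha = 0.05`; the call direction follows
the side of 1.00. For dose series, all individually significant doses must
deviate on the same side — otherwise the gene is reported `unchanged` with a
warning. An omnibus-plus-direction scheme was chosen over per-dose pairwise
testing because the classification groups genes into induced / suppressed /
unchanged without a dose–response trend model.

# The synthetic generators

The generators define the study conditions under which every calibration
and power property in the test suite is evaluated.

* **Screens** (`generate_screen`): viability is normal noise
  (`noise_sd = 0.1` by default, roughly a 10% assay CV) around arm means,
  truncated at zero; the control drug-arm mean is normalized to 1.0 (the
  drug-killed baseline) and resistance is an uplift `effect_size` above it
  (default 0.5). Toxic targets multiply both arms by `toxic_factor`
  (default 0.3, a strong nonspecific kill). Replicates default to 3 per
  clone per arm — the smallest design leaving residual degrees of freedom
  for the per-clone ANOVA; the source screen does not report its replicate
  count, so this is a free parameter.
* **Networks** (`generate_network`): Erdős–Rényi background edges at a
  configurable mean degree plus a planted required-gene set connected by a
  random recursive tree (always present for planted sizes ≥ 2, so the
  connectivity invariant holds even at mean degree 0).
* **IHC tables** (`generate_ihc`): a standard-normal latent factor per
  patient drives all antigens with loading `sync_rho`
  (`z = ρ·f + √(1−ρ²)·ε`), discretized by fixed standard-normal quintile
  bins to 0–4; each examiner adds rounded N(0, `examiner_sd`) rating noise,
  clipped to the scale. `sync_rho = 0` gives mutually independent antigens
  (the null of the synchronization test); `sync_rho = 1` with
  `examiner_sd = 0` gives perfectly rank-synchronized antigens. The same
  factor lowers recurrence probability through a logistic link
  (`recurrence_link`), reproducing the lower-PME-in-recurrence structure.
  Defaults (`sync_rho = 0.6`, `recurrence_link = 1`, `examiner_sd = 0.5`)
  are moderate values chosen once as plausible for coordinated tumor-marker
  expression with imperfect raters.
* **Cohorts** (`generate_cohort`): expression is standard normal;
  event times are exponential with hazard
  `baseline × HR^(expression > median)` per prognostic gene, the simplest
  model in which the median-split log-rank is well-posed. Censoring is an
  independent Bernoulli(`censor_rate`) indicator with censoring time
  uniform on `(0, T)` — independent of covariates and degenerate (no
  events) at rate 1.

What the generators do **not** emulate: infection efficiency and selection
artifacts, plate/batch effects, correlated off-target signatures among
clones, non-proportional hazards, cohort heterogeneity, or inter-examiner
bias beyond symmetric noise. Passing calibration on synthetic data therefore
demonstrates internal statistical correctness of the pipeline, not
robustness to those real-data failure modes.

# Numerical choices and problem sizes

* Quantiles everywhere use R's default type 7 (linear interpolation).
* Zero-variance ANOVA cases are resolved explicitly (see above) instead of
  propagating `NaN`.
* Ledger replay admits a source recorded in the same round as its candidate
  (a validation chained through a pending untestable prediction); dangling
  source references are an error naming the offending record.
* Re-predicted candidates keep their earliest round; negatives are not
  retested by simulated campaigns.
* The calibration suites run at sizes chosen to give stable Monte-Carlo
  estimates while keeping the default test run fast: 2000 single-target
  null screens (with a 60-replicate control arm so the five per-clone tests
  are effectively independent, as the binomial family formula assumes),
  50 000-sample permutation nulls where cutoff accuracy matters and 2000
  where only rejection is needed, 400 independence tables for the
  chi-square size estimate, 2000 null cohorts for log-rank uniformity, 250
  screens for FDR control and 60 for power. The survival simulations use
  cohorts of 400–500 patients — the scale of the published expression
  cohorts the screen targets, and the regime where the normal approximation
  behind the log-rank p-value is accurate; at much smaller cohorts
  (n ≲ 120) that approximation is measurably liberal (roughly a 10%
  inflation of small tail probabilities), which would surface as an
  inflated all-null rejection rate and is a property of the approximation,
  not of the Benjamini–Hochberg step. The acceptance script
  (`scripts/acceptance.R`) re-runs the same computations from scratch under
  a caller-supplied seed.

# Known limitations

* The chi-square tail test is anticonservative at n = 18 by construction;
  the exact binomial companion is the statistically sound reading and both
  are always reported.
* The hit-calling family rate assumes per-clone tests are independent;
  clones sharing a small control arm are positively correlated, which
  inflates the realized family rate above the closed form. Screens with
  generous control arms approach independence.
* `assemble_from_ledger` trusts recorded rounds; it validates referential
  consistency, not the unknowable history of the prediction tool that
  produced the candidates.
* The survival stage deliberately stops at median-split log-rank screening;
  it is a biomarker screen, not a hazard model (no Cox regression, no
  covariate adjustment).
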