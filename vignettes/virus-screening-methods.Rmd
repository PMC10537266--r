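---
title: "Screening laboratory Drosophila RNA-seq for natural virus infections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening laboratory Drosophila RNA-seq for natural virus infections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labvirome)
```

## The problem

Laboratory stocks of *Drosophila melanogaster* frequently carry natural RNA
virus infections — nora virus, Drosophila A virus (DAV), DCV, galbut virus
and others — that the original experimenters never intended or noticed.
RNA-seq libraries produced from such stocks contain viral reads, so a
public transcriptomic dataset can be screened retrospectively: which
libraries were infected, how prevalent was each virus within a project, do
viruses co-occur more often than chance, and how does infection perturb
host gene expression?

Two properties of multiplexed sequencing make this harder than it sounds.
First, *index hopping* (barcode switching) misassigns a small fraction of
reads between libraries sharing a flow-cell lane, so an uninfected library
sitting next to a heavily infected one acquires a low but nonzero viral
read count. Second, libraries from cell-culture contamination can inject
viral RNA that has nothing to do with the flies being sequenced. The
package implements the downstream inference for this setting, and a
synthetic-data generator with planted ground truth so every stage can be
validated end to end without any external download.

## Presence/absence calling

A virus is called present in a library when its read count passes **both**:

* a relative threshold: at least 1% (`rel_threshold = 0.01`) of the
  highest count observed for that virus — by default within the same
  project (`scope = "project"`; a pooled option exists, since screens
  differ in whether projects share flow cells);
* an absolute floor of 150 reads (`abs_threshold = 150`).

The relative rule targets index hopping: hopped reads scale with the
donor library's titre, so a fixed floor alone would fail next to an
extremely high-titre neighbour. The floor removes residual low-level
noise for viruses whose maximum count is modest. Raw read counts are used
(not library-size-normalised), because hopping operates on reads, not on
proportions. The rule is monotone — increasing a count can never revoke a
presence call — and the library holding the per-virus maximum is always
called when that maximum reaches the floor.

When duplicate libraries (technical re-samples) are available, the floor
can be tuned with `select_abs_threshold()`: for each candidate the
*duplicate discordance* — the fraction of (pair, virus) combinations whose
two members receive different calls — is computed, and the smallest
candidate attaining the minimum is chosen (ties break toward small
thresholds to retain sensitivity). Discordance is a declared
interpretation of "inconsistency between duplicates": it is the natural
zero-one loss on the calls themselves. The default candidate grid is
{10, 25, 50, 100, 150, 200, 300, 500}.

Viruses whose per-library counts are almost perfectly correlated across
many libraries (`flag_contaminant_clusters()`, Pearson on `log1p` counts,
components of the graph with r ≥ 0.95) likely share a single
contamination source rather than representing independent infections;
`log1p` is used because counts span four or more orders of magnitude.

## Sex verification and the switching rate

Library sex is verified from sex-specific marker genes
(`verify_sex()`): the CPM-normalised sum of male-marker counts must be at
least twice the female-marker sum to call a library male (and vice
versa); everything else — including libraries in which both panels are
silent — is ambiguous. The 2× margin is a documented default, not a
published constant; it is deliberately conservative so that ambiguous
libraries are excluded from switching-rate estimation rather than
guessed. FlyBase identifiers for the customary *D. melanogaster* panels
ship as `dmel_male_markers` (11 genes) and `dmel_female_markers`
(5 genes).

Marker reads observed in verified libraries of the *other* sex can only
have arrived by index hopping, which yields a direct rate estimate
(`estimate_switching_rate()`). Two numbers are reported:

* the **raw wrong-sex fraction** `rate_raw = W / T` (wrong-sex marker
  reads over all marker reads) with a Clopper–Pearson interval. Under a
  uniform within-lane hop model this estimates the hop rate *times the
  fraction of a source library's lane-mates that are of the opposite
  sex* — on a balanced mixed-sex lane, roughly half the hop rate;
* the **exposure-corrected rate** (the primary `rate`): `W` divided by
  the summed exposure
  `sum over lanes, panels of (panel reads) x (opposite-sex lane-mates) / (lane size - 1)`,
  which is consistent for the per-read hop rate itself. Since `W` is a
  sum of Poisson counts with mean `rate x exposure`, an exact Poisson
  (gamma-quantile) interval is attached.

Single-sex projects provide no wrong-sex signal; the estimator then
returns `NA` with `estimable = FALSE` rather than a fabricated zero. The
rate is reported for diagnostics alongside the calls; the primary caller
remains the relative-plus-floor rule.

## Prevalence and co-infection

Per-project prevalence is `k/n` with a Clopper–Pearson (exact
beta-quantile) interval — chosen over Wald or Wilson intervals because
single-positive projects (`k = 1`) are common in screens and exact
intervals keep at least nominal coverage there (empirically ≥ 95% at
`n = 100, p = 0.05` in the test suite, conservative as expected).

Association between two viruses within a project is tested on the 2×2
cross-tabulation of calls with an exact conditional test written from
first principles (`fisher_exact()`): log-gamma factorials (stable to
thousands of libraries), enumeration over the feasible support of the
top-left cell, and a two-sided p-value by the point-probability
("minimum-likelihood") rule with a `1 + 1e-7` relative tie tolerance —
the convention of the standard statistical environment — with tail
doubling available for comparison. The sample odds ratio
`n11*n00/(n10*n01)` is reported (infinite when a denominator cell is
empty and the numerator is not). `coinfection_scan()` tests all pairs in
every project and flags at a **raw** p < 0.01: no multiplicity
correction is applied, mirroring standard screening practice, and the
output says so — treat flags as candidates, not discoveries. Exact tests
on discrete support are conservative; the null flag rate sits slightly
below alpha, which the property tests assert as an inequality rather
than pretending exact uniformity.

## The per-gene expression model

For each virus, all projects in which it was called present are combined
and each gene's log2-CPM is modelled as

```
expression ~ sex + virus + sex:virus + (1 | project_genotype_tissue)
```

with uninfected females as the reference. Term-dropping rules: if the
virus occurs in only one sex, or the data contain one sex, the sex term
and the interaction are dropped (leaving `~ virus`); stratum columns with
a single level among the used libraries are dropped from the grouping
label, and a single-level grouping drops the random intercept entirely
(plain OLS). Age is never a covariate — public screens rarely report it.

Numerical strategy: the response is `log2((count + 0.5) / (effective
library size + 1) * 1e6)`. Effective library sizes are TMM-normalised
(edgeR) by default: when planted (or real) expression changes are not
balanced between up- and down-regulation, plain CPM shifts every
*unchanged* gene in the opposite direction (composition bias) and
inflates the null false-positive rate; TMM removes this. Genes must
exceed 1 CPM in at least 5% of libraries (`filter_genes()`) — declared
defaults, since published screens rarely state their filters.

The mixed model has a single variance component, which permits a robust
dependency-light fit: the group-indicator cross-product `ZZ'` is
eigen-decomposed **once per design**, making the marginal covariance
diagonal for every gene; REML then profiles to a 1-D optimisation over
the variance ratio (log-scale, bracket `e^-12..e^12`), with an explicit
boundary comparison so a zero group variance cleanly collapses to OLS.
Wald t-statistics use Satterthwaite-type degrees of freedom computed from
a numeric 2×2 Hessian of the REML criterion in
`(sigma^2_e, sigma^2_g)`; against `lmerTest` the estimates, standard
errors and df agree to at least four decimals in the test suite.
Rank-deficient genes are skipped with the reason recorded; a failed mixed
fit falls back to OLS with a flag.

Residual variances are optionally moderated across genes
(`moderate_variances()`, on by default): a scaled-inverse-chi-square
prior is fitted by matching moments of the log variances
(digamma/trigamma corrections, trigamma inverted by Newton), and each
gene's posterior variance is the df-weighted blend. The prior-df → 0
limit returns the raw variances; zero excess spread gives an infinite
prior df with the common scale estimated by the plain mean; a degenerate
(constant) variance vector is returned unchanged with a warning.
Moderation stabilises small-df designs but, without a mean–variance
trend, is mildly anticonservative on count data whose residual variance
depends on expression — which is why the calibration checks in this
package assert the raw (unmoderated) fit, and why moderation never
changes the effect estimates, only their uncertainties. This, together
with omitting precision weights (the package uses unweighted log-CPM
where precision-weighted engines exist), is a deliberate simplification;
the moderation stage partially compensates for the missing weights.

P-values are Benjamini–Hochberg adjusted within each coefficient
(`adjust_bh()`, the step-up rule written out and oracle-checked), and
genes are classed `up`/`down`/`ns` by |logFC| > 0.5 with adjusted
p < 0.001.

## Correlating effects across viruses

`effect_matrix()` aligns per-virus logFC vectors by gene id;
`correlate_effects()` computes pairwise correlations on each pair's
shared genes with p-values from the t-transform of r on n − 2 df, and
masks entries failing alpha (0.001). All tested genes enter the
correlation, not only significant ones — restricting to significant
genes would inflate correlations by selection. Pearson is the default;
Spearman is provided because screening reports are not consistent about
which they use, and the package surfaces rather than resolves that
ambiguity.

## What the generator emulates — and what it does not

`simulate_experiment()` produces a multi-project experiment with the
statistical structure the analysis assumes:

* strata: projects × lanes × genotypes × tissues × sexes, laid out so
  every lane mixes sexes and genotypes (hopping is only detectable on
  mixed lanes);
* infections: independent Bernoulli per library and virus at configured
  prevalence; infected titres log-normal (default median 5×10⁴ reads,
  log-sd 1.5, spanning the orders of magnitude seen in real screens
  where single libraries range from <1% to ~70% viral);
* hopping: a fraction `hop_rate` (default 0.002) of a lane's viral reads
  relocates uniformly over the `s − 1` lane-mates; each uninfected
  lane-mate receives a Poisson count with mean
  `hop_rate x lane total / (s - 1)`. The same model leaks marker-gene
  reads into wrong-sex lane-mates (flag `marker_leakage`), without which
  the switching-rate estimator would have no signal;
* expression: negative-binomial counts (default dispersion 0.2) with
  log2-scale fixed effects — sex (default |logFC| 1 on 10% of genes),
  per-virus main effects (|logFC| 1 on 10%; half up, half down) and
  sex:virus interactions (|logFC| 1 on 5%) — a normal random intercept
  per project×genotype×tissue group (sd 0.5 log2 units) and log-normal
  library sizes (median 5×10⁶ reads);
* duplicates: optional technical re-sample pairs whose second member
  shares the first's stratum and infection status, with counts re-drawn
  Poisson around the first member's counts;
* determinism: one seed, with fixed per-stage sub-seeds, gives
  bit-identical artefacts.

Deliberately not emulated: raw reads/FASTQ, ribosomal RNA, cell-culture
contamination mixtures, virus-virus interactions (statuses are
independent), expression-dependent dispersion trends, GC or length
biases, and batch effects beyond the group intercept. Passing the
recovery tests therefore shows the inference is correct *under its own
assumptions*; it does not certify performance on real data whose
violations of those assumptions (trended dispersion, correlated
infections, unbalanced lanes) are exactly what the diagnostics — the
contaminant-cluster flag, the switching-rate estimate, the duplicate
discordance profile — are there to reveal.

## Validation choices and problem sizes

The test suite validates each from-scratch component against an
independent oracle: the exact test against exhaustive hypergeometric
enumeration (500 random tables, margins ≤ 30) and the reference
implementation; the caller against a brute-force re-evaluation of the
rule (100 random matrices) plus a monotonicity property; BH against an
independently written step-up (1000 vectors); the REML/Satterthwaite fit
against `lmerTest`; moderation against `limma::squeezeVar` and by
recovering planted prior hyperparameters at 5000 genes.

Recovery runs use the generator defaults — 200 libraries, 2000 genes,
planted virus |logFC| 1.0, group sd 0.5, NB dispersion 0.2. At these
conditions the per-gene standard error of the virus coefficient is
0.13–0.17 log2 units (the coefficient is the female-stratum contrast
once the interaction is in the model), so per-gene error cannot fall
below that floor at any prevalence; the meaningful recovery target is
the *mean* recovered effect across planted genes, whose error the tests
bound at 0.1 log2 units (observed |bias| < 0.02 across seeds). Per-gene
mean absolute error (~0.13) is reported alongside for transparency. The
null-gene false-positive rate at raw p < 0.05 is asserted within three
binomial standard errors of 0.05. Switching-rate recovery uses 100
simulations of a 40-library single-project screen at hop rate 0.002,
requiring the truth inside the 95% interval at least 90 times (observed
93–98).

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)          # 2 projects x 100 libraries, 2 viruses
sim <- simulate_experiment(cfg)

calls <- call_infections(sim$virus_counts, sim$meta)
estimate_prevalence(calls, sim$meta)
coinfection_scan(calls, sim$meta, alpha = 0.01)

res <- run_de(sim$gene_counts, sim$meta, calls, "DAV")
attr(res, "summary")                 # up/down/ns per coefficient
head(volcano_table(res))
```

Or, end to end with every artefact written to disk:

```{r pipeline, eval = FALSE}
manifest <- run_pipeline(pipeline_config(outdir = "screen_out",
                                         sim = cfg))
```

## Known limitations

* The expression model is Gaussian on log2-CPM; very low counts are
  handled by the prior count and the expression filter, not by a count
  likelihood.
* Precision weights are not implemented; variance moderation partially
  compensates (see above).
* One random intercept only: crossed or nested random effects beyond the
  concatenated grouping label are out of scope.
* The co-infection scan deliberately applies no multiple-testing
  correction; its flags are screening candidates.
* The switching-rate correction assumes hops land uniformly on
  lane-mates; optical duplicates or patterned-flow-cell effects that
  violate uniformity would bias it.
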