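---
title: "Reversal scoring of disease expression signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversal scoring of disease expression signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revsig)
```

## The problem

Loss-of-function mutations in epigenetic regulators such as the H3K36me3
methyltransferase SETD2 produce a characteristic transcriptional state —
a set of genes pushed up and a set pushed down relative to wild-type
cells — that is associated with aggressive, chemo-resistant leukemia.
Connectivity mapping asks whether any drug, profiled in a large
perturbation compendium (L1000-style level-5 signatures), pushes those
same genes in the *opposite* directions. A drug that does is a candidate
for reversing the disease state.

`revsig` implements this computational arm as a reusable pipeline:

1. **Signature building** — call up/down gene sets from differential
   expression tables by FDR and fold-change thresholds, and map rodent
   symbols onto the (human) drug-profile universe.
2. **Reversal scoring (RGES/sRGES)** — score every drug profile with a
   Kolmogorov-Smirnov reversal statistic and summarize per drug across
   treatment conditions.
3. **MOA class enrichment** — ask which mechanism-of-action classes
   concentrate at the reversal end of the drug ranking, and select
   classes passing in two independent disease signatures.
4. **Reversal genes** — identify which signature genes a class reverses
   consistently, and which genes separate phenotype-sensitive from
   insensitive classes.
5. **Phenotype layer** — normalize plate screens, fit 4PL dose-response
   curves, form mutant/wild-type response fold-changes and correlate them
   with predicted reversal.
6. **Synthetic data** — generate all of the above inputs with planted
   ground truth, so every stage is testable without external databases.

## The reversal score

For one profile, genes are ranked by drug-induced fold-change (rank 1 =
most up-regulated). For a query set occupying positions
$V(1) < \dots < V(t)$ among $n$ genes, the unweighted connectivity-map
statistic is

$$a = \max_j\left(\tfrac{j}{t} - \tfrac{V(j)}{n}\right),\qquad
  b = \max_j\left(\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right),\qquad
  es = \begin{cases} a & a > b\\ -b & \text{otherwise,}\end{cases}$$

and the reversal gene expression score is
$\mathrm{RGES} = es_{up} - es_{down} \in [-2, 2]$. A reverser pushes
disease-up genes toward the bottom ($es_{up} \to -1$) and disease-down
genes toward the top ($es_{down} \to +1$), so strong reversal is strongly
negative. The source method names only "a Kolmogorov-Smirnov test"; we
adopt the unweighted $a$/$b$ running-maximum form because it is the form
for which $es_{up} - es_{down}$ and the $[-2,2]$ range are standard in
the reversal-scoring lineage.

Numerical conventions worth knowing:

* **Ties** in fold-change are broken by gene symbol in C-locale (radix)
  order, so rankings are total orders and results are
  locale-independent. The synthetic generator additionally adds a seeded
  jitter of order $10^{-9}$ so generated profiles are tie-free.
* **Missing signature genes** are intersected out per profile. If either
  intersected set is empty the profile is *skipped with a reason code*,
  never scored 0 — a zero would silently masquerade as "no effect".
* **Reversal duality.** Reversing a tie-free ranking maps the statistic
  components exactly as $a' = b - 1/n$ and $b' = a + 1/n$. The intuitive
  "antisymmetry" $|es' + es| \le 1/n$ follows whenever the two
  evaluations do not both take the $-b$ branch; for sets placed
  symmetrically around the ranking midpoint (where $a \approx b$), both
  branches can lose and the sum is not small. The tests assert the exact
  duality everywhere and the $1/n$ bound under its branch condition.

## Summarizing across conditions (sRGES)

Profiles of one drug differ by cell line, dose and duration. Two
summaries are provided. `"mean"` is the arithmetic mean of per-profile
RGES. `"condition_weighted"` first adjusts profiles toward a reference
condition (10 µM, 24 h by default): conditions are stratified by
(dose, time); each stratum's median offset of drug-level mean RGES
relative to the reference stratum — estimated from drugs measured in
both — is subtracted, and the adjusted scores are averaged. The exact
normalization used by the source method is not published, so we chose a
median-offset adjustment over a regression-weight scheme: it is simple,
robust to outliers, seed-stable, and its behaviour is directly testable
by planting a stratum offset and measuring how much survives
summarization. The strategy is recorded in the output table.

## MOA class enrichment

Drugs are ranked by sRGES in *descending* order, so the strongest
predicted reversers sit at the bottom. The same unweighted KS statistic
applied to a class's member positions is then negative when members
concentrate at the reversal end; no extra sign flip is needed under this
ranking convention. The enrichment score is descriptive; the
significance gate is a one-tailed Welch $t$-test of member versus
non-member sRGES (alternative: member mean lower). Welch rather than
pooled variance because class sizes are typically small and unequal.
Classes below `min_size` (default 3) or without a complement are
reported untested with a reason; degenerate variance falls back to
$p = 1$. A Benjamini-Hochberg column across tested classes is provided
as a convenience, but selection follows the raw one-tailed $p$ with the
sign constraint, mirroring the published selection rule: a class is a
candidate only if $es < 0$ and $p \le 0.05$ against *both* disease
signatures.

The source method invokes gene-set variation analysis at drug-class
level without parameters; whether it ran per-profile or on the
drug-level ranking is ambiguous. We implement the drug-level reading —
one enrichment score per class against a single sRGES ranking is the
only reading consistent with the stated output — and use the KS
statistic as the enrichment score, with the $t$-test (which *is*
specified) as the inferential gate.

## Reversal genes

A signature gene is *reversed* by a profile when its drug fold-change
strictly opposes its disease direction (a fold-change of exactly zero is
not a reversal). Two selection rules coexist deliberately:

* **class-level**: genes reversed in *more than* 60% of a class's
  profiles (strict, "more than 60%");
* **sensitivity analysis**: genes reversed in *at least* 60% of the
  pooled sensitive-class profiles (inclusive, "at least 60%"), combined
  with a rank test.

The sensitivity analysis compares, per gene, the within-profile
expression ranks (normalized to $[0,1]$; rank 1 = most up-regulated)
between profiles of phenotype-sensitive and insensitive drug classes.
For a disease-up gene the one-sided alternative is that sensitive
profiles push it toward the down-regulated end; for a disease-down gene,
the opposite. Normalized ranks are the default statistic because they
are comparable across profiles with different gene universes; raw
fold-change is available as an option. P-values come from the
Mann-Whitney-Wilcoxon test — exact for tie-free groups of at most 8,
normal approximation with tie and continuity correction above — and are
BH-adjusted over all tested signature genes. Selection requires
FDR ≤ 0.25 and the inclusive reversal fraction. Classes suspected of
indiscriminate over-reversal (e.g., BET inhibitors in the motivating
study) can be excluded from the comparison via configuration.

## Phenotype layer

Plate signals are normalized per plate against DMSO and empty wells,
$(s - \bar s_{empty}) / (\bar s_{DMSO} - \bar s_{empty})$, which is
invariant to per-plate affine drift. Dose-response curves use the
four-parameter logistic
$v = bottom + (top - bottom)/(1 + (d/IC_{50})^{hill})$, fitted by
box-bounded Levenberg-Marquardt on log-dose with a multi-start grid
(five log-spaced IC50 starts across the tested range × Hill slopes
0.5/1/2/4) to avoid local minima. A flat response (per-dose mean range
< 0.1) or a non-inhibitory fit (bottom > top) yields an honest
non-converged result; an IC50 outside 0.1×–10× the tested range is
flagged as extrapolated.

Per-drug response is the two-tier rule: the mutant/wild-type IC50 ratio
when both fits converge, otherwise the mean of per-concentration
viability ratios (ratio per concentration, then mean — matching the
paired plate design). Drugs are then placed in concordance classes:
**I** responsive by phenotype and by predicted reversal
(`response_fc <= sens_fc_max`, `srges < 0`), **II** responsive by
phenotype only, **III** non-responsive by both, neutral otherwise. The
published class boundaries are drawn graphically, so the numeric default
`sens_fc_max = 0.67` (≈1.5-fold sensitization) is an explicit
configuration choice, reported in the output, not a literature value.
Screen response patterns can also be clustered (correlation distance,
average linkage, cut at $k = 3$) to reproduce the usual
screen-archetype view.

## What the synthetic data does and does not emulate

The generator plants: a disease signature with exact pass counts under
both threshold modes; an identity-with-case-change homolog map (so the
mapping stage is exercised); drug classes with a planted reverser class
(sign-forced fold-changes on a `reversal_strength` fraction of signature
genes), optionally a disease-mimicking class; sensitivity-discriminating
genes reversed only by the phenotype-sensitive classes; and a plate
screen with 4-fold IC50 sensitization of sensitive drugs in the mutant
genotype, at concentrations 0.05/0.2/1/2/5 µM.

Defaults (1000 genes, 100+100 signature, 60 drugs in six 10-member
classes, 3 conditions/drug, `reversal_strength = 0.8`,
`noise_sd = 0.3`, effect size 1 in log2 units) were chosen once as a
desk-scale caricature of the motivating study's conditions and are the
conditions under which the test suite measures recovery, type-I control
and determinism. The test suite runs planted-class recovery over 20
seeds, type-I control over 50 seeds, reversal-gene recovery over 20
seeds at a 500-gene universe, and dose-response recovery over 50 noise
replicates; these sizes are the package's chosen validation conditions.

The generator does *not* emulate: landmark-gene inference or any other
aspect of how L1000 level-5 signatures are produced; correlated gene
modules (null fold-changes are i.i.d.); cell-line-specific biology
(conditions differ only by label and planted offsets); plate spatial
artifacts (edge effects, gradients); or read-level sequencing noise in
the DE tables. Passing tests therefore demonstrate that the *methods*
recover planted structure at realistic effect sizes — not that real
L1000 data will behave as cleanly.

## Known limitations

* The sRGES condition adjustment assumes stratum offsets are additive
  and shared across drugs; dose-response-shaped interactions are not
  modelled.
* The enrichment $t$-test treats drugs as exchangeable units; correlated
  drugs within a class (e.g., near-duplicate compounds) would inflate
  significance.
* The weighted (p ≠ 0) KS variants and live database queries are out of
  scope by design.

## A minimal run

```{r example, eval = FALSE}
config <- synthetic_config(seed = 1)
sim <- run_simulate(config, "data")
pred <- run_predict("data", "predict")
pred$candidates
corr <- run_correlate("data", "predict", "correlate")
corr$correlation
```
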