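---
title: "Methods: normalization, dual-test differential expression, and the top-scoring pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, dual-test differential expression, and the top-scoring pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaTSP)
```

## The problem

NanoString nCounter panels count individual barcoded transcripts, lane
by lane, with no amplification at the detection step. On small custom
panels applied to microdissected tumor-adjacent stroma, the practical
reality is low counts, heavy dropout, and lane-to-lane scale variation
from differences in input material. This package implements a complete
two-group analysis for that setting: count QC, normalization with
auditable exclusions, per-gene differential expression, and a
top-scoring-pair (TSP) ordering classifier whose statistic never sees a
normalization factor at all. The two analysis paths — normalized
univariate testing and rank-based TSP — are deliberately independent
downstream of ingestion, so a conclusion reachable by both is robust to
the processing choices either one makes.

## Lane quality control

A lane passes QC iff its binding density (barcode spots per µm² on the
imaging surface) lies in `bd_range` (default 0.05–2.25, the platform's
recommended interval, inclusive) and its ratio of fields of view counted
to attempted is at least `min_fov_ratio`. The FOV criterion is sometimes
quoted as a literal fraction "75/280"; we default to the conventional
ratio test at 0.75 but the literal reading is available as
`min_fov_ratio = 75/280`. Lanes with missing metadata are flagged
*unevaluable* rather than silently passed.

## Normalization model

Three multiplicative corrections are applied in a fixed order, each
with an acceptance gate:

1. **Positive-control factors.** Lane $l$ is summarized by the
   geometric mean $g_l$ of its six spiked positive controls; the factor
   is $G/g_l$ with $G$ the grand geometric mean over all lanes.
   Accepted range: 0.3–3 (inclusive). By construction the geometric
   mean of the factors is exactly 1.
2. **Background.** The arithmetic mean of the lane's eight negative
   controls is subtracted from every endogenous and housekeeping count
   and the result floored at zero. A zero after correction means the
   probe failed to register above background; it enters the missing
   mask rather than being treated as a measured zero. Subtraction (not
   thresholding) is the deliberate, less conservative choice: it keeps
   low-expression distributions statistically usable.
3. **Content factors.** Each lane is summarized by the geometric mean
   of its own `top_n` (default 75) highest background-corrected gene
   values; the factor is again grand-geomean over lane value. Accepted
   range: 0.1–10; out-of-range lanes are removed before any
   missingness filtering. The pool is endogenous plus housekeeping
   probes only — spike-ins never enter. Housekeeping genes are not used
   as a normalization basis by default: on panels like this one their
   reproducibility across lanes is typically too poor to anchor on.

Afterwards, entities with strictly more than `missing_threshold`
(default 0.5) missing values are excluded — samples then genes on the
univariate path, genes then samples on the TSP path — with the second
pass computed on the matrix left by the first. Every removed lane and
gene is recorded in an exclusion ledger with its stage and reason, and
the ledger plus survivors always account exactly for the input.

**A sharp property worth knowing.** Because both factor families divide
by a grand geometric mean, multiplying one lane's raw counts (all
probes) by a constant $c$ multiplies *every* lane's fully normalized
values by exactly $c^{1/L}$ ($L$ = lane count): each grand geometric
mean absorbs $c^{1/L}$. Relative expression — any between-lane
comparison, every downstream test statistic — is therefore exactly
invariant, while the absolute scale drifts by a vanishing global
constant. The test suite asserts this exact form at tolerance 1e-10; an
assertion of literal per-value invariance would be algebraically
incompatible with the geomean-of-factors-equals-1 identity.

## Univariate differential expression

Per gene, on pairwise-complete (unmasked) values with at least two per
group:

- **Mann–Whitney U**, two-sided; exact enumeration when the pooled
  sample size is ≤ 12 and tie-free, otherwise the normal approximation
  with tie and continuity corrections. The rank basis makes it
  invariant under monotone transforms of the pooled data.
- **Welch t**, two-sided, with Welch–Satterthwaite degrees of freedom —
  chosen over the pooled test because group variances on this kind of
  data are manifestly unequal. Degenerate (constant) inputs fall back
  to a limit convention (p = 1 for equal means, else 0) with a message.
- **Dual-test call**: a gene is declared differentially expressed at
  `alpha` only if *both* tests reject — with ~30 samples, requiring
  both the medians and the means to separate is a cheap insurance
  against distributional accidents. Dual calls are by construction a
  subset of either single test's calls.
- **q values** by Benjamini–Hochberg step-up, computed across genes
  from the MWU p values (the primary, distribution-free test); a
  Welch-based q is reported alongside but never drives calls.
- **ROC AUC** via the identity $A = U/(n_1 n_2)$ with ties counted ½,
  folded to $\max(A, 1-A)$ so the table is orientation-free; the
  direction of regulation is carried by the sign of
  $\log_2(\overline{\mathrm{GP4}}/\overline{\mathrm{GP3}})$, computed
  on linear-scale group means.

## The top-scoring pair

For a sample $s$ and genes $(i, j)$, the indicator is
$I_s = [x_i(s) > x_j(s)]$ — strict, so a within-sample tie counts
against the ordering (ties at zero are common after background
correction, and crediting them would manufacture signal). The pair
score is

$$\Delta_{ij} = \bigl|\hat P(I \mid \mathrm{GP3}) -
\hat P(I \mid \mathrm{GP4})\bigr| \in [0, 1],$$

maximized over all unordered pairs. Ties on $\Delta$ break on the
secondary rank score (the between-class difference in mean
within-sample rank gap of the two genes), then lexicographically, so
the search is fully deterministic. Classification applies the ordering:
a sample with $x_i > x_j$ votes the orientation class, a tie votes the
training majority (and is logged).

Since only within-sample orderings enter, any strictly increasing
per-sample transform leaves every indicator, score, search result, and
classification unchanged. That is the reason this path runs on raw,
background-corrected counts: content normalization could only change
the answer through its own artifacts, never improve it.

**Permutation significance.** Labels are reassigned uniformly at random
preserving group sizes. The honest null for a *searched* pair
re-maximizes over all pairs on every permutation (`mode = "search"`,
the default); rescoring only a fixed pair is available behind
`mode = "fixed_pair"`, and for a single fixed pair the two-sided tail
is also computed *exactly*: under permutation the count $a$ of
indicator-positive samples assigned to GP3 is hypergeometric, the score
is a function of $a$ alone, and the tail is a finite sum
(`tsp_exact_pair_p()`). On the reconstructed 13-vs-18 worked-example
geometry this exact tail is 0.00398, and the Monte-Carlo estimate at
100,000 permutations lands within sampling error of it. The
uncorrected $k/n$ tail estimate is reported, with the $(k+1)/(n+1)$
corrected value (never zero) always beside it.

## The synthetic cohort generator

Ground-truth cohorts drive every test. Endogenous and housekeeping
counts are negative-binomial with mean
$\mathrm{lane\ factor} \times 2^{\mathrm{baseline} + \mathrm{effect}}$
and variance $\mu + \phi\mu^2$ (Poisson at $\phi = 0$), then
zero-inflated at `dropout_prob`; negative controls are Poisson at
`background_lambda`; positive controls are Poisson with mean
proportional to concentration × lane factor — spike-in hybridization is
technical counting noise, and biological overdispersion belongs to the
endogenous probes only (a negative-binomial ladder would also,
unrealistically, read zero at the 0.128 fM probe often enough to break
the geometric mean). The positive ladder descends 128, 32, 8, 2, 0.5,
0.128 fM — 4-fold steps with a final ~3.9-fold step to land on the
printed endpoints. Planted log2 effects and a planted ordering pair
(with per-group ordering probabilities, imposed by within-sample
swaps) are recorded in a truth object sufficient to score recovery.

Defaults describe the cohort geometry the pipeline is designed around:
20 + 21 lanes pre-exclusion, 102 + 5 gene probes, lane-factor sdlog
0.35 (factors mostly within 2-fold), dispersion 0.5, background mean 5
counts, dropout 0.15 — enough zero-inflation to exercise the >50 %
filters without gutting the cohort. Baselines default to
Uniform(3, 9) on log2, spanning near-background to clearly quantifiable
expression. The distributional form is an assumption — the platform's
count law on amplified FFPE material is not known — so tests lean on
rank- and calibration-level properties rather than parametric detail.

What the generator does **not** emulate: probe cross-hybridization,
lane position effects, FFPE fragmentation chemistry, or correlated gene
modules. Passing tests therefore demonstrate algorithmic correctness
and statistical calibration under a plausible count model, not
robustness to every failure mode of real instrument data.

## Numerical and design choices

- Strict inequalities for the missingness thresholds (">50 %");
  inclusive endpoints for the factor acceptance ranges.
- The deterministic two-gene fixture (`construct_tsp_fixture`) encodes
  ordering counts exactly, with all values positive and tie-free; the
  (13, 18, 10, 4) geometry is the unique split of 24/31 correct
  classifications whose score rounds to 0.547, verified by enumeration
  in the test suite.
- Parameter-recovery experiments plant a FOXO1-sized effect
  (|log2 FC| = 4.6, 15 vs 18 samples) on a gene at the top baseline so
  the repressed group stays above background — with a low baseline the
  effect is censored by the detection limit, which is a property of the
  platform, not of the estimator.
- Problem sizes in the test suite (30-gene search oracles at 50 seeds,
  1,000 null genes for calibration, 100 recovery replicates, 20,000 to
  100,000 permutation draws) are chosen so the whole suite runs in well
  under a minute of compute per property while keeping binomial
  sampling error far below the asserted margins.
- All randomness flows from explicit integer seeds; identical
  configuration and seed reproduce artifacts byte for byte, and the run
  manifest (config hash, seed, version) suffices to reproduce any
  output.

## Known limitations

- The MWU normal approximation is slightly conservative at these group
  sizes; calibration tests band the rejection rate rather than pin it.
- With very strong repression, background masking removes the repressed
  group's values and the pairwise-complete convention can leave a
  truly regulated gene undertested — visible in the `n_used` columns.
- The TSP search is $O(G^2)$ per permutation in `"search"` mode; at
  panel scale (~100 genes) 100,000 permutations are routine, but the
  cost grows quadratically with panel size.
- No housekeeping-based normalization mode is offered beyond the off-
  by-default basis switch; no batch correction across cohorts.
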