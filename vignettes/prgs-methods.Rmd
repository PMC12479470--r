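---
title: "Pathway-responsive gene sets: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-responsive gene sets: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Pathway-membership gene sets (the curated lists in resources such as KEGG)
describe a pathway's structural components: receptors, kinases, transcription
factors. They say little about which genes *respond* when the pathway's
activity changes. A pathway-responsive gene set (PRGS) takes the opposite
view: it is built from compendia of perturbation experiments — each experiment
activates or inhibits one pathway and records a per-gene z-value of expression
change — and collects the genes that respond consistently across experiments.
`prgskit` builds such signatures, splits drug-response cohorts of cell lines
into sensitive and resistant groups from AUC chemosensitivity values, and asks
which pathways' response programs separate the two groups, using three
enrichment statistics with different input types and different nulls.

# Signature construction

For one pathway with experiments $e = 1,\dots,E$, each providing raw z-values
$z^{(e)}_g$:

1. **Duplicate collapse.** Probe-level duplicates of a gene within one
   experiment are resolved to the record with maximal $|z|$ (exact ties: first
   occurrence). Collapsing precedes filtering so the median is taken over one
   record per gene.
2. **Median filter.** Records with $|z^{(e)}_g|$ below the experiment-wide
   median of $|z^{(e)}|$ are dropped. The compendia carry only z-values, so
   magnitude is the available proxy for expression strength; filtering on the
   raw signed z is available as a sensitivity option (`median_on = "z"`).
3. **Sign adjustment.** $z \mapsto z \cdot s_e$ with $s_e = +1$ for activation
   and $-1$ for inhibition experiments, so "induced by pathway activity" is
   always positive. Adjustment precedes the (symmetric) Gaussian transform so
   direction survives it.
4. **Gaussian transform.** Within each experiment, a rank-based
   inverse-normal transform: the value of rank $i$ (average ranks on ties)
   maps to $\Phi^{-1}\!\big((i - 0.5)/n\big)$. This forces a common,
   essentially standard-normal scale on experiments whose raw distributions
   are heavy-tailed and mutually incomparable; the offset 0.5 is configurable.
5. **Aggregation.** The gene's z-score is the arithmetic mean of its
   transformed values over the experiments containing it; genes seen in fewer
   than `min_datasets = 2` experiments are dropped.

The **continuous** view is the full z-score mapping. The **discrete** view
keeps genes with $|z\text{-score}| > 2.58$ (strict), the two-sided
standard-normal critical value at $p = 0.01$ rounded to two decimals.

## A capacity limit worth knowing about

The inverse-normal transform caps each experiment's values at
$\Phi^{-1}(1 - 0.5/n)$ — about 3.3 for a thousand retained records — and only
the most extreme $\sim 0.5\%$ of records in an experiment can exceed 2.58 at
all. Since the aggregate z-score is a *mean* of such values, a gene can clear
the 2.58 threshold only by sitting in the top half-percent of nearly every
experiment. When the truly responsive fraction of a dataset is larger than
that tail capacity (e.g. 50 planted genes among 2,000, i.e. 2.5%), most
genuinely responsive genes *cannot* reach the discrete threshold, whatever
the effect size: the block of responsive genes shares the top ranks, and the
average transformed value of a 25-gene block in a 1,000-record list is
$\mathbb{E}[Z \mid Z > \Phi^{-1}(1-f)] \approx 2.3 < 2.58$. The package's
planted-truth tests measure exactly this: discrete-signature *precision* is
essentially 1 (what passes the threshold is real), while *recall* is a few
percent. Discrete PRGS should therefore be read as a high-confidence core,
not an inventory of the responsive program; analyses that need sensitivity
should use the continuous view (as the Bates test does), or lower the
threshold deliberately.

# Cohort splitting and differential expression

Sensitive lines are those with AUC $< 0.8$, resistant $\ge 0.8$; the split
takes the 8 lowest-AUC sensitive lines and up to 12 highest-AUC resistant
lines (at least 8), AUC ties broken lexicographically by cell-line id so the
result is order-stable. Drugs in which more than 90% (strict) of profiled
lines fall on one side of the boundary are excluded — with at least 10
profiled lines required for the fraction to be meaningful.

Differential expression is a per-gene two-sample t-test oriented **resistant
minus sensitive**, so "up" means higher in resistant lines. The
pooled-variance Student test is the default (Welch behind `var_equal =
FALSE`); genes with zero pooled variance get $t = 0,\ p = 1$. DEGs are
selected at raw $p < 0.01$ (strict), optionally with an additional strict
$|t| > 2.8$ magnitude filter; no multiple-testing correction is applied by
design, since the downstream enrichment statistics consume the DEG set as a
whole rather than interpreting per-gene significance.

# The three enrichment statistics

**GSEA-like running sum** (discrete PRGS + the full t-ranked list). Walking
the list ranked by descending t (ties lexicographic), set members add
$|t|^{p}/N_R$ and non-members add $1/(N - N_H)$ to separate cumulatives; the
enrichment score is the signed running difference at its maximum absolute
deviation ($p = 1$ by default). Significance uses random gene sets of the
same size drawn from the ranked list, with add-one smoothing:
$p = (1 + \#\{|ES^\ast| \ge |ES|\})/(1 + n_{perm})$. A phenotype-permutation
null is impossible with these inputs (the method sees only the ranked list),
so set permutation is the null of record; it is deterministic under a seed,
and the permutation scorer uses a closed form over hit positions that the
test suite checks against the full profile. Signatures containing both up-
and down-responsive genes place hits at both ends of the list, which
partially cancels the running sum; this dilution is intrinsic to
single-running-sum scores over signed signatures.

**Hypergeometric over-representation** (DEGs + discrete PRGS). The upper-tail
probability $P(X \ge k)$ of the observed overlap under random draws from the
expression universe. Being discrete, its p-value is conservative — in the
typical regime (tens of DEGs against a discrete signature of a handful of
genes) the overlap is 0 or 1 and the p-value mass sits at 1. Calibration is
therefore verified on the randomized PIT $P(X > k) + U\,P(X = k)$, which is
uniform exactly when the null law is correct; reported p-values remain the
conservative $P(X \ge k)$.

**Bates rank test** (continuous PRGS + DEGs). The signature's z-scores pass
through a sorting–rescaling cascade: an infinitesimal push away from zero,
the fold $r' = -1 - r$ (for $r \le 0$) or $1 - r$ (for $r > 0$), ascending
unique ranks of $r'$ (ties by gene id), and an affine rescale of the ranks to
an equally spaced grid spanning exactly $[-1, 1]$ with mean zero. The fold
places the most extreme $|z|$ mid-scale and near-zero genes at the endpoints;
the cascade is implemented exactly as defined, without second-guessing its
geometry. The statistic is the mean $R(G)$ of the overlapping genes' grid
values; its null is the Bates distribution (mean of $n$ i.i.d. uniforms on
$[-1,1]$), evaluated through the Irwin–Hall closed form. The p-value is
$\mathrm{batesCDF}(R, n)$ for $R$ at or below the midpoint and
$1 - \mathrm{batesCDF}(-R, n)$ above it — the reflection about the midpoint,
and the only reading of the rule that yields a valid tail probability; a
two-sided doubling is available but off by default. Sampling overlaps without
replacement from the finite grid deflates the variance by $(N-n)/(N-1)$
relative to the i.i.d. null, negligible at the sizes involved.

Numerical notes on the Bates CDF: the alternating Irwin–Hall sum is evaluated
only on the lower half $s \le n/2$ (few terms, tolerable cancellation) with
the symmetry $F(s) = 1 - F(n-s)$ covering the upper half; beyond $n = 50$ the
normal approximation (midpoint mean, variance $\mathrm{range}^2/12n$) takes
over, the two branches agreeing to about $3 \times 10^{-4}$ at the switch.

The LOESS-scaled z computation (`loess_z`) that produces differential
expression z-values from fold changes divides each log fold change by a LOESS
fit of $|{\log FC}|$ against mean expression (span 0.5, degree 2, both
configurable; fitted values floored at $10^{-8}$), making z invariant to an
overall rescaling of the fold changes.

# The synthetic-data generator

The generator emulates the statistical structure of a perturbation compendium
and a drug-response cohort, not their biology. Defaults are the study
conditions used throughout the tests: 5 pathways, 5 experiments per pathway,
2,000 genes, 50 responsive genes per pathway with effect $|z| = 4$ against
unit-variance Gaussian background, half the experiments inhibition-type
(sign-flipped, so the adjustment step must undo them); cohorts have 16 cell
lines (8 sensitive, AUC uniform on $[0.4, 0.8)$; 8 resistant, uniform on
$[0.8, 1]$) and a mean shift of 2 expression SD added, direction-matched, to
the dysregulated pathway's responsive genes in resistant lines. Effect sizes
were chosen so that recovery at these desk scales is limited by the
statistics, not by noise. Each pathway's planted set is drawn independently,
so distinct pathways can share a few responsive genes — as real response
programs do.

What the generator does *not* emulate: gene–gene correlation (an optional
consideration, but no test depends on it), batch effects, probe-level
structure, heavy-tailed raw z distributions (the transform tests use Cauchy
draws separately), or dose–response curve shape behind the AUC summary.
Passing tests on this generator demonstrate the statistics' internal
correctness and calibration, not performance on real compendia.

Test and acceptance problem sizes — 60 null cohorts for calibration, 499–999
permutations, a batch of 10 compendia for recovery, $10^6$ Monte-Carlo draws
per Bates grid — are the package's choice of desk scale: large enough that
calibration failures are signal, small enough to run routinely.

# Degenerate inputs and tie rules

Ties are never randomized: average ranks inside the Gaussian transform,
lexicographic gene-id tie-breaks in rankings and in the Bates cascade,
first-occurrence wins in duplicate collapse, and the first extremum position
in the running sum. Degenerate cases are errors rather than silent defaults:
empty gene-set overlap, a set covering the whole ranked list, a single-column
quantile normalization, two empty sets in a Jaccard index, a signature
disjoint from the universe. A pathway whose experiments all collapse below
two genes is skipped with a warning; a pathway with no scorable genes refuses
to build.

# Known limitations

- The discrete-signature recall ceiling described above: a strict 2.58
  threshold on a mean of rank-INT values can only ever select the top
  half-percent tail, so recall of a denser responsive program is structurally
  low. This is a property of the construction, reported honestly by the
  recovery tests, not a tuning artifact.
- The GSEA-like permutation null is over random gene sets, not phenotype
  relabellings; the two answer slightly different questions, and the former
  is the only one computable from the method's inputs.
- The hypergeometric branch is conservative at small overlaps (discreteness).
- The Bates cascade's geometry (extreme genes mid-scale) is preserved as
  defined; consumers should not interpret $R(G)$ as a directional effect
  size.
- No identifier harmonization: gene ids are opaque case-sensitive strings,
  and expression, AUC, and compendium inputs must already share a namespace.
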