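---
title: "Methods: simulating and analysing year-round root/soil AMF communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing year-round root/soil AMF communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfdyn)
```

## The study template

The pipeline targets a paired-compartment, year-round survey of arbuscular
mycorrhizal fungi (AMF): at each of two forest sites, the same five host
trees are sampled every two months, and each sampling yields one root and
one soil sample per tree. One site is sampled in all six bimonthly months
(May through the following March — note the year-round axis crosses the
calendar-year boundary, so `amf_months()` orders months by the sampling
calendar, not the calendar year); the other site retains three months
(May, November, March), for 90 samples in total. Soil chemistry (pH, total
carbon and nitrogen in percent, their ratio, and total phosphorus in
mg kg⁻¹) is measured once per tree and month on the soil surrounding the
sampled roots, so a root sample shares its pair's chemistry record.

Everything downstream consumes three tables: an integer OTU count matrix
(samples × OTUs), the design metadata, and the chemistry table, plus an
optional BLAST-style hit table for taxonomy labels.

## The community simulator

The simulator exists so that every stage of the analysis can be exercised
against known ground truth. It is a first-class, tested component, not a
test fixture.

**Count model.** Counts for sample $s$ are Dirichlet-multinomial:
$$ c_s \sim \mathrm{Multinomial}(N_s,\ \pi_s), \qquad
   \pi_s \sim \mathrm{Dirichlet}(\theta\, p_s), $$
with depth $N_s$ drawn uniformly from the observed per-sample range
(3,537–16,435 reads by default) and concentration $\theta$
(`overdispersion`, default 500). The paper-style survey reports no count
model, so we chose the Dirichlet-multinomial because it reproduces the
overdispersion amplicon replicates show; at $\theta = 500$ and a depth of
$10^4$ the variance of a proportion is inflated roughly twentyfold over
the multinomial, a moderate-noise regime for biological replicates of the
same stand. `overdispersion = Inf` recovers plain multinomial sampling.
The survey also does not report between-tree compositional variance, so
$\theta$ is an explicit free parameter rather than a calibrated one.

**Expected proportions.** The baseline community has 24 designated
dominant OTUs whose mean proportions default to the yearlong averages of a
real survey of this design (led by 0.184 and 0.177, summing to 0.84) and a
power-law tail of 676 rare OTUs carrying the remaining mass
($p_i \propto i^{-1/2}$, so the largest tail OTU sits near 0.3%, safely
below the 1% dominance bar). Sample-level expected proportions start from
the log baseline and add:

* a root-compartment log-fold offset (`compartment_effect`, default 0.7)
  on a designated root-preferential subset (by default the second-ranked
  dominant OTU plus 59 tail OTUs) — this is the effect the compartment
  PERMANOVA should recover;
* a pH response, `ph_slope` × (sample pH − site mean pH) on the log scale
  (default slope 0.8 on the four top dominant OTUs), giving the Mantel and
  RDA stages a planted linear signal;
* optional month-specific log-fold shifts (`month_effects`) used to build
  single-month contrasts for the pairwise-PERMANOVA power study;
* structural zeros: each of the 30 seasonal OTUs has designated absence
  months in which its proportion is forced to zero before renormalising.
  Zeros are structural rather than sampling-rate effects so that the
  persistence classifier has unambiguous truth.

**Randomness and reproducibility.** All draws derive from a single master
seed through fixed sub-streams keyed by sample index (counts), by
site/month/tree (chemistry) and by purpose offsets (hit tables), so a
dataset is bit-reproducible from its configuration and partial
regeneration does not shift unrelated draws. Chemistry values are normal
draws truncated to positive values; a non-positive configured mean is
rejected rather than truncated.

**Ground truth.** Truth labels are computed from the *expected*
proportions using exactly the aggregation the classifier applies to
observed data (group means → site means). Because the configured dominant
means include values of 0.9–1.2% — within one standard error of the 1%
threshold at the configured depths and replication — the truth table also
records guard-banded labels: `dominant_clear` (expected site means ≥ 1.5%)
and `nondominant_clear` (≤ 0.8%). Recovery tests assert perfect agreement
on the decisively separated OTUs; for borderline OTUs the classification
is a coin flip *by construction of the study design*, which is a property
of the design, not a defect of the classifier, and is deliberately left
untested.

**What the simulator does not emulate.** Read-level artefacts (chimeras,
quality filtering, clustering), phylogenetic correlation among OTUs,
spatial structure among trees, temporal autocorrelation of chemistry
beyond the monthly means, and OTUs rare enough to trip the 10-read filter
(the default community emulates the *retained* table; steeper tails
exercise the filter). Passing tests therefore demonstrate correctness of
the statistical machinery under a plausible generative model, not that the
model captures every feature of real amplicon data.

## Classification rules

* **Rarity filter.** An OTU is discarded when its total count is below 10
  *or* it is detected (count > 0) in fewer than 2 samples. Both criteria
  are evaluated on the input table as one conjunction; the removal report
  lists each OTU's totals, prevalence and reason. An OTU with exactly 10
  reads in exactly 2 samples survives.
* **Taxonomy.** Hits qualify when identity and cover are both ≥ 95
  (inclusive — the operational form of the rule; assignments at exactly
  95.0 qualify). The best hit is the lexicographic maximum by (identity,
  cover, subject id), making the rule deterministic under row
  permutations. No qualifying hit → `unclassified`; all qualifying hits
  titled "uncultured Glomeromycotina" → `uncultured`; otherwise the genus
  is the first word of the best qualifying named hit.
* **Dominance.** Group profiles are unweighted means of per-sample
  compositions within site × month × compartment. Site means are
  unweighted means over the site's profiles (equivalent to sample means
  under a balanced design), and an OTU is dominant when every site mean is
  ≥ 1%. Raising the threshold can only shrink the dominant set.
* **Persistence.** Within a site × compartment, detection in a month means
  a positive count in at least one sample; persistent = detected every
  sampled month, seasonal = detected in some but not all, absent = never.
  Sites are classified separately by default because they sample different
  month sets; `pooled = TRUE` merges sites per compartment for a single
  label per OTU, the aggregated view used in survey summary tables.
* **Co-dominance.** The Kikvidze–Ohsawa number is the $k$ minimising
  $D(k) = \sum_{i\le k}(x_i - m_k)^2 + \sum_{i>k} x_i^2$ over the
  descending abundance vector, with $m_k = 1/k$ (equal share of the whole
  community) by default. The citing literature leaves the ideal model
  ambiguous, so `ideal = "topk"` ($m_k = \sum_{i \le k} x_i / k$, equal
  share of the top-k mass) is provided as an explicit alternative rather
  than silently choosing one; the full deviation curve is returned either
  way. Ties go to the smallest $k$, and $D(k) = 0$ occurs exactly for $k$
  equal shares summing to one.

## Statistical conventions

* **Permutations.** All permutation tests default to 999 unrestricted row
  permutations with the observed ordering included:
  $p = (1 + \#\{T^* \ge T\})/(1 + n_\mathrm{perm})$, so p has resolution
  $1/(n_\mathrm{perm}+1)$ and is never zero. For $n \le 8$ an exhaustive
  mode enumerates all $n!$ permutations and reports the exact proportion
  (identity included, no +1). A `strata` argument restricts shuffles to
  within-block (e.g. trees) for sensitivity analyses; the default is
  unrestricted because the survey design declares no blocking for these
  tests.
* **PERMANOVA.** Sum-of-squares partitioning follows the Gower-centred
  inner-product matrix $G = -\tfrac12 C D^{(2)} C$; term sums of squares
  are sequential (Type I) differences of $\mathrm{tr}(H_j G)$ along the
  cumulative design, matching the convention of the standard ecology
  toolkit, and permutation relabels whole samples. Note that duplicating
  every sample leaves $R^2$ invariant but scales pseudo-F by the changed
  residual degrees of freedom — F is not sample-size-free.
* **Pairwise PERMANOVA** runs the one-factor test on each level pair and
  adjusts p-values by Bonferroni (the pairwise tool's convention;
  Benjamini–Hochberg and `"none"` selectable). Raw and adjusted values are
  both reported.
* **Mantel.** Spearman rank correlation over lower triangles; one matrix's
  rows/columns are permuted jointly. Ranks are computed once and permuted
  as a matrix, which is exact because joint row/column permutation leaves
  the off-diagonal multiset unchanged.
* **RDA.** Community relative abundances are column-centred; environment
  columns are z-scored; constrained axes come from the SVD of the fitted
  values of the multivariate regression, and axis variances are reported
  as proportions of the *total* community variance so constrained plus
  unconstrained proportions sum to one (within 1e-9). The model pseudo-F
  is tested by permuting rows of the centred community matrix — the
  residuals of the intercept-only reduced model. The per-OTU table uses
  direct Spearman correlations of each OTU against each environment
  variable with two-sided permutation p (the survey literature is silent
  on whether axis scores or direct correlations were used, and on multiple
  testing; direct correlation with optional BH adjustment is implemented
  and the choice documented here), flagging |r| ≥ 0.5.
* **ANOVA battery.** Shannon uses natural logs (the ecology toolkit's
  default). Levene's test centres on the group mean (the classical form;
  `center = "median"` gives Brown–Forsythe). Tukey HSD p-values come from
  the studentized-range distribution; at $k=2$ they equal the
  pooled-variance two-sample test exactly, which the tests verify
  numerically. Letters are produced by the insert-and-absorb algorithm, so
  levels sharing a letter are not significantly different at the stated
  confidence. Precheck failures (non-normality, heteroscedasticity) are
  reported and flagged but do not block the ANOVA — the survey convention
  is to precheck and proceed, and no fallback is specified, so the
  pipeline surfaces the flag instead of silently switching tests.
* **NMDS.** Global non-metric MDS minimising Kruskal stress-1 with
  monotone regression (weak tie treatment), best of 20 starts: one
  explicit metric-scaling start (rounded to 9 decimals so the descent is
  bit-stable across linear-algebra backends) plus seeded random
  configurations. Stress is therefore non-increasing in the number of
  restarts under a fixed seed. At least $k+2$ points are required for a
  $k$-dimensional embedding.

## Numerical choices and degenerate inputs

Comparisons of permuted statistics against observed ones use an absolute
epsilon of 1e-12 so that exact ties (e.g. under full enumeration of a
symmetric configuration) count as exceedances. Degenerate inputs fail
fast with named errors: zero-sum samples, duplicate identifiers,
non-integer or negative counts (located by row and column), unknown
compartment or month levels, zero-variance columns before z-scoring,
collinear environment matrices (QR rank check), constant vectors in
Shapiro–Wilk or Mantel, and zero residual variance in Tukey HSD. C/N is
derived as TC/TN and validated against any supplied C/N column to 1e-9.

## Problem sizes in the test-suite power studies

The suite's calibration and recovery studies run at deliberately compact
sizes: type-I calibration uses 500 replicates of a 12-sample null design
(no compartment effect, no pH response) with 199 permutations, where the
nominal 5% level is exact by exchangeability; compartment recovery uses
100 replicates of the full 90-sample default design; and the single-month
contrast uses 100 replicates of a three-month, one-site design with a
planted May shift (log-fold 1.5 on eight mid-ranked dominants) and the pH
response disabled — with it enabled, July and September genuinely differ
through their pH means and the "only May differs" premise would be false.
These sizes keep each study well separated from its acceptance bound
while completing in seconds to a couple of minutes.

## Known limitations

* Dominance truth near the 1% threshold is irreducibly noisy at realistic
  depths (see the guard bands above); analyses of real surveys should
  treat borderline dominance calls with the same caution.
* The per-OTU environment-correlation table is a screening device; its
  permutation p-values are marginal and, unless BH adjustment is
  requested, unadjusted.
* PERMANOVA assumes exchangeability under the null; with strong
  depth-driven heteroscedasticity between groups, pseudo-F conflates
  location and dispersion effects, as it does in any adonis-style
  analysis.
* The simulator draws chemistry independently across months and trees;
  real soil variables are temporally autocorrelated, so Mantel/RDA power
  estimates from simulation are likely optimistic.
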