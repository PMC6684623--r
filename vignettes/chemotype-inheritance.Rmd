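---
title: "Methods: chemotype fractions, KDE demarcation and segregation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemotype fractions, KDE demarcation and segregation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkylseg)
```

## The problem

Cannabis plants vary in two largely independent chemical axes of their
cannabinoid profile: the alkyl side-chain length of the resorcinyl core
(propyl C3 versus pentyl C5) and the ring type produced by the synthase
step (dicyclic CBD-type versus tricyclic THC-type). The ring axis is
governed by the codominant synthase locus complex (here called the B
locus, with alleles for THCA synthase and CBDA synthase, assayable by a
SCAR PCR marker). The genetic control of the alkyl axis is less clear:
candidate models range from a single codominant locus through digenic
additive or dominant inheritance to epistatic two-locus gene action.

`alkylseg` implements the analysis chain used to discriminate these
models in an F2 population from a cross between chemotypes divergent on
both axes:

1. summarise each plant's cannabinoid profile as chemotype *fractions*;
2. *demarcate* the multimodal fraction distributions into ordered
   categories objectively, by kernel density estimation;
3. test the category counts against named *segregation ratios* by
   Pearson chi-squared goodness-of-fit, both overall and conditioned on
   the B-locus genotype.

Because the original per-plant measurements are not publicly deposited,
the package also contains a first-class F2 cross simulator that
generates populations with the same statistical structure, used
throughout the test suite.

## Chemotype fractions

Eight analytes enter the computation: the acids CBDVA, THCVA, CBDA,
THCA and their decarboxylated neutral forms CBDV, THCV, CBD, THC.
Neutral contents are first expressed as acid equivalents by the
molecular-weight ratio (carboxylation adds one CO2, 44.009 g/mol), so
that post-harvest decarboxylation does not shift the composition:

```{r}
analyte_pairs()
```

The correction factors all lie between 1.14 and 1.16. Acid-equivalent
contents are then pooled and expressed as percentages of the total
cannabinoid fraction:

* `F_C3` = (CBDVA + THCVA + eq(CBDV) + eq(THCV)) / total, `F_C5 = 100 - F_C3`;
* `F_dicyclic` = (CBDVA + CBDA + eq(CBDV) + eq(CBD)) / total,
  `F_tricyclic = 100 - F_dicyclic`.

Other quantifiable cannabinoids (CBG, CBGA, CBN, CBC) are accepted in
input tables but excluded from all pools. Extraction replicates are
averaged at the content level (fractions of mean contents), and
repeatability is reported as the squared correlation between the two
replicates' fraction values across the plant set.

```{r}
compute_fractions(c(THCVA = 3, THCA = 1))
```

Mid-parent values (`midparent()`), the additive expectation for a
hybrid, are plain arithmetic means of the parental fractions.

## Demarcation by kernel density estimation

Chemotype categories are not imposed by fixed thresholds: the density of
the fraction variable is estimated with a Gaussian kernel and the
distribution is cut at its antimodes.

**Bandwidth.** The Sheather–Jones solve-the-equation plug-in bandwidth
is used (`sj_bandwidth()`). Density-derivative functionals are
estimated with the standard two-stage normal-scale pilots
(`a = 1.241 * lambda * n^(-1/7)`, `b = 1.230 * lambda * n^(-1/9)`,
scale `lambda = min(sd, IQR/1.349)`), and the fixed-point equation is
solved by a bracketing root-finder on a geometric bracket expanded from
the normal-reference bandwidth `1.059 * lambda * n^(-1/5)`; if no root
is bracketed within `[h_ref/100, 100 * h_ref]` the normal-reference
value is returned with a warning. On test samples the result agrees
with `stats::bw.SJ(, method = "ste")` to three significant figures;
the in-package implementation exists so that the bracketing and
fallback behaviour is explicit, and `bw.SJ` serves as an independent
cross-check in the tests.

**Grid.** The KDE is evaluated exactly (no binning) on 512 uniform grid
points spanning the data padded by three bandwidths, clipped to
`[0, 100]`. 512 points keep antimode placement stable to well under
0.2 percentage units.

**Modes and boundaries.** Local maxima/minima are read from sign
changes of the density's first differences; plateaus collapse to their
midpoints and boundary grid points may carry maxima. Category
boundaries are the antimodes between retained peaks. Two merge rules
then apply, in order:

1. *Unresolvable antimodes*: an antimode whose depth below the smaller
   flanking peak is less than 5% of that peak's height does not support
   a defensible cut; the two peaks are merged and the antimode is
   reported in the result (`unresolved_valleys`). The 5% constant is a
   package constant, exposed as `valley_depth_frac`. This is also how
   the package behaves on a quasi-continuous axis (such as the
   intermediate/high dicyclic range): it reports the unresolvable
   antimode rather than forcing a boundary.
2. *Minimum support*: a peak interval holding fewer than `min_support`
   observations (default 2, i.e. kernels supported by a single
   observation are not considered) is merged into the neighbour whose
   shared antimode has the higher density, ties going to the larger
   neighbour.

Categories are labelled `I, II, ...` by increasing fraction value;
intervals are left-open/right-closed (the first closed at both ends) so
boundary-coincident values are assigned deterministically to the lower
category.

```{r}
set.seed(12)
vals <- unlist(lapply(c(5, 27, 50, 73, 95), function(m) rnorm(20, m, 2)))
demarcate(estimate_density(vals))
```

## Segregation models

The model registry holds the four testable gene-action hypotheses:

| model | ratio | loci | gene effect |
|---|---|---|---|
| monogenic codominant | 1:2:1 | 1 | codominant |
| digenic additive | 1:4:6:4:1 | 2 | additive |
| digenic dominant | 9:3:3:1 | 2 | dominant at both loci |
| epistatic | 7:6:3 | 2 | dominance at one pair, partial dominance at the second, recessive epistasis |

`chi_square_gof()` computes the Pearson statistic with expected counts
proportional to the ratio terms, **no continuity correction**, and
`df = k - 1`; the decision compares the statistic to the upper-tail
critical value at `alpha` (default 0.05). These conventions reproduce
the published statistics for this analysis type exactly. Expected
counts below 5 are allowed (with a warning noting the classical
guideline), since F2 tail classes are routinely small. A ratio whose
length does not match the number of observed categories raises a shape
error — categories are never aggregated silently.

`genotype_conditioned_segregation()` splits the F_C3 values by B-locus
genotype and, by default, re-derives categories *within* each genotype
subset (`mode = "per-subset"`), because genotype-specific distributions
can be quadri- or tripartite even when the pooled population is
pentapartite. Global boundaries can be reused instead
(`mode = "global"`). Genotype classes below `min_n = 8` plants are
skipped; unscored plants are excluded and counted.

`bartlett_from_summaries()` implements Bartlett's variance-homogeneity
test from per-group variances and degrees of freedom only, so that
published summary tables can be re-analysed without raw data; it agrees
with `stats::bartlett.test()` to 1e-9 when the summaries come from the
same raw values.

## The cross simulator

`simulate_f2_study()` generates a complete study: homozygous divergent
parents, an F1 family, and an F2 from a single F1 female x F1 male
cross, with meiosis simulated as a two-point recombination chain
(no crossover interference; loci on different linkage groups behave as
r = 0.5). Gene action at the two alkyl loci A1 and A2 is selectable:

* `additive` — class = C3-allele count (five classes, 1:4:6:4:1);
* `digenic_dominant` — C5 dominant at both loci, double C3 recessive is
  the F_C3 maximum (four classes, 9:3:3:1);
* `epistatic_7_6_3` — C3 dominant at A1, the A1 homozygous-recessive
  genotype epistatic to A2, partial dominance at A2 (three classes,
  7:6:3 low:mid:high).

`enumerate_f2_classes()` verifies these mappings by exact integer
enumeration of the 16 equally likely two-locus gamete combinations.

Defaults are fixed to the study conditions: 35 F1 and 210 F2 plants,
duplicate extraction replicates, unlinked loci, and class-mean anchors
at the parental extremes (F_C3 0.8 and 88.3; F_dicyclic 0.9 and 96.1,
with the heterozygote at the incomplete-dominance mid-parent 48.5).
Within-class noise is Gaussian with sd 4.5 percentage units, truncated
to `[0, 100]` by inverse-CDF sampling — the value is chosen so that a
simulated F1 family's F_C3 variance is of the same order as the
smallest published F1 family variance; it is a tunable, not a measured
constant. An optional logit-scale noise mode (`skew = TRUE`) emulates
the skew toward the low-F_C3 parent seen in real populations; it is off
by default so that Mendelian class frequencies stay exact. The SCAR
call can be decoupled from the true B genotype by a marker
recombination fraction (`marker_r`). Plant contents are synthesised so
that `compute_fractions()` recovers the generated fractions exactly,
with a configurable share of each pool in the neutral form and
multiplicative per-replicate measurement noise.

What the simulator does *not* emulate: biochemical flux interactions
between pathway loci, tandem synthase copy-number variation,
environment or ontogeny effects, and within-plant sampling structure.
Passing tests on simulated data therefore show that the statistical
machinery recovers known generative structure — not that any particular
biological model is true of real populations.

## Numerical choices and degenerate inputs

* Zero-total plants are excluded from demarcation with a logged
  warning, never silently dropped.
* `sj_bandwidth()` refuses fewer than 4 observations or zero variance
  (relative sd below 1e-10) and instructs the caller to treat the group
  as a single category; the pipeline does exactly that.
* KDE mass clipped at the `[0, 100]` bounds is not reflected or
  renormalised; for classes near a bound the trapezoidal integral can
  fall below 1 and the density spikes at the bound (see Limitations).
* Ties in the min-support merge direction go to the larger neighbour;
  all other steps are deterministic, and the whole pipeline is
  order-invariant in its inputs and reproducible from a single seed.

## Validation design and known limitations

The test suite validates the pipeline at these problem sizes: mixture
K-recovery for K = 2..5 with 20 points per component over 200 seeded
replicates; end-to-end generating-ratio recovery on 100 simulated F2
populations (n = 210) per gene-action kind; 10,000-gamete
recombination-fraction recovery; and exact reproduction of the
published chi-squared, Bartlett and critical-value figures.

For the end-to-end recovery runs the class means are placed in the
interior of the scale (e.g. 10..90) with separation at least six
within-class standard deviations. Two limitations found and
characterised during this validation are worth knowing:

1. **Boundary pile-up shrinks the SJ bandwidth.** A class mean close to
   0 or 100 with truncated noise produces a half-Gaussian spike whose
   effective width is much smaller than the nominal noise sd. The
   solve-the-equation bandwidth adapts to that spike and under-smooths
   the interior classes, which can split into spurious modes. This is a
   property of the estimator (reproduced identically by
   `stats::bw.SJ`), not of this implementation.
2. **Very small classes can split.** Categories expected to hold fewer
   than about 15 observations (for example the 1/16 tail classes of a
   210-plant F2) occasionally present as two sub-modes, one of which
   holds 2–4 observations — too many to be removed by the
   single-observation kernel rule. K-recovery is essentially perfect at
   15+ observations per component and degrades below that; analysts
   should read a demarcation with a 2–4-plant category next to a small
   tail class with this in mind.

Neither limitation affects the deterministic statistics (fractions,
goodness-of-fit, Bartlett, critical values, enumerated ratios), which
are exact.
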