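---
title: "Karyotype inference from shallow read counts: model, calibration and design"
author: "karyotypeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype inference from shallow read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotypeR)
```

## The model

A sequencing library samples reads from a genome roughly in proportion
to how much *alignable* material each chromosome contributes. If
chromosome $c$ is present in $k_c$ copies and one copy contributes an
effective mass $e_c$, the probability that a retained read lands on $c$
is approximately

$$ p_c \;=\; \frac{k_c\, e_c}{\sum_{c'} k_{c'}\, e_{c'}}. $$

karyotypeR treats the vector of per-chromosome read counts as one
multinomial draw from these probabilities and inverts that relationship.
The pivot is the **autosomal baseline**

$$ N_a \;=\; \sum_{c \in \{1..22\} \setminus \{13,18,21\}} n_c, $$

which excludes the three autosomes whose trisomies survive to birth in
appreciable numbers, so $N_a$ reflects a euploid (two-copy) denominator
in essentially every sample a cohort will contain. The ratio statistics

$$ R_x = n_X / N_a, \qquad R_y = n_Y / N_a, \qquad R_c = n_c / N_a $$

are then linear in the copy number of their numerator chromosome and
free of sequencing effort: a sample sequenced ten times deeper has the
same expected ratios with smaller errors. The expected value of $R_x$
for $k$ copies of X is the **centroid**

$$ r_X(k) = \frac{k\, e_X}{2\, \Sigma_A}, \qquad
   \Sigma_A = \sum_{c \in \mathrm{baseline}} e_c, $$

and likewise $r_Y(k)$. Centroids are equally spaced in $k$, so the
classification problem is one-dimensional nearest-centroid per axis.

### Standard errors

Conditioning on $n = n_c + N_a$, the numerator is binomial with
proportion $p = n_c / n$, and $r = p/(1-p)$. The delta method gives

$$ se(r) \;=\; \frac{\sqrt{p(1-p)/n}}{(1-p)^2}, $$

computed with a 0.5 pseudocount on both counts so that a zero numerator
(e.g. $n_Y = 0$ in a 46,XX sample) still carries finite, positive
uncertainty — the rule-of-three regime. The suite verifies this error
against the Monte-Carlo spread of the ratio over 10,000 simulated
replicates at $N_a$ of $10^3$–$10^5$ (agreement within 10%, typically
within 2–3%).

## Calibration: why effective masses are not chromosome lengths

Raw build-37 sequence lengths put two copies of X at a ratio of ~0.059
and one copy of Y at ~0.011. Observed shotgun cohorts instead centre at
0.056 and 0.0026: mapping-quality filtering (MAPQ ≥ 30) removes reads in
repetitive and ampliconic sequence, which costs the Y chromosome the
large majority of its length. Effective masses are therefore
*calibration constants*, not lengths. The shipped shotgun table keeps
autosomal masses proportional to build-37 lengths (adequate because the
autosomes are affected nearly uniformly) and fixes
$e_X = 0.056\,\Sigma_A$ and $e_Y = 0.0052\,\Sigma_A$, so the derived
centroids are exactly

```{r}
cal <- builtinCalibration("shotgun")
c(rX2 = centroid(cal, "X", 2), rX1 = centroid(cal, "X", 1),
  rY1 = centroid(cal, "Y", 1))
```

Target-enriched ("1240k"-style) libraries concentrate reads on a SNP
panel whose per-chromosome density differs from genomic proportions, so
the shotgun masses do not transfer. The shipped `"capture"` table is a
seed only; `calibrateFromCohort()` re-estimates all 24 masses from a
cohort (≥ 20 samples spanning both common karyotypes) by splitting on
$R_y$ at half the current $r_Y(1)$, taking group medians (medians, so a
few aneuploid or contaminated samples cannot drag the estimate), and
iterating the split once. Parameter-recovery tests show centroids
re-estimated within 2% from 40 simulated samples at 200k reads.

## Copy assignment and the confidence band

The copy call is the nearest centroid; it is reported as *confident*
when

$$ |R - r(\hat k)| \;\le\; \max(3\,se,\; \beta \cdot gap), \qquad
   \beta = 0.25,\; gap = r(1), $$

and *uncertain* otherwise (an exact midpoint is always uncertain). The
band is a reconstruction of threshold optimisation against empirical
cohort spread: the $\beta \cdot gap$ term accepts well-resolved values
that sit slightly off-centroid (real libraries have residual
compositional biases the calibration cannot remove), while the $3\,se$
term keeps genuinely noisy estimates callable at low coverage. $\beta$
is exposed and configurable; 0.25 reproduces every reference
classification we encode in the tests (an $R_x$ of 0.033 at deep
coverage → one X; an $R_y$ of 0.0048 → two Y; $R_y = 2.3\times10^{-5}$
→ zero Y).

The signed z-score $(R - r(\hat k))/se$ is always reported. Two derived
diagnostics use it:

- **Mosaicism.** A confident call lying ≥ 4 SE from its centroid *toward
  an adjacent copy number* is consistent with a cell mixture; the
  mixture fraction is the linear interpolation
  $(R - r(\hat k)) / (r(k_{adj}) - r(\hat k))$, clamped to $[0,1]$. At
  $R_x = 0.033$ against centroids 0.028/0.056 this yields a ~18%
  two-X fraction — the 45,X0/46,XX mosaic Turner pattern. The threshold
  of 4 leaves margin above the $|z| \le 3$ region that the confidence
  band already treats as noise.
- **Cohort z-scores.** `cohortZ()` places one sample against the
  empirical distribution of a reference group (e.g. all XY samples in a
  study), with the $n-1$ standard deviation.

### Contamination geometry

A mixture of two individuals of different chromosomal sex adds a second
set of autosomes to the denominator: for an XY host with XX contaminant,
$R_x$ inflates toward $r_X(2)$ while $R_y$ deflates toward 0, and
symmetrically for an XX host. Both ratios therefore land *strictly
between* adjacent centroids — a region no pure sex-chromosome
aneuploidy occupies (XXY sits at $r_X(2)$ *and* $r_Y(1)$, not between).
The flag requires both axes uncertain with $R_x \in (r_X(1), r_X(2))$
and $R_y \in (0, r_Y(1))$. Same-sex contamination leaves the ratios at
their pure values and is undetectable by this geometry (about half of
contamination scenarios); heterozygosity-based estimators cover that
case and are out of scope here.

## Autosomal dosage and trisomy calls

`copyProfile()` normalises every chromosome to a copy estimate
$\hat c = 2 R_c / E2_c$ with $E2_c = e_c / \Sigma_A$, comparable across
chromosomes (mass cancels) and individuals (effort cancels) — the
cross-individual normalisation is inherent in the ratio form rather
than a separate rescaling step. Trisomy is called when $\hat c > 2.5$
(nearer three than two) **and** $z \ge 5$. Only 13, 18 and 21 are tested
by default: they sit outside the baseline, so their own trisomy cannot
bias the denominator. Testing a baseline chromosome is possible with a
leave-one-out denominator (`leaveOneOut = TRUE`) but is an extension
beyond the core method. The z threshold of 5 is deliberately
conservative — the scan implicitly multiple-tests across chromosomes,
and at the read counts where a trisomy is real, its z is in the tens.

## The simulator: what it emulates and what it does not

`simulateCounts()` draws counts multinomially with
$p_c \propto (1-\alpha)\, m_c(\text{host}) + \alpha\, m_c(\text{contaminant})$,
$m_c = k_c e_c$, on one shared calibration (contaminant assumed same
platform). Mixing *unnormalised* masses makes closed forms exact: a
50:50 XX/XY mixture has $E[R_x] = (r_X(2)+r_X(1))/2$ and
$E[R_y] = r_Y(1)/2$, which the suite checks to Monte-Carlo precision.
`thinCounts()` downsamples by per-chromosome binomial thinning — exactly
the count-level law of retaining each read independently, verified
distributionally against a per-read retention oracle.

The simulator is a generative twin of the *count* model only. It does
not emulate post-mortem damage, GC or fragment-length bias, reference
bias, index hopping, or batch structure. Passing tests therefore show
the statistics behave correctly when the count model holds; they do not
show robustness to compositional artefacts in real libraries — that is
what cohort calibration and the confidence band absorb in practice.

Coverage is converted to reads as $n = fold \times 3.1\times10^9 / 60$
(a 60 nt mean aligned fragment, typical of ancient DNA; both
configurable), so 0.0001-fold ≈ 5,167 reads.

## Power analysis and problem sizes

`powerExperiment()` reproduces the downsampling design used to validate
low-coverage assignment: per coverage level and replicate, simulate or
thin, call, and record $R_x$, $R_y$ and correctness. Child seeds derive
from the root seed by counter, so any single replicate is reproducible
in isolation. The suite runs a 45,X0 power curve at a base of
~0.01-fold thinned through two decades (≈517k → 5.2k reads, 100
replicates per level): the X=1/Y=0 assignment holds in ≥ 95/100
replicates at every level and the replicate SD of $R_x$ grows strictly
as coverage falls. Karyotype-recovery checks use 100 replicates of
100,000 reads per karyotype; these sizes keep the full suite under a
minute of simulation while leaving the Monte-Carlo error far from the
asserted margins.

## Numerical choices, degenerate inputs, limits

- **Ties**: a ratio exactly midway between centroids is uncertain, never
  a copy call.
- **$N_a = 0$**: a no-call with explanatory flags, not an error; empty
  inputs warn and return zero tables.
- **Low counts**: `low_count` flags $N_a$ below 1,000 (configurable);
  calls are still emitted with their (wide) errors.
- **Copy ranges**: X searched over 0–3, Y over 0–2. Higher polysomies
  are rare enough that extending the grid mostly manufactures
  false-positive bands.
- **Y discrimination floor**: with $r_Y(1) = 0.0026$, one vs two Y
  copies differ by ~12 expected Y reads at 5,000 total reads — Poisson
  overlap makes Y-copy discrimination unreliable below a few tens of
  thousands of reads, however thresholds are placed. X-copy calls (gap
  0.028) remain reliable down to ~5,000 reads. This asymmetry is
  intrinsic to the statistic, and is why the low-coverage guarantees
  quoted above are X-axis guarantees.
- **Structural variation**: the method sees whole-chromosome dosage
  only; micro-deletions, isochromosomes and translocation-derived
  aneuploidies are invisible.
- **Masking**: a BED accessibility mask (e.g. the 1000 Genomes strict
  mask) can restrict counting; membership uses the leftmost aligned
  position only — cheap, deterministic, and adequate for short
  fragments. Rx/Ry are computed unmasked by default; masking mainly
  serves per-chromosome coverage profiling.
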