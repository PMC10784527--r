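# karyotypeR

Karyotype and aneuploidy inference from low-coverage sequencing read
counts — built for ancient DNA, where genomes are routinely sequenced to
between ~0.0001-fold and a few fold coverage and classical cytogenetics
is obviously unavailable.

## What it does, for whom

Given per-chromosome counts of quality-filtered aligned reads (from a
BAM/CRAM, a `samtools view` text stream, or a TSV), karyotypeR infers
the number of X and Y chromosomes and scans for the viable autosomal
trisomies (13, 18, 21). It detects and distinguishes:

- typical karyotypes (46,XX; 46,XY),
- sex chromosome aneuploidies (47,XXY Klinefelter; 47,XYY; 45,X0
  Turner; 47,XXX),
- autosomal trisomies (e.g. 47,XY,+21 Down syndrome),
- contamination by a different-sex individual (which mimics no
  aneuploidy and is flagged, not miscalled),
- mosaic karyotypes (e.g. 45,X0/46,XX), via large deviations toward an
  adjacent copy number.

Intended users are ancient-DNA and population-genomics labs running
karyotype QC over cohorts of shallow genomes, but nothing is specific to
ancient data beyond the defaults.

## The statistics

All inference runs off an **autosomal baseline**

> N_a = reads on chromosomes 1–22, excluding 13, 18 and 21

(the exclusions are the only autosomal trisomies compatible with live
birth, so the denominator stays euploid even in affected samples), and
the ratio statistics

> R_x = n_X / N_a,  R_y = n_Y / N_a,  R_c = n_c / N_a.

Each ratio carries a delta-method standard error from the binomial
proportion p = n_c/(n_c + N_a), with a 0.5 pseudocount on both counts:
se(r) = sqrt(p(1−p)/n) / (1−p)².

A calibration table of per-copy effective masses e_c yields theoretical
centroids r_X(k) = k·e_X/(2ΣA); under the shipped shotgun calibration
r_X(2) = 0.056, r_X(1) = 0.028, r_Y(1) = 0.0026. Copy number is the
nearest centroid, accepted as *confident* within a band of
max(3·se, 0.25·gap); otherwise the call is *uncertain*. Both axes
uncertain with both ratios strictly between adjacent centroids is the
geometric signature of different-sex contamination. Autosomal dosage is
read off ĉ_c = 2·R_c/E2_c, with trisomies called at ĉ > 2.5 and z ≥ 5.

## Worked example

```r
library(karyotypeR)
cal <- builtinCalibration("shotgun")

# simulate a Klinefelter sample at ~0.002-fold coverage
tab <- simulateCounts(simSpec(xCopies = 2, yCopies = 1, nReads = 1e5,
                              calib = cal, seed = 1))
callKaryotype(tab, cal)
```

```
KaryotypeCall: sim_2X1Y_n100000_s1 -> 47,XXY
  Rx 0.05577 (X: 2, confident) | Ry 0.0025528 (Y: 1, confident)
```

Rx ≈ 0.056 sits at the two-X centroid (0.056) while Ry ≈ 0.0026 sits at
the one-Y centroid — two X copies plus one Y, i.e. 47,XXY, with both
axes inside their confidence bands. From a shell, the same pipeline is:

```sh
samtools view -q30 sample.bam | exec/karyotypeR count - --out counts.tsv
exec/karyotypeR call counts.tsv --out report.tsv
```

The report is one row per sample: counts, Rx/Ry with standard errors,
copy numbers, statuses, trisomies, ISCN string and flags
(`low_count`, `uncertain`, `contamination_suspect`, `mosaic_candidate`).

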