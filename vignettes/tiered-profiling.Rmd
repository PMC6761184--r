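---
title: "Tiered molecular profiling and subgrouping of infant gliomas: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered molecular profiling and subgrouping of infant gliomas: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantglioma)
```

## The problem

Gliomas diagnosed in roughly the first year of life behave unlike those of
older children. They are overwhelmingly single-driver tumors, and the driver
falls into one of two pathway classes: RAS/MAPK activation (KIAA1549-BRAF
fusion, BRAF V600E, FGFR1 fusion or intragenic tyrosine-kinase-domain
duplication, RAF1 fusion, MYBL1 gain) or an activating receptor
tyrosine kinase (RTK) fusion of ALK, ROS1, NTRK1/2/3 or MET, in which a 5'
partner is joined to the 3' portion of the kinase so that the tyrosine
kinase domain (TKD) is retained. Pathway class combines with tumor location
into three clinically distinct subgroups: Group 1 (hemispheric,
RTK-driven), Group 2 (hemispheric, RAS/MAPK-driven) and Group 3 (midline,
RAS/MAPK-driven, dominated by optic pathway/hypothalamic gliomas).

Because diagnostic material is mostly archival, drivers are found with a
tiered strategy rather than upfront sequencing: cheap targeted assays first
(droplet digital PCR hotspots and copy assays, count-panel fusion
detection), and only tier-1-negative samples proceed to tier 2 (targeted
RNA-seq, whole-transcriptome fusion calling, copy-number arrays). This
package implements that pipeline as testable code, together with a
synthetic-cohort generator and a deterministic 118-sample reference cohort
encoding the published marginal counts.

## Assay models

### Droplet digital PCR

A reaction is partitioned into 10,000-15,000 droplets; target molecules
distribute approximately Poisson, so with a fraction $\hat p = k/n$ of
positive droplets the per-droplet concentration is
$\hat\lambda = -\ln(1-\hat p)$ and the volumetric concentration follows by
dividing by the droplet volume (default 0.85 nL, the vendor-standard value;
it is configurable because it is instrument-specific). The mutant allele
fraction is reported from the Poisson-corrected concentrations,
$\mathrm{MAF} = 100\,\lambda_m/(\lambda_m+\lambda_w)$; computing it from
raw positive fractions is selectable (`maf_from_corrected = FALSE`), and at
the low occupancies typical of these assays the two nearly coincide.

Calling rules, with defaults exactly as published and every threshold held
only in the configuration:

* hotspot (BRAF V600E, H3F3A K28M/G35R): positive iff MAF $\ge$ 1% in
  *both* duplicate runs **and** each replicate contains $\ge$ 50
  fluorescent droplets. We interpret "fluorescent droplets" as positives
  summed over both channels within a replicate, required per replicate.
* CDKN2A: copy-number value $CN = 2(\lambda_t/\lambda_r)/r_{cal}$ against
  the APB31 reference and a two-copy calibrator; deleted strictly below
  1.2 (the boundary itself is neutral).
* FGFR1 TKD duplication: exon16:exon8 concentration ratio, duplicated at
  $\ge 1.125$ (the boundary is included because that ratio value is the one
  called duplicated). Replicate concentrations are averaged before ratio
  formation.

Saturated channels ($k = n$) are an error, not a value: $\lambda$ is
undefined there and the assay must be diluted, so the error propagates out
of the calling functions.

### Count-panel fusion detection

Lanes are background-corrected from the negative-control spikes. The
barcode-counting noise is Poisson, so the threshold is operationalised as
$B = \bar m + 2\sqrt{\bar m}$ (mean of the lane's negative controls plus
two Poisson standard deviations), subtracted with a floor at zero; a plain
mean subtraction is selectable. Technical normalization uses the geometric
mean of the four housekeeping transcripts (ABCF1, ALAS1, CLTC, HPRT1) —
the geometric mean is the platform convention — with the batch reference
equal to the mean of per-lane geometric means, which makes the step
idempotent. Lanes with a zero housekeeper fail QC and are excluded with a
recorded reason.

An expressed fusion is called by the extreme-outlier rule: for each
junction probe the quartiles are computed *across the lanes of a batch*
and a lane is flagged iff its value strictly exceeds $Q_3 + 3\,IQR$. The
cross-sample orientation matters: a junction probe is silent in
fusion-negative samples, so the expressing lane is an extreme outlier of an
essentially null distribution. Quartiles use the linear-interpolation
convention (R type 7), fixed and documented because calls near the fence
depend on it. A minimum batch of 8 lanes is required for stable quartiles.

Reporter-tag systems give partner-agnostic evidence for ALK, ROS1 and
NTRK2: tags placed before and after the breakpoint hotspot count
differently when only the 3' side is driven by a fusion promoter. The
statistic is $r = \log_2(\bar d + 1) - \log_2(\bar u + 1)$ (mean
downstream vs upstream tags, pseudocount 1), compared across the batch by
a robust z-score $(r - \mathrm{median})/(1.4826\,\mathrm{MAD})$, with a
call at $z \ge 5$ and mean downstream signal above a floor (default 10
normalized counts). The z cutoff and pseudocount are our quantification of
"significantly different", which the source protocol does not quantify;
both are configuration-exposed. The ratio is invariant to whole-lane
scaling, so global overexpression does not trigger calls. A zero batch MAD
falls back to IQR/1.349 and is flagged.

### Driver integration

Transcriptome fusion candidates from the four callers (deFuse, TopHat,
EricScript, FusionMap) are merged when they share a gene pair with
breakpoints within 1 exon (single-linkage on sorted breakpoints, so the
result is order-independent), and kept with support from $\ge 2$ distinct
callers. The consensus rule and the 1-exon tolerance are our choices: the
source names the callers but neither a consensus rule nor a
reconciliation of discordant breakpoints. A fusion is annotated activating
when the 3' breakpoint lies at or upstream of the kinase-domain start exon
(domain retained); the kinase-domain spans ship as an editable TSV of
approximate, literature-conventional exon ranges — only the ordering of
breakpoint vs domain start is consumed.

Integration enforces the tiered design: any tier-1 positive fixes the
driver and tier-2 evidence is never consulted. Simultaneous positives
within a tier are resolved by a configured precedence (SNV hotspot >
panel fusion > CNV) with the conflict recorded; these tumors are
essentially single-driver, so conflicts indicate assay artifacts more
often than biology. Samples with no positive evidence are driver NONE.

### Subgrouping and summaries

Group labels follow the pathway-by-location definition above; the single
published midline RTK tumor shows that midline RTK is *not* Group 1, so
that combination — like OTHER/NONE pathways and location "other" — is
UNCLASSIFIED. That label is this package's convention for samples the
source leaves unlabelled. Optic pathway/hypothalamic gliomas are midline.
Mixed-grade tumors count as HGG in enrichment summaries (this is what
reconciles the Group 1 grade table with the "enriched for HGG" fraction);
the choice is documented and switchable. Percentages are rounded half-up
to one decimal, the reporting precision of the source tables. One
published percentage (the Group 2 share of hemispheric tumors, 17/65) was
printed a tenth below its half-up rounding; tests therefore assert exact
counts plus percentages to within one unit in the last printed digit.

### Survival

OS is diagnosis to death or last follow-up; PFS is diagnosis to the first
progression requiring a change in clinical management, never exceeding OS.
The estimators are the standard clinical ones and are computed via the
`survival` package behind this module's interface: product-limit curves
with Greenwood variance and 95% bands on the log-survival scale (the
default of the R survival machinery the original analysis used; log-log is
selectable), the log-rank test, and Cox proportional hazards with Efron
tie handling (Breslow selectable) and Wald tests. The published survival
percentages depend on unpublished per-patient times and are **not**
reproduction targets; instead the module is validated against independent
oracles that never call `survival`: hand product-limit computations, a
hand O−E/V log-rank on four subjects, a brute-force partial-likelihood
grid search (agreement $\le 10^{-3}$), and a 500-replicate null
calibration of the log-rank type-I error.

## The synthetic world

The generator states one cohort world and keeps it fixed:

* **Cohort structure.** Driver frequencies default to the observed
  118-sample marginals; location and grade are drawn conditionally on
  pathway at the observed rates (e.g. 29/30 of RTK tumors hemispheric,
  25/30 HGG counting mixed). V600E allele fractions are uniform on
  0.10-0.50, a realistic clinical range.
* **Droplets.** Totals uniform on 10,000-15,000; channel positives
  Binomial$(n, 1-e^{-\lambda})$ with $\lambda_w = 0.5$ copies/droplet and
  $\lambda_m = \lambda_w v/(1-v)$ so the implied MAF equals the VAF.
  TKD-duplicated samples simulate a true exon ratio of 1.4 (intragenic
  duplication on one allele gives 3:2 = 1.5 at purity 1; 1.4 reflects
  imperfect purity and is comfortably above the 1.125 boundary).
* **Count lanes.** Negative controls Poisson(4); housekeepers lognormal
  around platform-typical means (600-1500) with 20% CV; a per-lane size
  factor with 15% CV scales every probe. Junction probes sit at a
  one-count baseline — a junction probe has essentially no target in
  fusion-negative RNA — and this, not the fence, is what makes the stated
  specificity target ($\le 1$ false call per 100 null lanes) achievable at
  the stated negative-control mean of 4. Driver-matching probes are
  elevated 50x; reporter tags (baseline 200) step 10x downstream of the
  breakpoint in fused samples.
* **Survival.** OS exponential at group-specific medians taken from the
  published per-group summaries (1.9 / 3.6 / 6.5 years); PFS is the
  earlier of an exponential draw at the PFS median and the OS event, so
  PFS $\le$ OS while OS stays exactly exponential. Censoring draws, with
  the configured probability, a uniform time on (0, PFS event), applied to
  both endpoints — rate 1 censors everything. This mechanism is
  *informative*, so unbiased-recovery checks run at rate 0. Only the
  exponential family is claimed; the source reports KM summaries, not
  shapes.
* **Tier-2 evidence.** Fusion drivers emit candidates from three of the
  four callers with $\pm 1$-exon jitter; MYBL1 gains arrive as pre-called
  copy-number events; OTHER drivers emit a non-recurrent pair so tier 2 is
  exercised without mapping to an enumerated driver.

What a green test establishes, and what it does not: the simulator
reproduces the count structure, the Poisson partition statistics and the
latent cohort marginals, so green tests establish that the calling rules
and integration logic are implemented correctly and meet the stated
operating characteristics *in this world*. It does not emulate FFPE RNA
degradation, probe-specific efficiency, batch drift, or clustered
fluorescence gating errors, so the measured sensitivity/specificity are
not field performance claims.

The deterministic reference cohort is a pure constructor reproducing every
published marginal count (118 = 65 hemispheric + 53 midline; drivers
28/21/3/2/1/1 RAS/MAPK and 12/8/7/3 RTK; groups 29/17/39; Group 1 grades
5/21/3; Group 3 all-LGG with 27 pilocytic, 31 OPHG, 38/39 BRAF; GTR
12/9/3). Joint attributes the publication does not pin are filled
deterministically in sample-id order: Group 2's drivers are 6
KIAA1549-BRAF + 5 V600E + 3 FGFR1-TACC1 + 2 FGFR1-TKD + 1 PML-RAF1 (6/17
non-BRAF), Group 3's one non-BRAF sample is the MYBL1 gain, the midline
RTK tumor is a MET-fused HGG, the three mixed-grade Group 1 tumors are
NTRK-fused, and the 32 remaining samples alternate OTHER/NONE. Ages are
group means and fixture survival fields are synthetic fills — they are
never used as reproduction targets.

## Worked example

```{r example}
fx <- reference_cohort()
assays <- simulate_assays(fx, noiseless = TRUE)
res <- run_pipeline(fx, assays$droplets, assays$panel,
                    assays$fusions, assays$cnv)
res$headline
res$summary$groups
```

With noiseless assays every driver is recovered and the headline fractions
equal the published ones (47.5% RAS/MAPK, 23.7% KIAA1549-BRAF, 25.4% RTK,
96.7% of RTK hemispheric, 82.8% HGG in Group 1, 73.6% of midline tumors
RAS/MAPK-driven, 97.4% of Group 3 BRAF-altered, 69.2% pilocytic; the Group
2 share of hemispheric prints as 26.2, the half-up rounding of 17/65).

## Numerical choices and degenerate inputs

* Quantile convention type 7 everywhere quartiles feed a fence.
* Bisection to the calling boundaries uses $10^{-6}$-$10^{-7}$ tolerance;
  the boundary semantics (TKD inclusive, CDKN2A exclusive) are encoded in
  the rules, not the bisection.
* Saturated droplets, zero reference channels, zero housekeepers, missing
  tag sides, sub-minimum batches, contradictory duplicate evidence and
  orphan sample ids are all hard errors with diagnostic messages, never
  silent values.
* Configuration is JSON (via jsonlite); no YAML reader is assumed.
* Seeds: every stochastic generator is driven by an explicit seed; equal
  seeds give byte-identical outputs.

## Known limitations

* The fixture's within-group joint distributions beyond the published
  marginals are conventions, not data.
* Imbalance scoring assumes a mostly fusion-negative batch for its robust
  baseline; a batch enriched for fusions of one gene would inflate the MAD
  and lose sensitivity.
* The Cox wrapper rejects complete separation rather than penalising
  (no Firth correction).
* 2-D droplet cluster gating, RCC parsing and the upstream fusion callers
  are out of scope; their outputs are consumed as plain-text tables.
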