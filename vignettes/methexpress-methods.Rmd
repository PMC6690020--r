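---
title: "Methods and modelling choices in methexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in methexpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpress)
```

`methexpress` integrates whole-genome bisulfite sequencing (WGBS)
methylomes with matched expression profiles collected across several
tissue regions — the design of multi-region brain methylome studies,
where each region contributes one methylome and one transcriptome from
the same individual. This vignette explains the statistical model of
every stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices that an informed user should know about.

## Coordinate conventions and input formats

All in-memory intervals are 0-based half-open; conversions happen only
at parse and write boundaries. Bismark-style cytosine reports are
1-based (shifted on read), BED and UCSC rmsk tables are already 0-based
half-open, and RepeatMasker `.out` files are 1-based inclusive
(normalized on read). The two repeat dialects parse to identical
records, which is asserted by a test. Malformed lines fail loudly with
a line number unless `tolerant = TRUE` is passed.

CpG sites on the two strands of a dyad are kept separate by default,
preserving the full information of the caller output. `merge_dyads()`
sums the counts of the two strands at the plus-strand anchor position.
Because CpG methylation is maintained symmetrically in vivo, destranding
is the standard way to roughly double per-site depth before testing, and
the differential-methylation power analyses below use it.

## Per-site quantification

The methylation level of a site is $\beta = n_\mathrm{meth} /
(n_\mathrm{meth} + n_\mathrm{unmeth})$, defined only at positive depth.
Sites with depth below 10 are discarded by `filter_by_depth()` before
any analysis; this threshold is exposed (`min_depth`) because the
useful cutoff depends on the sequencing depth of the study.

Promoters are the fixed 2-kb window upstream of the TSS
(`promoter_of()`, strand-aware, clipped at position 0 and at the
chromosome end when lengths are known). Gene bodies are
`[tx_start, tx_end)` including introns. When a site falls in both a
promoter and a gene body the promoter label wins: promoters are the unit
of every downstream analysis here, so the priority keeps the promoter
site universe complete. Methylation-level quartile bins are half-open —
$[0, .25), [.25, .5), [.5, .75), [.75, 1]$ — with the top bin closed, so
no level is double-counted.

## Differential methylation

For each pair of samples, the tested universe is the intersection of
their depth-filtered sites. Each shared site contributes a 2x2 table of
methylated/unmethylated counts. `fisher_exact_2x2()` computes the
two-sided Fisher exact p-value by the probability-mass rule: the sum of
hypergeometric probabilities, over all tables with the observed margins,
not exceeding the probability of the observed table (with the
conventional relative tie slack of `1e-7`). The implementation is
vectorized over sites because a seven-region study tests 21 pairs of
tens of thousands of sites each; it is checked against exhaustive
enumeration for every small table shape in the test suite. Degenerate
tables (a zero row margin) return p = 1 and are flagged.

Multiple testing is corrected per sample pair with Benjamini–Hochberg
(`bh_adjust()`, delegating to `stats::p.adjust`); `m` is the size of the
pair's tested universe. Sites with $q \le$ `q_threshold` (default 0.05)
are classified `hyper` or `hypo` by the sign of
$\beta_B - \beta_A$. A minimum absolute difference filter
(`min_abs_diff`, default 0) is available for users who want the
conventional 25-point rule, but it is off by default: the default
pipeline applies only the q-value rule.

A gene is a differentially methylated gene (DMG) when its first exon —
the 5'-most exon in transcription order — overlaps a CpG island that
contains at least one significant DMS (`call_dmgs()`). Both the
standard threshold (0.05) and a stricter reporting threshold
(`dmg_q = 0.01`) are exposed, since a study typically reports a
high-confidence DMG subset at the stricter level.

Fisher's exact test on discrete counts is conservative under the null;
the calibration test verifies that on a simulated null methylome the
raw $p \le 0.05$ fraction stays below 0.055 and BH calls are absent.
There is no overdispersion correction — biological replicates within a
region are out of scope, as is region-level DMR segmentation.

## Expression normalization and clustering

Expression values arrive as FPKM, which is already depth- and
length-scaled; between-sample composition bias is removed with a
trimmed-mean-of-M-values (TMM) variant that operates directly on the
expression units with the library-size term dropped. M and A are
computed over genes positive in both samples, the top and bottom 30% of
M and 5% of A are trimmed, and the factor is the precision-weighted
mean of the remaining M. Two details matter for correctness and are
deliberate:

* precision weights are computed on column-total-normalized abundances
  (the delta-method variance on the proportion scale, matching how
  `edgeR` weights on `x / lib.size`), because weights on raw values
  change non-uniformly when a sample is rescaled and would break the
  scale equivariance that any normalization factor must have;
* the reference sample (upper quartile closest to the mean upper
  quartile) is likewise selected on column-total-normalized values, so
  the reference choice cannot flip when one sample is rescaled.

With both choices, multiplying one column by $s$ multiplies its factor
by exactly $s$ (before the geometric-mean-1 rescaling), which a test
asserts to well below 1%. `edgeR::calcNormFactors` under the
equal-library-size convention agrees with the implementation to ~1% on
clean fixtures and serves as the independent cross-check.

For clustering, normalized values are transformed per gene to
$z = \mathrm{zscore}(\log_2(x + 1))$ and capped at $\pm 2$; capping
bounds the influence of any single region, at the cost of compressing
extreme profiles. Zero-variance genes are excluded (they carry no
pattern). Genes are pre-filtered by maximum pairwise fold change
$\ge 4$ with a pseudocount of 1 — consistent with the $\log_2(x + 1)$
transform and robust to zeros; 4 is the conventional middle of the
usual 2–64 ladder.

Clustering is k-medoids (PAM) with `k = 7` (one cluster per region in
the emulated design): deterministic greedy BUILD, then SWAP applying
the best strictly-improving medoid/non-medoid exchange until none
exists. No random restarts — results are a pure function of the input;
every tie breaks toward the lower gene index and labels are
canonicalized by sorting medoids, so labels are stable across runs.
Because a 1-exchange local search can stall even on tiny inputs, the
solver enumerates all medoid sets when $\binom{n}{k} \le 10^4$ and
returns the global optimum; large instances (the real use case) use the
local search. The SWAP-never-worsens property and agreement with
`cluster::pam`'s local search are tested.

Each region is then assigned the cluster with the highest mean z in
that region; the region's BRSG (region-specific gene) set is that
cluster's membership. The mapping is not forced to be a bijection — a
warning reports collisions, which on real data indicate that fewer than
`k` distinct regional programs exist.

## Methylation–expression integration

CpG islands are paired with every promoter they overlap by at least
1 bp (a CGI spanning a divergent promoter pair yields two pairs). The
methylation of a CGI in a region is the median $\beta$ over its
depth-filtered sites; the median is robust to the strong bimodality of
per-site methylation. Pairs missing a region median are dropped from
the screen (and counted); the even-count median is the midpoint of the
central order statistics.

The screen computes Pearson's r between the per-region methylation
vector and the gene's TMM-normalized expression vector — expression
enters on the normalized FPKM scale, not as capped z-scores, because
Pearson r is scale-invariant and capping would distort the very
profiles being tested. The p-value is the two-sided t-test
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ df. Following the emulated
study design, no multiple-testing correction is applied to the screen
by default (raw $p \le 0.05$ over ~3k pairs); `bh = TRUE` adds
q-values for users who want them. When several CGI–gene pairs survive
for one gene, the smallest-p pair represents the gene. Records are
finally flagged by BRSG and DMG membership, giving the
sign x BRSG x DMG classification table.

At $n = 7$ regions the screen only reaches significance at
$|r| \gtrsim 0.755$; power is therefore high only for strong couplings
(planted $|r| = 0.95$ is recovered at $\ge 80\%$, asserted by test)
and the raw-p screen should be read as a candidate generator, not an
error-controlled discovery procedure.

## Repeat-element methylation

Repeats are stratified by class and subtype and split by CGI content
(>= 1 bp overlap). Metaprofiles rescale each element body to 100 bins
(sites map to bin $\lfloor 100\,o/L \rfloor$), attach fixed-width
100-bp flanks split into 20 bins, and flip minus-strand elements so
profiles are in element orientation. Per-bin means pool sites over all
elements; empty bins are `NA`, never zero. The binned series is
smoothed with LOESS (degree-1 local fits, tricube weights, span 0.3 by
default — enough to remove bin noise without flattening the
edge/center contrasts of interest); raw and smoothed series are both
reported.

Inner/outer statistics compare all sites inside the elements of a class
against all sites within 100 bp outside element boundaries. Flank sites
falling inside *any* annotated repeat are excluded from the outer pool
by default — repeat density makes flanks frequently overlap neighboring
elements, which would contaminate the contrast. Pools aggregate sites
rather than per-element means (a per-element mode exists). Subtypes are
classified hypo (< 0.25) / hyper (>= 0.75) / intermediate by the median
of per-element medians, mirroring the quartile bins used for genomic
features.

## The synthetic study generator

`simulate_dataset()` emulates the data structure every stage assumes,
at desk scale: 2 chromosomes x 2 Mbp, 300 multi-exon genes, 240
promoter CGIs, ~210 repeats over four classes, 7 regions, 40,000 CpG
cytosines plus 10% non-CpG sites, all placed so that genes never
overlap, each CGI spans its gene's TSS (hence overlaps both promoter
and first exon), and repeats sit intergenically with >= 200 bp
spacing. The full pipeline runs on this default in well under five
minutes on one CPU; the test suite uses scaled-down configurations of
the same generator.

Latent methylation is compartment-specific: promoter CGIs
Beta(1, 9) (hypomethylated), gene bodies and intergenic space
Beta(8, 2), repeat interiors Beta(8, 2), repeat flanks Beta(8.5, 1.5).
The flank mean of 0.85 against the interior mean of 0.80 plants the
0.05 inner/outer gap that the flank statistics must recover. LINE-like
interiors carry an edge-high positional shape and SINE-like interiors a
center-high shape (0.9 vs 0.6 thirds), the two canonical metaprofile
morphologies. Read depth is negative-binomial per site and region
(mean 15, size 5 by default) — deliberately close to the depth-10
cutoff so the filter is exercised nontrivially; methylated counts are
binomial in the latent level. Non-CpG sites are near-unmethylated
(Beta(0.5, 20)), exercising the CpG/non-CpG split.

Planted structure, recorded in machine-readable truth tables:

* **DMSs** — 200 CpG dyads by default, each shifted by
  $\Delta\beta = 0.5$ in one region of a random pair. Both strands of a
  dyad share the shift (CpG methylation is symmetric), and the shift
  direction points away from the nearer boundary so the full magnitude
  is realized; levels are clipped to $[0.02, 0.98]$ with a warning
  otherwise. Sensitivity is assessed at depth mean 30 on destranded
  sites, where recovery exceeds 90% with empirical FDR under 5%; at the
  default depth of 15 a per-pair BH correction leaves little power for
  a 0.5 shift, which is the expected behavior of the test, not a defect
  of the implementation.
* **Expression clusters** — 25 genes per region receive +3 log2 units
  in exactly one region, giving the one-high-cluster-per-region
  structure that PAM must recover (adjusted Rand >= 0.9 asserted).
* **Coupled genes** — 5 positive and 3 negative genes whose promoter
  CGIs receive per-region methylation profiles spread over
  [0.15, 0.85]; their log2 expression is a linear function of the
  profile with noise calibrated so the true correlation magnitude is
  0.95.

Everything is a pure function of (config, seed): identical inputs give
byte-identical output files, asserted by test. What the generator does
**not** emulate: sequence content (no FASTQ, no bisulfite-conversion
error), biological replication and inter-individual variance, LD-like
spatial correlation of methylation beyond the shared dyad level,
transcript-level quantification uncertainty, and genome-scale repeat
density. Passing tests on this generator therefore demonstrate the
correctness and calibration of the algorithms under the declared model,
not performance on any particular real genome.

## Numerical and degenerate-input policy

* Fisher ties use relative slack `1e-7`; BH is exact.
* Zero-depth sites have undefined $\beta$ and are rejected by
  `level_bin_proportions()`.
* Zero-variance rows are excluded from z-scoring and from the
  correlation screen, with warnings/counts.
* Empty promoters after clipping (TSS at position 0) are dropped with a
  warning; flanks beyond a chromosome start are truncated, never
  wrapped.
* `call_dms(a, b)` and `call_dms(b, a)` give mirrored differences and
  identical p/q values; identical inputs give no calls.
* The pipeline writes a provenance header (package version, config
  hash, seed) on every output and an MD5 manifest; re-running with the
  same config reproduces the digests exactly.

## Reproducing the analyses

`scripts/acceptance.R --seed <int> --out <path>` regenerates all
simulated inputs from the seed, runs every stage, and writes the
package's headline quantities (oracle deviations, null calibration,
sensitivity/FDR, cluster recovery, screen power/size, TMM equivariance
error, repeat statistics, determinism flag) as JSON. The README shows a
worked end-to-end example with the numbers it prints.
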