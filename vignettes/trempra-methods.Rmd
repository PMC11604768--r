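---
title: "Methods: models, parameters and numerical choices in trempra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in trempra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`trempra` covers the computational side of a barcoded synthetic-promoter
reporter screen: library design, barcode dictionary construction, barcode
counting, transcription-rate estimation, and differential testing, plus a
synthetic-data generator that stands in for sequencing data. This
vignette records the models each stage implements, the tunable parameters
with their defaults and rationale, and the numerical decisions made where
the design was genuinely open. It states no empirical result beyond what
the package's test suite and `scripts/acceptance.R` themselves compute.

## Motif catalog

A PWM seed is an IUPAC string with an L x 4 weight matrix. Resolution is
two-pass: (1) runs of fully degenerate positions are trimmed from both
ends — "fully degenerate" is read strictly as the code `N`; other
degenerate codes at the ends carry information and are resolved, not
trimmed; (2) each remaining degenerate position is replaced by the base
with maximal PWM weight *among the bases the code permits*. Restricting
the argmax to the code's own base set keeps the resolved motif consistent
with the seed (for `R`, only A or G can be chosen even if C had the
largest weight); for `N` all four bases compete. Ties go to the
alphabetically first base, making resolution deterministic. A position
whose permitted weights are all zero is an error naming the position; an
all-`N` seed is an "empty motif" error.

Deduplication removes any motif whose entire sequence occurs as a
contiguous substring of another, distinct motif (so of `CAAAAAC` and
`AAAAA` only the former survives). Containment is checked on the forward
strand only; reverse-complement containment is deliberately not removed,
since TRE units are built from the motif as given and a reverse-complement
context is a different promoter sequence. Among exact duplicates the
first by input order wins, and input order is preserved — both choices
exist purely to make the catalog reproducible.

Negative-control motifs are base-composition-preserving permutations of
experimental motifs, redrawn (bounded at 100 attempts) until the scramble
differs from, and is not contained in, its source. Homopolymers cannot
change under permutation and are skipped with a warning.

## Promoter design

A TRE unit is `flank5 + (motif + spacer) x 3 + motif + rotation + filler +
flank3`, synthesized at a fixed 160 nt. The spacer length for a motif of
length L is the smallest nonnegative s minimizing
`min_k |L + s − P (k + ½)|` with helical period P = 10.5 bp/turn
(canonical B-DNA; configurable), so that the center-to-center spacing of
adjacent copies is as close as possible to a half-integer number of
turns, orienting neighbours on opposite faces of the helix. Because
spacings are integers and half-turn targets have fractional parts 0.25 or
0.75, the attained deviation is always exactly 0.25 bp; the library
invariant asserts deviation ≤ 0.25 bp on every unit.

Six configurations per experimental motif are realized as two spacer
sets (independent random-sequence draws) times three rotation offsets
{0, 4, 8} nt. The exact published factorization of "six configurations"
is not printed anywhere we could anchor to, but figure labels of the
form "rotation 8, spacer set 1" imply the two factors, and 4/8-nt shifts
correspond to roughly one- and two-thirds of a helical turn. The rotation
segment sits between the last motif copy and the 3' filler, rotating the
TRE block relative to the downstream minimal promoter. Negative-control
motifs get one configuration each.

All random segments derive from a 31-bit string hash of
`(seed, spacer-set seed, motif id, rotation)`, so any unit can be
regenerated in isolation and the library is reproducible regardless of
generation order. Each assembled oligo is scanned for
MluI/SpeI/KpnI/XbaI recognition sites (the cloning strategy's enzymes);
any site outside the two designed flank positions triggers a redraw of
the random segments, up to `max_redraws = 1000`, after which the unit is
an error. Sites that involve only fixed sequence (inside the motif, at
the 5'-flank/motif junction, or across a motif–motif junction when the
phasing spacer has length zero) cannot be repaired by redrawing and are
reported as "incompatible with the restriction strategy"; the synthetic
seed generator only emits motifs that pass this designability screen.

The shipped flanks are arbitrary fixed 20-nt primer landing sites plus
the MluI (5') and SpeI (3') cloning sites — the published flanks live in
supplementary material not reproduced here — and are fully configurable.
Coordinates are 0-based half-open throughout. Commercial (pass-through)
units are appended unmodified and may exceed 160 nt. Every unit is
crossed with minTK, minProm and minCMV, giving `promoter_id =
unit_id|min_promoter`.

## Barcode dictionary

Dictionary read pairs carry the unit core (the oligo between the primer
flanks) on one read and the barcode as the first 24 nt of the other.
Observed unit sequences are compared directly against all expected cores
and assigned to the unique core within Levenshtein distance 2; an
ambiguous read (two or more cores at the same minimal qualifying
distance) is unassigned. The published pipeline first collapsed unit
reads with a clustering tool and then distance-checked; the cluster step
was a throughput device, and checking each distinct observed sequence
directly implements the same acceptance contract. Any barcode observed
with two or more distinct matched units — within or across pairs — is
discarded entirely, which is what makes the final map injective. The
minimal-promoter identity comes from pool metadata, since each cloning
replicate received one minimal promoter.

## Barcode counting

Sample barcodes are the first 24 nt of each read; reads shorter than
24 nt or with non-ACGT characters there are counted as dropped (reads
with `N` are dropped rather than left for clustering to absorb — an
explicit choice where the source is silent). Spike-in reads are
identified before clustering by exact 24-nt prefix match, which suffices
because spike-ins are designed distinct.

Clustering is greedy sphere clustering at Levenshtein radius 1: the
highest-count unassigned barcode (count ties broken lexicographically,
for determinism) becomes a centroid and absorbs every unassigned barcode
within the radius. This is the sphere-clustering (`-s`) contract of
starcode; the message-passing internals of that tool are not reproduced.
A cluster is retained iff its centroid is a dictionary barcode and every
other member that is in the dictionary maps to the same promoter; the
retained cluster's total count is assigned to the centroid. Cluster
totals always conserve reads.

QC flags (never drops) samples whose TRE-read fraction falls below
`max(0.5 x cohort median, 0.5)`; both the multiplier and the floor are
configurable, since no threshold is published.

## Quantification

RPM is `count x 1e6 / sample total`. The transcription-rate estimate of a
promoter in an RNA sample is the aggregate ratio: the sum of RNA RPM over
the promoter's dictionary barcodes divided by the sum of DNA RPM over the
same barcodes in the plasmid input. With several DNA input replicates the
RPM values are averaged per barcode before summing (replicate handling is
not specified at the source; averaging on the RPM scale keeps the
denominator unbiased by depth). Zero-DNA promoters get flagged undefined
ratios, never imputed values.

Upper-quartile depth factors divide each sample's 75th percentile of
*nonzero* raw counts by the reference sample's; quartiles use linear
interpolation (R's default type 7). Restricting to nonzero counts
follows common normalization practice — whether the original computation
included zeros is unknowable from the text, and with zeros included the
quartile would collapse for sparse samples.

Profile summaries cluster rows and columns of a rate or fold-change
matrix by Euclidean distance with complete linkage, and produce a biplot
by column-standardizing (mean 0, sd 1; constant columns dropped with a
warning) and taking a rank-2 SVD: promoter coordinates `U D`, sample
coordinates `V`.

## Differential activity

The model is a declared negative-binomial LRT analogue of the two-design
formulation used with MPRAnalyze; equivalence is at the level of the
design formulas, the degrees of freedom, and the Wilks-based p-values —
not bit-level likelihoods.

**Stage 1 (DNA).** Per-barcode plasmid abundances come from the
log-linear model `~ barcode + batch + condition` on DNA counts. Batch
and condition jointly index DNA samples one-to-one here, so the model is
the barcode x sample independence model, whose Poisson MLE is closed
form; the implementation uses the depth-normalized mean per barcode.
Barcodes with zero DNA everywhere are excluded from their promoter's
fit. For promoters with more than 100 barcodes, the 100 highest by
summed DNA count are used (ties broken lexicographically).

**Stage 2 (RNA).** RNA counts are NB with mean `depth factor x abundance
x exp(beta_{p,c})` and one dispersion per promoter. The dispersion is
estimated from within-condition replicate variation only: with saturated
barcode-by-condition cell means (whose NB MLE is the sample mean), the
profile likelihood in the dispersion is maximized on a 28-point
log-spaced grid with quadratic refinement, with a Cox–Reid adjustment of
half the log-determinant of the per-cell information. Estimating the
dispersion this way keeps it unconfounded by condition effects and by
the sampling noise of the plug-in stage-1 abundances — noise that is
shared between conditions and cancels in the contrast the test examines.
Profiles are moderated toward the library-average profile with 20
observations' worth of prior (empirical-Bayes sharing in the style of
edgeR), stabilizing low-count promoters. Estimates falling below an
expression-matched trend (promoters binned into five mean-count classes,
a common dispersion profiled per bin) are raised to the trend: a
downward-noisy dispersion inflates the LRT of exactly that promoter, and
across thousands of promoters the smallest p-values would otherwise be
dominated by such dips — the same asymmetry DESeq2 applies to
below-trend dispersion estimates. Above-trend estimates are kept as
their own (possibly genuinely noisy-high, hence conservative) values.
Designs without replicated conditions fall back to an iterated Pearson
moment estimate. The dispersion floor is 1e-8.

**Testing.** The full model has a free effect per condition, the reduced
model one shared effect; `LRT = 2(l_full − l_reduced)` is referred to a
chi-square with `#conditions − 1` degrees of freedom. Fold changes are
natural-log contrasts divided by ln 2. FDR is Benjamini–Hochberg (the
source names only "FDR"; BH is the default of the tool it used). The
LRT statistic is reported alongside p-values because p-values underflow
for strong responders.

**Recentering.** Quantile depth factors absorb part of a one-sided
global response into the per-sample scale: if a fraction q of promoters
responds by a factor e, every null promoter acquires an apparent shift
of roughly −q·ln e and true effects are attenuated by the same amount.
Under the median-of-ratios assumption that most promoters do not
respond, the per-condition contrast is recentered at the center of its
null bulk before the reduced model is refit (the full-model likelihood
is invariant under shifting offsets against effects, so only the reduced
fit is repeated). The center is estimated on the high-information half
of promoters, anchored by the recursive half-sample mode — which stays
on the null component under one-sided contamination, the central-matching
idea of empirical-null calibration — and refined as the median of
contrasts within two model-based standard errors of the anchor, keeping
the estimate's noise at root-n scale. Recentering applies when at least
20 promoters are fit and can be disabled (`recenter = FALSE`); it should
be disabled when most of the library is expected to respond, in which
case fold changes are only identifiable relative to the library anyway.

**Numerical scheme.** All promoters are fit simultaneously: Newton
updates for the condition effects aggregate scores and Fisher
information by (promoter, condition) with `rowsum()`, with steps clamped
to ±2; convergence is declared below 1e-4 and promoters whose final step
exceeds 0.01 are flagged `not_converged`. Promoters with no RNA signal
anywhere are flagged `all_zero_rna` with p = 1 and no fold change.

**Known limitation.** The plug-in stage-1 abundances leave a mild
liberal bias in mid-range null p-values at ordinary DNA coverage (at
80 reads/barcode over 4 input replicates the null standard deviation of
the signed root-LRT is about 1.04 rather than 1); it vanishes as DNA
coverage grows and does not visibly affect Benjamini–Hochberg
discoveries at the 5% level in the package's null simulations. A joint
DNA/RNA convolution likelihood would remove it at considerable
complexity.

## Synthetic data

The generator draws, per promoter: a barcode count from a log-normal
with meanlog `log 65` and sdlog `sqrt(2 log(82/65))` — calibrated so the
discretized distribution targets the study's reported per-promoter
barcode representation (mean ≈ 82, median ≈ 65); a baseline rate
log-uniform over a 300-fold span (the study's reported dynamic range of
rate estimates); and within-promoter plasmid copy proportions from a
flat Dirichlet. DNA counts are NB with mean `dna_depth x n_b x
proportion` and dispersion 0.2; RNA counts additionally carry the
promoter's rate (rescaled so the library-average RNA depth matches
`rna_depth`) and its condition effect. The NB dispersion default of 0.2
is a free parameter — no value is published — chosen to produce
realistic overdispersion. Per-sample depth wobble is log-normal with
sd 0.1. A `dirichlet_concentration` of `Inf` gives equal copy
proportions, making every barcode's count exactly NB with the stated
mean — the configuration used when a simulation must realize "mean m
reads per barcode, dispersion phi" literally. Under the default skewed
proportions the information per promoter is substantially lower, and
detection thresholds measured under equal proportions do not transfer;
barcode-abundance skew is a genuine power limitation of real libraries.

Read-level simulation draws real 24-mers kept pairwise ≥ 3 edits apart —
mirroring random-24-mer reality at library scale while guaranteeing that
radius-1 sphere clustering is identifiable in small tests — and emits
every read `count` times, so FASTQ files and count tables agree by
construction. Substitution errors apply per base in the emitted
barcodes (ε ≤ 0.05); spike-in reads are appended at the configured
fraction; a JSON layout file records where the barcode and unit core sit
in the reads. PCR jackpotting, index hopping and quality-score error
profiles are not simulated.

What passing tests on these simulations do and do not show: they verify
the pipeline's arithmetic, determinism, and statistical calibration
under the generative model the analysis itself assumes (NB counts,
independent barcodes, well-separated barcode sequences). They cannot
certify behavior under PCR artifacts, barcode cross-talk, or
chromatin-context effects absent from the generator.

## Problem sizes

The test suite exercises the design stage at full library scale (325
motifs, 2106 units, 6318 promoters) and the differential stage at 2000
promoters x 80–100 barcodes with 3 RNA replicates per arm; the null
false-discovery check averages 20 such simulations, and the sensitivity
check uses 500 affected promoters among 2000 at 100 barcodes each —
matching the screen scale the method is meant for while remaining
single-CPU friendly. Read-level simulations are kept to a few promoters
and tens of barcodes, where exhaustive oracles (brute-force Levenshtein
scans, enumerated clusterings) remain feasible.
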