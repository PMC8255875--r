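---
title: "breeddiv: methods, parameter choices and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{breeddiv: methods, parameter choices and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`breeddiv` implements the analysis chain of a typical breed-conservation
SNP-chip study. This vignette documents the statistical content of each
stage, the defaults and why they are what they are, what the built-in
simulator does and does not emulate, and the numerical decisions taken
where more than one convention exists. Nothing here states an empirical
result that the test suite does not itself compute.

## Data model and quality control

A `genotype_dataset` holds a samples × SNPs dosage matrix (0/1/2 copies of
`allele_b`, `NA` for missing), a sample table whose breed label comes from
the PED family-ID column, and a map (chromosome, bp position, the two
alleles). Dosages are oriented so that `allele_b` is the minor allele over
the whole file, ties broken toward the lexicographically smaller allele —
a deterministic orientation, so that writing and re-reading a dataset is
the identity. Coordinates are 1-based inclusive bp as in PLINK MAP files.
Chromosome X is loaded and appears in map summaries, but is excluded from
ROH and LD, which are defined on the 18 autosomes; no sex-aware recoding of
male X heterozygotes is attempted.

QC retains SNPs with per-SNP call rate ≥ 0.95 (over all samples) and pooled
MAF ≥ 0.05, both inclusive. MAF for QC is computed over all breeds pooled:
the filter defines one common post-QC panel before any per-breed analysis;
within-breed MAF is a diversity statistic, not a filter. Removal reasons
are logged per SNP (call rate checked first).

## Diversity statistics

Per breed and SNP: allele frequency f from non-missing calls, MAF =
min(f, 1−f), H~O~ = heterozygote fraction, H~E~ = 2f(1−f). H~E~ carries no
small-sample correction by default, matching common SNP-chip reporting; a
`2n/(2n−1)` correction sits behind `unbiased = TRUE`. Breed means are taken
over the common post-QC panel: SNPs monomorphic within a breed enter as
MAF 0 / H~O~ 0 / H~E~ 0 rather than being dropped, because the competing
convention (drop them) makes means incomparable across breeds typed on one
chip; `drop_monomorphic = TRUE` computes the other convention. SNPs with no
call at all in a breed are dropped from that breed's means with a logged
count. The within-breed distance is genotype IBS: per-SNP similarity 1,
0.5 or 0 (identical genotype / one shared allele / opposite homozygotes),
D~ST~ the mean over jointly called SNPs, D = 1 − D~ST~, and the breed value
the unweighted mean over all C(n,2) pairs.

## Runs of homozygosity

Defaults: ≥ 40 homozygous SNPs, span ≥ 1,000 kb, density ≥ 1 SNP/1,000 kb,
no internal adjacent-SNP gap > 1 Mb, ≤ 1 heterozygous and ≤ 5 missing calls
per run. These are the standard medium-density-chip criteria; at ~66 kb
marker spacing they make a qualifying run ≈ 2.6 Mb of consecutive
homozygosity, long enough that chance homozygosity is negligible.

The criteria define what a run is, not how to find one. PLINK's sliding
window is a heuristic whose output depends on window parameters; `breeddiv`
instead uses exact, deterministic semantics: a candidate run must start and
end on homozygous SNPs (het/missing edges are trimmed), and segments are
selected greedily left to right — at the leftmost admissible start, the
longest extension satisfying every criterion is emitted, then scanning
resumes after it. This makes the detector checkable against a brute-force
oracle that enumerates every homozygous-bounded interval (the acceptance
suite does exactly that on 500 random chromosomes), at the cost of not
reproducing PLINK byte-for-byte; ROH-derived quantities from window
scanners should be expected to agree only approximately. Segment length is
`end_bp − start_bp` (PLINK convention, no +1). F~ROH~ divides the summed
segment lengths by L~AUTO~, the SNP-covered autosomal span (sum over
autosomes of max − min position).

## LD and effective population size

r² is the squared Pearson correlation between dosage vectors over jointly
non-missing samples — genotypic (composite) LD, the natural choice when
phase is unknown and what SNP-chip pipelines compute by default. Pairs are
within-chromosome, autosomal, up to 5 Mb. Binning is upper-inclusive with
edges every 0.01 Mb to 0.05 Mb, every 0.05 Mb to 1 Mb, then per whole Mb to
5 Mb; "adjacent" pairs (consecutive SNPs) are summarized separately,
whatever their distance. Binning is done in integer bp so pairs landing
exactly on an edge are never misassigned by floating-point error.

Sved's equilibrium relation E[r²] ≈ 1/(1 + 4Nc) inverts to
Ne = (1/4c)(1/r² − 1). Current Ne uses the (0.95, 1] Mb bin (a flag
switches to the pair-weighted mean of all bins ≤ 1 Mb, the other reading of
"all 1 Mb bins"); the historical trajectory maps each bin midpoint d to
c = d·(cM/Mb)/100 Morgans and T = 1/(2c) generations ago. Physical distance
converts to genetic distance with one genome-average rate, `cm_per_mb`,
default 1.0 cM/Mb — the constant is study-specific and must be chosen
explicitly for real data (pig high-density maps average below 1); every Ne
scales as 1/`cm_per_mb`, so reported Ne is only as good as that constant.
Sample r² is biased upward by ≈ 1/n; `sample_correction = TRUE` subtracts
it before inversion (off by default, since most published chip analyses do
not correct). The acceptance suite shows the corrected estimator recovers a
simulated N = 50 within a factor of 1.5 after 150 generations — three
times the 1/(2c) = 50-generation timescale the 1 Mb bin looks back at; at
shorter histories the 1 Mb LD has not equilibrated and Ne comes out high.

## Differentiation

**F~ST~.** Weir & Cockerham (1984) variance components a (among
populations), b (among individuals within) and c (within individuals),
computed per SNP from sample sizes, allele frequencies and observed
heterozygote frequencies, r = 2 populations. The headline value is the
weighted ratio of sums Σa/Σ(a+b+c) — the estimator PLINK reports — with
the unweighted mean of per-SNP ratios also returned, since the two can
differ noticeably and publications rarely say which they used. Negative
per-SNP components stay in the sums; only the final reported value is
clamped at 0. SNPs where either breed has no call, or with fewer than
three called genomes total, are skipped.

**Distances and the tree.** Chip genotypes are not sequences, so a
convention is needed to feed a nucleotide-distance model: each breed is
collapsed to a consensus sequence — majority allele per SNP, IUPAC
two-base code on an exact 50/50 tie, `-` when untyped. Ambiguity codes and
gaps are then removed by pairwise deletion, which is exactly how
MEGA-style pipelines treat them; a per-individual concatenation mode is
deliberately not implemented (it changes the question from between-breed to
between-individual distance). The Tajima–Nei (equal-input) distance is
d = −b·ln(1 − p/b) with b = (1 − Σg²ᵢ + p²/h)/2 and
h = Σ_{i<j} x²ᵢⱼ/(2gᵢgⱼ) over the differing-site pair patterns; with equal
base frequencies b = 3/4 and the formula collapses to Jukes–Cantor, which
the tests verify to 1e−9. Saturation (p ≥ b) is an explicit error, not an
NA.

Neighbour-joining is implemented from scratch (Q-matrix minimization,
standard branch-length and reduction formulas, final 3-taxon star
resolution) with lexicographic tie-breaking for determinism. On additive
matrices NJ is exact, and the acceptance suite demands exact recovery of 50
random 6–10-taxon trees. Negative branch lengths — possible on non-additive
input — are clamped to 0 with the deficit moved to the sister branch so
path lengths are preserved as far as possible; clamp counts are recorded.

## PCA

Dosages are mean-imputed per SNP, centered by 2f and scaled by √(2f(1−f));
the eigendecomposition of the resulting GRM gives scores (eigenvectors ×
√eigenvalue). Variance fractions are computed against the sum of **all**
positive eigenvalues — the mathematically honest denominator — while the
top-K renormalization, which published "variance explained" percentages
often actually use, is returned alongside (`variance_fractions_topk`).
Signs are fixed by making each eigenvector's largest-magnitude entry
positive. SNPs fixed in the pooled sample are dropped before scaling; no LD
pruning is applied, matching standard chip-study practice.

## The simulator: what a green test does and does not establish

`simulate_breeds` is a discrete-generation diploid Wright–Fisher model:
founder haplotypes drawn in linkage equilibrium from a uniform MAF law on
[0.05, 0.5] (the chip's ascertained spectrum), Poisson recombination at a
uniform `cm_per_mb`, random mating with selfing allowed, breed splits
copying the ancestral gene pool through one WF draw, optional admixture
pulses (each parent of the target drawn from the source with probability
α) and optional missingness (default 1%) injected afterwards to exercise
QC. There is **no mutation** — standing variation only — which keeps drift
expectations closed-form: E[F~ST~] = 1 − (1 − 1/2N)^t, He decay
(1 − 1/2N) per generation, allele-frequency martingale. Defaults state the
emulated world: 12 breeds, N = 100, 50 generations, 30 samples each, 18
autosomes × 2,222 SNPs at ~66 kb spacing. Tests run scaled-down genomes
(hundreds of SNPs, 1–6 chromosomes) purely for runtime; the processes are
identical.

`simulate_inbred_line` breeds a closed full-sib line from an outbred
couple; pedigree F follows F_t = ¼(1 + 2F_{t−1} + F_{t−2}), so t = 1..4
gives 0.25, 0.375, 0.5, 0.59375, and realized autozygous tracts provide
ground truth for ROH detection.

What the simulator does **not** emulate: ascertainment bias beyond the
founder MAF law, genotyping error (only missingness), non-uniform
recombination, selection, overlapping generations, sex chromosomes, and
real pig demography. A green simulation test therefore establishes that
the estimators recover the parameters of an idealized WF world — not that
any particular real-data value is right. Real-data caveats that remain:
the recombination-rate constant dominates Ne; ROH window heuristics differ
between tools; consensus-sequence distances compress within-breed
variation.

## Numerical choices and degenerate inputs

* QC on an all-failing panel, PCA without polymorphic SNPs, F~ST~ without a
  positive denominator SNP, NJ on asymmetric input, distances without
  jointly called sites — all explicit errors, never silent NA/0.
* Single-SNP chromosomes report undefined (NA) spacing, excluded from the
  grand mean; single-sample breeds report SD 0 with `sd_defined = FALSE`.
* Overlapping ROH segments passed to `froh` raise an error: the detector
  can never produce them, so they indicate foreign or corrupted input.
* `apply_qc` is idempotent and never alters surviving genotype values.
* Seeded runs are byte-identical end to end (`run_all` writes a manifest
  with parameters, seed and input checksums sufficient to re-run).

## Open choices resolved here

* Current-Ne bin: the (0.95, 1] Mb bin by default, "all pairs ≤ 1 Mb"
  behind a flag — both defensible readings of common usage.
* Table-style means include breed-monomorphic SNPs (flag for the converse).
* PCA variance denominators: both all-positive and top-K reported.
* Consensus (not per-individual) sequences feed the distance/tree stage.
* He uncorrected by default; 1/n LD correction off by default.
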