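---
title: "Methods: discriminating stable nucleosomes by chromatin marks and DNA sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminating stable nucleosomes by chromatin marks and DNA sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `nucleoclass`, the
assumptions it makes, the parameters that matter, and the design decisions
taken where several reasonable choices existed. It states no empirical
result beyond what the package's own tests and `scripts/acceptance.R`
compute.

## The problem and the data model

A *stable* nucleosome sits at roughly the same chromosomal coordinate
across the cell population, so its ChIP-Seq reads pile up into a peak.
Single-end reads (25 bp by default in the generator; the pipeline uses
whatever length the BED interval records) are assumed to start at the
fragment 5' end: `+`-strand reads upstream of the nucleosome's 5' edge,
`-`-strand reads downstream of its 3' edge. Extending every read 150 bp in
its 3' direction — the mononucleosomal fragment length — therefore stacks
both strands' reads over the nucleosome. This geometry is the basis of the
caller and of the synthetic generator, and it is why the strand ratio
`s = max(n+, n-)/min(n+, n-)` of read starts inside a true nucleosome peak
is near 1.

ChIP-Seq is an enrichment, not a purification, and most reads are
background. The pipeline therefore (i) collapses PCR duplicates — one read
per `(chrom, start, strand)` key, the 5'-end criterion that is exact for
fixed-length single-end data; (ii) equalizes unique-read depth across
samples by seeded uniform down-sampling to the smallest sample, because
peak detectability scales with depth; and (iii) only analyses peaks with
statistically significant enrichment over the genome-wide background.

## Nucleosome calling

Per chromosome the caller builds a per-bp extended-read pileup, denoises
it, and takes peak edges from a Laplacian-of-Gaussian (LoG) filter: a peak
is a maximal run of negative filter response (negative curvature between
two zero-crossings) containing non-trivial signal.

Tunable parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `denoise_method` | `"wavelet"` | stationary (a-trous, B3-spline) wavelet shrinkage; `"gaussian"` kernel smoothing is the alternative. Both satisfy the same contract: non-negative output, constants preserved, total signal conserved to well under 1%, resolved peaks kept distinct. |
| `levels` | 4 | wavelet depth; detail planes up to 2^4 bp scale are thresholded at 3 robust (MAD) SDs. |
| `log_sigma` | 30 bp | Gaussian scale of the LoG filter. At 20 bp the curvature estimate tracks plateau-top counting noise and can split a single ~150 bp pileup into fragments; 30 bp is wide enough to bridge that noise yet narrow enough to separate nucleosomes ≥ 300 bp apart. |
| `width_min`, `width_max` | 80, 250 bp | raw-width quality bounds. |
| `max_strand_ratio` | 3 | peaks with one empty strand get `s = Inf` and always fail. |
| `alpha` | 1e-5 | per-peak (unadjusted) Poisson threshold. |

The enrichment test uses the upper-tail Poisson probability
`P(X >= k)` computed through the survival function (never `1 - CDF`,
which loses precision in the far tail; the unit tests check agreement with
a direct log-space series summation to 1e-10). The background rate for a
peak of raw width `w` is `lambda = n_reads * (w + 149) / L` on its
chromosome — the expected number of 150 bp-extended reads overlapping a
`w`-wide window if reads were uniform. This genome-wide-density definition
is a deliberate choice: the datasets this design targets have no mock-IP
control, so enrichment can only be measured against the sample's own
average density. `k` is the raw extended-read count within the raw
detected edges (not the denoised signal), so significance is judged on
observed reads.

Each accepted peak is reported as a canonical interval of width exactly
147 bp: `[mid - 73, mid + 74)` with `mid = floor((raw_start + raw_end)/2)`.
147 is odd, so the canonical interval is asymmetric by one bp on the 3'
side; the fixed convention makes outputs bit-reproducible. When two
canonical intervals from one sample overlap, the lower-p peak is kept —
stable nucleosomes are non-overlapping by definition.

## Modification overlap features

For each stable outcome nucleosome, each feature channel contributes the
count of deduplicated reads whose 5' end falls in a closed 101 bp window
(±50 bp) around the relevant canonical boundary: `+` reads at the 5'
boundary, `-` reads at the 3' boundary. "Maps within ±50 bp" is read as
the 5'-end coordinate falling in a closed window — the 5' end is the
mapped position of a single-end tag, and closed bounds make the edge cases
exact. Counts use deduplicated but not depth-normalized feature reads by
default (`preprocess_samples` output can be substituted to get the
normalized variant); counting reads rather than binary peak overlap keeps
the matrix dense.

## Discriminatory motif features

Motif features are built on two disjoint partitions to avoid data reusage:
a stratified discovery fraction `f = 0.2` of each class elicits the
motifs, and the withheld classification set receives the feature matrix.
Feeding discovery sequences into the matrix builder is a hard error, not a
warning.

Elicitation scores every k-mer (`k = 5..10`) observed in the discovery
sequences by the two-sample proportion z-statistic on per-sequence
*presence*, where a motif is present if it or its reverse complement
occurs (both strands are searched; a presence is counted once per sequence
regardless of strand or multiplicity). Presence, not count, drives the
score because 147 bp sequences make per-sequence counts noisy; counts are
used later, in the classification matrix, where abundance carries signal.
Candidates need support in at least 5% of one class's discovery sequences
(suppresses singleton noise words) and a non-zero z. Ranking is by `|z|`
descending with deterministic tie-breaks: total occurrence count, then
length, then alphabetical. Tied z-scores are common in strongly separated
data (every consensus-derived k-mer can be present in all positive and no
negative sequences), and breaking ties by abundance puts the most
tandem-repeated words — the consensus core — first. A candidate that is a
substring of an already retained motif (in either orientation) is dropped
as redundant; at most 300 motifs are returned.

Matrix entries are mismatch-tolerant match counts: windows of the motif's
length in the sequence and in its reverse complement at Hamming distance
≤ `M = 2`, overlapping windows all counted. `M` is global rather than
length-scaled; note that for `k = 5` a 2-mismatch criterion is extremely
permissive (most random windows match), so short motifs contribute mainly
through count contrasts rather than presence.

## Classification and importance

Classes are balanced by down-sampling the larger class to the smaller one
(seeded), and every reported performance number is the mean over 10
balanced repeats. The forest uses `n_tree = 500` and
`m_try = floor(sqrt(p))` (floor is the conventional integerization).
Accuracy is `1 - OOB error`; auROC is computed from OOB class-vote
fractions by the midrank formula, which is exactly the trapezoidal
interpolation through tied vote values and reaches 1.0 exactly in the
separable case. Importance is the mean decrease in Gini index averaged
over repeats, annotated with the direction (class with higher mean feature
value).

Permutation significance refits the forest on label-permuted copies and
uses the add-one estimator `p = (1 + #{permuted >= observed}) / (1 + B)`,
which is conservative and can never return zero; Bonferroni adjustment
multiplies by the number of features. The default `B = 1000` with
100-tree refits keeps a full run in the minutes range; `B` and
`perm_n_tree` are plain configuration knobs for users who want finer
floors (the attainable minimum p is `1/(B + 1)` by construction, so
resolving very small p-values requires proportionally many permutations).
Under a label-randomized null the estimator is calibrated: the acceptance
suite checks that the fraction of features with `p < 0.05` stays inside
the binomial band around 5%.

## Downstream satellite statistics

Repeat composition takes the union of a mark's canonical intervals and the
union of each family's annotation intervals before intersecting, so no bp
is double-counted; families must be disjoint in the annotation (asserted).
Occupancy aligns a family's instances by start and reports, per offset,
the fraction of instances covered there by at least one canonical
nucleosome of the mark, with the denominator restricted to instances long
enough to reach the offset. The scalar summary is the mean occupancy over
offsets up to the median instance length — a defined reduction chosen
because the full profile's natural single-number summary is its average
over the aligned region most instances share; the complete profile is
always returned so any other reduction can be recomputed. The TCCATT
occurrence histogram counts exact forward-strand overlapping matches on
the extracted nucleosome sequences.

## What the generator emulates, and what it does not

`synth_config()` defaults define the simulated study conditions used by
the tests and the acceptance script: one 300 kb chromosome; 14 satellite
II arrays (units of two `ATTCCATTCG` copies plus 1–2 `ATG`) and 5
satellite III arrays (7–13 `ATTCC` copies plus one `ATTCGGGTTG`),
satellite II dominant as it is in the pericentromeric genome; 50 planted
147 bp nucleosomes per class spaced ≥ 300 bp, positives inside satellite
arrays and negatives in background sequence; ~40 signal reads per
nucleosome with 5 bp 5'-end jitter; uniform background at 5e-4 reads/bp; a
6% per-read duplication probability (duplicate fraction ≈ 5.7%, mid
single digits as in typical early ChIP-Seq data); and a 3-fold spread of
per-sample depth multipliers. Consensus units are emitted uppercase (the
mixed case in the published consensus encodes conservation, not sequence,
and matching is case-insensitive anyway). Both classes get the same
read-count distribution, so classifiers cannot learn a depth artifact —
classes differ only in sequence context and feature co-localization.

The generator deliberately does not model mappability or GC bias,
chromatin-state segmentation, fragment-length variation, or a structured
(non-uniform) background; real ChIP-Seq background is not uniform, and no
mock-IP sample exists in the targeted datasets to estimate it from.
Passing tests on this generator therefore demonstrate correctness of the
pipeline's logic and calibration of its statistics under the stated
assumptions — not performance on real data, where background structure
and repeat mappability would matter. Note also that one planted duplicate
mechanism (PCR re-emission) is not the only source of coincident reads:
dense jittered pileups collide at the same start by chance, and the
deduplicator collapses both kinds, exactly as it would on real data.

## Degenerate inputs and numerical conventions

All coordinates are 0-based half-open internally; BED round-trips are
identities. Reads with `.` strand are rejected (strand-specific scoring is
undefined without strand). Empty samples cannot be depth-normalized (no
meaningful minimum). A constant-label matrix cannot be fit. An empty
repeat-instance set has no occupancy profile. Motifs longer than the
sequence match zero times (not an error). `sd` over a single balanced
repeat is reported as `NA` rather than 0. Problem sizes throughout the
tests (300 kb genome, 100 nucleosomes, 10 repeats, 1000 permutations)
were chosen so the statistics they check are well-resolved at desk scale;
the vignette's parameter table and `synth_config()` defaults record them.
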