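# nucleoclass

Some chromatin marks are mutually exclusive at the level of a single
nucleosome: the histone variant H2A.Z lacks the arginine-3 site carried by
canonical H2A/H4, so a nucleosome cannot bear both H2A.Z and the symmetric
dimethylation H2A/H4R3me2s. That makes the pair a clean two-class problem:
which other histone modifications, and which DNA sequence features,
discriminate stable nucleosomes carrying one mark from those carrying the
other? `nucleoclass` implements the complete analysis for this question
from aligned ChIP-Seq reads (BED), a genome (FASTA) and repeat annotations
(BED), and ships a seeded synthetic-data generator so that every stage is
testable end-to-end without any external download.

The pipeline, for epigenomics/regulatory-genomics analysts:

1. **Pre-processing** — PCR duplicates are collapsed to one read per
   `(chrom, start, strand)` key, and samples are normalized to the lowest
   unique-read count by seeded down-sampling.
2. **Stable-nucleosome calling** (NPS style) — reads are extended 3' to
   150 bp (the mononucleosomal fragment length), the per-bp pileup is
   denoised (stationary wavelet shrinkage, or a Gaussian kernel), peak
   edges are the zero-crossings of a Laplacian-of-Gaussian filter, and
   peaks are kept only if width `80 <= w <= 250` bp, strand ratio
   `s = max(n+, n-)/min(n+, n-) <= 3`, and Poisson upper-tail
   `p <= 1e-5` for the read count against the genome-wide background rate.
   Each surviving peak is reported as a canonical 147 bp interval centered
   on the raw midpoint.
3. **Histone-modification features** — for each stable nucleosome, a
   37-entry array counts deduplicated feature-channel reads whose 5' ends
   fall within ±50 bp of the relevant boundary, strand-specifically (`+`
   reads at the 5' boundary, `-` reads at the 3' boundary).
4. **DNA sequence features** — a discriminatory-motif scheme on two
   disjoint partitions: motifs of length 5–10 are elicited on a discovery
   set (20% of sequences) by a two-sample proportion z-statistic on
   per-sequence presence (both strands), and mismatch-tolerant
   (Hamming ≤ 2) match counts are built on the withheld classification
   set. Discovery/classification leakage is a hard error.
5. **Classification** — balanced random forests (`n_tree = 500`,
   `m_try = floor(sqrt(p))`), with the larger class down-sampled to the
   smaller and performance averaged over 10 balanced repeats of the
   out-of-bag (OOB) accuracy and auROC. Feature importance is the mean
   decrease in Gini index (MDG); its significance comes from refitting on
   label-permuted data, with the add-one estimator
   `p = (1 + #{permuted MDG >= observed}) / (1 + B)` and Bonferroni
   adjustment.
6. **Satellite analysis** — occurrence histograms of a motif of interest
   (TCCATT, part of the satellite II/III consensus), the fraction of
   stable-nucleosome-bound bp annotated to each repeat family, and
   *occupancy*: at each offset of start-aligned satellite instances, the
   fraction of instances covered there by a stable nucleosome of the mark.

## Worked example

```r
library(nucleoclass)

cfg <- synth_config(seed = 1)   # 300 kb genome, satellite II/III arrays,
                                # 50 planted nucleosomes per class
res <- run_pipeline(cfg)

ev <- res$evaluations$modification
sprintf("OOB accuracy %.1f%% +/- %.1f%%, auROC %.3f",
        100 * ev$accuracy_mean, 100 * ev$accuracy_sd, ev$auroc_mean)
head(res$importance$modification, 3)
head(res$motifs, 3)
res$occupancy
```

Output from the run above:

```
stable nucleosomes: 50 positive-mark, 50 negative-mark
modification features: OOB accuracy 99.0% +/- 0.7%, auROC 1.000
top features by mean decrease in Gini:
    feature        mdg           p p_adjusted
1  H4K20me3 21.9148658 0.004975124  0.1840796
2   H3K9me3 21.3104466 0.004975124  0.1840796
3 H2BK120ac  0.5311747 0.587064677  1.0000000
top motifs:
      motif        z direction
1    TCCATT 4.472136  positive
2    CCATTC 4.472136  positive
3 GATTCCATT 4.472136  positive
TCCATT present in 100% of positive vs 2% of negative sequences
          mark        family occupancy n_instances
1 H2A.H4R3me2s  satellite II 0.2901830          14
2 H2A.H4R3me2s satellite III 0.2468696           5
3        H2A.Z  satellite II 0.0000000          14
...
```

Reading this: the two channels planted to co-localize with the positive
mark (H4K20me3 at intensity 10, H3K9me3 at 6) dominate the Gini importance
ranking and reach the smallest p-value the permutation count allows; the
elicited motifs are fragments of the satellite II consensus unit (TCCATT
first); and satellite arrays are occupied by stable positive-mark
nucleosomes (occupancy ≈ 0.29 over aligned satellite II instances) but not
at all by the negative mark.

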