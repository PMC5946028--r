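# mirtrans

Genome-wide correlation analysis between transcriptional activity and
mature microRNA expression.

## The problem

miRNA biogenesis starts with transcription (usually by RNA polymerase II)
of a long primary transcript, followed by extensive processing (DROSHA,
DICER) down to the ~22-nt mature miRNA. How much of the variation in mature
miRNA levels across a genome is set by transcription, and how much by
processing? Because miRNA gene structures are mostly unknown, the practical
proxy is: take each pre-miRNA stem-loop, extend its coordinates by a window
*k* (1–20 kb on both the 5′ and 3′ sides), collect the Pol2 ChIP-seq peak
signal (both DNA strands) or mRNA abundance (miRNA-coding strand only)
overlapping the extended segment by at least one nucleotide, aggregate per
locus (sum, or max), and correlate the aggregate with mature miRNA
abundance (5p + 3p combined) across loci.

`mirtrans` implements that pipeline for R users working with processed
peak calls (BED/narrowPeak), miRBase-style GFF3 stem-loop annotation,
pri-miRNA coordinate tables, and quantification TSVs — plus a
synthetic-data generator with known ground truth so every stage can be
validated without external downloads.

## The statistics

For paired vectors (x_i, y_i) over n miRNA loci:

- **Spearman rank correlation** ρ: Pearson correlation of midranks, with a
  two-sided p-value from t = r·√((n−2)/(1−r²)) on n−2 df.
- **Weighted Pearson** with frequency-weight semantics:
  r_w = Σw(x−x̄_w)(y−ȳ_w) / √(Σw(x−x̄_w)² · Σw(y−ȳ_w)²), effective
  n = Σw. Weights come from miRBase-style expression evidence (w1 =
  stem-loop reads, w2 = reads per million, w3 = mature reads), so likely
  genuine miRNAs count more.
- **Attenuation (disattenuation) correction** from replicates:
  ρ̂ = r̄_xy / √(r_xx · r_yy), where r̄_xy is the mean of the four
  replicate cross-pairings and r_xx, r_yy are replicate–replicate
  reliabilities.
- **Mann–Whitney U** (tie-corrected normal approximation) to contrast
  "early" miRNAs (miRBase family number below a cut-off; discovered early,
  more likely genuine) against "late" ones.
- **Hierarchical clustering** of per-sample correlation profiles
  (euclidean, 1−Pearson, or 1−uncentered-correlation distances; single /
  average / complete linkage), serialized as Newick.

## Worked example

```r
library(mirtrans)

smp <- simulate_mirna_sample(seed = 1)
smp
#> Synthetic miRNA-transcription sample
#>   1500 loci (600 early, 900 late) on 4 chromosomes; seed 1
#>   2 replicates; 4790 peaks, 2158 transcripts per replicate

# link host-strand mRNA signal within 10 kb of each early pre-miRNA
early <- apply_number_cutoff(smp$loci, 1000)$early
ext <- extend_intervals(early, 10000, smp$chrom_sizes)
linked <- link_signals(ext, smp$transcripts[[1]], strand_mode = "match", agg = "sum")
pairs <- build_paired_vectors(linked, smp$mirna_quant[[1]])
cor_spearman(pairs$x, pairs$y)
#> spearman correlation: r = 0.333, n = 600, two-sided p = 5.31e-17

# the same correlation over all miRBase-style entries flips sign
ext_all <- extend_intervals(smp$loci, 10000, smp$chrom_sizes)
pairs_all <- build_paired_vectors(
  link_signals(ext_all, smp$transcripts[[1]], strand_mode = "match", agg = "sum"),
  smp$mirna_quant[[1]])
cor_spearman(pairs_all$x, pairs_all$y)
#> spearman correlation: r = -0.1583, n = 1500, two-sided p = 7.135e-10

# why: late-numbered loci are strongly transcribed but barely matured
compare_early_late(smp, window_kb = 10, cutoff = 1000)$mirna
#> Mann-Whitney U = 487128, two-sided p = 8.265e-154
#>   group a: mean 85.5 +/- 12.1 (n = 600)
#>   group b: mean 6.773 +/- 1.46 (n = 900)
```

The early subset correlates positively with local transcription (r = 0.33)
while the pooled set correlates negatively (r = −0.16): the late loci sit
in strongly transcribed regions yet produce almost no mature miRNA, so
they invert the pooled trend — exactly the situation the number cut-off,
pri-miRNA and weighting filters are designed to expose.

Replicates allow correcting the observed correlations for measurement
noise:

```r
ra <- replicate_analysis(smp, window_kb = 20, filter = "all")
#  rna raw mean -0.159, reliabilities 0.919 / 0.969, corrected -0.168
```

The end-to-end driver `run_pipeline(run_config(...))` sweeps windows
{1, 2, 5, 10, 20} kb × filters {all, cut-offs, pri-miRNA} × methods
{Spearman, Pearson, weighted Pearson (w1–w3)} over both track types,
writes TSV/Newick outputs, and clusters multi-sample correlation profiles.

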