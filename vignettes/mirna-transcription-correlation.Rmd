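---
title: "Methods: correlating transcription with mature miRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlating transcription with mature miRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrans)
```

## The analysis

Mature miRNA abundance is the product of transcription and processing.
To ask how much transcription explains, the pipeline correlates two
proxies of transcriptional activity around each miRNA locus — Pol2
ChIP-seq peak signal and overlapping mRNA abundance — with mature miRNA
abundance (5p + 3p combined per stem-loop), across all loci of a sample.

Because miRNA gene structures (promoters, transcript boundaries) are
mostly unknown, the locus is defined operationally: the pre-miRNA
stem-loop coordinates are extended symmetrically by a window $k$ on both
sides in genomic coordinates, and any feature sharing at least one
nucleotide with the extended segment is attributed to the locus. The
strand rules differ by track: ChIP-seq peaks count on both DNA strands
(ChIP is unstranded and polymerase occupancy is the quantity of
interest), while transcripts count only on the miRNA-coding strand
(antisense RNA is not evidence of pri-miRNA transcription). Features with
undefined strand are skipped (and tallied) under the matching rule rather
than treated as matching — the conservative reading. Per locus, feature
signals are summed by default; the maximum is selectable and bounded
above by the sum for non-negative signals. Where pri-miRNAs have been
experimentally mapped, their intervals replace the pre-miRNA anchor:
mRNA overlap can then be searched on the raw pri interval, Pol2 overlap
on its extension.

Two deliberate simplicities are inherited from the design this package
operationalizes: overlap is naive (1 bp suffices; no promoter calling or
peak-to-gene assignment), and extension is symmetric in genomic
coordinates, not strand-oriented — extending "both the 5′ and 3′
directions" by the same distance is the same set of base pairs either
way.

## Stratifying miRNAs

miRBase accumulated entries over time; later (higher-numbered) entries
are enriched for poorly expressed, weakly conserved RNAs that may not be
genuine miRNAs. Three devices separate the signal:

* **Name-number cut-off.** The family number is parsed from the miRBase
  name (`hsa-mir-21` → 21; letter variants and copy suffixes such as
  `-302a` or `-124-2` are ignored; `let` families parse the same way).
  The "early" group is *strictly below* the threshold. Cut-offs are
  monotone: lowering the threshold only removes loci.
* **pri-miRNA evidence.** Keep only loci with an experimentally
  determined primary transcript (and number below 1000), and link over
  the pri interval. Note that this filter swaps in intervals with a
  median length of ~41 kb, so its linked sample size can *exceed* the
  all-miRNA count at small windows even though its candidate set is
  smaller.
* **Expression weighting.** Instead of excluding entries, weight each
  miRNA in a Pearson correlation by miRBase-style expression evidence:
  w1 = total stem-loop deep-sequencing reads, w2 = normalized reads per
  million, w3 = mature-miRNA reads (5p + 3p). A paired miRNA without a
  weight is an error, never a silent zero.

## Statistics

* Spearman is the Pearson correlation of midranks; Pearson is computed on
  raw values. Both report two-sided p-values from the $t$ approximation
  ($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df) — the exact small-sample
  permutation p-value is not used. $|r| = 1$ reports $p = 0$; a constant
  input yields an NA coefficient with an explanatory flag, never a silent
  zero. Significance is read at $p < 0.05$.
* Weighted Pearson uses frequency-weight semantics: effective
  $n = \sum w$ and $df = \sum w - 2$, so integer weights reproduce
  exactly the unweighted Pearson of the case-replicated data set. An
  option rescales weights to sum to $n$ for sensitivity analysis; weights
  are used unrounded by default.
* Attenuation correction divides the mean observed cross-correlation
  (arithmetic mean over the four replicate pairings) by
  $\sqrt{r_{xx} r_{yy}}$. The estimator is derived for Pearson
  correlations; applying it to Spearman coefficients is an approximation
  used knowingly. Corrected values beyond $\pm 1$ are reported as-is with
  an `out_of_range` flag. Non-positive reliabilities are an error.
* Mann–Whitney U counts pairs won plus half the ties, with the
  tie-corrected normal approximation and continuity correction; when both
  groups are entirely tied the variance is zero and $p$ is reported as 1.
  Group means and standard errors of the mean accompany the test.
* Clustering distances are euclidean, $1 -$ Pearson, or $1 -$ uncentered
  correlation (default, with average linkage — the customary Cluster 3.0
  settings; all combinations are selectable because the original choice
  is not documented). Samples are sorted lexicographically before
  agglomeration so merges are deterministic; trees serialize to Newick
  and to a merge table.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with emitted ground truth. Per locus $i$:

$$\log T_i \sim N(\mu_{group}, \sigma_T), \quad E_i \sim \mathrm{Beta},
\quad M_i = T_i E_i \varepsilon_i, \quad A_i = T_i \eta_i$$

with $\log\varepsilon, \log\eta \sim N(0, \sigma_{bio})$; each replicate
observes log-values plus $N(0, \sigma_{meas})$. All noise is
multiplicative lognormal because abundances are non-negative and
heavy-tailed. Defaults (frozen as the package's study conditions):

| parameter | default | meaning |
|---|---|---|
| n_early / n_late | 600 / 900 | early and late locus counts |
| number_cutoff | 1000 | family-number boundary encoded in names |
| pri_length_median | 41 kb | lognormal pri length (human-like; 36 kb mouse preset) |
| mu_logT early / late | 3.0 / 5.0 | late loci are more strongly transcribed |
| sd_logT | 1.0 | spread of latent transcription |
| eff early / late | Beta(8,2) / Beta(0.3,40) | processing efficiency ≈ 0.8 vs ≈ 0.007 |
| sigma_bio | 1.5 | biological noise (log sd) |
| sigma_meas | 0.6 | per-replicate measurement noise (log sd) |
| peaks_lambda, sigma_share | 2, 1.0 | extra peaks per locus; unevenness of their signal shares |

The group asymmetry — late loci transcribed more but matured almost not
at all — makes the pooled mRNA~miRNA rank correlation negative
(≈ −0.2 at defaults, within the −0.1 to −0.3 range typical of tissue
panels) while the early subset is positive (≈ +0.3), so the number
cut-off visibly "rescues" the correlation. Measurement noise was set so
replicate–replicate rank correlations fall in the 0.84–0.98 band
expected of well-run consortium data.

Pol2 peaks deserve a note. Each locus receives one peak over the
stem-loop region itself (travelling-polymerase occupancy) plus a
Poisson number of additional peaks placed uniformly across the pri-miRNA
span; per-peak signals are uneven lognormal shares of the locus total
(which tracks $T_i$). Narrow extension windows therefore capture a noisy
fraction of the locus signal and wide windows recover it completely, so
the mean correlation grows with the window — the capture mechanism behind
the window-extension trend. The stem-loop peak keeps every locus linked
at every window, which stabilizes the compared sample across windows.
This trend is a property of positively correlated subsets: on the pooled
set, whose latent correlation is negative, better capture makes the
correlation more negative, so the trend is evaluated on the cut-off
subset.

Decoys exercise the strand rules: a fraction of loci get an antisense
transcript, and background peaks/transcripts are scattered at random
positions.

**What the generator does not emulate.** Real genomes have clustered and
overlapping miRNAs sharing a pri-miRNA, cell-type-specific gene
structures, non-uniform chromatin background, and peak callers'
artifacts; miRNA names here encode the group by construction, whereas
real late-numbered entries are only enriched for misannotation. Passing
tests therefore validate the pipeline's statistical machinery and its
qualitative mechanisms, not quantitative claims about any real sample.

## Numerical and design choices

* Coordinates are 0-based half-open internally (BED convention); GFF3
  converts on read/write. Round-trips are exact for integer coordinates;
  signals are written with fixed 4-decimal formatting.
* narrowPeak signal is column 7 (signalValue); plain BED falls back to
  the score column under a reader option. Duplicate ids in a
  quantification file are an error (silent summing would double-count).
* Loci with no overlapping feature are dropped rather than scored 0
  (an option keeps them at 0); zero-abundance miRNAs are kept — rank
  correlation tolerates ties at zero — with an option to drop.
* Pairing restricts to miRNAs present in both inputs, ordered
  lexicographically; correlations require $n \ge 3$ and fail there, not
  at pairing.
* The whole pipeline is deterministic given config + seed: identical
  runs produce byte-identical output tables.
* Problem sizes used by the test-suite and the acceptance script: unit
  tests run on 150-locus genomes; end-to-end properties use the default
  1500-locus sample, with 10 seeds for the window trend and 20 seeds for
  the replicate band and attenuation recovery (n = 500 per axis).

## Known limitations

* Raw-scale Pearson on lognormal abundances is dominated by the extreme
  tail; single samples can show weighting lowering the coefficient even
  though the expression-weighted correlation is higher on average (the
  acceptance script reports the 20-seed mean lift). Rank correlation is
  the robust primary statistic.
* The attenuation estimator applied to Spearman coefficients is an
  approximation; for strongly non-normal data the corrected value is
  indicative, not exact.
* Multi-copy pre-miRNAs overlapping the same extended window are emitted
  one record per locus entry; whether signals should be deduplicated
  across copies is ambiguous and left to the caller.
* No multiple-testing correction or confidence intervals are produced;
  p-values are raw and two-sided.
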