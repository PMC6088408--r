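---
title: "Correcting gene-independent depletion in pooled CRISPR-KO screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting gene-independent depletion in pooled CRISPR-KO screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenseg)
```

## The problem

In a pooled CRISPR-Cas9 knockout screen, each cell receives one single-guide
RNA (sgRNA) from a genome-wide library; cells carrying guides that knock out
fitness-essential genes drop out of the population, and the change in guide
abundance between the sequenced endpoint and the plasmid library — the log2
fold-change (logFC) — measures each gene's fitness effect. The readout is
confounded by a *gene-independent* response: Cas9 cutting itself is toxic in
proportion to the number of target loci, so guides falling in copy-number
amplified regions deplete regardless of whether their target genes do
anything. Left uncorrected, this inflates false positive fitness genes
precisely in the amplified regions that are most interesting in cancer
models.

screenseg removes this bias without requiring copy-number data. The premise:
true fitness effects are properties of individual genes, so a *contiguous
genomic stretch* in which guides targeting several adjacent genes share one
depletion level is biologically implausible as a gene-driven signal and far
more plausible as a regional artefact. The method therefore

1. orders replicate-averaged sgRNA logFCs by genomic coordinate,
2. segments each chromosome into stretches of statistically equal logFC
   with circular binary segmentation (CBS),
3. centers every segment whose guides collectively target at least
   `min_genes` distinct genes (default 3), and
4. optionally back-transforms corrected logFCs into replicate-level read
   counts for downstream mean-variance callers.

## Pre-processing model

Counts are filtered (guides with fewer than 30 plasmid reads are dropped;
the inequality is strict) and normalised by the median-ratio method: one
batch per screen comprising the plasmid column and all treatment
replicates; the size factor of sample $j$ is
$s_j = \mathrm{median}_i\, k_{ij} / g_i$ with $g_i$ the geometric mean of
guide $i$ across all samples, the median running over guides with $g_i > 0$.
Per replicate, $\mathrm{logFC}_i = \log_2\!\big((t_i + \varepsilon)/(c +
\varepsilon)\big)$, then averaged across replicates. The pseudocount
$\varepsilon$ (default 0.5) only matters for treatment dropouts that survive
the plasmid filter; set `pseudocount = 0` to disable it.

## Segmentation

For an ordered chromosome vector $x_1,\dots,x_m$, CBS compares every
circular arc $(i, j]$ against its complement with a pooled-variance
two-sample $t$ statistic and asks whether the best-separating arc is
stronger than chance. A useful identity drives the implementation: with
$R_\ell$ the partial-sum bridge of $x$, the between-group sum of squares of
the arc of width $k = j - i$ is

$$B(i,j) = \frac{(R_j - R_i)^2\, m}{k\,(m-k)},\qquad
  t^2 = \frac{B\,(m-2)}{C - B},$$

where $C$, the total centred sum of squares, is invariant under
permutation. $t^2$ is strictly increasing in $B$, so both the arc search
and the permutation comparison operate on $B$. The search over all
admissible $(i,j)$ is exact; since $(R_j - R_i)^2$ can never exceed the
squared range of the bridge, widths are visited from the admissible edges
inward (where the weight $m/(k(m-k))$ is largest) and the scan stops as
soon as no remaining width can alter the outcome. This pruning changes no
result — the tests verify equality with exhaustive enumeration — but makes
10,000-permutation runs on thousand-guide chromosomes take seconds.

A split is accepted when the permutation p-value of the maximal $|t|$ falls
below `alpha` (default 0.01, with 10,000 permutations and at least 2
markers per resulting piece); accepted arcs convert to one or two linear
change-points and the pieces are segmented recursively. The permutation
loop stops early only when the verdict is decided: non-significance is
certain once exceedances reach $\lceil \alpha (n_{\mathrm{perm}}+1)\rceil$
(the final p-value can no longer fall below `alpha`), and significance is
declared once the 99.99% Clopper–Pearson upper bound on the p-value drops
below `alpha`, never before 500 permutations. Setting `early_stop = FALSE`
forces the full run. All permutations draw from R's RNG, so a seed in
`cbs_params()` makes whole-genome runs bit-reproducible. No outlier
smoothing or split-undoing is applied; borderline extra splits are
inexpensive because the correction step re-centers each piece
independently and the minimum-genes gate still protects single-gene
signals.

## Correction

Within each accepted segment the number of *distinct* target genes is
counted (case-sensitive symbols). Segments with at least `min_genes = 3`
genes are centered: the segment mean (or median, with `center = "median"`
for outlier-heavy data) is subtracted from every member guide. Everything
else is untouched — corrected profiles are bit-identical to the input
outside corrected segments, and a second application with the same
segments is a no-op. The default is fully unsupervised: no essential genes
are pre-filtered. `choose_min_genes()` reproduces the adaptive calibration
over candidate thresholds $\{2, 3, 5, 10\}$, with and without removing a
filter set of a priori essentials, scoring each trial by the reduction in
area under the recall curve for amplified and amplified-non-expressed
genes versus an essential test set.

Because centering acts on whole segments, an essential gene sitting alone
in its own segment (its ~5 guides strongly depleted, flanks flat) has only
1 distinct gene and is never corrected; this is the mechanism by which
true signal survives.

## Corrected counts

Downstream callers that model count mean-variance need counts, not logFCs.
For a guide with plasmid count $c$, corrected logFC $N$ and uncorrected
replicate counts $t^*_1,\dots,t^*_n$ summing to $T^*$:

$$t_i \;=\; n\, c\, 2^{N}\, \frac{t^*_i}{T^*},$$

which fixes the replicate mean at $c\,2^N$ while preserving the observed
replicate proportions; when $T^* = 0$ the mean is split equally. Note the
derivation equates a mean of logs with the log of a mean, which is exact
only for equal replicates; `roundtrip_check()` reports the resulting
deviation — $\log_2(\mathrm{AM}/\mathrm{GM})$ of the replicate
proportions — rather than hiding it. Counts are emitted as reals
(`round_counts = TRUE` for integral output) and are intended to be passed
downstream with re-normalisation disabled.

## Depletion calling and diagnostics

Items ranked by increasing logFC are classified against gold-standard
essential ($E$) and non-essential ($N$) sets. Scanning control items only,
$\mathrm{PPV}(k) = |P(k)\cap E| / |P(k)|$; $k^*$ is the largest rank with
$1-\mathrm{PPV}(k)\le \mathrm{FDR}$ (default 0.05), $F^*$ the logFC at that
control rank, and every library item with logFC strictly below $F^*$ is
called depleted. The strict inequality means the $F^*$-defining control is
itself never called; with realistic set sizes the 5% budget carries $k^*$
past the last essential so the boundary effect is at most one gene.
Gene-level calls average guide logFCs per gene first.

Recall curves over the full ranking (area by trapezoid; ~0.5 for
uninformative scores), AURC reductions, and precision/recall areas for
top-$k$ pre-correction guides against the corrected ranking
(`profile_preservation()`) quantify correction impact. Two copy-number
diagnostics summarise bias when CN data are available: the *starting
point* (smallest CN > 2 whose segment mean-logFCs differ from CN = 2 by
Welch's t-test at $\alpha = 0.05$) and the *critical point* (the CN
maximising the absolute slope difference of least-squares fits to the
CN-response left and right of a candidate knee; candidates with fewer than
two distinct CN values on either side are skipped, and a sole surviving
candidate is returned flagged `weak`). For exactly piecewise-linear
continuous responses, the slope difference ties between the knee and the
CN below it — a property of the statistic, not a bug — so the package
reports the argmax and its strength, and the test fixtures use
flat-then-accelerating responses where the argmax is unambiguous.
`fitness_gene_impact()` accounts for attenuated (significant before, not
after) and distorted (significant both, opposite sign) genes, partitioning
attenuated loss-of-fitness genes sequentially into non-expressed
(FPKM < 0.05), amplified, prior-known non-essential and mild-phenotype
(above the upper quartile of loss-gene logFCs) classes.

## The synthetic test surface

`simulate_screen()` generates screens with known ground truth: genes tiled
in order along chromosomes (5 guides each), plasmid abundances drawn once
from a log-normal, true guide logFCs composed of an essential shift, a
regional bias shift and Gaussian noise, and treatment counts drawn
negative-binomially around `plasmid * 2^logFC` per replicate. The default
configuration — 2000 genes over 10 chromosomes, 3 replicates, 10% planted
essentials at −3, three 30-gene bias regions at −2, noise SD 0.25, NB
dispersion 0.05, ~1000 median plasmid reads per guide — was chosen to
resemble a genome-wide screen at 100× coverage compressed to desk scale;
its bias regions mimic the high-CN segments that motivate the method, and
its ground truth labels those genes amplified and non-expressed so every
evaluation operation has planted positives. What the generator does *not*
model: guide-efficiency heterogeneity, off-target cutting, GC/mappability
covariates, structural-variant mechanisms, or real inter-replicate
correlation structure. Passing tests on this surface demonstrate that the
algorithmic chain recovers what it is defined to recover, not that any
particular biological screen is bias-free after correction.

`worked_fixture()` is a 60-guide miniature (plasmid 160 everywhere,
treatments exactly `160 * 2^logFC`) whose normalisation, segmentation,
centering and count inversion all have closed-form expectations.

## Numerical choices and problem sizes

* Ordering ties in (chromosome, start) break by guide identifier;
  coordinates are 1-based and ordering uses the guide start only.
* Segments must contain at least `min_width = 2` markers; a length-1
  chromosome is one segment by construction.
* Corrected segment centers are zero to 1e-12 (asserted on every tested
  run); count inversion identities hold to 1e-9 relative.
* The test suite and the acceptance script use 10–20 simulated screens of
  the default 10,000-guide size for end-to-end checks, 200 pure-noise
  vectors of length 100 for calibration, and 50 three-block vectors of
  length 120 for change-point recovery; these sizes give stable aggregate
  metrics in a few minutes on one core while exercising every code path.

## Known limitations

* Permutation p-values make borderline splits seed-dependent by nature;
  the minimum-genes gate absorbs most of the practical consequences.
* The FDR threshold requires both control sets to be represented among
  scored items and is undefined otherwise (hard error).
* Median-ratio normalisation assumes most guides are unchanged; in the
  worked fixture, where 60% of guides sit in a biased region, the
  normalisation visibly re-centers on the biased majority — real
  genome-wide libraries are far from this regime.
* Corrected counts inherit the printed derivation's equal-replicate
  simplification; `roundtrip_check()` quantifies the gap.
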