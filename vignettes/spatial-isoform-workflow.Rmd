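---
title: "Methods: spatial isoform analysis from spot-barcoded long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial isoform analysis from spot-barcoded long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isospot)
```

# Overview

Spot-barcoded spatial transcriptomics captures polyadenylated RNA on a slide
of barcoded 55 µm spots; sequencing the same cDNA on a long-read platform
yields full-length transcripts but with per-base error rates high enough that
the 16-nt spatial barcode can no longer be read off directly. `isospot`
implements the computational chain needed to recover spatial isoform biology
from such hybrid designs:

1. **Barcode assignment** — anchor an adapter, match the downstream segment
   against the spot whitelist with error-tolerant alignment, and score the
   best candidate with a naive Bayes classifier trained on labeled simulated
   reads.
2. **Catalog handling** — merge externally assembled transcript catalogs into
   a non-redundant set and classify every transcript against a reference
   annotation with one-letter class codes, including retained introns and
   antisense overlaps.
3. **Quantification** — UMI-deduplicated transcript-by-spot count matrices
   with quality-control filters.
4. **Region statistics** — rank-sum markers per tissue region, Fisher
   enrichment of transcript classes (e.g. intron retention) between region
   sets, and isoform-diversity comparisons.
5. **Differential transcript usage (DTU)** — a quasi-binomial model of
   within-gene usage between regions, a screen-and-confirm procedure at a
   target overall false discovery rate (OFDR), and isoform-switch calling.

A first-class synthetic-data module generates every input with known ground
truth, so the full pipeline is testable without external data.

# Barcode assignment

## Model

Each read is expected to contain `adapter + barcode(16) + UMI(12) + poly-T +
cDNA`; barcode plus UMI plus one anchoring base fit the 29 bases that the
matched short-read design allocates to read 1. The adapter (default: a fixed
22-nt read-1 primer suffix, `DEFAULT_ADAPTER`) is aligned semi-globally
(adapter end-to-end, read ends free, unit costs) against both orientations of
the read; an identity of at least 0.7 (`1 - dist/22`) is required. The
barcode window starts immediately after the adapter. All whitelist barcodes
within Levenshtein distance `max_dist = 2` of the extracted segment are
candidates, ranked by distance, then descending short-read abundance, then
lexicographically; barcodes are unique so ties always resolve.

Five features describe the best candidate: the segment–candidate edit
distance; the margin to the best other whitelist barcode (capped at
`max_dist + 1`); the adapter identity; the offset between the candidate's
semi-global placement and the expected position; and the quantile bin of the
candidate's short-read abundance. A discrete naive Bayes classifier over
equal-frequency bins (default 8) with Laplace add-one smoothing converts the
feature vector into a posterior probability of a correct assignment; reads
are assigned when the posterior reaches the cutoff (default 0.95, reported
both on `[0,1]` and a 0–100 scale). The feature set is this package's own
definition: published hybrid workflows describe the approach — alignment
features feeding a naive Bayes discriminator — without fixing an exact
feature list, so we fix one and document it.

## Training regime

The classifier is trained on a labeled simulation with the same layout and a
configurable error model (defaults 5%/5%/5% substitution/insertion/deletion;
empirical per-base rates are platform-dependent and deliberately exposed as
configuration). A fraction of decoy reads (default 0.3) carries a random
barcode-length segment sampled at guaranteed distance ≥ 3 from the whitelist.
During training only, the candidate search is widened to `max_dist + 2`:
decoys and heavily corrupted reads then produce scored-but-wrong candidates,
which is what populates the false class. At assignment time only candidates
within `max_dist` are scored; feature values outside the training range clamp
to boundary bins. Without the widened net, a well-separated whitelist yields
no false examples at desk scale and the classifier cannot be fit.

The alignment primitives (banded Levenshtein matrix, semi-global placement,
Hamming scans) are implemented in C++; the banded matrix is checked in the
test suite against base R's `adist` on full whitelists, and the semi-global
aligner against hand-constructed reads.

# Transcript catalogs and class codes

Transcript models are stranded exon chains in 1-based inclusive coordinates
(the GTF convention; interval arithmetic is done directly on inclusive
bounds). Unstranded records are rejected because strand separates antisense
overlap from same-strand overlap. Merging removes single-exon transcripts,
then collapses transcripts with identical (chromosome, strand, intron chain),
taking the union of terminal exon ends; new stable identifiers are assigned
in coordinate order, which makes the merge idempotent.

Classification assigns the single highest-priority code over all
span-overlapping references:

| code | meaning |
|------|---------|
| `=`  | identical intron chain, same strand |
| `k`  | query chain contains the reference chain as a contiguous sub-chain |
| `m`  | all reference introns matched or retained in query exons, ≥ 1 retained |
| `n`  | ≥ 1 reference intron retained, but `m` fails |
| `j`  | ≥ 1 shared intron |
| `o`  | same-strand exonic overlap only |
| `x`  | opposite-strand exonic overlap |
| `i`  | query inside a single reference intron |
| `y`  | reference inside a single query intron |
| `u`  | no overlap |

The priority order `=` > `k` > `m` > `n` > `j` > `o` > `x` > `i` > `y` > `u`
is fixed by this package (the code vocabulary itself is standard, but no
total order is mandated anywhere); `k` requires *contiguous* sub-chain
containment, exonic overlap means ≥ 1 bp of exon–exon intersection, and ties
between references at the same code are broken by larger exonic overlap, then
lexicographic reference id. Codes for partial fragments and repeats from the
wider vocabulary of assembly-comparison tools are out of scope. The
classifier is validated two ways: against the synthetic generator's
construction labels (retained-intron variants must classify `m`/`n`,
exon-skipping variants `j`, antisense variants `x`), and against a
brute-force checker that evaluates each code's predicate independently on
random exon chains.

Gene identity is inherited from the matched reference for codes
`=`, `k`, `m`, `n`, `j`, `o`; novel transcripts (`x`, `i`, `y`, `u`) receive
new gene ids clustered by same-strand span overlap.

# Quantification and QC

Counts are molecules, not reads: within each (spot, transcript) group UMIs
are collapsed with the directional rule — an edge connects UMIs at Hamming
distance 1 when the more abundant one has at least `2·count − 1` reads, and
molecules are the connected components grown from the most abundant roots.
The directional collapse is the standard error-robust choice and yields
integer counts by construction.

Quality control keeps spots whose total count and detected-transcript number
lie strictly inside configurable open intervals (defaults 50–4000 and
50–2000) and whose count fraction from a flagged gene list (e.g. ribosomal
or mitochondrial genes) stays below a cap (default 40%); transcripts must
then be detected in at least 2 surviving spots. Spot rules run before feature
rules, and the whole filter is iterated to a fixed point: removing features
lowers spot totals, so a single pass would not be idempotent, whereas the
fixed point is.

# Region statistics

Markers use a two-sided Wilcoxon rank-sum test of each feature in a region
against all remaining spots (normal approximation with tie correction),
Benjamini–Hochberg adjusted within each region's family. Counts are first
scaled per spot to the median library size; the rank test is invariant to the
usual subsequent log transform, and the reported log2 fold change is taken on
the normalized-count scale with a pseudo-count of 1 (a log-scale fold change
would compress large shifts and make the conventional 0.1 threshold
meaningless). Constant features get `p = 1` and zero fold change by
convention.

Region-level transcript sets are selected at `log2FC > 0.1` and raw
`p < 0.05`; the enrichment step consumes raw-p selections by design (the
selection is a screening heuristic, not an inference), with BH-adjusted
selection available behind a flag. Class enrichment crosses (target class vs
other classes) with (foreground vs background regions) after discarding
exact matches (`=`), and reports the *sample* odds ratio `(ad)/(bc)` with a
two-sided Fisher exact p-value (point-probability rule; validated against
full hypergeometric enumeration). Degenerate margins give an undefined odds
ratio and `p = 1`. Isoform diversity compares per-gene distinct-isoform
counts between region pairs with a two-sided Mann–Whitney U test; pairs with
fewer than two genes on either side are flagged and skipped.

# Differential transcript usage

## Filtering

Tested transcripts must be multi-exon, belong to genes that retain at least
two isoforms (re-checked to a fixed point after every removal), be expressed
above `1e6 / median library size` counts-per-million in at least
`max(2, 10% of the smaller group)` spots, and have a total count of at least
one.

## Model

For transcript *t* of gene *g*, the response in spot *s* is
`(k_ts, n_gs − k_ts)` with `n_gs` the gene total over retained isoforms, a
logit link and a two-level region covariate. With a saturated two-group
design the IRLS fixed point has a closed form — the fitted usage in each
group is its pooled proportion — so the package computes the maximum
likelihood estimate directly and vectorizes it across transcripts; the test
suite verifies exact agreement (estimate, standard error, t, p) with
`stats::glm(..., family = quasibinomial())`. The Pearson dispersion
`X²/(n−2)` is floored at 1 and scales the Wald standard error; inference uses
a t distribution on `n − 2` degrees of freedom. Complete separation (usage 0
or 1 in a group) triggers a Haldane–Anscombe 0.5 adjustment on the
aggregated table and a flag; groups with fewer than two usable spots yield a
flagged `p = 1`. No empirical-Bayes variance shrinkage is applied: plain
quasi-binomial Wald t statistics are the defined behavior, and a shrinkage
hook can be layered on the interface without changing it.

## Stage-wise testing and switches

Stage 1 screens genes on the Šidák-corrected minimum transcript p-value,
`1 − (1 − min p)^T` (Bonferroni available), BH-adjusted across genes at the
OFDR (default 0.05). Stage 2 confirms transcripts within screened genes with
a Holm correction at the same level. Šidák is the default screen because it
is the least conservative of the standard min-p combiners while still valid
under independence; each contrast (pairwise `A:B` or one-vs-rest `A:rest`)
forms its own test family. A gene is an isoform switch when at least two
confirmed transcripts in the same contrast have opposite-sign log-odds
ratios.

Under a 500-gene null (2–4 isoforms per gene, negative binomial gene totals
of mean 50, multinomial isoform sampling, 100 spots per group) the realized
OFDR — the fraction of replicates with any confirmed gene — stays within the
binomial confidence band of the 0.05 target, and transcript p-values are
indistinguishable from uniform by a Kolmogorov–Smirnov test; a planted
0.8/0.2 → 0.2/0.8 usage flip at depth 100 with 200 spots per group is
recovered as a confirmed switch with log-odds errors well inside ±0.3.

# The synthetic-data module

The generator emulates: a whitelist of distinct barcodes (optionally with a
minimum pairwise Hamming distance) on an integer grid with negative binomial
short-read abundances; reads with the exact layout above, i.i.d. per-base
substitutions applied before deletions and insertions (the simplest
generative process with controllable marginal rates), optional
reverse-complementing, and decoy reads with guaranteed whitelist separation;
reference annotations as spaced multi-exon gene loci; catalogs with
engineered retained-intron, exon-skipping and antisense variants carrying
truth labels; and count matrices with per-spot negative binomial gene totals
and multinomial (optionally Dirichlet-multinomial) isoform usage per region.
Identical seeds give bit-identical output, and within every spot the isoform
counts of a gene sum exactly to the drawn gene total.

What it does **not** emulate — and hence what green tests do not certify on
real data: homopolymer- and signal-level error structure of real long reads,
base qualities (a constant placeholder is written), PCR amplification bias
and chimeras, transcript-length or positional coverage bias, segmentation
errors in region labels, and spatial autocorrelation of expression beyond
region membership. Junction variants additionally require references with at
least four exons so that a reference intron survives the skip; retained
introns in two-exon references produce single-exon transcripts, which the
merge step removes by design.

# Numerical and scale choices

* Adapter identity threshold 0.7, `max_dist` 2, 8 naive Bayes bins, Laplace
  add-one, posterior cutoff 0.95 — all configurable; the cutoff is
  conservative on purpose since published workflows report assignment rates
  but not cutoffs.
* Levenshtein matching is exhaustive over the whitelist (no k-mer prefilter)
  so it can be checked against an oracle; the C++ band makes this fast at the
  few-thousand-spot scale this package targets.
* Fisher p-values use the point-probability rule, matching enumeration to
  1e-9; odds ratios are sample odds ratios, reported as infinite or undefined
  at zero cells and margins rather than continuity-corrected.
* The test suite and the acceptance script run simulations at deliberate desk
  scale: 500–1000-spot whitelists, 10,000–20,000 reads, 250-gene references,
  500-gene null panels with 100 spots per group and 50–200 replicates. These
  sizes give the statistical checks (binomial confidence bands, KS tests)
  adequate resolution while keeping a full run in minutes on one core.

# Known limitations

* The naive Bayes assumes feature independence given the class; margin and
  edit distance are correlated, which in practice makes posteriors
  overconfident near the extremes — the default cutoff absorbs this, but
  calibrated probabilities should not be read off the score.
* UMI collapse is within-spot only; index hopping between spots is not
  modeled.
* The quasi-binomial model treats spots as independent; spatial correlation
  within a region inflates the effective dispersion, which the Pearson floor
  only partially absorbs.
* One-vs-rest contrasts reuse spots across contrasts, so contrast families
  are dependent; the OFDR guarantee is per contrast, and the cross-contrast
  switching-gene total is reported both with and without deduplication.
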