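# isospot

Full-length isoform analysis for spot-barcoded spatial transcriptomics read
on long-read platforms.

Spatial expression slides capture RNA on barcoded spots; sequencing the same
cDNA with long reads yields complete transcript isoforms, but per-base error
rates of a few percent make the 16-nt spatial barcode unreadable by exact
matching. `isospot` is for analysts who have such hybrid data (or want to
prototype methods for it): it recovers spot identities from noisy reads,
organizes assembled transcripts against a reference, counts molecules per
spot, and tests where and how isoform usage changes across tissue regions.
Every input can also be simulated with known ground truth, so the whole chain
is verifiable end to end.

## What it computes

* **Barcode assignment.** An adapter is anchored by semi-global alignment in
  both read orientations; the downstream segment is matched against the spot
  whitelist by banded Levenshtein distance (`max_dist = 2`); the best
  candidate is scored by a discrete naive Bayes classifier
  `P(correct | features)` over five alignment features (edit distance, margin
  to the runner-up, adapter identity, position offset, abundance quantile),
  trained on a labeled simulation with decoy reads. Reads are assigned at a
  posterior cutoff (default 0.95).
* **Catalog merging and class codes.** Catalogs collapse on identical intron
  chains (single-exon transcripts removed); each transcript gets one class
  code against the reference with priority
  `=` > `k` > `m` > `n` > `j` > `o` > `x` > `i` > `y` > `u` — covering exact
  matches, containment, retained introns (`m`, `n`), junction matches,
  exonic and antisense overlap, intronic, and intergenic transcripts.
* **Quantification.** UMIs collapse per (spot, transcript) with the
  directional rule (edge when Hamming distance = 1 and
  `count(u) >= 2·count(v) − 1`); QC filters spots by total counts, detected
  transcripts and flagged-gene fraction, then features by spot support.
* **Region statistics.** Wilcoxon rank-sum markers (BH-adjusted per region),
  Fisher exact enrichment of a transcript class (e.g. intron retention)
  between region sets over non-exact transcripts, with the sample odds ratio
  `(ad)/(bc)`, and Mann–Whitney comparisons of per-gene isoform diversity.
* **Differential transcript usage.** Per transcript, a quasi-binomial logit
  model of `(transcript count, gene total − transcript count)` on the region
  factor; Wald t statistics on log-odds ratios with Pearson dispersion
  (floored at 1); stage-wise testing at an overall FDR of 0.05 — Šidák min-p
  gene screen with BH, then Holm confirmation within screened genes — and
  isoform-switch calls for genes with confirmed opposite-sign effects.

## Worked example

```r
library(isospot)

## barcode assignment on simulated noisy reads
wl     <- make_whitelist(300, seed = 1, min_hamming = 5)
layout <- read_layout(orientation = "mixed")
errors <- error_model(0.05, 0.05, 0.05)        # sub / ins / del per base
model  <- train_barcode_model(wl, layout, errors, n_reads = 10000, seed = 2)
reads  <- simulate_reads(wl, layout, errors, 10000, decoy_fraction = 0.1, seed = 3)
asg    <- assign_barcodes(setNames(reads$sequence, reads$read_id),
                          wl, layout, model)
attr(asg, "summary")
#>              step reads
#> 1           input 10000
#> 2   adapter_found  9895
#> 3 candidate_found  3555
#> 4        assigned  3555
assigned <- !is.na(asg$barcode)
correct  <- assigned & !is.na(reads$true_barcode) &
            asg$barcode == reads$true_barcode
sum(correct) / sum(assigned)
#> [1] 0.9994
```

At 5%/5%/5% per-base errors only about a third of reads retain a barcode
within edit distance 2 — the pipeline trades recall for precision, and
99.9% of what it assigns is correct.

```r
## transcript classification against a reference
ref     <- simulate_reference(40, exons_range = c(4, 8), seed = 4)
catalog <- simulate_catalog(ref, n_ir = 10, n_junction_variants = 10,
                            n_antisense = 10, seed = 5)
ann     <- annotate_catalog(merge_catalogs(list(catalog)), ref)
attr(ann, "class_freq")
#>  =  k  m  n  j  o  x  i  y  u
#> 40  0 10  0  9  0  8  0  0  0
```

All 40 reference copies classify `=`, the 10 engineered retained-intron
variants classify `m`, and the skip/antisense variants classify `j`/`x`
(duplicated constructions collapse during merging, hence 9 and 8).

```r
## differential transcript usage with a planted switch in gene g01
gmap  <- setNames(lapply(1:10, function(i) sprintf("g%02d_t%d", i, 1:2)),
                  sprintf("g%02d", 1:10))
usage <- list(A = list(g01 = c(0.8, 0.2)), B = list(g01 = c(0.2, 0.8)))
cm    <- simulate_counts(gmap, c("A", "B"), 150, usage = usage,
                         depth = 80, seed = 6)
d     <- run_dtu(cm, "A:B")
subset(d$results, gene_id == "g01",
       select = c(transcript_id, log_odds_ratio, std_error, p_value, confirmed))
#>        transcript_id log_odds_ratio  std_error       p_value confirmed
#> g01_t1        g01_t1      -2.764912 0.03486356 2.202386e-202      TRUE
#> g01_t2        g01_t2       2.764912 0.03486356 2.202386e-202      TRUE
d$switches
#>   gene_id n_confirmed   transcripts log_odds_ratios
#> 1     g01           2 g01_t1,g01_t2   -2.765,2.765
```

The estimated log-odds ratios straddle the generative value
`logit(0.8) − logit(0.2) = ±2.773`, and g01 is the only switch called; the
nine null genes are not confirmed.

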