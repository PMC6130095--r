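# strandsig

Quantifies how mutational signatures interact with DNA replication — on
which template strand each mutagenic process acts, and how its activity
changes between early- and late-replicating DNA. It is aimed at cancer
genomics analysts who have per-sample somatic SNV calls and a
replication-timing (or replication-origin) annotation, and want
signature-level rather than mutation-type-level answers.

## The model

Somatic SNVs are classified into the 96 pyrimidine-centric trinucleotide
types and oriented to the replication template: in a left-replicating
domain the reference strand templates the leading strand, so a plus-strand
pyrimidine mutation there is a leading-template event (and conversely in
right-replicating domains). Domains come from the slope of a binned timing
profile in 20-kbp windows (|slope| ≥ 250 rtu/Mb; flatter windows — timing
peaks and valleys — are dropped). Counting per sample over 96 types × 2
templates gives strand-resolved catalogs, from which 192-element signatures
are extracted by bootstrapped NMF (rank chosen by minimizing
`error_K/max(error) + (1 − stability_K)` with stability ≥ 0.8) and condensed
into *directional signatures*: 96 weights, each flagged leading or lagging.

Per-sample exposures are then obtained by non-negative least squares on the
block system

    S = ( S_LD  S_LG )        e = ( e_matching )
        ( S_LG  S_LD ) ,          ( e_inverse  )

where `S_LD`/`S_LG` hold the leading-/lagging-flagged signature weights and
the spectrum `m = (m_LD; m_LG)` stacks the trinucleotide-normalized leading
and lagging mutation counts. `e_matching` measures a signature acting on its
annotated strands, `e_inverse` the same signature with strands swapped.
Cohort statistics are exact two-sided binomial sign tests on per-sample
`e_matching − e_inverse` differences (and on per-sample slopes of exposure
versus timing quartile), with Benjamini-Hochberg correction across
signatures, minimum exposure 10, and Tukey-fence (k = 2) outlier handling.
A synthetic-data generator plants known asymmetries, timing gradients and
signature libraries so the whole chain is testable without protected data.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data with a planted 3:1 matching:inverse asymmetry and a mutation rate
rising 2-fold from the earliest to the latest timing quartile:

```sh
Rscript analysis/01_simulate.R   # genome, domains, 40 x 10k-mutation cohort
Rscript analysis/02_regions.R    # domains re-derived from the timing profile
Rscript analysis/03_catalog.R    # strand-resolved catalogs
Rscript analysis/04_extract.R    # NMF extraction + directional annotation
Rscript analysis/05_decompose.R  # matching/inverse exposures
Rscript analysis/06_stats.R      # cohort statistics + randomized control
```

Stage 4 selects the planted rank and recovers the planted signatures:

```
 K     error stability objective
 2 3564.6412 0.9995603 1.0004397
 3  841.0018 0.9995513 0.2363776
 4  809.4741 0.8770477 0.3500366
 5  782.2608 0.7713838 0.4480663
selected K = 3
cosine similarity of extracted vs planted 96-type signatures:
      [,1]  [,2]  [,3]
[1,] 0.999 0.030 0.024
[2,] 0.041 0.999 0.027
[3,] 0.019 0.009 1.000
per-type direction-flag agreement with best-matching planted signature: 100.0% 100.0% 100.0%
```

and stage 6 reports the cohort statistics (three extracted signatures; the
planted asymmetry is matching-biased, so every exposed sample has
`e_matching > e_inverse` and the timing slopes are positive):

```
 signature n_exposed n_outliers median_difference pct_matching            p
   novel_1        39          0          4518.010          100 3.637979e-12
   novel_2        38          0          4486.127          100 7.275958e-12
   novel_3        39          0          4107.724          100 3.637979e-12

 signature  n median_slope_matching pct_positive_matching   q_matching
   novel_1 40              295.9652                  97.5 7.457857e-11
   novel_2 39              349.1523                 100.0 5.456968e-12
   novel_3 40              319.1926                 100.0 5.456968e-12
```

`median_difference` is the cohort median of `e_matching − e_inverse` in
exposure (normalized mutation-count) units; `pct_matching` the percentage
of exposed samples with matching > inverse; `median_slope_matching` the
median per-sample OLS slope of matching exposure against quartile index.
Under the randomized-annotation control the asymmetry magnitude collapses
roughly 70-fold.

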