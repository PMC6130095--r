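---
title: "Quantifying replication strand asymmetry and timing dependence of mutational signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replication strand asymmetry and timing dependence of mutational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

DNA replication is asymmetric: the leading strand is synthesized
continuously and the lagging strand discontinuously, by partly different
polymerases, and different genomic regions replicate at different times in S
phase. Mutational signatures — probability vectors over the 96
pyrimidine-centric trinucleotide substitution types — summarize the
mutagenic processes active in a tumor, but in their ordinary form they are
blind to replication. `strandsig` makes signatures replication-aware: every
mutation is oriented to the template strand (leading or lagging) on which
its pyrimidine sat during replication, signatures are extracted in a
strand-resolved 192-type space, and per-sample exposures are split into a
*matching* component (the signature acting on its annotated strands) and an
*inverse* component (the same signature with strands swapped). Cohort-level
sign tests then ask whether a signature systematically prefers one template
strand, and whether its activity rises or falls with replication timing.

# From mutations to strand-resolved catalogs

A somatic SNV is classified by the pyrimidine of its Watson-Crick base pair:
records with a purine reference are reverse-complemented (substitution and
trinucleotide context as a unit), which yields the standard 96 types and a
flag saying which strand carried the pyrimidine. Replication direction comes
from a domain annotation: fixed-width windows (20 kbp by default) over a
binned replication-timing profile, each keeping the least-squares slope of
timing versus position. Windows flatter than 250 rtu/Mb — timing peaks
(origin clusters), valleys (termination zones) and plateaus, where direction
is undefined — are discarded. In a left-replicating domain the reference
(plus) strand templates the leading strand, so a plus-strand pyrimidine
mutation there is a leading-template event; all other combinations follow by
symmetry. Counting mutations per sample over the 96 types x 2 templates
gives the 192-column catalog that all downstream stages consume.

Two numerical conventions matter here:

* **Coordinates.** All internal intervals are 0-based half-open (BED);
  1-based mutation positions are converted at the reader boundary.
* **Timing dialect.** Published replication-timing tracks disagree on
  whether larger values mean earlier replication. The package exposes a
  single flag, `rtu_high_is_early` (default `FALSE`, i.e. timing behaves
  like "time of replication": small = early). Under the default, a
  positive timing slope means the fork travels rightwards (right-replicating
  domain) and quartile Q1 collects the lowest timing values; setting the
  flag inverts both rules consistently. We chose the default so that the
  direction rule "negative slope = left-replicating" and the quartile rule
  "Q1 = earliest" hold simultaneously without special cases.

Trinucleotide content differs between the two template-strand classes, so
catalogs and signatures are made comparable to genome-based references by
scaling each entry with `genome_count(trinuc) / strand_count(trinuc,
template)`. Zero strand counts with positive entries raise an error by
default rather than being silently imputed — a zero there almost always
means a broken annotation, not genuine absence (a pseudocount policy is
available).

# Signature extraction and directional annotation

Strand-specific signatures are extracted by non-negative matrix
factorization (multiplicative updates, Frobenius loss) of the 192 x samples
catalog, wrapped in a multinomial bootstrap: each resample redraws every
sample's counts, factorizes at rank K (best of several random restarts),
and the pooled signatures from all resamples are partitioned into K groups
by cosine distance (`cluster::pam`). The mean silhouette width of that
partition is the *stability* of rank K; the mean Frobenius residual its
*error*. K is chosen to minimize `error_K / max(error) + (1 − stability_K)`
among ranks with stability of at least 0.8 (ties to the smaller K; if no
rank qualifies the most stable one is returned, flagged). Signatures whose
95th-percentile exposure is below 20% of the mean per-sample total exposure
are removed and exposures refit.

The retained, genome-normalized strand signatures are pooled with an
optional 96-type reference catalog — each reference embedded with equal
values in its leading and lagging halves — and clustered by unsupervised
hierarchical clustering with cosine distance and complete linkage. Cluster
representatives are the reference signature in its original form when one is
present, otherwise the mean of the members' collapsed strand halves. A
declarative override table supports manual reassignment after the cut
(never interactively); we cut the tree first and apply overrides second,
since inspection happens on the cut result. Each representative is finally
*directionalized*: for every one of the 96 types, the summed leading versus
lagging weight across the cluster's strand members decides a leading/lagging
flag. Types with less than 0.5% of the signature's mass (a configurable
threshold — the evidence there is noise-dominated) or with exactly tied
weights inherit the majority direction of the other types in their
substitution group; a group with no informative types inherits the overall
majority, and a complete tie defaults to leading. These tie-break rules are
deterministic on purpose: reruns must be byte-identical.

# Matching and inverse exposures

Let `S_LD` (96 x N) hold the leading-flagged weights of the N directional
signatures (zeros elsewhere) and `S_LG` the lagging-flagged weights. With a
sample's trinucleotide-normalized spectra `m_LD` and `m_LG` on the two
templates,

```
S = | S_LD  S_LG |      m = | m_LD |      e = | e_matching |
    | S_LG  S_LD |          | m_LG |          | e_inverse  |
```

and `e = argmin_{e >= 0} ||m − S e||` (non-negative least squares). The
first N coefficients measure each signature acting on its annotated strands,
the last N the same signature with strands swapped; their difference (or a
log2 fold change with a pseudo-exposure of 1) is the per-sample asymmetry.
Exposures are in genome-scale normalized mutation-count units, so the
"minimum exposure 10" filter below has a natural scale. Two refinements
control spurious assignments:

* **Pruning.** The signature with the smallest total exposure is removed
  (both halves at once) and the fit repeated, as long as the residual stays
  within 0.5% of the *original* residual. We read the tolerance as relative
  to the unpruned fit — each accepted removal is re-measured against that
  original baseline, not chained — and made it configurable.
* **Robustness.** The spectrum is perturbed (1000 draws by default) with
  Gaussian noise of sd equal to 5% of each entry, clamped at zero since a
  negative mutation frequency is meaningless; a signature whose perturbation
  quartiles deviate from the unperturbed exposure by 30% or more is dropped
  for that sample and the rest refit. A signature with zero unperturbed
  exposure is flagged only when perturbed exposures exceed an absolute
  floor (default 10, the minimum-exposure scale).

# Cohort statistics

Per signature, samples whose total (matching + inverse) exposure reaches 10
enter the asymmetry test; their matching − inverse differences, after
Tukey-fence outlier removal (k = 2, type-7 quantiles — the fence values
depend on the quantile definition, so it is pinned), feed an exact two-sided
binomial sign test (zeros discarded, smaller tail doubled, capped at 1).
The timing analysis decomposes each quartile's catalog separately, fits an
ordinary least-squares line of exposure versus quartile index 1–4 per sample
(a switch allows mean timing as the predictor instead), and sign-tests the
per-sample slopes. Benjamini-Hochberg correction is applied across
signatures within each metric, mirroring how the two panels of a
cohort-level summary are read. We apply the minimum-exposure rule to the
*sum* of matching and inverse exposure (the natural "is this signature
present" measure; configurable), and compute the median difference after
outlier removal.

Spatial profiles around replication origins use direction-annotated 1-kbp
bins emitted outwards from each origin midpoint, truncated at half the
distance to the neighboring origin; profiles average per-bin exposures
across non-outlier samples, reporting empty bins as `NA` rather than zero.

# The synthetic-data generator

Real inputs at study scale (thousands of protected whole genomes, published
timing tracks) cannot ship with a package, so every stage is exercised on
synthetic data with planted ground truth. The generator emulates:

* a random i.i.d. (optionally first-order Markov) genome, default 40% GC;
* origins every 400 kbp with timing rising linearly from 10 rtu at the
  origin to 90 rtu at the termination midpoint — a 400 rtu/Mb gradient,
  comfortably above the 250 rtu/Mb slope threshold, so domain derivation
  from the emitted profile recovers the emitted directions exactly;
* a library of well-separated directional signatures occupying disjoint
  substitution groups (pairwise cosine 0) with smooth within-group weights
  and alternating strand preferences;
* cohorts in which each mutation draws a signature (per-sample exposure
  weights), a strand-resolved channel from that signature's spectrum at a
  planted matching:inverse odds ratio, and then a genomic site whose
  trinucleotide context and template orientation match the channel —
  site-conditional placement, so trinucleotide normalization is genuinely
  exercised — with site weights multiplied per timing quartile (e.g. 1,
  1.3, 1.6, 2 for a late-replication enrichment).

Defaults are 40 samples at 10,000 mutations per sample, the scale at which
the package's recovery guarantees are stated. What the generator does *not*
emulate: real human sequence composition (CpG depletion, repeats),
mappability artifacts, sequencing error, tumor purity, inter-sample
heterogeneity of signature direction, or origin-density structure inside
domains. Passing tests therefore demonstrate correctness of the machinery
and calibration of the statistics under the stated model — not robustness
to every artifact of real tumor data.

# Problem sizes and numerical choices

Tests and the acceptance analysis run on two 300-kbp chromosomes
(20 replication domains, ~400k indexed sites), 40-sample cohorts, 20-seed
batteries for power and type-I checks, and desk-scale NMF settings (4
bootstrap resamples, 2 restarts, K candidates 2–5); the planted signatures
are orthogonal, so model selection is stable well below the production
defaults (100 resamples, 10 restarts, K 2–7, documented in
`run_config()`). The NNLS solver is compared against an iteratively refined
dense grid search on randomly drawn small systems, filtered to
well-conditioned instances (smallest Gram eigenvalue above 1e-3) so that
the argmin comparison is meaningful.

One design point deserves emphasis: the randomized-annotation negative
control shares a single shuffled domain annotation across all samples, so
its residual direction bias is common-mode and only averages out with many
domains. The control analysis therefore uses many small (2-kbp) domains;
with few large domains a sign test will happily detect the residual of the
shared shuffle — that is a property of the control's geometry, not of the
statistic.

Other numerical choices: NMF iterations stop on a relative error decrease
below 1e-9 (cap 10,000); the multiplicative updates guarantee a
non-increasing Frobenius error, which the tests assert per run; silhouettes
use the same cosine distance as the clustering; rank-1 extractions have
stability 1 by convention (a single cluster has no silhouette); all
quantile computations are type-7; degenerate inputs (all-zero spectra,
single-bin chromosomes, all-identical timings) return defined results with
warnings rather than failing.

# Known limitations

* Exposure units depend on the trinucleotide normalization of the inputs;
  comparisons across differently normalized cohorts are not meaningful.
* The sign test treats samples as exchangeable; batch structure or shared
  annotation noise (see the control discussion above) violates that.
* Greedy pruning removes one signature at a time without backtracking; with
  strongly collinear libraries the pruned set can depend on tie-breaks —
  the robustness filter is the intended guard for that regime.
* Per-cancer-type extraction is supported but untested beyond single-cohort
  synthetic runs; the reference catalog path assumes COSMIC-style row
  labels.
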