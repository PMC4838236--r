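---
title: "Gamma-retrovirus integration profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-retrovirus integration profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripr)
```

# The scientific setting

Gamma-retroviruses (MLV, FeLV) integrate non-randomly: their integrase binds
BET/bromodomain proteins, which in turn bind acetylated chromatin, so
proviruses accumulate at active promoters and enhancers. Mapping many
thousands of *unselected* insertion sites shortly after infection — before
clonal outgrowth can distort the picture — therefore reads out the active,
cell-type-specific regulatory landscape, and in practice is strongly skewed
towards cancer driver genes. `gripr` implements the downstream statistics of
such a screen: which genes are targeted more than chance allows, whether any
clonal selection has crept in, how insertions distribute around transcription
start sites (TSSs) and chromatin-mark peaks, and whether the top targets are
enriched for annotated gene sets.

All coordinates in the package are 0-based half-open (BED convention); an
insertion is a strand-oriented point, carrying the number of independent
junction fragments ("copies") that support it.

# Common insertion sites: the windowed hypergeometric test

Each gene's span is extended by a flank of `flank = 25000` bp on both sides
(local regulatory elements sit within a few tens of kb); the **mappable
genome** is estimated as the union of all such windows, of total length
$N$ bp. Insertions outside the union are excluded from the null. Writing $n$
for the number of insertions inside the union, $K$ for the length of one
gene's window and $k$ for the insertions assigned to that gene, the
enrichment p-value is the upper hypergeometric tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),$$

i.e. insertion positions are modelled as draws of base pairs without
replacement from the window union. For a one-sided $2\times2$ table this is
identical to Fisher's exact test, so the two names describe one computation.

Assignment is exclusive: an insertion belongs to the gene whose *body* is
nearest among all windows containing it (distance 0 inside the body), with
ties broken by distance to the TSS and then by gene id. Each gene's test
still uses its full window length $K$ even where windows overlap; this mild
inconsistency between exclusive counting and overlapping window lengths is
inherent to the window construction and is recorded in every output header.

Raw p-values are Benjamini–Hochberg adjusted across all genes with at least
one insertion. The ranked target list applies the field's reporting rule:
filter at `p_raw < alpha` (default 0.05; very large datasets may need a
stricter `alpha` so the ranked list stays comparable in size), then order by
insertion count $k$ descending, optionally expanding the list across a tied
boundary count.

# Clonal-selection diagnostics

Integration itself is orientation-neutral, but enhancer-mediated activation
of a driver gene favours one proviral orientation, so expanding clones leave
a "heads–tails" signature. For each gene cluster the forward/reverse split is
compared with the remainder of the dataset by Fisher's exact test. The
two-sided p sums the probabilities of all tables (fixed margins) whose point
probability does not exceed the observed one — the standard convention — with
a relative tolerance of $10^{-7}$ for floating-point ties; a one-sided tail
is available because directional contrasts (e.g. comparing how often two
sets of predicted upstream regulators are themselves integration targets)
are naturally one-sided. Bonferroni and BH corrections take an explicit
family size, which may exceed the number of p-values supplied: nominally
significant findings are corrected within the full screen that produced
them.

The second diagnostic is the copy count: post-integration expansion would
inflate junction-fragment copies at the top targets. `copies_per_insertion()`
reports the mean (rounded half away from zero to one decimal, the reporting
convention), and `copy_number_test()` applies Welch's unequal-variance
two-tailed t-test between top-target insertions and the dataset as a whole.

# TSS profiles and position classes

Distances to the nearest TSS are signed in the gene's reading direction
(negative = upstream). The histogram default — 500 bp bins over ±10 kb — was
chosen to resolve the characteristic double peak at roughly ±1.5 kb with a
trough at the TSS itself. Position classification mirrors the six-class
vocabulary of standard peak-annotation tools (`inside`, `upstream`,
`downstream`, `overlapStart`, `overlapEnd`, `includeFeature`); a point
insertion can only realise the first three, the interval classes exist for
peak-sized features.

# Chromatin-mark association and Monte-Carlo overlap

An insertion overlaps a mark iff its point lies inside a peak interval; no
slop window is added. Venn-style combination counts summarise the global
association. For the sharper question — do the *most significant* insertion
target genes coincide with the *most significant* peak-score genes? — the top
`size = 500` entries of each ranked list are intersected (score ties at the
boundary expand the list, and the effective size is carried through), and
significance comes from Monte-Carlo simulation: draw `effective_size` genes
uniformly without replacement from the full gene universe, record how often
the overlap reaches the observed value.

Two conventions matter here:

* **Zero exceedances.** When no simulation reaches the observed overlap the
  estimate is reported as the bound $p = 1/n_\mathrm{sim}$ with an explicit
  `is_bound` flag — the true p is smaller. The alternative
  $(\mathrm{exceed}+1)/(n_\mathrm{sim}+1)$ estimator is available behind the
  `estimator` flag but is not the default, because the bound form is what
  overlap tables conventionally print. Reports carry $-\log_{10}p$
  ("transformed p") alongside.
* **The sampler.** The overlap of a uniform without-replacement sample with
  a fixed list depends only on the intersection size, which is exactly
  hypergeometric. The default method therefore draws each simulated overlap
  from `rhyper()` — distributionally identical to sampling gene identities
  and orders of magnitude faster, which is what makes $6\times10^7$
  simulations routine. `method = "resample"` draws explicit gene identities
  instead; the test suite checks both against exhaustive enumeration on
  small universes.

The default `n_sim` is $10^6$; runs that need to bound very small p-values
(e.g. establishing that an observed 56-gene overlap between top-500 lists
never occurs in $6\times10^7$ draws, a bound of $1.67\times10^{-8}$) set
`n_sim` explicitly.

A pairwise hypergeometric p for raw insertion/peak overlap is available when
a population is supplied; it treats the union of gene windows (in bp) as the
population, the mark's peak union as the success class and insertions as
draws. This population choice is documented here because alternatives
(feature counts rather than base pairs) exist and give different numbers.

# Gene-set enrichment

Enrichment of an annotated set (cancer drivers, literature-flagged genes)
among the top $n$ targets is a chi-squared goodness of fit of the annotated
count $k$ against a background proportion $p_0$:

$$\chi^2 = \frac{(k - np_0)^2}{np_0} + \frac{((n-k) - n(1-p_0))^2}{n(1-p_0)},$$

with the upper tail on 1 df and **no continuity correction** — the Yates
correction is designed for small expected counts in $2\times2$ tables and
systematically weakens the statistic here. The canonical background for
cancer drivers is the Cancer Gene Census fraction of the genome, about
2.2% ($p_0 = 0.022$); note that the published fraction is itself a rounded
number, so reproduction of published p-values from it is faithful on the
$-\log_{10}$ scale rather than digit-for-digit. A control-list comparison
(e.g. 29/100 literature-annotated top targets vs 5/100 in a random gene
sample) uses the control rate as $p_0$. Symbol matching is
case-insensitive, and unmatched symbols are reported, never dropped
silently.

`expression_overlap_profile()` sweeps overlap significance across sample
sizes (top 50, 100, 150, … of the target list vs an expression ranking); a
flat profile at small sizes indicates that the preferred integration targets
are not simply the most abundantly expressed genes.

# The synthetic-data generator

The generator exists so that every stage is testable at desk scale, with
known ground truth. It emulates:

* a multi-chromosome toy genome (default 4 × 5 Mb, 100 non-overlapping genes
  of 5–20 kb, random strands);
* a peak set covering a Bernoulli-selected fraction of TSSs (default 0.3,
  peak width 2 kb) — a stand-in for an active histone mark;
* insertions from a two-channel mixture: with probability `pi` (default 0.6,
  the order of magnitude seen in gamma-retroviral screens where more than
  half of integrations target a small fraction of the genome) a peak-bearing
  gene is chosen — designated *hot genes* multiply their selection weight —
  and the point is placed at TSS ± offset, where |offset| peaks at
  `tss_offset_mode = 1500` bp (sd 500 bp) and an exclusion zone of 200 bp
  around the TSS reproduces the double-peak-with-trough shape without
  claiming a mechanism; otherwise the position is uniform over the genome;
* per-insertion clonal copy counts `1 + Geometric(p)` with `p = 0.385`,
  giving a mean near 2.6 copies/insertion, the scale typical of an
  unselected screen;
* per-gene orientation bias: strand is forward with probability `beta`
  (default 0.5 = no bias), overridable per gene to plant a heads–tails
  signal.

All randomness derives from one master seed through fixed per-stage
substreams, so the genome, the peaks and the insertions regenerate
independently — in particular, designating hot genes does not perturb the
genome they live in.

What the generator does **not** emulate: sequence context and alignment
artefacts, chromatin domains larger than single peaks, correlated peak sets
for multiple marks, saturation of hotspots in very deep datasets, or
counter-selection of deleterious insertions. Passing the recovery tests
therefore shows that the statistics detect the structure they model, not
that real screens are free of these complications.

# Validation experiments and problem sizes

Two built-in simulation studies double as the package's validation surface:

* `sim_cis_recovery()`: 10 hot genes at weight 20 among 5000 insertions;
  across 20 seeds the CIS top-10 recovers at least 8 of the 10 designated
  genes in ≥ 95% of runs (in practice all 10 in every run).
* `sim_orientation_screen()`: with `beta = 0.5` everywhere the corrected
  discovery rate across ~100-gene screens stays within the nominal 5%
  (in practice 0); with `beta_hot = 0.95` at genes carrying ≥ 30 insertions,
  detection before correction exceeds 80% power (in practice 100%).

These sizes — 100 genes, a 20 Mb genome, a few thousand insertions, 20
seeds — were chosen as the smallest configuration in which the asymptotic
behaviour of the tests is already visible; the suite runs in well under a
minute on a laptop core.

# Numerical choices and edge cases

* Coordinates: 0-based half-open everywhere; the insertion point is the BED
  start, and `end` is validated (`start + 1` expected) but otherwise unused.
* Gene windows truncate at position 0; chromosome right ends are unknown to
  a gene table, so there is no right truncation.
* Duplicate `(chrom, pos, strand)` records merge on ingest by summing
  copies; strand `"."` is an error under `strict = TRUE` and is kept as `NA`
  (invisible to orientation analysis) otherwise.
* Assignment tie-breaks are total and deterministic: body distance, then TSS
  distance, then lexicographic gene id; nearest-TSS ties likewise resolve to
  the smaller gene id.
* The two-sided Fisher sum is capped at 1 to absorb summation epsilon;
  the BH step-up is delegated to `p.adjust`, with an explicit family size.
* Reported means round half away from zero (2.55 → 2.6), matching the
  reporting convention rather than R's banker's rounding.
* Degenerate inputs fail loudly: empty insertion sets for mean copies,
  zero-variance pairs for the Welch test, all-zero margins for Fisher,
  infeasible gene packing for the generator.

# Known limitations

* The hypergeometric null treats base pairs inside the window union as
  exchangeable; mappability, GC and replication-timing structure in real
  genomes are not modelled.
* Window length $K$ is not corrected for inter-window overlap (see above) —
  a deliberate reproduction of the standard construction.
* The pairwise insertion/peak hypergeometric depends on an arguable
  population choice; it is provided as an option, not a headline statistic.
* The orientation screen conditions on the observed cluster sizes; genes
  with very few insertions have essentially no power and simply dilute the
  correction family, which is why the family size is an explicit parameter.
* Ranked gene lists (expression, peak p-scores) and annotated gene sets are
  consumed as inputs; peak calling and pathway inference live upstream of
  this package.
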