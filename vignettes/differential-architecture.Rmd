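---
title: "Differential chromatin architecture between two conditions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential chromatin architecture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hicswitch)
```

## Scope

hicswitch compares the three-dimensional organisation of a genome between
two biological conditions — typically a parental cell line and a derived
(e.g. drug-resistant) line — from binned Hi-C contact maps, and relates the
architectural changes to gene expression and histone-mark peak data. Three
questions drive the design:

1. Which genomic bins switch A/B compartment between the conditions, and
   what fraction of the genome do they cover?
2. Where are TAD boundaries, and which of them weaken or strengthen?
3. Do genes in switching bins change expression in the expected direction,
   and is histone-peak coverage associated with compartment state?

Everything operates on fixed-width genomic bins (0-based, half-open).
Compartment and TAD procedures are cis: each chromosome is analysed from
its own intra-chromosomal matrix.

## Matrix preparation

Raw pair counts are binned into symmetric per-chromosome matrices. Bins
with zero marginal counts — and optionally bins below a marginal-sum
quantile (`mask_low_coverage(min_fraction)`) — are masked out of all
downstream computation. Balancing uses iterative correction (ICE): a
multiplicative per-bin bias `b` is estimated so that
`balanced[i,j] = raw[i,j] / (b_i * b_j)` has equal row sums over unmasked
bins. The bias vector is reported under a geometric-mean-1 convention;
convergence is declared when the relative marginal spread falls below
`tol` (default 1e-6, capped at `max_iter = 300` with a warning flag rather
than an error).

The standalone masking default is a 0.02 quantile, a conventional
low-coverage filter for real libraries. The end-to-end pipeline default is
`mask_min_fraction = 0`, i.e. only dead bins are removed: a fixed quantile
trim always removes the lowest-coverage 2% of bins, and on clean data
those are precisely the most insulated boundary bins — biology, not
dropout. Users with real libraries showing mappability dropout should
raise the knob back to ~0.02.

## Compartment calling

The pipeline is the classical eigenvector construction: distance-decay
normalisation (observed/expected against the mean contact frequency per
distance, diagonal excluded), then the Pearson correlation matrix of O/E
rows, then the eigenvector of the largest-magnitude eigenvalue. The
eigenvector is computed by power iteration with a deflation step that
estimates the runner-up eigenvalue; a near-tied spectrum is flagged as
"no dominant structure". Dense `eigen()` serves as an independent
cross-check in the test suite, not as the implementation.

The eigenvector sign is arbitrary, so it is anchored to a reference track:
by default gene density (TSS count per bin), falling back to peak coverage
when only ChIP data are supplied. The vector is flipped iff its
correlation with the reference is negative, making orientation idempotent;
a zero-correlation reference leaves the sign unchanged with a warning.
Bins with PC1 > 0 are labelled A, PC1 < 0 labelled B; an exact zero is NA
because the strict inequalities leave it undefined.

A per-bin switch class is the pair of labels (AA, AB, BA, BB; NA if either
condition is unlabelled; AB = A in condition 1, B in condition 2).
Genome fractions are reported over *eligible* bins (labelled in both
conditions); the all-bins denominator is reported alongside since
published figures rarely state which denominator they use.

## TAD boundaries from insulation

At TAD resolution (40-kb bins by default) the insulation score of bin `i`
is `log2(C_i / mean(C))`, where the community contacts `C_i` sum the
balanced signal over the square window `[i-w, i) x (i, i+w]` — every
contact that crosses the bin within `window_bp`. The mean runs over bins
with complete windows; edge bins are NA. A zero `C_i` is capped at the
finite minimum minus 1 and flagged.

Candidate boundaries are bins whose score decreases monotonically into
them over `search_range_bp` (200 kb) upstream and increases monotonically
away downstream, with plateaus allowed along the slopes and a minimum
plateau resolved to its leftmost bin. Candidate detection runs on a
3-bin running mean of the track: single-bin Poisson bumps otherwise break
the monotone-slope rule at exactly the shallow valleys (weakened
boundaries) one most wants to keep. Quantification is never smoothed:
each candidate's `mean_left`/`mean_right` (100-kb flanks, bin excluded),
`delta = mean_left - mean_right`, and valley strength
`(mean_left + mean_right)/2 - score(bin)` are computed on the raw track.

Retention defaults to `strength >= 0.1` (log2 units). The literal
delta-threshold rule is available (`filter = "delta"`) but is not the
default because a perfectly symmetric valley has `delta = 0` and would be
rejected — contradicting the candidate definition it follows.
`min_strength = 0.1` keeps boundaries whose valley is at least ~7% below
its shoulders; isolated single-bin compartment discordances dent the
track by less than this (see the generator section), while genuine
boundaries at the study's depth measure 0.2 and above.

The insulation window default is 200 kb (5 bins at 40 kb). The window
sets the valley width: with a wide window the 100-kb flanks sit deep
inside the valley and measured strength collapses toward zero; at 5 bins
the flanks ride the valley shoulders, so strength tracks the true depth
of the insulation deficit. A directionality-index track (chi-square-like
statistic over 2-Mb up/downstream sums) is provided as an independent
cross-check; on strong boundaries its negative-to-positive sign flips
co-locate with insulation minima.

TADs are the intervals between boundary points (boundary = bin start, a
zero-width split). Adjacent boundaries closer than 400 kb merge into one
extended boundary region that is excluded from the TAD list rather than
reported as a domain. Boundaries are matched across conditions by
interval overlap after dilation by one bin, greedily nearest-first and
one-to-one; per matched pair `r = log2(strength2 / strength1)` classifies
the boundary as weakened (`r < -log2(1.25)`), strengthened
(`r > +log2(1.25)`) or stable. The 25% change threshold and the valley
strength metric are reported in the run metadata; neither is standardised
in the literature.

## Integration with expression and peaks

Each gene is assigned the switch class of the bin containing its TSS
(half-open; TSS on a bin start belongs to that bin). TSS assignment
rather than midpoint or overlap keeps the mapping single-bin and
regulatory in spirit. Fold changes are `log2((fpkm2 + 1)/(fpkm1 + 1))`;
the unit pseudocount keeps FPKM 0 representable. Per-class medians and
quartiles are reported, along with the qualitative flag
`median(AB) < 0 < median(BA)` (down-regulation in A-to-B bins,
up-regulation in B-to-A bins). `de_flag()` applies strict
`|lfc| > 1` (and optional `q < 0.05`) thresholds; differential testing
itself is out of scope and should come from a dedicated tool.

Peak sets are reduced to per-bin base-pair coverage by interval
intersection (signal-weighted behind a flag); A-bins and B-bins are
compared with a two-sided Mann–Whitney rank-sum test. Overlapping peaks
are not flattened, so stacked peaks count multiply.

## The synthetic two-condition study

The generator exists so every stage can be tested against known truth
without any external data. Expected counts follow

    lambda_ij = L * (|i-j|+1)^(-alpha) * (1 + c * s_i s_j) *
                prod_b (1 + t_b)^[i,j on the same side of boundary b]

with Poisson sampling per unordered pair. Defaults describe the reference
study: one 80-Mb chromosome at 40-kb resolution (2000 bins), decay
exponent `alpha = 1`, checkerboard contrast `c = 0.6`, about 2 million
contacts (~1000 per bin), five boundaries of strength `t = 1` of which
40% are weakened to `t/2` in condition 2, 9%/10% of bins switching A-to-B
/ B-to-A, 2000 genes with ±1.5 log2 planted class effects and 0.5 log2
noise on a baseline of ~32 FPKM, and peaks at 2 per bin.

Several structural choices deserve explanation because the multiplicative
checkerboard acts at *all* distances:

* **Compartment blocks change sign only at a subset of the planted
  boundaries** (every other one, keeping A/B bin totals balanced), so
  compartment blocks span about two TADs. A compartment block edge
  insulates exactly like a TAD boundary under this model; if block edges
  were placed independently of the boundary list, they would be genuine
  insulation boundaries missing from the truth, and boundary precision
  would be meaningless. An independent geometric block mode
  (`segmentation = "geometric"`) is kept for matrix-level tests.
* **Weakened boundaries are planted at boundaries that are not block
  edges.** At a block edge the condition-invariant compartment contrast
  dominates the valley, so a change in `t` is not identifiable from the
  insulation profile — a documented limitation of insulation-based
  strength comparison, not of the generator.
* **A fraction of bins (5%) carries isolated fine-scale sign flips**, as
  real 40-kb PC1 tracks do. These give the eigenvector short-range,
  per-bin support; with perfectly block-constant signs a bin's compartment
  signal would rest entirely on noisy long-range contacts.
* **All flipped bins (fine-scale and condition-2 switches) keep a minimum
  mutual distance of 3 bins and stay 15 bins clear of boundaries.**
  Isolated flips dent the insulation track by well under the 0.1
  retention threshold; clustered flips would fabricate boundaries, and
  flips near boundaries would change valley shape between conditions and
  contaminate the strength comparison. Switch-flip counts are exact
  (rounded to whole bins), so realized switch fractions match their
  targets to within half a percentage point.
* **Gene density is 3x higher in A bins**, which both mirrors real
  genomes and gives the PC1 orientation anchor a genuine correlation with
  compartment state; with uniformly placed genes, orientation would be a
  coin flip.

What the generator does *not* emulate: restriction-fragment and GC biases
(ICE is exercised by construction, not by planted bias), overdispersion
(Poisson only), inter-chromosomal contacts, translocations, protocol
artifacts, and compartment switches that occur as contiguous multi-bin
domains. Passing recovery tests therefore demonstrates correctness of the
estimators under this model, not performance on any real library.

## Numerical choices

* ICE: relative tolerance 1e-6, 300 iterations, warning (not error) on
  non-convergence; zero-marginal bins auto-masked.
* O/E: diagonal excluded (self-ligation artifacts); distances with zero
  expectation give NA.
* Eigenvector: deterministic start vector, tolerance 1e-12 on the
  iterate, degenerate-spectrum flag at a relative gap of 1e-6.
* Candidate plateaus: leftmost minimum; candidate windows containing NA
  are skipped.
* Boundary matching: greedy nearest-first on bin distance, ties broken by
  position order.
* Pairs with non-positive strength are excluded from change
  classification and counted.
* All simulation seeds are explicit; artifact-specific sub-seeds are
  derived from one master seed so matrices, expression and peaks can be
  regenerated independently.

## Problem sizes used in the shipped checks

The reference study (2000 bins, ~2e6 contacts) runs the full comparison
in ~3 minutes on one core; the test suite additionally uses 150-500-bin
studies for structural properties, brute-force insulation oracles at up
to 50 bins, 200-bin matrices for the balancing contract, and 1000
null-model replicates for the rank-sum calibration. The byte-identity
reproducibility check runs a 400-bin study twice.

## Known limitations

* Compartment calls at 40-kb bins with ~1000 contacts/bin are near the
  depth limit of the classical correlation-eigenvector construction;
  bins with tiny |PC1| are the ones that mislabel.
* Boundary strength compares insulation valleys only; a boundary
  co-located with a compartment edge is insensitive to `t` changes (see
  above).
* The 400-kb merge rule reads the minimum-TAD prose literally as "merge
  into a boundary region"; a discard variant would change TAD counts on
  boundary-dense chromosomes.
* Switch fractions depend on the denominator (eligible vs all bins); both
  are reported.
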