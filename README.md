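# hicswitch

Differential analysis of 3D genome architecture between two conditions
from Hi-C contact maps: A/B compartment calling and switch
quantification, insulation-score TAD boundary detection with
cross-condition strength comparison, and integration of compartment
switches with gene expression fold changes and histone-mark peak
coverage. A synthetic two-condition Hi-C generator with known ground
truth makes every stage testable without external data.

The package is aimed at analysts comparing a derived cell state against
its parental line — e.g. a drug-resistant clone against the sensitive
parent — who want the architectural summary statistics such studies
report: the fraction of the genome that switches compartment, how many
TAD boundaries weaken or strengthen, and whether expression follows the
switches.

## The methods in brief

**Compartments.** Per chromosome, the raw contact matrix is ICE-balanced
(`balanced[i,j] = raw[i,j]/(b_i b_j)` with equal marginals), divided by
the mean contact frequency at each genomic distance (observed/expected),
and converted to the Pearson correlation matrix of its rows. The
eigenvector of the largest-magnitude eigenvalue (PC1), sign-anchored to
gene density, classifies bins: PC1 > 0 is compartment A, PC1 < 0 is B. A
bin whose PC1 sign differs between conditions is a switch (AB = A in
condition 1, B in condition 2); switch fractions are reported over bins
labelled in both conditions.

**TAD boundaries.** At 40-kb resolution the insulation score of bin *i*
is `log2(C_i / mean(C))`, where `C_i` sums balanced contacts crossing the
bin within a 200-kb window. Candidate boundaries are monotone insulation
minima within a 200-kb search range; each is quantified by its 100-kb
flank means (`delta = mean_left - mean_right`) and valley strength
(flank mean minus valley score), and retained when strength >= 0.1.
Boundaries are matched across conditions by interval overlap (one bin of
slack); `log2(strength2/strength1)` beyond +-log2(1.25) classifies a
boundary as strengthened/weakened. Intervals between boundaries become
TADs; boundaries closer than 400 kb merge into extended boundary
regions. A directionality-index track is available as a cross-check.

**Integration.** Genes inherit the switch class of the bin containing
their TSS; expression change is `log2((FPKM2+1)/(FPKM1+1))`, summarised
per class. Peak sets reduce to per-bin base-pair coverage, compared
between A and B bins with a two-sided Mann-Whitney test.

See `vignettes/differential-architecture.Rmd` for the full model
description, parameter rationale, and the synthetic study design.

## Worked example

Simulate the reference two-condition study (one 80-Mb chromosome at
40-kb bins, ~2 million contacts per condition, 9%/10% planted A-to-B /
B-to-A switch fractions, five TAD boundaries of which 40% weaken) and
run the full comparison:

```r
library(hicswitch)
ds  <- simulate_dataset(simulation_config(), seed = 1)
res <- run_differential_pipeline(ds$matrix1, ds$matrix2,
                                 genes = ds$genes, peaks = ds$peaks)
res
#> Differential 3D-genome comparison
#>   bins: 2000 (eligible in both conditions: 2000)
#>   compartment switching: 19.30% of eligible bins (A->B 9.20%, B->A 10.10%)
#>   boundaries: 5 (cond1) / 6 (cond2)
#>   boundary strength: 40.00% weakened, 0.00% strengthened, 60.00% stable (5 pairs)
#>   expression median lfc: AB -1.373, BA 1.436 (direction consistent: TRUE)
#>   peak coverage: A 950.8 bp/bin vs B 981.8 bp/bin, rank-sum p = 0.345
```

Reading the output: 19.30% of eligible bins changed compartment
(planted: 19%), split 9.20% A-to-B and 10.10% B-to-A (planted: 9%/10%).
All five planted boundaries are recovered in both conditions (condition
2 additionally picks up one spurious shallow minimum, which stays
unmatched); 40% of the five matched pairs are classified weakened,
matching the planted fraction. Genes in A-to-B bins are down-regulated
(median log2 fold change -1.37) and genes in B-to-A bins up-regulated
(+1.44), recovering the planted +-1.5 effects up to the pseudocount
shrinkage; the simulated peaks carry no compartment preference and the
rank-sum test correctly finds none (p = 0.35).

`run_differential_pipeline(..., out_dir = "out/")` additionally writes
PC1 bedGraphs, switch/boundary/TAD BED files, per-gene tables, and a
deterministic JSON report. A thin command-line wrapper with `simulate`
and `run` subcommands is installed at `inst/scripts/hicswitch.R`.

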