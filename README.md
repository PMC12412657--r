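# fissionkit

Tools for dating and characterising a centric chromosomal fission from
comparative and population genomics. The package is aimed at
evolutionary genomicists studying karyotype change between closely
related species — the canonical setting is one lineage carrying a
fissioned chromosome, a sister lineage retaining the ancestral
chromosome, and an outgroup to polarise changes.

## What it computes

**Fission dating from GC-biased substitution clusters.** Telomeric
regions experience elevated GC-biased gene conversion, producing
clusters of weak-to-strong (AT→GC) substitutions. A region that became
a neo-telomere at time T carries this signature in proportion to T.
The pipeline:

1. polarises single-nucleotide differences (SNDs) between target and
   query with an outgroup (`polarize_snds`),
2. calls **bias-clustered substitutions** (BCS): weak-to-strong SNDs
   inside any 300-bp window with ≥ 4 SNDs of which ≥ 80% are
   weak-to-strong (`find_bcs`, exact over all window offsets),
3. computes **UBCS** per window or region: observed BCS minus a
   seeded permutation expectation (`ubcs_by_window`,
   `ubcs_for_region`),
4. dates the fission as
   **T = T_div × (1 − R1/R2)** (`estimate_fission_time`,
   `date_fission`), where R1 compares query- vs target-derived UBCS at
   the breakpoint flank and R2 compares query UBCS between the initial
   telomeric region and an interior control.

**Allele-age dating from net divergence.** Windowed π, Dxy and
Weir–Cockerham FST from a two-population VCF (`window_stats`), net
divergence Da = Dxy − (π_x+π_y)/2 and **T = Da/(2μ)** generations
(`da_and_time`).

**Supporting analyses.** Hard/soft variant filtering with a
per-site audit trail and exact HWE test (`filter_variants`,
`hwe_exact_p`); SV fixation screening (`sv_fixation_screen`);
region-class contrasts with exact Mann–Whitney tests
(`region_contrast`); telomeric-repeat scanning and interstitial
telomeric sequence (ITS) calling (`scan_telomeric_repeats`,
`call_its`); synteny-based fission/fusion polarisation and breakpoint
localisation (`call_rearrangements`, `localize_breakpoint`); exonic
splicing enhancer disruption scoring and exon-skipping consequence
prediction — frame, premature termination codon, domain truncation,
RT-PCR amplicon sizes (`scan_ese`, `mutation_ese_impact`,
`skipping_consequence`).

**Synthetic data with ground truth.** Every stage has a
seed-deterministic generator (`simulate_fission_triple`,
`simulate_divergent_populations`, `simulate_rearranged_genomes`,
`simulate_transcript_locus`) that emits standard formats plus a truth
record, so the whole pipeline is verifiable without genome assemblies.

## Worked example

```r
library(fissionkit)

# simulate a 10-Mb fission triple: divergence 2.8 Myr, fission at 40%
# of that time (truth T = 1.12 Myr), breakpoint at 7 Mb
sim <- simulate_fission_triple(seed = 1, emit_genomes = FALSE)

est <- date_fission(sim$snds, sim$regions, T_div = 2.8e6, seed = 1)
est
#> Fission-time estimate: T = 1.281e+06 years (T_div = 2.8e+06, R1 = 1.704, R2 = 3.14)

est$ubcs[, c("label", "lineage", "observed_bcs", "expected_bcs", "ubcs")]
#>              label lineage observed_bcs expected_bcs     ubcs
#> 1 breakpoint_flank   query         2867      647.525 2219.475
#> 2 breakpoint_flank  target         1550      247.562 1302.438
#> 3        telomeric   query         4459     1412.530 3046.470
#> 4          control   query         1141      170.859  970.141
```

The telomeric region shows the strongest excess of clustered AT→GC
substitutions (UBCS 3046), the control region the baseline (970), and
the query breakpoint flank an intermediate excess (2219) reflecting the
time it has spent as a neo-telomere. This single seed recovers
T = 1.28 Myr against the planted 1.12 Myr; averaging the estimator over
20 seeds (as `scripts/acceptance.R` does) gives 1.08 Myr.

Dating a derived allele from population data:

```r
pop <- simulate_divergent_populations(L = 1e6, T_gen = 1e5, seed = 1)
geno <- vcf_genotype_matrix(pop$vcf, pop$samples_x, pop$samples_y)
ws <- window_stats(geno, 2e4, 2e4, chrom_length = 1e6, callable = pop$callable)
wsum <- function(v) sum(v * ws$n_callable) / sum(ws$n_callable)
da_and_time(wsum(ws$dxy), wsum(ws$pi_x), wsum(ws$pi_y), mu = 3.03e-9)$T_generations
#> [1] 99964.28
```

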