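---
title: "Methods: dating and characterising a chromosomal fission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating and characterising a chromosomal fission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fissionkit)
```

# The scientific setting

When a chromosome undergoes a centric fission, each broken end must
acquire a functional telomere to persist. Telomeric and subtelomeric
regions experience elevated GC-biased gene conversion (gBGC), which
leaves a measurable signature: clusters of weak-to-strong (W→S, i.e.
AT→GC) substitutions. A region that *became* telomeric at some time T
ago carries this signature in proportion to the time it has spent in the
telomeric state. `fissionkit` implements the statistics needed to read
that clock from a pair of closely related genomes (one fissioned, one
not) plus an outgroup, together with the population-genomic and
molecular-consequence analyses that typically accompany such a study:
windowed differentiation around the breakpoint, net-divergence dating of
individual derived alleles, telomeric-repeat scanning, synteny-based
polarisation of the rearrangement, and splicing-disruption prediction
for candidate causal mutations.

# SND polarisation

`polarize_snds()` walks three aligned sequences (target, query,
outgroup). A column is a usable single-nucleotide difference (SND) iff
the target and query disagree and the outgroup matches exactly one of
them; the lineage the outgroup does *not* match carries the derived
allele. Columns with gaps, N, or an outgroup allele matching neither
or both sequences are discarded — no parsimony rescue, because a
mis-polarised SND fabricates ancestry. CpG context is not masked (no
such filter is applied by default; the substitution model underlying
the clock does not require it). A W→S flag is set when the ancestral
base is A/T and the derived base is G/C.

# BCS and the UBCS statistic

A **bias-clustered substitution (BCS)** is a W→S SND lying in at least
one 300-bp window that contains ≥ 4 SNDs of the same lineage of which
≥ 80% are W→S. `find_bcs()` evaluates *every* integer window offset.
Internally this is done by enumerating every distinct window *content*:
the content of any window is a contiguous run of the position-sorted
SNDs, and a run i..j is realisable iff an integer start s exists with
max(pos[j]−299, pos[i−1]+1) ≤ s ≤ min(pos[i], pos[j+1]−300). This is
provably identical to the exhaustive scan (the test suite checks exact
agreement against a literal all-offsets oracle) at O(n · k) cost, where
k is the maximal number of SNDs per window. A scan anchored only at SND
positions would *not* be equivalent: four W→S SNDs at 100..130 followed
by two non-W→S SNDs at 350, 360 qualify only through the window
[50, 350), whose left edge is not an SND.

Only the W→S substitutions inside a qualifying window are counted as
BCS — the statistic is about biased substitutions; the non-biased ones
sharing the window merely provide the local density.

**UBCS** for a region is `observed − expected` BCS, where the
expectation is a Monte-Carlo permutation null: the W→S labels are
shuffled uniformly over the region's SND positions (positions and the
total label count preserved), 1000 permutations by default, seeded.
This conditions on the local SND density and isolates *clustering of
the bias* as the signal. Two conventions deserve note:

* **Sign.** We report observed − expected, so positive UBCS means an
  excess of clustered GC-biased substitutions. The statistic's name
  ("unexpected" bias) and the use of elevated telomeric values in the
  dating ratios both require this orientation.
* **The null model.** A permutation null was chosen over any analytic
  approximation because the exact-window BCS rule makes the null
  distribution awkward analytically, while the permutation is exact up
  to Monte-Carlo error, conditions on the observed positions, and is
  cheap at these problem sizes (the inner loop is compiled).

Under the null (labels genuinely i.i.d.), E[observed | label count] =
E[expected | label count] exactly, so UBCS is centred at zero — the
suite verifies this over 220 simulated windows.

# Fission dating

With R1 = UBCS_query(breakpoint flank) / UBCS_target(breakpoint flank)
and R2 = UBCS_query(initial telomere) / UBCS_query(interior control),
the fission time is estimated as

$$T = T_{div} \times (1 - R_1 / R_2)$$

`estimate_fission_time()` applies this formula exactly as stated; a
rate-mixture derivation would instead suggest T ∝ (R1−1)/(R2−1), but
the implemented estimator is the published one and we deliberately do
not "fix" it. T_div is always supplied by the user (e.g. from a
demographic model fit); it is never inferred here. Estimates outside
[0, T_div] are reported with an out-of-range flag rather than clamped.

Region conventions: the breakpoint flank defaults to 2 Mb total
(± 1 Mb); the telomeric region and its interior control have identical
width (2 Mb by default) because the estimator compares like with like;
all widths are arguments.

# The fission-triple generator and its calibration

`simulate_fission_triple()` plants the signal the estimator reads:
a Poisson background of SNDs per lineage (default 0.004/bp — a
realistic divergence for sister rodent species at a few Myr separation)
with W→S probability 0.3, plus 300-bp cluster seeds of W→S SNDs at
baseline rate 6e-5/bp, amplified ×k_tel (default 3) in telomeric
regions of both lineages and ×k_tel·(1−f) in the query breakpoint
flank. Under ideal proportionality of UBCS to cluster intensity this
gives E[R1] = k_tel(1−f), E[R2] = k_tel, hence E[R1]/E[R2] = 1−f and
the printed estimator recovers T = f·T_div. The generator is thus
**formula-consistent by construction**: recovery tests validate the
pipeline implementation, not the formula's biological derivation.

Two calibration subtleties shaped the defaults:

* UBCS is not *perfectly* proportional to cluster intensity, because
  the permutation null partially rediscovers the planted dense spans at
  a rate that grows with the region's overall W→S fraction. Keeping the
  background substitutions dominant (0.004/bp against 6e-5/bp × 12-SND
  clusters) and the background W→S fraction moderate (0.3) makes this
  deflation small and nearly uniform across regions; the residual error
  of the recovered time is about −2% at f = 0.4, well inside the 15%
  band the recovery test allows.
* Larger clusters (12 SNDs) reduce the *relative* deflation per
  cluster and the Jensen bias of the UBCS ratios, at no cost to
  realism for a synthetic benchmark.

The generated genomes additionally carry terminal (TTAGGG)n arrays and
an interstitial telomeric array at the breakpoint, written identically
into all three sequences (a conserved ancestral ITS), so the repeat
scanner can be validated on the same data without creating spurious
SNDs; SNDs falling inside repeat arrays are removed from the truth
table for consistency.

What the generator does *not* emulate: linked substitution processes,
rate variation along the chromosome, CpG hypermutability, alignment
error, and lineage-specific SND ascertainment. Passing recovery tests
therefore demonstrates correctness of the statistics and their wiring,
not robustness to real-data artefacts.

# Divergence dating from net divergence

For two populations, per-site nucleotide diversity uses the unbiased
pairwise estimator 2j(n−j)/(n(n−1)) over called chromosomes, raw
divergence is d_xy = p_x(1−p_y) + p_y(1−p_x), and windows divide summed
per-site values by the *callable* site count, so monomorphic callable
sites contribute zero (all-sites genotyping semantics). Net divergence
Da = D_xy − (π_x+π_y)/2 converts to time as T = Da/(2μ) generations
(μ defaults to 3.03e-9/site/generation in the simulator; generation
time defaults to 1 year). Negative Da is reported raw with the time
flagged undefined — clamping would hide model misfit.

`simulate_divergent_populations()` is calibrated so that E[Da] = 2μT
holds *exactly*: polymorphism is modelled as shared ancestral variation
(the same allele frequency q ~ U(0,1) in both populations, genotypes
drawn by independent binomial sampling), which contributes identically
to D_xy and to (π_x+π_y)/2 in expectation. Private-to-one-population
polymorphism with uniform frequencies would instead contribute 3π/2 to
D_xy against a π/2 correction and bias the clock upward. When unequal
diversity targets are requested, the excess of the more diverse
population is added as private low-frequency polymorphism
(q ~ U(0, 0.1)), whose residual upward bias on D_xy is below 4% of the
excess; the defaults use equal targets (π = 1e-3, a realistic rodent
value), where the construction is exact. Default sample sizes are 14
and 13 diploids. Sites are independent (no linkage), which is adequate
for mean-statistic recovery but not for haplotype-structure statistics.

# FST and region contrasts

FST uses the Weir & Cockerham (1984) two-population variance
components a, b, c computed from called genotype counts; windows report
the ratio-of-sums Σa / Σ(a+b+c) ("weighted" convention, matching the
common command-line tools). Per-site components are exported for other
weightings. The estimator can legitimately go negative near zero
differentiation and is reported raw.

Region-class contrasts (e.g. breakpoint flank vs the rest of the
fissioned chromosome vs other chromosomes) use a two-sided
Mann–Whitney test: exact when both classes have ≤ 12 windows —
enumeration over all C(n+m, n) assignments via dynamic programming on
doubled midranks, which handles ties exactly — and the normal
approximation with tie and continuity correction otherwise. The two
paths agree to |Δp| ≤ 0.02 at the boundary in the test suite.

# Variant and SV filtering

`filter_variants()` reproduces a conventional resequencing filter
stack in an auditable form. Genotype-level masking first (GQ < 20,
DP outside [5, 150] by default), then ordered site filters:
multiallelic, within 5 bp of an indel, called fraction < 0.95
(vcftools `--max-missing` semantics: the value is the *minimum called
fraction*), minor-allele frequency < 0.05, exact Hardy–Weinberg
p < 0.001. Each removed site records its first failing rule, making
the audit deterministic, and the filter is idempotent. The HWE test is
the standard exact test, two-sided by probability mass, applied after
masking. The SV screen flags variants ≥ 50 bp with missing rate ≤ 0.05
that are homozygous in every called focal-species individual and absent
from every called individual of the other species.

# Telomeric repeats

`scan_telomeric_repeats()` counts non-overlapping exact matches of the
repeat unit (TTAGGG by default) and its reverse complement per tiling
window; density is unit-length × hits / window-length. Matching is
window-local, so a pure-repeat window has density slightly below 1 when
the window width is not a unit multiple. No degenerate-unit matching is
attempted — exact matching is deterministic and sufficient for
validating planted arrays; fuzzy units would be a flag on top of the
same machinery. `call_its()` merges dense windows (density ≥ 0.4,
bridging ≤ 1 sparse window) into runs, keeps runs ≥ 1 kb, and labels a
run terminal when it touches the outer 100 kb of the chromosome,
interstitial otherwise. The density/span/margin defaults are package
choices (exposed as arguments) — they recover planted arrays with at
most one window of boundary error across random seeds while calling
nothing on motif-free sequence.

# Synteny-based polarisation

`call_rearrangements()` works per reference chromosome: a candidate
split exists when ≥ 2 query chromosomes each cover ≥ 5% of it with ≥ 2
blocks. The outgroup decides polarity: one outgroup chromosome
continuous across the candidate breakpoint ⇒ the split arose in the
query lineage (fission_in_query); different outgroup chromosomes on the
two sides ⇒ the joined reference state is derived (fusion). A 1:1
reference chromosome whose *outgroup* mapping splits is likewise a
fusion. A complementary query-side pass recognises the mirrored
signatures (fission_in_ref / fusion_in_query), so that swapping which
genome is called "reference" attributes the same biological event to
the same lineage. Strand is ignored for the call — inversions inside a
segment do not change which query chromosome a block belongs to.
`localize_breakpoint()` orders blocks along the reference, chooses the
split minimising misassignments, tolerates ≤ 10% stray blocks (reported
individually), and returns the inter-block gap; fully interleaved
tables are declared ambiguous rather than guessed at.

# Splicing consequences

ESE scanning scores every window of each position-weight matrix as the
sum of per-position weights; a window passes at the matrix threshold.
Matrices are strand-specific. The four SR-protein matrices shipped
under `inst/extdata/pwm` are **synthetic stand-ins** (see the README
there): they reproduce the qualitative behaviour needed for testing —
in particular the SRSF2 matrix is built around a CAGCAG-type core so a
C→T change converting CAGCAGA to CAGTAGA crosses the threshold
downward ("disrupted") — but real analyses should supply
experimentally derived matrices in the same format. "Significant
reduction" of an ESE score is operationalised as threshold-crossing;
the raw score change is also reported so users can apply their own
cutoff.

`skipping_consequence()` decides frame preservation by the skipped
exon's coding length mod 3, then translates the post-skip CDS to find a
premature termination codon (any stop before the final codon). Domains
whose exon range begins at/after the PTC exon are lost; a domain
containing the PTC is partially truncated. RT-PCR amplicon lengths for
inclusion/exclusion isoforms follow from primer positions; their
difference always equals the skipped exon's transcript length,
independent of primer placement — an identity the tests assert. The
transcript generator guarantees a coding-compatible sequence (random
non-stop codons, terminal TAA) with the requested mod-3 class for the
designated skippable exon, and can plant an ESE word at a chosen
position (repairing any stop codon this could create outside the word).

# Numerical and reproducibility choices

* All internal coordinates are 0-based half-open; 1-based appears only
  in region strings and VCF POS. One convention everywhere prevents
  off-by-one drift between modules.
* The W→S fraction threshold is applied as ws_count ≥ 0.8·count − 1e-9
  to make the boundary case (exactly 80%) robust to floating-point
  representation.
* Every stochastic routine takes an explicit seed and echoes it in its
  output; `ubcs_for_region()` derives a per-region seed from the base
  seed and the region start so that a region equal to a tile of
  `ubcs_by_window()` reproduces that tile's value bit-for-bit. UBCS of
  a union of disjoint regions is *not* the sum of the parts, because
  permutations are region-local.
* Problem sizes in the tests and acceptance script (10-Mb chromosome,
  2-Mb regions, 20 seeds for the fission clock; 1 Mb, 20 seeds for the
  Da clock) were chosen so each recovery has Monte-Carlo error
  comfortably inside its acceptance band.

# Known limitations

* The UBCS permutation null conditions on SND positions but not on
  their spatial autocorrelation; data with strong intrinsic clustering
  of *all* substitutions (not just biased ones) will show conservative
  expected counts.
* The dating formula is applied as published; its derivation is not
  re-examined here, and the generator's calibration makes the recovery
  tests circular with respect to that derivation by design.
* The site-independent population model cannot support LD-based or
  haplotype-based statistics.
* Synteny polarisation assumes three genomes; reconstructing ancestral
  karyotypes across many species is out of scope.
* The shipped PWMs are synthetic; classifications under them are
  demonstrations of machinery, not biological claims.
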