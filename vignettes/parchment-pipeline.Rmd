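---
title: "Screening, authenticating and localizing parchment DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, authenticating and localizing parchment DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vellum)
```

`vellum` reconstructs, at desk scale, the analysis chain used for shotgun
ancient-DNA libraries from single-individual skin artefacts: species
screening across candidate genomes, endogenous-DNA quantification,
mitochondrial contamination bounding and haplogroup placement, and breed
affinity from a SNP panel, with a ZooMS peptide-mass module as the
independent proteomic check. This vignette describes the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical conventions, so that results
are interpretable without reading the source.

## The screening model

Reads are aligned ungapped and end-to-end against every candidate genome.
The aligner splits a read of length $L$ into $m+1$ non-overlapping blocks
and takes a seed of `seed_len` bases from the start of each: any placement
with at most $m$ mismatches must match one block exactly (pigeonhole), so
the search is complete whenever $\mathrm{seed\_len} \le \lfloor L/(m+1)
\rfloor$. With the default `seed_len = 7` this holds for every read the
30 bp length filter admits at $m \le 3$; reads too short for the guarantee
fall back to an exhaustive scan, so the hit set is complete at every
length. An `N` on either side counts as a mismatch. Larger seeds (e.g. 12)
are accepted for speed, at a documented loss of completeness for short
reads. Indels are out of scope: the reads are short and the screening
question is about bulk homology, not precise alleles.

Per tolerance $m \in \{0,1,2,3\}$ each read falls in exactly one of five
classes — unique to one genome, multiple places in one genome, unique in
several genomes, multiple places in several genomes, or no hit — and
fractions are reported per genome with all reads as the denominator (a
multi-genome read counts for each genome it hits). The species call is the
genome maximising the unique-to-one-genome fraction at $m=0$; if the margin
to the runner-up is below 2 percentage points (configurable) the call is
refused as ambiguous rather than guessed. All reads are screened; no
subsampling is applied.

## Mapping quality and the endogenous filter chain

True aligner mapping qualities are model-specific, so the package uses an
explicit three-tier surrogate: a sole best hit with no alternative within 2
mismatches scores 37; a sole best hit with a close alternative 25; tied
best hits 0. Thresholding at 30 therefore retains exactly the confidently
unique tier, and the later uniqueness filter coincides with it by
construction — the two stages are kept separate anyway so their counts are
individually reported.

The chain runs mapq → duplicate removal → contaminant subtraction →
uniqueness. The order is a package decision (deduplicating before or after
the mapq filter changes counts) and can be permuted via the `order`
argument. Duplicates share (contig, strand, 5′ start) — for a minus-strand
hit the 5′ start is its rightmost coordinate — and the surviving read is
the one with the greatest base-quality sum, ties broken by read id, which
makes the rule total and deterministic where external tools are
version-dependent. Contaminant subtraction removes any read with at least
one placement in the contaminant genome at $\le 3$ mismatches,
irrespective of mapping quality on either side. The mitochondrial contig
is excluded from the nuclear chain.

Percentages everywhere come from one formatter: half-up rounding at one
decimal. Genome retrieval is the fraction of nuclear bases covered at
least once by surviving hits. Sex is called from the X-to-autosome mean
depth ratio with thresholds 0.8 (XX) and 0.6 (XY); the expectation is ~1
for two X copies and ~0.5 for one, and the band between the thresholds
refuses rather than guesses.

## The mitochondrial contamination statistic

The consensus is the majority base per position (ties and zero depth give
N). Diagnostic (haplotype-informative) positions are operationalised as
consensus-vs-reference differences at depth ≥ 10 outside supplied exclusion
intervals — in real ovine data the 75–76 bp tandem repeat in the control
region, which aligns ambiguously; the generator plants such a motif so the
exclusion logic is exercised. With $c$ consensus-base observations among
$n$ read-site observations summed over diagnostic sites, support is
$\lfloor 100c/n \rfloor$ and maximum contamination $\lceil 100(n-c)/n
\rceil$. Floor and ceil are deliberate: both round in the direction that
overstates contamination, which is the conservative direction for an upper
bound, and it is the only convention consistent with published count pairs
such as 282/291 → 96%/4%. Observations are counted per read per site;
with an empty diagnostic set the estimator refuses with an explicit error
instead of returning a vacuous 0%.

The statistic conflates contamination with sequencing error, heteroplasmy
and residual damage, so it is an upper bound, not an estimate of
contamination alone. Its sampling error matters at realistic depths: with
20 diagnostic sites at 25× (~500 observations) the binomial standard error
at a true rate of 10% is ±1.3 points, so point estimates regularly land 2
points from the truth; the package's recovery tests show exactly this
behaviour (the ±2-point band holds ~100% and ~96% of the time at ρ = 0.02
and 0.05, but only ~87% at ρ = 0.10).

## Distances, trees and placement

Jukes–Cantor distances use complete deletion: every column with a gap or N
in any sequence is removed before $p$ is computed, and $d = -\frac34
\ln(1 - \frac43 p)$, with an explicit saturation error at $p \ge 0.75$.
Neighbour joining is the Saitou–Nei algorithm (via `ape::nj`) wrapped with
symmetry validation and clamping of negative branch lengths to zero; on an
additive matrix the tree's path lengths reproduce the input exactly, which
is the property the tests assert. Bootstrap supports resample alignment
columns with replacement; each replicate's random stream is derived from
the seed by counter, so supports are reproducible and independent of
evaluation order, and taxa are sorted internally so permuting the input
leaves supports unchanged. Placement adds the sample to the reference
alignment, reports references ranked by distance, and the sample's sister
group in the tree. The multiple alignment itself is consumed, not
computed.

## Pseudo-haploid genotypes and breed affinity

At each panel site the eligible observations are bases from hits with
mapping quality ≥ 30 and base quality ≥ 15; one is drawn uniformly at
random and doubled to a homozygous genotype. The random pick is keyed by
(seed, site id), so calls do not depend on the order sites are processed.
Transition pairs (C/T, G/A) are excluded at the site level because
post-mortem deamination produces exactly those changes; strand-ambiguous
pairs (A/T, C/G) are removed at merge time because orientation cannot be
reconciled; merged calls are complemented when the call's allele pair is
the reverse complement of the panel's. Only A/C and G/T sites can survive
both filters — asserted as an invariant — which is also why deamination
cannot flip a surviving genotype: C→T or G→A at such a site produces an
off-panel base and a missing call, never the other allele.

Allele sharing is mean identity-by-state, $s = \sum \mathrm{IBS} / 2L$ over
each comparison's own overlap (pairwise deletion — parchment calls are
sparse), with $1-s$ the distance; the exact formula behind published
sharing maps is typically unstated, and mean IBS is the standard choice,
so it is documented prominently here. Breed summaries average individuals,
not loci, within breed. The optional surface is inverse-distance-weighted
interpolation (power 2) on breed coordinates — exact at the breed points
and bounded by the input range; it is emitted as data, not as a map.

## The ZooMS module

Collagen peptide-mass fingerprinting: trypsin digestion (cleave after K/R
except before P, up to 2 missed cleavages), monoisotopic $[M+H]^+$ masses
(residue masses + water 18.010565 + proton 1.007276), hydroxyproline
modifications as +15.994915 per allowed hydroxylation, and tolerance
matching (default ±0.2 Da, typical of externally calibrated MALDI-TOF;
ppm also supported). A species' score is the fraction of its *diagnostic*
markers matched; calls refuse when the top two scores are within 0.2. The
bundled marker table is synthetic demonstration data — real marker masses
are user-supplied, and discrimination quality is entirely a property of
that table. Raw spectrum processing (baseline, peak picking, calibration)
is out of scope; peak lists come in as two-column TSV.

## What the generator emulates — and what it does not

`simulate_genomes()` evolves every species from one ancestral sequence by
independent substitution, so expected pairwise identity between species
$i,j$ is $(1-d_i)(1-d_j) + d_i d_j/3$. The default divergences (0.04,
0.05, 0.08, 0.15 for the sheep-, cow-, goat- and human-like genomes) put
pairwise divergences in the 8–25% range the screen must separate. A shared
repeat (100 bp × 5 by default) is planted verbatim at identical
coordinates in all genomes to create cross-mapping homology, and each
mitochondrial contig receives a 75 bp tandem duplication emulating the
control-region repeat. A second same-species individual is generated at
0.002 divergence.

`simulate_reads()` draws fragments from a lognormal (mean 45, sd 12 bp,
truncated to 18–150 bp; only the 49 bp read length is fixed by the
sequencing design, so the fragment distribution is chosen as typical for
ancient skin), sequences 49 bp single-end, appends adapter when the fragment is
shorter than the read, and applies a double-stranded damage model: 5′
C→T with probability $\delta \,(1-\lambda)^{k-1}$ at position $k$ and the
mirrored 3′ G→A (defaults $\delta = 0.1$, $\lambda = 0.3$, modest damage
appropriate to young material). Base qualities are constant Q35 —
downstream they are only thresholded at Q15, so modelling quality decay
would add nothing the pipeline can see. The default source mix is 95%
target with small second-individual, cow-, goat- and human-like fractions,
matching the low cross-contamination regime the method is meant to verify.
Layout, damage and error draw from independent seed-derived streams, so
changing the damage rate does not change which fragments are drawn — this
is what makes the damage-robustness property testable read-for-read.

`simulate_panel()` uses the Balding–Nichols model: per-site ancestral
frequencies uniform on [0.1, 0.9], per-breed frequencies
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, Hardy–Weinberg genotypes within
breed — the simplest model with one interpretable differentiation
parameter (default $F_{ST}=0.15$, strong breed structure). Allele pairs
are drawn uniformly from all six unordered base pairs so the transition
and strand-ambiguity filters remove realistic fractions (~2/3 of sites).
Breed coordinates default to a British-Isles-like grid.

Not emulated: indels and recombination, realistic chromosome counts and
repeat landscapes, reference-genome incompleteness, library-preparation
chemistry beyond a configurable duplicate fraction, base-quality decay,
and linkage between panel sites. Passing tests therefore demonstrate that
the estimators recover what the generative model puts in — contamination
fractions, source mixtures, breed membership — not that real parchment
libraries are free of the artefacts the generator omits; in particular
reference-build incompleteness, which inflates cross-species unique
fractions in real data, is invisible here.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open internally, 1-based only in SAM export.
Consensus ties give N; zero-depth positions give N. The percentage
formatter rounds half away from zero at one decimal; the contamination
statistic floors/ceils as above. The estimator refuses on an empty
diagnostic set; `neighbour_joining()` rejects asymmetric matrices and
fewer than 3 taxa; JC distances error at saturation and on all-gap
comparisons; the species and PMF calls return `"ambiguous"` inside their
margins instead of a forced winner. All randomness flows from one integer
seed through named streams (`derive_seed`), so every result in a run is
reproducible bit-for-bit, and identical seeds give byte-identical
`run_all()` bundles.

## Problem sizes

The test-suite study conditions are desk-scale by design: toy genomes of
~90 kb per species (two autosomes, an X, a 16.6 kb mitochondrial contig),
read sets of 4,000–100,000, mitochondrial depths of ~25×, panels of 6,000
sites × 8 breeds × 12 individuals, and 100-replicate bootstraps in the
end-to-end bundle (1,000 remains the default for standalone tree work).
These sizes make every property — aligner completeness against brute
force, contamination recovery across ρ ∈ {0.02, 0.05, 0.10}, breed
localization over 20 seeded panels — recomputable from scratch in minutes
while keeping the estimators' sampling behaviour visible rather than
asymptotically hidden.

## Known limitations

The mapping-quality surrogate is not BWA's model; absolute thresholds
transfer only in the sense documented above. The aligner is ungapped, so
reads spanning indels against the reference are lost rather than clipped.
The contamination bound counts read-site observations, treats every
discordant observation as potential contamination, and is dominated by
binomial noise at low depth. Breed affinity uses mean IBS on pseudo-haploid
calls — it localizes relative affinity; it is not an admixture model and
gives no calibrated ancestry fractions. The IDW surface is a visual
summary with no spatial statistics behind it.
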