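---
title: "Methods: simulating and analysing X-island selective introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing X-island selective introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandswap)
```

# The biological setting

*Anopheles coluzzii* and *An. gambiae* s.s. (historically the 'M' and 'S'
molecular forms) are incipient sympatric species kept apart largely by
assortative mating. Their genomes are nearly homogenised by gene flow
except for a few pericentromeric "islands of divergence", the largest of
which sits on the X chromosome and contains the diagnostic rDNA marker.
The experimental idea this package models is a **reciprocal island
swap**: use the rDNA marker to drag the S-form X island into an M-form
genetic background through repeated backcrossing, derive strains that
differ *only* at the island (RbMM vs RbSS), and test whether mating
preference follows the island.

The package implements the full computational chain around that design:
the breeding-scheme simulation, pooled-sequencing allele-frequency
tables, FST genome scans with introgressed-segment delineation,
codon-level annotation of fixed differences with field-conservation
filtering, and the goodness-of-fit statistics used for mating assays and
Mendelian ratios.

# The crossing design and its simulator

`run_introgression_design()` simulates, generation by generation:

1. **F0** — M males × SS females. X-linkage forces all daughters to be
   MS and all sons S at the marker.
2. **Backcrosses 1–4** — MS females × fresh M males. Each generation,
   80 females oviposit individually, ten 2nd-instar larvae per family
   are genotyped at the rDNA marker, pure-MM families are discarded (a
   family counts as *mixed* as soon as one genotyped larva carries an S
   allele), and MS daughters from the kept families become the next
   generation's mothers.
3. **Fixation crosses 1–2** — random mating within the introgressed
   strain (100 females × 100 males per cage). The final generation's MM
   females and M males found the RbMM strain; SS females and S males
   found RbSS.

Individuals carry ancestry-block haplotypes (ordered `[start, end)`
blocks labelled M or S): two X copies in females, one in males, two
copies of each modelled autosome arm, plus unrecombining mitochondrial
(maternal, S in the recombinant strains) and Y (paternal, M) labels.

## Recombination model

`meiosis()` draws crossover counts from a Poisson distribution with mean
equal to the map length in Morgans and places them by inverse-CDF
sampling on the piecewise-constant intensity — an inhomogeneous Poisson
process with no crossover interference. The gamete starts from a fair
coin and alternates parental source at each crossover. Parameters:

* X length **24.4 Mb**, with the island spanning **18.1 Mb to the
  centromeric end** and the rDNA marker at **24.3 Mb** ("very near the
  centromere"); one autosome arm (49.4 Mb, "2L") is modelled by default
  to track background-genome homogenisation.
* Base crossover rate **1.5 cM/Mb**, a typical anopheline autosomal
  scale, giving 0.366 Morgans for the X.
* **20-fold** rate suppression inside the island window. Published
  estimates for this pericentromeric region span roughly 16–35×; 20 is
  a round value inside that range. At fold 20 essentially no crossover
  falls inside the island during the six simulated generations, so the
  island travels as one piece — which is the premise of the design.
* Recombination is applied in both sexes for autosomes (anopheline
  males recombine); the male X is hemizygous and passes intact.

Expected behaviour used as test oracles: gametes tile the chromosome
exactly; crossover counts match the Poisson mean; MS daughters are 50%
of backcross daughters (binomial); autosomal S ancestry halves each
generation of crossing to M, reaching (1/2)^5 ≈ 3.1% in the recombinant
strains; and the first fixation generation's daughters follow 3:4:1
MM:MS:SS. On that last point, a 3:1 MS/MM expectation is sometimes
quoted for this generation, but random mating of 1:1 MS/MM females with
1:1 M/S males gives 4:3 by direct calculation; the simulator reports its
simulated ratios and the tests check the 3:4:1 expectation.

## Family structure and brood handling

Each family can contribute at most 50 daughters and 50 sons (the brood
cap). Offspring within a family are independent draws, so the simulator
instantiates them lazily: the ten genotyped larvae, plus only as many
further offspring as are actually recruited as next-generation parents
or strain founders. This leaves every per-generation statistic unchanged
while keeping a full six-generation run under ~2 s, which in turn allows
the multi-seed recovery analyses below (20 independent runs) inside the
test suite. Family-level selection means genotype counts are clustered
by family; single-generation ratios can therefore wander noticeably even
though their expectations are exact, and the tests average over
generations or seeds accordingly.

# Pooled allele frequencies

The synthetic marker panel has two site classes:

* **diagnostic sites** — fixed M/S differences, every 10 kb inside the
  island (the alternate allele is by convention the S allele);
* **background sites** — shared polymorphism, every 50 kb outside the
  islands, with the same alternate-allele frequency (uniform on
  0.05–0.95) in both founder forms.

A pool's true frequency at a site is the mean of the origin-conditional
frequencies over all chromosome copies carried by the pool (2 per
female, 1 per male on X). The observed value is `Binomial(depth, p) /
depth` rounded to the nearest multiple of `1/ploidy_grid`; the defaults
(depth 200, grid 20, i.e. 5% increments) mirror deep pooled sequencing
analysed at an expected pool ploidy of 20.

What this deliberately does **not** model: founder drift or private
variation at background sites (both forms share the exact site
frequency), linkage between nearby background alleles, sequencing error,
or reference bias. Consequently background FST reflects only binomial +
grid noise; passing the recovery tests shows the scan machinery recovers
a planted signal under the stated noise model, not that it is robust to
every artefact of real pool-seq data.

# FST scan, smoothing and segment calling

Per site, `pairwise_fst()` computes `F_ST = 1 − H_s/H_t` with
`H = 1 − Σ pᵢ²`; `H_s` is the mean heterozygosity of the two compared
pools and `H_t` the heterozygosity of the mean alternate frequency
across the *reference pools*. The original analysis computed `H_t`
across all five sequenced populations; here the reference set defaults
to exactly the two compared pools, a reproducible semantics that does
not depend on how many pools happen to be loaded (the caller can pass
any reference set). Sites with `H_t = 0` are undefined and dropped from
the track; negative values (`H_s > H_t`) are reported as-is, with a
`clamp` flag for users who prefer a floor at 0.

Smoothing uses a penalised cubic smoothing spline
(`stats::smooth.spline`) fitted per chromosome over site positions. The
original scan used a proprietary spline routine with a stiffness of
2.72^16 in that software's parameterisation; that exact curve is not
recoverable, so the package exposes the generic penalty `lambda`
(default `1e-6`) and calibrates it on synthetic plateaus instead: a
constant track is reproduced exactly, a dense 0→1 step keeps plateau
centres within 0.05, and `lambda → ∞` tends to the least-squares line.

`call_segments()` takes maximal runs of sites with smoothed FST at or
above the **0.8** threshold, merges runs separated by under **100 kb**,
and discards segments shorter than **200 kb**. These defaults were tuned
on the synthetic planted-island data (10 kb marker spacing) and are all
configurable. Under the default design the caller recovers the planted
18.1–24.4 Mb island boundary to within ±200 kb in at least 18 of 20
seeds, and the segment contains the rDNA marker. Before FST, sites are
filtered to a minimum depth of 10 per involved pool and biallelic
records only; the original study's site filters are not stated, so these
are declared package defaults, not inferences.

# Coding differences and field conservation

`find_fixed_differences()` flags sites where each pool carries the
opposite allele at frequency ≥ 0.95 (configurable). For each such site
`classify_snp_effect()` locates the codon via the gene model's CDS
chain, strand and phase, reverse-complements on the minus strand, and
reports the effect, a codon string in the `gGg/gAg` dialect (lowercase
context, uppercase substituted base, reference before alternate) and a
protein change such as `G74E` (1-based codon coordinates). The
classifier is validated against an independent oracle that translates
the whole CDS on both alleles, over every single-base substitution of
all 64 codons on both strands.

`conservation_filter()` then asks whether each strain difference is
reproduced in independent field pools of the two forms. The M-form
allele is *defined* as the allele at high frequency in the field M pool,
not by reference/alternate status. Thresholds follow the asymmetric
wording of the source analysis: "fixed or nearly fixed (freq > 0.95)" is
read as **≥ 0.95** (applied to the M side for any conservation call and
to the S side for `conserved_high`), while the S-side mid tier uses a
strict **> 0.8**. Both are configurable. Calls are grouped by gene and
the onset (minimum conserved-high position) is reported — the analogue
of the observed conservation starting at ~18.1 Mb. Sites missing from
the field table are reported in a side channel rather than silently
dropped.

The synthetic truth set (`synthetic_coding_dataset()`) plants 20
conserved-high nonsynonymous differences across exactly 12 of 16
island genes, plus mid-conserved and non-conserved decoys, mirroring the
structure of the real candidate-gene table; the pipeline must recover
the 20/12 exactly.

# Mating statistics

`g_test()` implements the likelihood-ratio chi-square
`G = 2 Σ Oᵢ ln(Oᵢ/Eᵢ)` with `df = k − 1`, the `0·ln 0 ≡ 0` convention
(zero observed cells are legal), internal normalisation of expected
proportions, and no continuity correction — the combination that
reproduces the published assay statistics. `pearson_test()` delegates to
`stats::chisq.test(correct = FALSE)`. `summarize_assay()` applies the
test per replicate and to pooled counts per mating combination, with
percentages; `mendelian_ratio_test()` and `hwe_expected_props()` cover
ratio and Hardy–Weinberg checks. No multiple-testing adjustment is
applied, matching the original analysis — users comparing many rows
should adjust downstream (e.g. `p.adjust`).

Two printed values in the source tables are not reproduced by either
statistic and are documented rather than chased: the first-backcross
36:3 ratio is quoted with χ² = 39.2 where the likelihood-ratio value is
32.9 (Pearson 27.9), and one male-choice row (15 vs 16) prints 0.1 where
both statistics give ≈ 0.03. The SS female rows print 34.6, the
truncation of the full-precision 34.657 (= 2·25·ln 2); statistics carry
full precision internally and the 1-decimal display is only a
convention.

Calibration properties verified in the tests: the G-test's Monte-Carlo
type-I error at n = 30 matches its exact size computed by enumeration
over the binomial null (the discrete test is conservative, ~3–4% at the
nominal 5%), and power is monotone in the distance of the mating
preference from 0.5.

# Numerical and design choices

* Coordinates are 1-based inclusive in VCF/GFF/tibbles and 0-based
  half-open in BED; haplotype block arithmetic is half-open internally.
  All conversions pass through `to_bed()`/`from_bed()`.
* All randomness flows through R's RNG; `design_config(seed = )` seeds a
  run and the seed is recorded in every output header and the JSON run
  manifest. Writers are deterministic and atomic (write-then-rename).
* Ties and degenerate inputs: meiosis with a zero-length map returns an
  intact parental haplotype; smoothing falls back to raw values (with a
  warning) below 4 sites per chromosome; `H_t = 0` sites are undefined
  rather than 0 or 1; extinction of MS families aborts with the
  generation index and counts.
* Only single-nucleotide substitutions are annotated; indels pass
  through unannotated. One CDS chain per gene is assumed (no splice
  variants), and functional descriptions of candidate genes are static
  metadata, not computed.

# Problem sizes

The shipped analyses use the design defaults (80 families × 10 genotyped
larvae × 6 generations; ~1,000 panel sites; depth 200). The recovery
analyses in the test suite run 20 independent seeds of the full design,
10,000 gametes for the crossover calibration, 2,000 simulated assays for
the type-I error check, and the all-codon enumeration (64 × 9
substitutions × 2 strands). These sizes were chosen so the whole suite
completes in a few minutes on a single core while keeping Monte-Carlo
standard errors well inside the asserted tolerances.

# Known limitations

* No fitness or viability differences between genotypes: the observed
  first-backcross distortion towards MS is *reported* by the statistics
  module but deliberately not built into the simulator.
* No inversion karyotypes, no sequence-level mutation model, no
  read-level variant calling or genotype likelihoods.
* The spline stiffness is a generic penalty, not the original
  software's parameter; boundary precision is therefore validated on
  synthetic plateaus, and real-data boundary estimates (e.g. whether a
  differentiated flank ends at 14.5 or 14.8 Mb) are outside what this
  package can arbitrate.
* Field pools are modelled as independent binomial samples at the
  planted frequencies; real field populations add structure, admixture
  and sampling artefacts the conservation filter has not been tested
  against.
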