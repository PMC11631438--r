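---
title: "Surrogate-parent DNM calling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-parent DNM calling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfolk)
```

This vignette is the package's own account of the science it implements: the
surrogate-parent model for de novo mutation (DNM) calling, the parental-age
burden-testing framework, the simulator that benchmarks both, and the
numerical and design choices that were genuinely open.

## 1. The surrogate-parent model

A DNM is a variant present in a child and absent from both parental germline
genomes. With both parents sequenced, calling reduces to finding sites where
the child is heterozygous and both parents are homozygous reference. When a
parent is missing, a full sibling can substitute for them wherever the
sibling and the proband co-inherited the same haplotype from that parent:
over such an identity-by-descent (IBD) segment the sibling's shared
haplotype *is* the missing parental contribution. The calling rule is
unchanged — proband heterozygous, every real or surrogate parent homozygous
reference — and requiring the surrogate to be homozygous reference also
polarises the call: a variant carried by the surrogate can never be reported
as a DNM in the proband.

Assumptions: biallelic SNVs on autosomes; sibling relationships as recorded
in the pedigree; phased genotypes for IBD scanning (statistical phasing is
out of scope — use an external phasing tool or the simulator's truth phase).

**Callable fractions.** At a locus, each sibling inherits the same
missing-parent haplotype as the proband with probability 1/2, independently
across siblings and between the two parents. With one real parent and `n`
surrogate siblings the expected callable fraction is `1 − 2⁻ⁿ`; with no
parents it is `(1 − 2⁻ⁿ)²` because both proband haplotypes must be covered,
possibly by different siblings. A single sibling can cover both at once
("double surrogate") over the ~25% of the genome where the pair shares both
parental haplotypes. `theoretical_callable_fraction()` implements the laws;
the test suite verifies that `accessible_regions()` applied to simulated
sibships converges to them for `n` from 1 to 4 (to within 2 percentage
points over 300–400 simulated families per configuration).

## 2. IBD scanning and parental origin

`infer_sibling_ibd()` is a native scanner, not a wrapper: for each of the
four haplotype pairings between two phased siblings it finds maximal runs of
matching alleles over retained common markers and merges runs separated by
short spans. Defaults, chosen to mirror widely used IBD-detection settings
where they translate to a physical-distance scanner:

| parameter | default | meaning |
| --- | --- | --- |
| `min_maf` | 0.10 | markers below this minor allele frequency are ignored (rare variants are uninformative and error-prone) |
| `max_gap_bp` | 1,000 | adjacent match runs separated by at most this span are merged, tolerating isolated discordant genotypes |
| `min_length_bp` | 2 × 10⁶ | minimum segment length |
| `min_markers` | 100 | minimum supporting markers |

One mapping was ambiguous: seed/extend lengths in centimorgans have no
unique bp equivalent, so this scanner works in physical distance throughout
and exposes `min_length_bp` directly.

**Parental origin.** A segment shared between siblings is maternal or
paternal in origin. With the mother sequenced, the natural test — does the
shared haplotype equal one of the mother's two haplotypes over the segment —
fails when the mother's own meiosis recombined her haplotypes inside the
segment (a ~10–30% event for segments tens of cM long). The package
therefore scores *per-marker consistency*: a marker conflicts when the
shared allele is absent from the mother's genotype. A maternal haplotype
conflicts nowhere regardless of maternal recombination, while a paternal
haplotype conflicts wherever the mother is homozygous for the other allele
(an O(10%) fraction of common markers). Segments with at most 1% conflicting
markers are labelled maternal, others paternal; the 1% headroom absorbs
isolated genotype errors.

**Endpoint accuracy.** Past a true recombination breakpoint the siblings'
haplotypes keep matching *by chance* (per-marker match probability roughly
0.5–0.8 at common markers), so inferred endpoints overshoot truth by a
geometric number of markers — a few kb at default densities, not the single
inter-marker gap an identical-haplotype argument would suggest. Tests assert
endpoint agreement within 100 kb plus >90% reciprocal overlap. This
overshoot also motivates the density filter below.

## 3. The filter stack

Filters annotate calls rather than delete them (`pass` is a verdict column),
so each filter's contribution can be audited and benchmarked.

- **Panel** — the site segregates in the population panel
  (`panel_af > 0`). Presence, not frequency, is the criterion: a
  panel-known variant in a proband is far more likely inherited through a
  mis-inferred region than recurrent de novo.
- **Shared** — the variant is carried by ≥ 2 pedigree members who are not in
  a parent–child relationship (a DNM transmitted to one's own child is
  exempt). Catches gene-conversion artifacts and inherited variants leaking
  through IBD errors.
- **Cluster** — transitive chaining of calls pairwise within 50 bp; a chain
  of *more than* 6 calls containing at least one known variant is removed
  whole. Chain size and span follow the stated operating point; the
  known-variant anchor distinguishes inherited haplotype blocks from genuine
  multinucleotide mutation events.
- **VAF** — variant allele fraction below 0.30. Germline heterozygotes
  centre on 0.5; consistently low VAFs indicate clonal somatic
  contamination. `screen_vaf_distribution()` applies the same idea per
  individual (flag when the median VAF is below 0.40).
- **Density** (region-level) — sliding 100-kb windows (50-kb step)
  containing more than 3 Mendelian violations are excised with a 10-kb
  margin. Clustered violations betray regions where the siblings actually
  inherited *different* parental haplotypes, so the "violations" are
  ordinary polymorphism. The window, count and margin are declared package
  defaults (config-exposed), not reproduced from an external source.

## 4. Burden testing under the parental-age model

Expected maternal and paternal counts of each 1-mer class are linear in
parental age at conception; the per-child expectation is their sum, scaled
by a single multiplicative accessibility factor
`accessible_bp / reference_genome_bp`. Coefficients are a *configurable
input* (TSV schema with the reference genome size in the header) — the
package deliberately ships no human fit, since the canonical table is
external; the simulator documents its own truth values (see §6).

Observed counts are compared with expectations by the exact Poisson upper
tail `P(X ≥ obs)` (`stats::ppois`; expectations here are single-digit
counts, where normal approximations are poor). Significance is one-tailed
`p < 0.05` with no multiple-testing correction by default, matching the
framework's exploratory use; a Bonferroni option exists. Families and
carrier groups are tested by summing children's observed and expected counts
per type — each child's expectation is accessibility-scaled *first*, then
summed (the alternative order is not meaningfully different for the
per-child scales involved, but the choice is fixed and documented here).

**Discreteness and test size.** An exact Poisson test is conservative: its
attained size depends on the expected count, approaching the nominal 0.05
only for large expectations. The type-I-error check therefore runs at the
family-total scale (three children, expectation ≈ 210 under the simulator's
defaults), where 10,000 null draws attain a rejection rate within 0.01 of
nominal; at per-type scale the suite asserts conservativeness (≤ 0.05) only.

**Effect sizes.** The excess of observed over expected counts is attributed
entirely to the carrier parent: `fold = (E_carrier + excess) / E_carrier`.
Because ~75% of DNMs are paternal, a given overall enrichment implies a much
larger maternal fold than paternal. `detection_threshold()` gives the
smallest significant count; `min_detectable_fold()` converts it into the
smallest carrier-parent inflation the data have power to flag. A spec-level
note: the smallest significant count for an expectation of 5 at α = 0.05 is
10 (`P(X ≥ 10) = 0.032`, `P(X ≥ 9) = 0.068`), verified against brute-force
pmf summation in the tests.

## 5. The BXD generation-time regression

For recombinant inbred mouse strains, each strain's C>A rate per site per
generation is regressed on its mean generation time (years of inbreeding /
generations, centred at the minimum observed value so intercepts are rates
at the youngest parental age) plus the Mutyh genotype class, by OLS. A
genotype × generation-time interaction is fitted separately: a mutator
acting in ageing gametes would steepen the slope of the affected class,
whereas one acting in the early embryo shifts only the intercept. On data
generated without interaction the interaction coefficient is exactly zero
(tested). The published strain table is an external download; the package
ships the reader and regression, and the corresponding acceptance check runs
only where the user supplies the CSV.

The cellular repair-assay score is `log2(fraction_variant / fraction_wt)`
with a 10⁻³ pseudocount for a zero variant numerator: 0 means wild-type-like
8-oxoguanine repair, negative means deficient.

## 6. What the simulator emulates — and what it does not

`simulate_family()` generates, at genotype level: founder haplotypes
(markers placed as a Poisson process, default 10⁻³/bp; alternate frequencies
from a U-shaped Beta(0.5, 0.5) spectrum rich in the common variants IBD
scanning needs); meioses with Poisson crossover counts on a constant 1 cM/Mb
map; per-child DNM counts Poisson-distributed around the parental-age model,
placed uniformly at non-segregating positions on the correct parental
haplotype; optional gene-conversion tracts (the gamete copies the homologous
parental haplotype); optional per-haplotype genotype-error flips; and allele
depths (depth ~ Poisson(50), alternate reads Binomial(depth, dosage/2)).
Full truth records — planted DNMs, breakpoints, conversion tracts, true IBD
segments — make oracle benchmarking possible, and identical seeds reproduce
outputs byte for byte.

Default truth coefficients are the package's own documented values: ~70 DNMs
per child at parental ages (28, 32), 75% paternal, spectrum shares C>T 0.38,
A>G 0.26, C>A 0.10, C>G 0.09, A>T 0.09, A>C 0.08 — the broad shape of the
human germline spectrum. Their reference genome size equals the default
2 × 100 Mb layout, so default simulations run at accessibility scale 1 and a
child's planted burden is realistic *per genome*, though compressed per bp.
A mutator configuration multiplies the targeted parent's expectation for the
targeted class; the embryonic mode instead deposits unphased extra mutations
post-zygotically on either haplotype, reflecting a maternal-genotype effect
acting on the embryo rather than the gametes.

Not emulated: read-level sequencing (no BAMs — depths are sampled directly),
linkage disequilibrium and demography in founders, sex chromosomes, indels
and multinucleotide events, germline mosaicism shared between siblings, and
half-sibships. Consequently, passing tests demonstrate correctness of the
calling geometry, the filter logic and the statistics under the stated
generative model — not robustness to alignment artifacts, LD-driven phasing
error, or mosaic sharing (sib-shared DNMs are knowingly uncallable by the
sharing filter's design; the benchmark reports them as their own
false-negative category).

## 7. Numerical choices and degenerate inputs

- Coordinates are 0-based half-open everywhere internally; VCF positions are
  converted on read/write and BED output is half-open as on disk.
- Interval arithmetic uses small vectorized kernels (merge via cumulative
  maxima, intersection/subtraction via two-pointer sweeps); interval sets
  here are tens of segments, where per-call overhead matters more than
  asymptotics.
- Two-surrogate mother/father designation is arbitrary by symmetry; the
  package fixes it deterministically (lexicographically smallest id becomes
  the surrogate mother) and the accessible-region construction is tested to
  be invariant under relabelling.
- Ambiguous parental origin (no informative markers, missing mother) is
  `unknown`, never guessed; phasing in two-surrogate mode is `unknown` by
  construction.
- Empty surrogate sets yield empty accessible regions, not errors; an empty
  accessible region makes the rate estimate an error (division by zero is
  never silently returned).
- Calls lacking allele depths pass the VAF filter with a warning rather than
  being dropped.
- `poisson_upper_tail` evaluates `P(X ≥ k)` as `ppois(k − 1, λ,
  lower.tail = FALSE)`, which is exact; the brute-force log-space pmf
  summation appears in the tests as an independent oracle, not in the
  implementation.

## 8. Problem sizes used by the test and acceptance suites

Chosen to exercise every code path in minutes on a single core: unit tests
simulate 2 × 20–30 Mb genomes at 5 × 10⁻⁴–10⁻³ markers/bp; the sharing
geometry uses 1,000 sibling pairs on the full default 2 × 100 Mb layout
(breakpoint-level, no markers); callable-fraction convergence uses 300–400
breakpoint-level families per configuration; burden calibration uses 10,000
null draws. The acceptance script simulates 1,000 sibling pairs and reports
the mean double-surrogate sharing fraction.

## 9. Known limitations

- IBD endpoints overshoot truth by chance matching (§2); the density filter
  and the shared/panel filters are the compensating controls, as in the
  underlying method.
- The burden test inherits exact-test conservatism at small expected counts.
- Carrier-parent fold estimates attribute all excess to one parent; a real
  embryonic mutator splits its excess across both haplotypes, and the
  package's embryonic simulation mode exists precisely to probe that
  distinction.
- The IBD scanner assumes correct phasing; switch errors fragment segments
  and shrink the accessible genome rather than creating false calls (the
  conservative failure mode).
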