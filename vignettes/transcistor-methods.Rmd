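---
title: "Direct haplotyping with solid-phase double ARMS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct haplotyping with solid-phase double ARMS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcistor)
```

## The problem and the method

Defining haplotypes in unrelated individuals is a long-standing obstacle in
human and veterinary genetics: statistical phasing infers phase from
population structure and can carry substantial error, while direct methods
(cloning, allele-specific sequencing) have been slow and low-throughput.
Double ARMS (Amplification Refractory Mutation System) is a direct,
molecular solution: allele-specific primers at *both* ends of an amplicon
mean that product only forms when the two specified alleles lie on the same
chromosome — amplification itself is the cis/trans readout.

The assay this package models multiplexes that idea on spectrally addressed
beads. In phase 1, all forward and reverse allele-specific primers are
present both in solution and covalently anchored to bead classes (one primer
per bead class, up to 100 classes per tube); solution-phase amplicons are
captured ("kidnapped") onto both their forward- and reverse-anchored beads
and extended. In phase 2, the washed beads are interrogated by single rounds
of primer extension with one fluorescently labeled primer per aliquot.
A flow analyser then reports, per bead class and label primer, an event
count and a reporter/background fluorescence ratio. Because every amplicon
is represented on two bead classes, and every SNP participates in reactions
with multiple partners, the readout carries heavy built-in redundancy that
the decoder exploits as quality control.

`transcistor` implements the full computational counterpart: primer-panel
design over an allele alignment, mechanistic simulation of the two-phase
readout, decoding of readouts into constituent haplotypes, allele calling
against a known panel, and cohort statistics including the composite-versus-
direct linkage-disequilibrium comparison. It was developed against the ovine
MHC *DRB1* exon 2 system — 237 aligned bases, 60 polymorphic sites, 33
alleles observed in a 109-ram cohort — and those numbers are the package's
defaults throughout.

## Primer design

Allele-specific primers place the discriminating base at the 3′ terminus:
one primer per base observed at a polymorphic site, per orientation.
Interior polymorphic positions are wobbled with IUPAC degeneracy codes taken
from the panel consensus (`consensus_iupac()`), so one synthesis covers all
alleles at non-discriminating positions. The published primer panel also
used multi-position discrimination sets; the packaged transcription of that
table is parsed and validated (`table2_primers()`), but the pipeline designs
*split* primers — a single discriminating base each — because decoding maps
each positive primer to exactly one base.

Tunable design parameters (`design_constraints()`):

* `tm_target_c = 55`, `tm_tolerance_c = 3` (°C) — the design window used for
  this locus. Primer length is the shortest within `min_len`–`max_len`
  (16–30 nt) whose *mean* melting temperature over the degenerate expansions
  falls inside the window; a wobbled primer has no single Tm, so min, mean
  and max over expansions are reported and the window applies to the mean.
* Tm model: unified nearest-neighbor thermodynamics with duplex-initiation
  terms and a monovalent-salt entropy correction (defaults 50 mM Na⁺,
  250 nM oligo); the Wallace rule `2(A+T) + 4(G+C)` is selectable where
  exact integer arithmetic is convenient (e.g. in tests).
* Complementarity screens: the longest antiparallel Watson–Crick run
  achievable by any pair of degenerate expansions (computed degeneracy-aware,
  without enumerating expansions), both overall (`> 8` fails) and anchored at
  a 3′ terminus (`> 4` fails — the extension-prone dimer geometry). These
  thresholds are our defaults; the source method states the goal, not
  numbers, so they are configurable.

Two design modes exist. The strict, per-site operation
(`design_allele_specific_primers(strict = TRUE)`) returns nothing for a
site/base whose Tm window is unreachable and drops screen failures, with a
diagnostic. The panel-level designer used by the pipeline
(`design_panel_primers(strict = FALSE)`) instead takes the closest-Tm length
and keeps screen failures, flagging both in the output: a missing
allele-specific primer would silently convert heterozygous sites into
homozygous calls, which is a worse failure mode for an end-to-end assay than
an off-window primer. The choice is the user's; both surfaces are exported.

## Assay simulation

`enumerate_amplicons()` is the mechanistic core: an amplicon (f, r) forms on
a chromosome iff both primers' 3′ bases match that chromosome at their
sites, the forward footprint is strictly upstream of the reverse footprint,
and the span is within `max_amplicon_len` (3500 bp in multiplex, 10 kb
single-plex — the empirically demonstrated limits). Amplification is
cis-only by construction; no chimeric template is modeled. The two worked
genotype cases follow directly: a double heterozygote produces 2 cis species
lighting 4 bead populations, a single heterozygote 2 species, a double
homozygote 1 species lighting 2 bead populations — and every species lights
at least its duplicate pair of beads.

`simulate_readout()` emits the dense per-tube table (every bead class ×
every label primer). Event counts are drawn from rounded, zero-truncated
Normals at the empirically observed summary statistics — positive cells
195 ± 12 events, negative cells 9 ± 5 — and the reporter ratio is ≥ 4 for
cells drawn from the positive distribution, < 4 otherwise. The Normal family
is a modeling choice: the source statistics are summaries, not a generative
law, and every parameter of `assay_noise_model()` is replaceable. Two
phenomenological error channels complete the model: `dropout_rate` silences
a true cell (PCR failure; also the stand-in for the reduced efficiency of
solid-phase PCR, which is not modeled kinetically) and `false_capture_rate`
promotes a negative cell (promiscuous priming). A seed is mandatory —
readouts are reproducible by contract.

## Decoding

Positivity (`positivity_rule()`) applies the two published rules as separate
observables: events ≥ 100 *and* reporter ratio ≥ 4, with both duplicate
beads of a reaction required. Comparisons are inclusive, the natural reading
of "a threshold of 100" and "at least four fold". Raising `min_events` can
only shrink the positive set (tested as a monotonicity property).

Each positive reaction asserts one cis constraint between its two
discriminating bases; constraints aggregate with a support count
(`phase_constraints()`). Assembly (`assemble_haplotypes()`) seeds at the
smallest heterozygous site — its two bases, sorted, go to haplotypes 1
and 2; the labels are arbitrary, so all comparisons are on unordered
pairs — and propagates phase along edges in decreasing support order using a
parity union–find. Conflicting edges between a site pair are resolved by
total-support majority (a tie, a third base at a site, or a globally
inconsistent edge set returns status `conflicted`; `strict_conflicts = TRUE`
makes any conflict fatal). Heterozygous sites not connected to the seed's
component return `ambiguous` with the disconnected blocks listed. Sites with
no positive coverage are carried as gaps rather than failing the
individual. The decoder never emits more than two haplotypes.

`brute_force_oracle()` is the independent check: it enumerates all
2^(h−1) phase configurations of the h heterozygous sites (guarded at
h ≤ 12), simulates each configuration's zero-noise positive set, and keeps
the consistent ones. On all tested instances the decoder returns `ok`
exactly when the oracle has a unique survivor, and the pairs agree.

## Reaction layout

Which primer pairs react is a design file, not a property of the chemistry.
The default layout (`default_reaction_layout(style = "all_pairs")`) lays out
*every* geometrically legal forward × reverse site pair, mirroring the
assay's property that products can form from every co-tubed primer
combination; sites are split into contiguous blocks and tubes formed per
block pair so no tube exceeds the 100-bead-class capacity. All-pairs is the
only layout that guarantees a direct cis constraint between any two
heterozygous sites: homozygous sites transmit no phase information, so
sparser layouts cannot phase het sites separated by runs of hom sites. A
`chain_skip` economy layout (nearest neighbour plus one skip partner) is
provided for bead-budget exploration; it phases two het sites only when they
are linked through other het sites, and the decoder correctly reports the
remaining cases as `ambiguous` — matching the oracle.

## Synthetic cohorts

The generator is first-class, tested code; it is how the package is
exercised without any real sequence. `cohort_spec()` defaults describe the
study system: 33 alleles, 237-column alignment, 60 polymorphic sites (a
quarter of them tri-/tetra-allelic, two thirds of those triallelic — the
source describes "mostly biallelic, a substantial proportion with three or
even four" without printing the split), the published 33-value frequency
spectrum renormalized, and 109 individuals under Hardy–Weinberg sampling.
Polymorphic sites are placed at least 16 bp from the alignment ends so both
primer orientations are geometrically designable (the real primer panel has
the same property, spanning positions 13–216 of 237). One master seed
derives fixed-offset streams for panel, cohort and per-individual assay
noise, so stages are independently reproducible.

What the generator does *not* emulate: mutation/recombination processes,
pedigree structure, allele-sequence homology (backbones are random), primer
chemistry failures beyond the two phenomenological rates, and
instrument-level artefacts. Passing tests therefore demonstrate the
computational pipeline's correctness under the stated noise model, not
wet-lab performance.

For linkage-disequilibrium studies, `sample_two_locus_cohort()` draws
haplotype pairs from a four-class frequency vector; its `coupling_bias`
re-phases repulsion double heterozygotes into coupling. That operation
leaves every genotype — hence the composite estimator — untouched while
raising the true coupling-haplotype frequency, giving a Hardy–Weinberg
violation with a *known sign*: direct r must exceed composite r.

## Population statistics

`frequency_table()` counts chromosomes (two per individual; failed decodes
excluded with n adjusted) and reports percent frequencies to one decimal,
the published table's dialect; raw counts are always carried alongside.
Novel haplotypes are named `NOVEL-001`, `NOVEL-002`, … deterministically by
first-seen order. Conversions from printed percent tables re-derive integer
counts via `round(f/100 × n_chromosomes)` — the only convention under which
the published 0.9% and 0.5% rows at 218 chromosomes mean two carriers and
one carrier respectively.

Composite LD uses the genotype-class closed form
Δ̂ = (1/n)[2N_AABB + N_AABb + N_AaBB + ½N_AaBb] − 2p̂_Ap̂_B, with the
correlation denominator including the within-locus Hardy–Weinberg departure
terms D̂_A, D̂_B (the coefficient's standard form); a simple denominator
without those terms is selectable because the source does not print its
formula. Direct LD is the textbook haplotype quantity D = p_AB − p_Ap_B.
The study's own printed values for its two end sites (modal haplotype
frequency 0.31; composite r 0.23 vs direct r 0.17) require the cohort's raw
genotypes, which were never published; they are documented here as
non-reproducible and are not computed by this package's checks. What *is*
checked is the estimators' behaviour: agreement within Monte-Carlo error
under random mating, and sign-known divergence under the built-in
Hardy–Weinberg violation.

## Numerical and scale choices

* Coordinates are 1-based inclusive everywhere; reverse primers are stored
  5′→3′ as synthesized with descending printed coordinates, their footprint
  being the coordinate-sorted span.
* Alignments must be gap-free and equal-length (true of this locus's exon
  alignments); gapped input is rejected, not handled.
* Allele identity and novelty are defined over polymorphic sites only —
  invariant columns carry no information.
* The packaged transcription of the published primer table keeps three rows
  whose printed span and sequence length disagree (the source table
  evidently lost a character in each); the lenient loader flags them, the
  strict loader refuses them, and tests pin exactly that behaviour.
* Test and check problem sizes are chosen to exercise the claimed
  properties at comfortable desk scale: the end-to-end cohort at the study's
  own size (109 individuals, 60 sites), robustness and decoder-contract runs
  on a 10-site/1,000-individual and 8-site/500-genotype configuration, and
  LD identity at n = 10,000 individuals with bootstrap standard errors.

## Known limitations

* No PCR kinetics, primer competition, or hairpin free-energy computation;
  the complementarity screen is a run-length rule, not thermodynamics.
* No statistical phasing fallback: individuals whose het sites cannot be
  phased from constraints are reported `ambiguous` by design — avoiding
  deductive inference is the method's point.
* Mixtures beyond a diploid pair (chimerism, mixed infections) are out of
  scope; the decoder assumes at most two haplotypes.
* The bead-capacity model is a hard cap of 100 classes per tube; requesting
  more is an error rather than an automatic re-plan.
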