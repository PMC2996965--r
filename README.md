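# transcistor

Direct molecular haplotyping with solid-phase double-ARMS bead assays.

`transcistor` is the computational toolkit for a direct (non-statistical)
haplotyping assay: multiplex double allele-specific PCR (double ARMS), where
allele-specific primers at **both** ends of an amplicon mean product only
forms when the two specified SNP alleles are *cis* — on the same chromosome.
Amplicons are captured on spectrally addressed bead classes (one anchored
primer per class, up to 100 classes per tube, every product represented in
duplicate), interrogated by fluorescent primer extension, and read out as
per-bead event counts. The package provides:

* **Allele panels** — aligned allele sets, polymorphic-site detection, IUPAC
  consensus, and matching of assembled haplotypes to known alleles (or
  flagging them novel): `allele_panel()`, `find_polymorphic_sites()`,
  `consensus_iupac()`, `match_haplotype()`.
* **ARMS primer design** — 3′-terminal discrimination, IUPAC wobbles at
  interior polymorphic positions, nearest-neighbor melting-temperature
  windows (55 ± 3 °C default), degeneracy-aware complementarity screens, and
  a tab-separated primer-table dialect: `design_panel_primers()`,
  `tm_estimate()`, `complementarity_screen()`, `read_primer_table()`.
* **Assay simulation** — mechanistic enumeration of cis-only amplicons for a
  diploid genotype, duplicate bead capture, and dense per-tube readouts with
  an empirically parameterised noise model (positive cells 195 ± 12 events,
  background 9 ± 5): `enumerate_amplicons()`, `simulate_readout()`.
* **Phase decoding** — the published positivity rules (events ≥ 100,
  reporter ratio ≥ 4× background, both duplicate beads required), cis
  constraints with support counts, haplotype assembly by parity union-find
  with majority conflict resolution, and an exhaustive phase-enumeration
  oracle: `decode_readout()`, `assemble_haplotypes()`,
  `brute_force_oracle()`.
* **Population statistics** — chromosome-count frequency tables, rare-allele
  carrier counts, and linkage disequilibrium both ways: the composite
  coefficient from unphased genotypes,
  Δ̂ = (1/n)[2N_AABB + N_AABb + N_AaBB + ½N_AaBb] − 2p̂_Ap̂_B, and the direct
  haplotype-based D = p_AB − p_A p_B with its correlation r:
  `frequency_table()`, `composite_ld()`, `direct_ld()`, `ld_compare()`.
* **Synthetic cohorts** — a seeded generator of allele panels, primer
  layouts and Hardy-Weinberg diploid cohorts with known truth, defaulting to
  the study system's shape (33 alleles, 237-bp alignment, 60 polymorphic
  sites, 109 individuals): `cohort_spec()`, `generate_panel()`,
  `sample_cohort()`, `simulate_study()`.

Packaged fixtures transcribe the published cohort allele table
(`table1_alleles()`) and allele-specific primer table (`table2_primers()`).

## Worked example

Simulate a study-shaped cohort end to end — generate a 60-site panel, design
the allele-specific primer panel, lay out the multiplex tubes, simulate every
individual's bead readout at zero noise, decode, and call alleles:

```r
library(transcistor)

spec <- cohort_spec(seed = 1)        # 33 alleles, 60 sites, 109 individuals
study <- simulate_study(spec)
study
#> study_result: 109 individuals, 28 alleles called, recovery 100.0%

head(study$freq_table, 3)
#>   allele_name chromosome_count frequency_percent
#> 1      SYN001               52              23.9
#> 2      SYN002               34              15.6
#> 3      SYN003               25              11.5
```

Every individual decodes with status `ok`, the assembled haplotype pairs
equal the generator's truth for 100% of individuals, and the frequency table
reproduces the true chromosome counts exactly. (28 of the 33 alleles appear:
the spectrum is skewed, and rare alleles can be absent from a 218-chromosome
draw.) Under the empirical noise parameters with 0.5% dropout and
false-capture rates, recovery on a 1,000-individual cohort stays ≥ 99%, with
failed individuals reported as `conflicted`/`ambiguous` rather than called
wrongly.

The published cohort table gives the study's own summary statistics:

```r
ft <- as_frequency_table(table1_alleles(), n_chromosomes = 218)
nrow(ft)                   # 33 alleles
top_k_cumulative(ft, 3)    # 51.4  (top three alleles > 50%)
carriers_by_count(ft, 1)   # 11 alleles seen in one animal
carriers_by_count(ft, 2)   # 7 alleles seen in two sheep
```

Phase information changes LD estimates. On a cohort with a built-in
Hardy-Weinberg violation (repulsion double heterozygotes re-phased into
coupling), the unphased composite estimator cannot see the shift:

```r
ch <- sample_two_locus_cohort(10000, rep(0.25, 4), coupling_bias = 0.8,
                              seed = 33)
ld_compare(ch$hap1_a, ch$hap1_b, ch$hap2_a, ch$hap2_b)
#> composite LD: p_A=0.4908 p_B=0.5017 D=0.0019 r=0.0077 (n=10000)
#> direct LD: p_A=0.4908 p_B=0.5017 p_AB=0.2949 D=0.0487 r=0.1949 (n=10000)
#> modal two-site haplotype ab at frequency 0.302
```

A thin command-line front-end covers the same pipeline
(`exec/transcistor design|simulate|decode|synth|ld`).

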