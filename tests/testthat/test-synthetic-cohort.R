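test_that("panel generation honours the requested site structure", {
  spec2 <- cohort_spec(n_alleles = 2, alignment_length = 60,
                       n_polymorphic_sites = 1, fraction_multiallelic = 0,
                       allele_freqs = c(0.5, 0.5), n_individuals = 2,
                       seed = 3)
  p2 <- generate_panel(spec2)
  diff_cols <- sum(strsplit(p2$sequences[[1]], "")[[1]] !=
                     strsplit(p2$sequences[[2]], "")[[1]])
  expect_equal(diff_cols, 1L)

  loc <- small_locus()
  s <- find_polymorphic_sites(loc$panel)
  expect_equal(nrow(s), loc$spec$n_polymorphic_sites)
  # multiallelic share within one site of the requested fraction
  want <- round(loc$spec$fraction_multiallelic * nrow(s))
  expect_lte(abs(sum(s$n_bases >= 3) - want), 1L)
  # sites respect the edge margin (primer geometry)
  expect_true(all(s$position >= loc$spec$edge_margin))
  expect_true(all(s$position <=
                    loc$spec$alignment_length - loc$spec$edge_margin + 1))

  # determinism: the same seed rebuilds the identical panel
  p_again <- generate_panel(loc$spec)
  expect_identical(p_again$sequences, loc$panel$sequences)

  # infeasible: more alleles than the site alphabet can distinguish
  expect_error(generate_panel(
    cohort_spec(n_alleles = 5, alignment_length = 60,
                n_polymorphic_sites = 1, allele_freqs = rep(0.2, 5),
                seed = 4)), "infeasible")
})

test_that("cohort sampling follows the frequency spectrum", {
  loc <- small_locus()
  spec_fix <- cohort_spec(n_alleles = 10, alignment_length = 120,
                          n_polymorphic_sites = 8,
                          allele_freqs = c(1, rep(0, 9)),
                          n_individuals = 20, seed = 11)
  truth <- sample_cohort(loc$panel, spec_fix)
  expect_true(all(truth$allele1 == "SYN001"))
  expect_true(all(truth$allele2 == "SYN001"))

  # binomial check on the top allele at the study spectrum
  spec_big <- cohort_spec(n_individuals = 2000, seed = 8)
  panel_big <- generate_panel(spec_big)
  truth_big <- sample_cohort(panel_big, spec_big)
  p_top <- spec_big$allele_freqs[1]
  n_chrom <- 2 * spec_big$n_individuals
  obs <- sum(c(truth_big$allele1, truth_big$allele2) == "SYN001")
  se <- sqrt(n_chrom * p_top * (1 - p_top))
  expect_lt(abs(obs - n_chrom * p_top), 4 * se)

  expect_error(sample_cohort(loc$panel, cohort_spec(
    n_alleles = 3, allele_freqs = rep(1 / 3, 3), seed = 5)),
    "allele_freqs")
})

test_that("reaction layouts cover site pairs within capacity", {
  spec3 <- cohort_spec(n_alleles = 4, alignment_length = 90,
                       n_polymorphic_sites = 3, fraction_multiallelic = 0,
                       allele_freqs = rep(0.25, 4), n_individuals = 2,
                       seed = 13)
  p3 <- generate_panel(spec3)
  pr3 <- design_panel_primers(p3, strict = FALSE)
  sites3 <- find_polymorphic_sites(p3)$position
  lay3 <- default_reaction_layout(pr3, style = "chain_skip")
  covered <- unique(data.frame(
    a = pr3$site[match(lay3$fwd_label, pr3$label)],
    b = pr3$site[match(lay3$rev_label, pr3$label)]))
  covered <- covered[order(covered$a, covered$b), ]
  expect_equal(unname(as.matrix(covered)),
               matrix(c(sites3[1], sites3[2],
                        sites3[1], sites3[3],
                        sites3[2], sites3[3]),
                      ncol = 2, byrow = TRUE))

  # all-pairs layout on the small locus is phase-connected and within cap
  loc <- small_locus()
  expect_true(layout_is_connected(loc$layout_all, loc$primers))
  for (tube in unique(loc$layout_all$tube)) {
    m <- unique(c(loc$layout_all$fwd_label[loc$layout_all$tube == tube],
                  loc$layout_all$rev_label[loc$layout_all$tube == tube]))
    expect_lte(length(m), 100L)
  }

  # a tight bead budget forces a split into several tubes
  study <- e2e_study()
  lay_small <- default_reaction_layout(study$primers, bead_cap = 40)
  expect_gt(length(unique(lay_small$tube)), 1L)
  for (tube in unique(lay_small$tube)) {
    m <- unique(c(lay_small$fwd_label[lay_small$tube == tube],
                  lay_small$rev_label[lay_small$tube == tube]))
    expect_lte(length(m), 40L)
  }
  expect_true(layout_is_connected(lay_small, study$primers))
})

test_that("coupling-biased cohorts keep genotypes but shift haplotypes", {
  ch0 <- sample_two_locus_cohort(3000, rep(0.25, 4), coupling_bias = 0,
                                 seed = 17)
  ch1 <- sample_two_locus_cohort(3000, rep(0.25, 4), coupling_bias = 1,
                                 seed = 17)
  # same seed: genotype dosages identical, phase re-arranged
  expect_equal(ch0$hap1_a + ch0$hap2_a, ch1$hap1_a + ch1$hap2_a)
  expect_equal(ch0$hap1_b + ch0$hap2_b, ch1$hap1_b + ch1$hap2_b)
  p_ab0 <- mean(c(ch0$hap1_a & ch0$hap1_b, ch0$hap2_a & ch0$hap2_b))
  p_ab1 <- mean(c(ch1$hap1_a & ch1$hap1_b, ch1$hap2_a & ch1$hap2_b))
  expect_gt(p_ab1, p_ab0)
})

test_that("full pipeline recovers truth and reproduces frequencies exactly", {
  study <- e2e_study()
  expect_equal(study$recovery_rate, 1)
  expect_true(all(study$calls$status == "ok"))
  expect_equal(sum(grepl("NOVEL", c(study$calls$allele1,
                                    study$calls$allele2))), 0L)
  truth_counts <- sort(table(c(study$truth$allele1, study$truth$allele2)),
                       decreasing = TRUE)
  got <- study$freq_table$chromosome_count[
    match(names(truth_counts), study$freq_table$allele_name)]
  expect_identical(got, as.integer(truth_counts))
  expect_equal(sum(study$freq_table$chromosome_count),
               2L * nrow(study$calls))
})
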