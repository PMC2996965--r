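# minimal hand-built readout for two primers f/r forming one reaction
.mini_readout <- function(ef, er, ratio_f = 10, ratio_r = 10) {
  data.frame(tube = 1L, bead_id = c(1L, 2L),
             anchored_primer = c("F", "R"), label_primer = c("R", "F"),
             events = c(ef, er), reporter_ratio = c(ratio_f, ratio_r),
             stringsAsFactors = FALSE)
}
.mini_layout <- data.frame(tube = 1L, fwd_label = "F", rev_label = "R",
                           stringsAsFactors = FALSE)

test_that("positivity needs threshold events, ratio, and both beads", {
  expect_true(call_positive(.mini_readout(195, 195), .mini_layout)$positive)
  expect_false(call_positive(.mini_readout(9, 9), .mini_layout)$positive)
  # one bead strong, duplicate at background: reaction rejected
  expect_false(call_positive(.mini_readout(195, 9), .mini_layout)$positive)
  # ratio rule is independent of the event count
  expect_false(call_positive(.mini_readout(195, 195, ratio_f = 2),
                             .mini_layout)$positive)
  # thresholds are inclusive
  ro <- .mini_readout(100, 100, ratio_f = 4, ratio_r = 4)
  expect_true(call_positive(ro, .mini_layout)$positive)
  # missing duplicate cell is an error naming the reaction
  expect_error(call_positive(.mini_readout(195, 195)[1, ], .mini_layout),
               "duplicate cell")
})

test_that("raising the event threshold can only shrink the positive set", {
  loc <- small_locus()
  set.seed(202)
  g <- small_random_genotype(loc)
  nm <- assay_noise_model(false_capture_rate = 0.05, dropout_rate = 0.05,
                          seed = 303)
  ro <- simulate_readout(g$pair, loc$primers, nm, layout = loc$layout_all)
  prev <- NULL
  for (thr in c(50, 100, 150, 190)) {
    pos <- call_positive(ro, loc$layout_all, positivity_rule(min_events = thr))
    keys <- paste(pos$fwd_label, pos$rev_label)[pos$positive]
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("genotype extraction reports hom, het, missing and conflicted sites", {
  loc <- small_locus()
  hom_g <- haplotype_pair(loc$panel$sequences[[1]], loc$panel$sequences[[1]])
  ro <- simulate_readout(hom_g, loc$primers, zero_noise(1),
                         layout = loc$layout_all)
  pos <- call_positive(ro, loc$layout_all)
  gc <- genotype_from_positives(pos, loc$primers)
  expect_true(all(gc$n_bases == 1L))
  expect_true(all(gc$flag == ""))

  set.seed(404)
  g <- small_random_genotype(loc)
  het <- names(which(g$truth[[1]] != g$truth[[2]]))
  ro <- simulate_readout(g$pair, loc$primers, zero_noise(2),
                         layout = loc$layout_all)
  pos <- call_positive(ro, loc$layout_all)
  gc <- genotype_from_positives(pos, loc$primers)
  expect_equal(sort(gc$site[gc$n_bases == 2L]), sort(as.integer(het)))

  # spike a false positive asserting an extra base at a multiallelic site:
  # pick a reaction whose forward primer carries a base absent from the
  # genotype while the reverse partner matches a true chromosome
  tri <- loc$sites$position[loc$sites$n_bases >= 3][1]
  spare <- setdiff(strsplit(loc$sites$bases[loc$sites$position == tri],
                            ",")[[1]],
                   c(g$truth[[1]][as.character(tri)],
                     g$truth[[2]][as.character(tri)]))[1]
  fi <- match(pos$fwd_label, loc$primers$label)
  ri <- match(pos$rev_label, loc$primers$label)
  rev_base_true <- substr(g$pair$hap1, loc$primers$site[ri],
                          loc$primers$site[ri]) == loc$primers$disc_bases[ri]
  hit <- which(loc$primers$site[fi] == tri &
                 loc$primers$disc_bases[fi] == spare & rev_base_true)[1]
  expect_false(is.na(hit))
  pos$positive[hit] <- TRUE
  gc2 <- genotype_from_positives(pos, loc$primers)
  expect_equal(gc2$n_bases[gc2$site == tri],
               gc$n_bases[gc$site == tri] + 1L)
  if (gc2$n_bases[gc2$site == tri] > 2L) {
    expect_equal(gc2$flag[gc2$site == tri], "too_many_bases")
    expect_equal(assemble_haplotypes(
      phase_constraints(pos, loc$primers), gc2)$status, "conflicted")
  }
})

test_that("assembly handles hom-only, round-trips truth, and flags ambiguity", {
  loc <- small_locus()
  # fully homozygous: one haplotype, status ok
  hom_g <- haplotype_pair(loc$panel$sequences[[1]], loc$panel$sequences[[1]])
  ro <- simulate_readout(hom_g, loc$primers, zero_noise(3),
                         layout = loc$layout_all)
  dec <- decode_readout(ro, loc$primers, layout = loc$layout_all)
  expect_equal(dec$status, "ok")
  expect_length(dec$haplotypes, 1L)

  # zero-noise round trip equals the simulated truth (unordered)
  set.seed(505)
  for (i in 1:30) {
    g <- small_random_genotype(loc)
    ro <- simulate_readout(g$pair, loc$primers, zero_noise(600 + i),
                           layout = loc$layout_all)
    dec <- decode_readout(ro, loc$primers, layout = loc$layout_all)
    expect_equal(dec$status, "ok")
    expect_lte(length(dec$haplotypes), 2L)
    expect_equal(haplotype_pair_key(dec$haplotypes),
                 haplotype_pair_key(g$truth))
  }

  # two het sites with no covering reaction between them: phase undetermined
  s <- loc$sites$position
  pruned <- loc$layout_all
  sa <- loc$primers$site[match(pruned$fwd_label, loc$primers$label)]
  sb <- loc$primers$site[match(pruned$rev_label, loc$primers$label)]
  keep <- !(sa == s[1] & sb == s[2])
  pruned <- pruned[keep, ]
  bases <- strsplit(loc$sites$bases, ",")
  b1 <- vapply(bases, `[`, "", 1L)
  b2 <- b1
  b2[1:2] <- vapply(bases[1:2], `[`, "", 2L)  # het at first two sites only
  g <- haplotype_pair(small_locus_hap(loc, b1), small_locus_hap(loc, b2))
  ro <- simulate_readout(g, loc$primers, zero_noise(9), layout = pruned)
  dec <- decode_readout(ro, loc$primers, layout = pruned)
  expect_equal(dec$status, "ambiguous")
  expect_true(length(dec$diagnostics$ambiguous_blocks) >= 2)
})

test_that("decoder agrees with the exhaustive phase-enumeration oracle", {
  loc <- small_locus()
  # h = 0: single configuration, trivially consistent
  hom_g <- haplotype_pair(loc$panel$sequences[[1]], loc$panel$sequences[[1]])
  ro <- simulate_readout(hom_g, loc$primers, zero_noise(3),
                         layout = loc$layout_all)
  dec <- decode_readout(ro, loc$primers, layout = loc$layout_all)
  orc <- brute_force_oracle(dec$genotype_calls, attr(dec, "positives"),
                            loc$primers)
  expect_length(orc, 1L)

  set.seed(707)
  for (i in 1:60) {
    g <- small_random_genotype(loc)
    lay <- if (i %% 2) loc$layout_cs else loc$layout_all
    ro <- simulate_readout(g$pair, loc$primers, zero_noise(800 + i),
                           layout = lay)
    dec <- decode_readout(ro, loc$primers, layout = lay)
    orc <- brute_force_oracle(dec$genotype_calls, attr(dec, "positives"),
                              loc$primers)
    truth_key <- haplotype_pair_key(g$truth)
    expect_true(truth_key %in% vapply(orc, haplotype_pair_key, ""))
    if (dec$status == "ok") {
      expect_length(orc, 1L)
      expect_equal(haplotype_pair_key(dec$haplotypes),
                   haplotype_pair_key(orc[[1]]))
    } else if (dec$status == "ambiguous") {
      expect_gt(length(orc), 1L)
    }
  }

  # combinatorial guard
  fake <- data.frame(site = 1:13, bases = "A,C", n_bases = 2L, flag = "",
                     stringsAsFactors = FALSE)
  expect_error(brute_force_oracle(fake, .mini_layout, loc$primers),
               "refusing")
})

test_that("conflicting cis edges resolve by support majority, ties conflict", {
  gc <- data.frame(site = c(10L, 20L), bases = c("A,C", "G,T"),
                   n_bases = 2L, flag = "", stringsAsFactors = FALSE)
  g_base <- data.frame(site_a = 10L, site_b = 20L,
                       allele_a = c("A", "A"), allele_b = c("G", "T"),
                       support = c(3L, 1L), stringsAsFactors = FALSE)
  class(g_base) <- c("phase_graph", "data.frame")
  dec <- assemble_haplotypes(g_base, gc)
  expect_equal(dec$status, "ok")
  # majority wins: A phases with G
  k <- haplotype_pair_key(dec$haplotypes)
  expect_equal(k, haplotype_pair_key(list(c("10" = "A", "20" = "G"),
                                          c("10" = "C", "20" = "T"))))
  # tie: conflicted
  g_tie <- g_base
  g_tie$support <- c(2L, 2L)
  expect_equal(assemble_haplotypes(g_tie, gc)$status, "conflicted")
  # strict mode: any conflict suffices
  expect_equal(assemble_haplotypes(g_base, gc,
                                   strict_conflicts = TRUE)$status,
               "conflicted")
  # >2 bases at a site: conflicted with the site named
  gc3 <- gc; gc3$bases[1] <- "A,C,G"; gc3$n_bases[1] <- 3L
  dec3 <- assemble_haplotypes(g_base, gc3)
  expect_equal(dec3$status, "conflicted")
  expect_equal(dec3$diagnostics$too_many_bases, 10L)
})
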