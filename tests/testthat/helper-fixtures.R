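# Shared fixtures, built in code and cached for the session: panels, primer
# sets, layouts and the two simulated studies the acceptance checks reuse.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Two-site toy locus: site 20 (C/T) and site 50 (A/G) on a 70 bp backbone.
toy_two_site <- function() {
  .cached("toy", function() {
    set.seed(2024)
    bb <- sample(c("A", "C", "G", "T"), 70, replace = TRUE)
    mk <- function(b20, b50) {
      s <- bb; s[20] <- b20; s[50] <- b50; paste(s, collapse = "")
    }
    panel <- allele_panel(c(h_ca = mk("C", "A"), h_tg = mk("T", "G")))
    primers <- design_panel_primers(panel, strict = FALSE)
    # one forward pair (site 20) x one reverse pair (site 50)
    pair <- primers[(primers$orientation == "forward" & primers$site == 20) |
                      (primers$orientation == "reverse" & primers$site == 50), ]
    list(panel = panel, primers = primers, pair = pair, mk = mk)
  })
}

# Small 8-site locus used by decoder/oracle tests.
small_locus <- function() {
  .cached("small", function() {
    spec <- cohort_spec(n_alleles = 10, alignment_length = 120,
                        n_polymorphic_sites = 8,
                        allele_freqs = rep(0.1, 10), n_individuals = 1,
                        seed = 11)
    panel <- generate_panel(spec)
    sites <- find_polymorphic_sites(panel)
    primers <- design_panel_primers(panel, strict = FALSE)
    list(spec = spec, panel = panel, sites = sites, primers = primers,
         layout_all = default_reaction_layout(primers, style = "all_pairs"),
         layout_cs = default_reaction_layout(primers, style = "chain_skip"),
         backbone = strsplit(panel$sequences[[1]], "")[[1]])
  })
}

small_locus_hap <- function(loc, bases) {
  s <- loc$backbone
  s[loc$sites$position] <- bases
  paste(s, collapse = "")
}

# random genotype over the small locus; returns haplotype_pair + truth maps
small_random_genotype <- function(loc) {
  sb <- strsplit(loc$sites$bases, ",")
  b1 <- vapply(sb, function(b) sample(b, 1), "")
  b2 <- vapply(sb, function(b) sample(b, 1), "")
  list(pair = haplotype_pair(small_locus_hap(loc, b1),
                             small_locus_hap(loc, b2)),
       truth = list(stats::setNames(b1, loc$sites$position),
                    stats::setNames(b2, loc$sites$position)))
}

# Study-scale cohort: 109 individuals, 60-site panel, zero noise.
e2e_study <- function() {
  .cached("e2e", function() simulate_study(cohort_spec(seed = 1)))
}

# 1,000 individuals on a 10-site panel under empirical noise parameters
# with 0.5% dropout and false-capture rates.
noisy_study <- function() {
  .cached("noisy", function() {
    f <- 0.6^(1:12)
    spec <- cohort_spec(n_alleles = 12, alignment_length = 120,
                        n_polymorphic_sites = 10, allele_freqs = f / sum(f),
                        n_individuals = 1000, seed = 42)
    simulate_study(spec, noise = "empirical",
                   false_capture_rate = 0.005, dropout_rate = 0.005)
  })
}

zero_noise <- function(seed) {
  assay_noise_model(pos_events_sd = 0, neg_events_sd = 0, seed = seed)
}
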