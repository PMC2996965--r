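#' Specification for a synthetic locus and cohort
#'
#' Describes a synthetic highly polymorphic locus shaped like the study
#' system: an exon-length alignment with a fixed number of polymorphic
#' columns (mostly biallelic, a substantial minority tri-/tetra-allelic), a
#' skewed allele-frequency spectrum, and Hardy-Weinberg diploid sampling.
#' Defaults mirror the study cohort: 33 alleles over 237 aligned bases with
#' 60 polymorphic sites, frequencies from the packaged published table
#' (renormalized), 109 individuals.
#'
#' @param n_alleles Number of distinct alleles.
#' @param alignment_length Alignment columns.
#' @param n_polymorphic_sites Mutated columns.
#' @param fraction_multiallelic Share of sites carrying 3-4 bases.
#' @param allele_freqs Frequency vector summing to 1 (default: the published
#'   33-allele spectrum, renormalized).
#' @param n_individuals Cohort size.
#' @param mating `"hwe"` (random union of gametes).
#' @param edge_margin Minimum distance of polymorphic sites from either
#'   alignment end, so both primer orientations are geometrically designable.
#' @param seed Integer master seed; per-stage streams (panel, cohort, per-
#'   individual assay noise) are derived from it by fixed offsets.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_alleles = NULL, alignment_length = 237L,
                        n_polymorphic_sites = 60L,
                        fraction_multiallelic = 0.25,
                        allele_freqs = NULL, n_individuals = 109L,
                        mating = "hwe", edge_margin = 16L, seed) {
  if (missing(seed)) stop("cohort_spec requires a seed")
  if (is.null(allele_freqs)) {
    f <- table1_alleles()$frequency_percent
    allele_freqs <- f / sum(f)
  }
  if (is.null(n_alleles)) n_alleles <- length(allele_freqs)
  if (length(allele_freqs) != n_alleles) {
    stop("allele_freqs length ", length(allele_freqs), " != n_alleles ",
         n_alleles)
  }
  if (abs(sum(allele_freqs) - 1) > 1e-9) stop("allele_freqs must sum to 1")
  stopifnot(n_polymorphic_sites <= alignment_length,
            fraction_multiallelic >= 0, fraction_multiallelic <= 1,
            mating == "hwe")
  structure(
    list(n_alleles = as.integer(n_alleles),
         alignment_length = as.integer(alignment_length),
         n_polymorphic_sites = as.integer(n_polymorphic_sites),
         fraction_multiallelic = fraction_multiallelic,
         allele_freqs = allele_freqs,
         n_individuals = as.integer(n_individuals),
         mating = mating, edge_margin = as.integer(edge_margin),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic allele panel
#'
#' Random invariant backbone plus `n_polymorphic_sites` mutated columns.
#' Among mutated columns, `fraction_multiallelic` carry 3 or 4 bases (two
#' thirds triallelic, one third tetra-allelic); alleles are pairwise distinct
#' at the polymorphic sites. Allele names are `SYN001`, `SYN002`, ...
#' (synthetic — no real sequence is used).
#'
#' @param spec A [cohort_spec].
#' @return An [allele_panel].
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 101L)
  k_max <- 4L
  if (spec$n_alleles > k_max^spec$n_polymorphic_sites) {
    stop("infeasible: more alleles than site combinations allow")
  }
  lo <- spec$edge_margin
  hi <- spec$alignment_length - spec$edge_margin + 1L
  if (hi - lo + 1L < spec$n_polymorphic_sites) {
    stop("alignment too short for ", spec$n_polymorphic_sites,
         " sites at edge margin ", spec$edge_margin)
  }
  backbone <- sample(c("A", "C", "G", "T"), spec$alignment_length,
                     replace = TRUE)
  sites <- sort(sample(lo:hi, spec$n_polymorphic_sites))
  n_multi <- round(spec$fraction_multiallelic * spec$n_polymorphic_sites)
  n_tetra <- round(n_multi / 3)
  k_per_site <- rep(2L, spec$n_polymorphic_sites)
  if (n_multi > 0) {
    which_multi <- sample(spec$n_polymorphic_sites, n_multi)
    k_per_site[which_multi] <- 3L
    if (n_tetra > 0) k_per_site[which_multi[seq_len(n_tetra)]] <- 4L
  }
  k_per_site <- pmin(k_per_site, spec$n_alleles)
  site_bases <- lapply(k_per_site, function(k)
    sort(sample(c("A", "C", "G", "T"), k)))
  ## allele-by-site base assignment; every site must show all its bases
  prof <- matrix("", spec$n_alleles, spec$n_polymorphic_sites)
  for (j in seq_len(spec$n_polymorphic_sites)) {
    repeat {
      col <- sample(site_bases[[j]], spec$n_alleles, replace = TRUE)
      if (length(unique(col)) == length(site_bases[[j]])) break
    }
    prof[, j] <- col
  }
  ## repair duplicate allele profiles without orphaning any site base
  for (iter in seq_len(1000L)) {
    key <- apply(prof, 1L, paste, collapse = "")
    dup <- which(duplicated(key))
    if (!length(dup)) break
    a <- dup[1L]
    repaired <- FALSE
    for (j in sample(spec$n_polymorphic_sites)) {
      b_now <- prof[a, j]
      if (sum(prof[, j] == b_now) < 2L) next  # would orphan this base
      alt <- setdiff(site_bases[[j]], b_now)
      prof[a, j] <- sample(alt, 1L)
      repaired <- TRUE
      break
    }
    if (!repaired) stop("could not make allele profiles pairwise distinct")
  }
  if (anyDuplicated(apply(prof, 1L, paste, collapse = ""))) {
    stop("could not make allele profiles pairwise distinct")
  }
  seqs <- vapply(seq_len(spec$n_alleles), function(a) {
    chars <- backbone
    chars[sites] <- prof[a, ]
    paste(chars, collapse = "")
  }, "")
  names(seqs) <- sprintf("SYN%03d", seq_len(spec$n_alleles))
  allele_panel(seqs)
}

#' Sample a diploid cohort with known truth
#'
#' Hardy-Weinberg sampling: each individual's two alleles drawn i.i.d. from
#' the spec's frequency spectrum. The pair order is exchangeable and carries
#' no information.
#'
#' @param panel An [allele_panel] (typically from [generate_panel]).
#' @param spec The [cohort_spec].
#' @return data.frame of class `truth_set`: `individual`, `allele1`,
#'   `allele2` (allele names).
#' @export
sample_cohort <- function(panel, spec) {
  stopifnot(inherits(panel, "allele_panel"), inherits(spec, "cohort_spec"))
  if (length(panel) != length(spec$allele_freqs)) {
    stop("panel has ", length(panel), " alleles but allele_freqs has ",
         length(spec$allele_freqs))
  }
  set.seed(spec$seed + 202L)
  nm <- names(panel$sequences)
  draws <- matrix(sample(nm, 2L * spec$n_individuals, replace = TRUE,
                         prob = spec$allele_freqs), ncol = 2L)
  out <- data.frame(individual = sprintf("IND%04d",
                                         seq_len(spec$n_individuals)),
                    allele1 = draws[, 1L], allele2 = draws[, 2L],
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_set", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Default multiplex reaction layout
#'
#' `"all_pairs"` (default): every geometrically legal forward x reverse site
#' pair is laid out — the configuration in which every possible primer
#' combination reacts, so any two heterozygous sites are joined by a direct
#' cis constraint. Sites are split into contiguous blocks and tubes formed
#' per block pair (forward primers of the upstream block, reverse primers of
#' the downstream block, both orientations for within-block tubes) so that no
#' tube exceeds the bead-class capacity.
#'
#' `"chain_skip"`: an economy layout pairing each site with its nearest
#' downstream neighbour and one skip-level partner. Uses far fewer bead
#' classes but phases two heterozygous sites only if they are linked through
#' other heterozygous sites.
#'
#' @param primers A `primer_panel`.
#' @param bead_cap Maximum bead classes per tube (array capacity, 100).
#' @param max_amplicon_len Maximum amplicon span (bp).
#' @param style `"all_pairs"` or `"chain_skip"`.
#' @return Layout data.frame (`tube`, `fwd_label`, `rev_label`) with
#'   attribute `uncoverable`: sites with no legal partner.
#' @export
default_reaction_layout <- function(primers, bead_cap = 100L,
                                    max_amplicon_len = 3500,
                                    style = c("all_pairs", "chain_skip")) {
  style <- match.arg(style)
  sites <- sort(unique(primers$site))
  n_fwd <- vapply(sites, function(s)
    sum(primers$site == s & primers$orientation == "forward"), 0L)
  n_rev <- vapply(sites, function(s)
    sum(primers$site == s & primers$orientation == "reverse"), 0L)
  site_pairs <- if (style == "all_pairs") {
    grid <- expand.grid(i = seq_along(sites), j = seq_along(sites))
    grid[grid$i < grid$j, , drop = FALSE]
  } else {
    k <- length(sites)
    rbind(
      if (k >= 2) data.frame(i = 1:(k - 1), j = 2:k),
      if (k >= 3) data.frame(i = 1:(k - 2), j = 3:k)
    )
  }
  ## a pair is coverable if the upstream site has forward primers and the
  ## downstream site reverse primers, within the amplicon limit
  ok <- n_fwd[site_pairs$i] > 0 & n_rev[site_pairs$j] > 0 &
    (sites[site_pairs$j] - sites[site_pairs$i] + 1) <= max_amplicon_len
  site_pairs <- site_pairs[ok, , drop = FALSE]
  uncoverable <- sites[!(seq_along(sites) %in%
                           c(site_pairs$i, site_pairs$j))]

  fwd_of <- function(is) primers$label[primers$orientation == "forward" &
                                         primers$site %in% sites[is]]
  rev_of <- function(is) primers$label[primers$orientation == "reverse" &
                                         primers$site %in% sites[is]]
  layout <- list()
  add_tube <- function(tube, fwd_labels, rev_labels, pair_subset) {
    ## reactions of this tube: the requested site pairs, all base combos
    for (r in seq_len(nrow(pair_subset))) {
      fl <- intersect(fwd_labels,
                      primers$label[primers$site == sites[pair_subset$i[r]]])
      rl <- intersect(rev_labels,
                      primers$label[primers$site == sites[pair_subset$j[r]]])
      if (length(fl) && length(rl)) {
        layout[[length(layout) + 1L]] <<- expand.grid(
          tube = tube, fwd_label = fl, rev_label = rl,
          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      }
    }
  }

  if (style == "all_pairs") {
    ## contiguous site blocks; cap so fwd(block a) + rev(block b) fits a tube
    per_block <- max(1L, bead_cap %/% 2L)
    blocks <- list(); cur <- integer(0); load_f <- 0L; load_r <- 0L
    for (i in seq_along(sites)) {
      if (length(cur) && (max(load_f + n_fwd[i], load_r + n_rev[i]) >
                          per_block)) {
        blocks[[length(blocks) + 1L]] <- cur
        cur <- integer(0); load_f <- 0L; load_r <- 0L
      }
      cur <- c(cur, i); load_f <- load_f + n_fwd[i]; load_r <- load_r + n_rev[i]
    }
    blocks[[length(blocks) + 1L]] <- cur
    g <- length(blocks)
    tube <- 0L
    for (a in seq_len(g)) for (b in a:g) {
      tube <- tube + 1L
      fl <- fwd_of(blocks[[a]])
      rl <- rev_of(blocks[[b]])
      sub <- site_pairs[site_pairs$i %in% blocks[[a]] &
                          site_pairs$j %in% blocks[[b]], , drop = FALSE]
      if (nrow(sub)) add_tube(tube, fl, rl, sub) else tube <- tube - 1L
    }
  } else {
    ## greedy-pack chain+skip pairs into tubes under the bead cap
    tube <- 1L; members <- character(0); assigned <- FALSE
    for (r in seq_len(nrow(site_pairs))) {
      fl <- fwd_of(site_pairs$i[r]); rl <- rev_of(site_pairs$j[r])
      fl <- primers$label[primers$orientation == "forward" &
                            primers$site == sites[site_pairs$i[r]]]
      rl <- primers$label[primers$orientation == "reverse" &
                            primers$site == sites[site_pairs$j[r]]]
      new_members <- union(members, c(fl, rl))
      if (length(new_members) > bead_cap && length(members)) {
        tube <- tube + 1L
        members <- character(0)
        new_members <- c(fl, rl)
      }
      members <- new_members
      layout[[length(layout) + 1L]] <- expand.grid(
        tube = tube, fwd_label = fl, rev_label = rl,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(layout)) stop("no coverable site pairs")
  out <- unique(do.call(rbind, layout))
  rownames(out) <- NULL
  ## capacity check
  for (tube in unique(out$tube)) {
    m <- unique(c(out$fwd_label[out$tube == tube],
                  out$rev_label[out$tube == tube]))
    if (length(m) > bead_cap) stop("tube ", tube, " exceeds bead capacity")
  }
  attr(out, "uncoverable") <- uncoverable
  out
}

#' Check phase connectivity of a reaction layout
#'
#' Graph over the laid-out sites with an edge per covered site pair; returns
#' TRUE when connected (so any set of heterozygous sites could in principle
#' be phased into one block when all pairs are covered).
#'
#' @param layout Layout data.frame from [default_reaction_layout].
#' @param primers The `primer_panel`.
#' @return Logical.
#' @export
layout_is_connected <- function(layout, primers) {
  sa <- .primer_site(primers, layout$fwd_label)
  sb <- .primer_site(primers, layout$rev_label)
  nodes <- sort(unique(c(sa, sb)))
  if (length(nodes) <= 1L) return(TRUE)
  adj <- split(c(match(sb, nodes), match(sa, nodes)),
               c(match(sa, nodes), match(sb, nodes)))
  seen <- logical(length(nodes))
  stack <- 1L
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    nb <- adj[[as.character(v)]]
    stack <- c(stack, nb[!seen[nb]])
  }
  all(seen)
}

#' Sample a two-locus cohort for LD studies
#'
#' Draws each individual's two haplotypes i.i.d. from the four two-site
#' haplotype classes (random union of gametes), then optionally re-phases
#' double heterozygotes found in repulsion (Ab/aB) into coupling (AB/ab)
#' with probability `coupling_bias`. Re-phasing leaves every genotype — and
#' hence the composite LD estimator — untouched while raising the true
#' coupling-haplotype frequency, so a positive `coupling_bias` builds in a
#' known divergence: direct r exceeds composite r.
#'
#' @param n Number of individuals.
#' @param hap_freqs Length-4 numeric, frequencies of AB, Ab, aB, ab (sum 1).
#' @param coupling_bias Probability of re-phasing a repulsion double het.
#' @param seed Integer RNG seed.
#' @return data.frame with logical columns `hap1_a`, `hap1_b`, `hap2_a`,
#'   `hap2_b` (index-allele presence per haplotype and site).
#' @export
sample_two_locus_cohort <- function(n, hap_freqs = c(0.35, 0.15, 0.15, 0.35),
                                    coupling_bias = 0, seed) {
  if (missing(seed)) stop("sample_two_locus_cohort requires a seed")
  stopifnot(length(hap_freqs) == 4L, abs(sum(hap_freqs) - 1) < 1e-9,
            coupling_bias >= 0, coupling_bias <= 1)
  set.seed(as.integer(seed))
  classes <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                    ncol = 2L, byrow = TRUE)  # AB, Ab, aB, ab
  h1 <- sample.int(4L, n, replace = TRUE, prob = hap_freqs)
  h2 <- sample.int(4L, n, replace = TRUE, prob = hap_freqs)
  out <- data.frame(hap1_a = classes[h1, 1L], hap1_b = classes[h1, 2L],
                    hap2_a = classes[h2, 1L], hap2_b = classes[h2, 2L])
  if (coupling_bias > 0) {
    repulsion <- (out$hap1_a != out$hap2_a) & (out$hap1_b != out$hap2_b) &
      (out$hap1_a != out$hap1_b)
    flip <- repulsion & stats::runif(n) < coupling_bias
    ## re-phase to coupling: AB / ab
    out$hap1_a[flip] <- TRUE; out$hap1_b[flip] <- TRUE
    out$hap2_a[flip] <- FALSE; out$hap2_b[flip] <- FALSE
  }
  out
}

#' Run a full synthetic study end to end
#'
#' Generates the panel, designs the allele-specific primer panel, lays out
#' the multiplex reactions, samples the diploid cohort, simulates every
#' individual's bead readout, decodes haplotypes, matches them against the
#' panel, and aggregates the frequency table — reporting per-individual
#' recovery against the generator's truth.
#'
#' @param spec A [cohort_spec].
#' @param constraints [design_constraints] for primer design.
#' @param noise `"zero"` (deterministic signal at the positive/negative
#'   means) or `"empirical"` (195 +/- 12 vs 9 +/- 5 with the given error rates).
#' @param false_capture_rate,dropout_rate Error rates for `noise = "empirical"`.
#' @param rule [positivity_rule] for decoding.
#' @param bead_cap,layout_style Passed to [default_reaction_layout].
#' @return List of class `study_result`: `panel`, `primers`, `layout`,
#'   `truth`, `calls` (per-individual allele calls + status), `recovery`
#'   (logical per individual), `recovery_rate`, `freq_table`.
#' @export
simulate_study <- function(spec, constraints = design_constraints(),
                           noise = c("zero", "empirical"),
                           false_capture_rate = 0.005, dropout_rate = 0.005,
                           rule = positivity_rule(),
                           bead_cap = 100L, layout_style = "all_pairs") {
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "cohort_spec"))
  panel <- generate_panel(spec)
  sites <- find_polymorphic_sites(panel)
  primers <- design_panel_primers(panel, constraints, strict = FALSE)
  layout <- default_reaction_layout(primers, bead_cap = bead_cap,
                                    style = layout_style)
  truth <- sample_cohort(panel, spec)
  ## truth profiles over polymorphic sites
  prof <- lapply(panel$sequences, function(s)
    stats::setNames(strsplit(s, "")[[1]][sites$position],
                    sites$position))
  novel_env <- new.env(parent = emptyenv())
  novel_env$n <- 0L
  name_hap <- function(hap) {
    m <- match_haplotype(panel, hap, sites = sites)
    if (m$call != "novel") return(m$call)
    key <- paste(hap, collapse = "")
    if (is.null(novel_env[[key]])) {
      novel_env$n <- novel_env$n + 1L
      novel_env[[key]] <- sprintf("NOVEL-%03d", novel_env$n)
    }
    novel_env[[key]]
  }
  n <- spec$n_individuals
  calls <- data.frame(individual = truth$individual,
                      allele1 = NA_character_, allele2 = NA_character_,
                      status = NA_character_, n_haplotypes = NA_integer_,
                      stringsAsFactors = FALSE)
  recovery <- logical(n)
  for (i in seq_len(n)) {
    genotype <- haplotype_pair(
      panel$sequences[[truth$allele1[i]]],
      panel$sequences[[truth$allele2[i]]])
    nm <- if (noise == "zero") {
      assay_noise_model(pos_events_sd = 0, neg_events_sd = 0,
                        seed = spec$seed + 303L + i)
    } else {
      assay_noise_model(false_capture_rate = false_capture_rate,
                        dropout_rate = dropout_rate,
                        seed = spec$seed + 303L + i)
    }
    readout <- simulate_readout(genotype, primers, nm, layout = layout)
    dec <- decode_readout(readout, primers, rule, layout = layout)
    calls$status[i] <- dec$status
    calls$n_haplotypes[i] <- length(dec$haplotypes)
    if (dec$status == "ok" && length(dec$haplotypes)) {
      haps <- dec$haplotypes
      if (length(haps) == 1L) haps <- c(haps, haps)
      calls$allele1[i] <- name_hap(haps[[1L]])
      calls$allele2[i] <- name_hap(haps[[2L]])
      truth_key <- haplotype_pair_key(list(prof[[truth$allele1[i]]],
                                           prof[[truth$allele2[i]]]))
      recovery[i] <- haplotype_pair_key(haps) == truth_key
    }
  }
  structure(
    list(panel = panel, primers = primers, layout = layout, truth = truth,
         calls = calls, recovery = recovery,
         recovery_rate = mean(recovery),
         freq_table = frequency_table(calls)),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "study_result: %d individuals, %d alleles called, recovery %.1f%%\n",
    nrow(x$calls), nrow(x$freq_table), 100 * x$recovery_rate))
  invisible(x)
}
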