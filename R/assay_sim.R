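#' A diploid genotype as an unordered pair of haplotypes
#'
#' @param hap1,hap2 Full-length sequences over the panel's coordinate system
#'   (equal length). Homozygotes repeat the same sequence.
#' @return List of class `haplotype_pair`.
#' @export
haplotype_pair <- function(hap1, hap2) {
  hap1 <- toupper(hap1); hap2 <- toupper(hap2)
  if (nchar(hap1) != nchar(hap2)) stop("haplotypes differ in length")
  structure(list(hap1 = hap1, hap2 = hap2), class = "haplotype_pair")
}

#' Assay noise model
#'
#' Per-cell event counts are modeled as rounded, zero-truncated Normals with
#' the empirically observed signal statistics (positive cells 195 +/- 12
#' events, negative cells 9 +/- 5). The Normal family is a modeling choice —
#' the source statistics are summaries, not a generative law — and every
#' parameter is replaceable. `false_capture_rate` promotes a negative cell to
#' the positive distribution (promiscuous priming); `dropout_rate` silences a
#' true cell (PCR failure). A seed is mandatory: readouts are reproducible by
#' contract.
#'
#' @param pos_events_mean,pos_events_sd Positive-cell event count moments.
#' @param neg_events_mean,neg_events_sd Negative-cell (background) moments.
#' @param false_capture_rate,dropout_rate Probabilities in `[0, 1]`.
#' @param seed Integer RNG seed (required).
#' @return List of class `assay_noise_model`.
#' @export
assay_noise_model <- function(pos_events_mean = 195, pos_events_sd = 12,
                              neg_events_mean = 9, neg_events_sd = 5,
                              false_capture_rate = 0, dropout_rate = 0,
                              seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("assay_noise_model requires an integer seed (reproducibility contract)")
  }
  stopifnot(pos_events_mean >= 0, neg_events_mean >= 0,
            pos_events_sd >= 0, neg_events_sd >= 0,
            false_capture_rate >= 0, false_capture_rate <= 1,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(
    list(pos_events_mean = pos_events_mean, pos_events_sd = pos_events_sd,
         neg_events_mean = neg_events_mean, neg_events_sd = neg_events_sd,
         false_capture_rate = false_capture_rate, dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "assay_noise_model"
  )
}

## base at reference position `pos` of haplotype string
.base_at <- function(hap, pos) substr(hap, pos, pos)

## does primer row i of `primers` match haplotype `hap` at its 3' site?
.primer_matches <- function(primers, i, hap) {
  .base_at(hap, primers$site[i]) %in%
    strsplit(primers$disc_bases[i], ",")[[1]]
}

#' Enumerate allele-specific amplicons for a diploid genotype
#'
#' The core double-ARMS event: an amplicon (f, r, chromosome) forms iff the
#' forward primer's 3' base matches that chromosome at its site, the reverse
#' primer's 3' base matches the same chromosome at its site, the forward
#' footprint lies strictly upstream of the reverse footprint, and the span is
#' within `max_amplicon_len`. Amplification is cis-only: no chimeric
#' template, so product formation is itself the phase readout.
#'
#' @param genotype A [haplotype_pair].
#' @param primers A `primer_panel`.
#' @param max_amplicon_len Maximum span (bp). Default 3500, the multiplex
#'   limit; single-plex reactions support up to 10000.
#' @return data.frame: `fwd_label`, `rev_label`, `chromosome`, `span_start`,
#'   `span_end`, `species` (fwd x rev identity, chromosomes collapsed).
#' @export
enumerate_amplicons <- function(genotype, primers, max_amplicon_len = 3500) {
  stopifnot(inherits(genotype, "haplotype_pair"),
            inherits(primers, "primer_panel"))
  fwd <- which(primers$orientation == "forward")
  rev_ <- which(primers$orientation == "reverse")
  multi <- grepl(",", primers$disc_bases)
  out <- list()
  for (chrom in 1:2) {
    hap <- if (chrom == 1L) genotype$hap1 else genotype$hap2
    hap_base <- substring(hap, primers$site, primers$site)
    ok <- hap_base == primers$disc_bases
    if (any(multi)) {
      ok[multi] <- vapply(which(multi), function(i)
        hap_base[i] %in% strsplit(primers$disc_bases[i], ",")[[1]], TRUE)
    }
    fok <- fwd[ok[fwd]]
    rok <- rev_[ok[rev_]]
    if (!length(fok) || !length(rok)) next
    grid <- expand.grid(f = fok, r = rok, KEEP.OUT.ATTRS = FALSE)
    keep <- primers$fp_hi[grid$f] < primers$fp_lo[grid$r] &  # strictly upstream
      (primers$fp_hi[grid$r] - primers$fp_lo[grid$f] + 1L) <= max_amplicon_len
    grid <- grid[keep, , drop = FALSE]
    if (!nrow(grid)) next
    out[[length(out) + 1L]] <- data.frame(
      fwd_label = primers$label[grid$f], rev_label = primers$label[grid$r],
      chromosome = chrom, span_start = primers$fp_lo[grid$f],
      span_end = primers$fp_hi[grid$r], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(fwd_label = character(0), rev_label = character(0),
               chromosome = integer(0), span_start = integer(0),
               span_end = integer(0), stringsAsFactors = FALSE)
  res$species <- paste(res$fwd_label, res$rev_label, sep = "|")
  res
}

#' Count distinct amplicon species for one primer-pair reaction
#'
#' Collapses the two chromosomes: a double heterozygote yields 2 cis species,
#' a single heterozygote 2, a double homozygote 1.
#'
#' @param genotype A [haplotype_pair].
#' @param primers A `primer_panel`, typically restricted to the one forward
#'   group and one reverse group under test.
#' @param max_amplicon_len See [enumerate_amplicons].
#' @return Integer count of distinct (forward allele, reverse allele) species.
#' @export
count_amplicon_species <- function(genotype, primers,
                                   max_amplicon_len = 3500) {
  amp <- enumerate_amplicons(genotype, primers, max_amplicon_len)
  length(unique(amp$species))
}

#' Count positive bead populations for one primer-pair reaction
#'
#' Every amplicon species is captured in duplicate, on its forward-anchored
#' and its reverse-anchored bead, so a double heterozygote lights 4 bead
#' populations, a double homozygote 2 — and any genotype producing product
#' lights at least 2. This duplication is the assay's built-in QC.
#'
#' @inheritParams count_amplicon_species
#' @return Integer count of distinct bead classes carrying >= 1 captured
#'   amplicon.
#' @export
count_positive_bead_populations <- function(genotype, primers,
                                            max_amplicon_len = 3500) {
  amp <- enumerate_amplicons(genotype, primers, max_amplicon_len)
  length(unique(c(amp$fwd_label, amp$rev_label)))
}

## All geometrically legal (fwd, rev) reactions for a primer panel.
.legal_reactions <- function(primers, max_amplicon_len = 3500) {
  fwd <- which(primers$orientation == "forward")
  rev_ <- which(primers$orientation == "reverse")
  if (!length(fwd) || !length(rev_)) {
    return(data.frame(fwd_label = character(0), rev_label = character(0),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(f = fwd, r = rev_, KEEP.OUT.ATTRS = FALSE)
  ok <- primers$fp_hi[grid$f] < primers$fp_lo[grid$r] &
    (primers$fp_hi[grid$r] - primers$fp_lo[grid$f] + 1L) <= max_amplicon_len
  data.frame(fwd_label = primers$label[grid$f[ok]],
             rev_label = primers$label[grid$r[ok]],
             stringsAsFactors = FALSE)
}

#' Simulate the two-phase bead readout for one individual
#'
#' Phase 1: solution PCR with all primers of a tube, amplicons kidnapped onto
#' their forward- and reverse-anchored beads. Phase 2: one labeled primer per
#' aliquot interrogates the covalently retained strands. The emitted table is
#' dense — every bead class crossed with every label primer of the tube. A
#' cell is true-positive iff its anchored primer and its label primer flank
#' the same amplicon species; counts are then drawn from the noise model, and
#' the reporter/background fluorescence ratio is >= 4 for cells drawn from
#' the positive distribution and < 4 otherwise.
#'
#' @param genotype A [haplotype_pair].
#' @param primers A `primer_panel`.
#' @param noise An [assay_noise_model] (seed required).
#' @param layout Reaction layout data.frame (`tube`, `fwd_label`,
#'   `rev_label`); default: all legal reactions in one tube.
#' @param max_amplicon_len See [enumerate_amplicons].
#' @param beads_per_reaction Beads per class per tube (bookkeeping only).
#' @return data.frame of class `reaction_readout`: `tube`, `bead_id`,
#'   `anchored_primer`, `label_primer`, `events`, `reporter_ratio`.
#' @export
simulate_readout <- function(genotype, primers, noise, layout = NULL,
                             max_amplicon_len = 3500,
                             beads_per_reaction = 2000L) {
  stopifnot(inherits(noise, "assay_noise_model"))
  if (is.null(layout)) {
    layout <- .legal_reactions(primers, max_amplicon_len)
    layout$tube <- 1L
  }
  stopifnot(all(c("tube", "fwd_label", "rev_label") %in% names(layout)))
  amp <- enumerate_amplicons(genotype, primers, max_amplicon_len)
  true_species <- unique(amp[, c("fwd_label", "rev_label")])
  set.seed(noise$seed)
  parts <- list()
  for (tube in sort(unique(layout$tube))) {
    lt <- layout[layout$tube == tube, , drop = FALSE]
    members <- sort(unique(c(lt$fwd_label, lt$rev_label)))
    if (length(members) > 100L) {
      stop("tube ", tube, " needs ", length(members),
           " bead classes; the array supports at most 100")
    }
    grid <- expand.grid(anchored_primer = members, label_primer = members,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ## true cells: (bead f, label r) and (bead r, label f) for each amplicon
    ## species whose reaction is laid out in this tube
    tt <- merge(true_species, lt, by = c("fwd_label", "rev_label"))
    truth_keys <- c(paste(tt$fwd_label, tt$rev_label, sep = "\r"),
                    paste(tt$rev_label, tt$fwd_label, sep = "\r"))
    is_true <- paste(grid$anchored_primer, grid$label_primer,
                     sep = "\r") %in% truth_keys
    n <- nrow(grid)
    eff_pos <- is_true
    if (noise$dropout_rate > 0) {
      eff_pos[is_true] <- stats::runif(sum(is_true)) >= noise$dropout_rate
    }
    if (noise$false_capture_rate > 0) {
      promote <- !is_true & stats::runif(n) < noise$false_capture_rate
      eff_pos <- eff_pos | promote
    }
    events <- integer(n)
    events[eff_pos] <- as.integer(round(pmax(0, stats::rnorm(
      sum(eff_pos), noise$pos_events_mean, noise$pos_events_sd))))
    events[!eff_pos] <- as.integer(round(pmax(0, stats::rnorm(
      sum(!eff_pos), noise$neg_events_mean, noise$neg_events_sd))))
    parts[[length(parts) + 1L]] <- data.frame(
      tube = tube,
      bead_id = match(grid$anchored_primer, members),
      anchored_primer = grid$anchored_primer,
      label_primer = grid$label_primer,
      events = events,
      reporter_ratio = ifelse(eff_pos, 10, 1),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, parts)
  attr(res, "beads_per_reaction") <- as.integer(beads_per_reaction)
  class(res) <- c("reaction_readout", "data.frame")
  res
}

#' Read / write readout tables
#'
#' Tab-separated readout dialect: `tube`, `bead_id`, `anchored_primer`,
#' `label_primer`, `events`, `reporter_ratio`, plus an optional `individual`
#' column in long-format cohort files.
#'
#' @param path File path.
#' @return `read_readout`: a `reaction_readout` data.frame.
#' @export
read_readout <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("tube", "bead_id", "anchored_primer", "label_primer", "events",
            "reporter_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing readout column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$events < 0)) stop("negative event counts")
  class(df) <- c("reaction_readout", "data.frame")
  df
}

#' @rdname read_readout
#' @param readout A `reaction_readout`.
#' @export
write_readout <- function(readout, path) {
  utils::write.table(as.data.frame(readout), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
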