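#' Positivity rule for bead readouts
#'
#' A cell is positive when its event count reaches `min_events` (the
#' threshold separating specific from non-specific amplification) AND its
#' reporter/background fluorescence ratio reaches `min_reporter_ratio`.
#' A reaction is positive only when both the beads representing it — the
#' forward-anchored and the reverse-anchored duplicate — are positive.
#' Comparisons are inclusive (`>=`).
#'
#' @param min_events Event-count threshold (default 100).
#' @param min_reporter_ratio Reporter/background ratio threshold (default 4).
#' @param require_both_beads Require the duplicate cells to both pass.
#' @return List of class `positivity_rule`.
#' @export
positivity_rule <- function(min_events = 100, min_reporter_ratio = 4,
                            require_both_beads = TRUE) {
  stopifnot(min_events > 0, min_reporter_ratio > 0)
  structure(list(min_events = min_events,
                 min_reporter_ratio = min_reporter_ratio,
                 require_both_beads = isTRUE(require_both_beads)),
            class = "positivity_rule")
}

#' Call positive reactions from a bead readout
#'
#' Applies the positivity rule cell-wise, then the duplicate-bead QC rule
#' reaction-wise: reaction (f, r) is positive iff both the cell on the
#' f-anchored bead labeled with r and the cell on the r-anchored bead labeled
#' with f pass.
#'
#' @param readout A `reaction_readout`.
#' @param layout Reaction layout data.frame (`tube`, `fwd_label`,
#'   `rev_label`).
#' @param rule A [positivity_rule].
#' @return `layout` with logical column `positive` plus the duplicate cells'
#'   `events_fwd_bead`, `events_rev_bead`.
#' @export
call_positive <- function(readout, layout, rule = positivity_rule()) {
  stopifnot(inherits(rule, "positivity_rule"),
            all(c("tube", "fwd_label", "rev_label") %in% names(layout)))
  key <- paste(readout$tube, readout$anchored_primer, readout$label_primer,
               sep = "\r")
  pass <- readout$events >= rule$min_events &
    readout$reporter_ratio >= rule$min_reporter_ratio
  i1 <- match(paste(layout$tube, layout$fwd_label, layout$rev_label,
                    sep = "\r"), key)
  i2 <- match(paste(layout$tube, layout$rev_label, layout$fwd_label,
                    sep = "\r"), key)
  if (anyNA(i1) || anyNA(i2)) {
    bad <- which(is.na(i1) | is.na(i2))[1L]
    stop("readout is missing a duplicate cell for reaction ",
         layout$fwd_label[bad], " x ", layout$rev_label[bad],
         " (tube ", layout$tube[bad], ")")
  }
  out <- layout
  out$events_fwd_bead <- readout$events[i1]
  out$events_rev_bead <- readout$events[i2]
  out$positive <- if (rule$require_both_beads) pass[i1] & pass[i2] else
    pass[i1] | pass[i2]
  out
}

## single-row lookup helpers over a primer_panel
.primer_site <- function(primers, label) {
  primers$site[match(label, primers$label)]
}
.primer_bases <- function(primers, label) {
  strsplit(primers$disc_bases[match(label, primers$label)], ",")[[1]]
}

#' Per-site genotype calls from positive reactions
#'
#' A site's base set is the union of the discriminating bases of its primers
#' appearing in positive reactions. Sites covered by the layout but showing
#' no positive reaction are recorded as missing (gap), not dropped; sites
#' accumulating more than two bases are flagged for conflict handling
#' downstream.
#'
#' @param positives Output of [call_positive].
#' @param primers A `primer_panel` (split primers: one discriminating base
#'   per label).
#' @return data.frame: `site`, `bases` (comma-joined, `-` when missing),
#'   `n_bases`, `flag` (`""`, `"missing"`, or `"too_many_bases"`).
#' @export
genotype_from_positives <- function(positives, primers) {
  covered <- sort(unique(primers$site[primers$label %in%
                                        c(positives$fwd_label,
                                          positives$rev_label)]))
  pos <- positives[positives$positive, , drop = FALSE]
  seen <- list()
  add <- function(label) {
    s <- as.character(.primer_site(primers, label))
    seen[[s]] <<- union(seen[[s]], .primer_bases(primers, label))
  }
  for (i in seq_len(nrow(pos))) {
    add(pos$fwd_label[i]); add(pos$rev_label[i])
  }
  bases <- vapply(as.character(covered), function(s) {
    b <- seen[[s]]
    if (is.null(b)) "-" else paste(sort(b), collapse = ",")
  }, "")
  n <- vapply(as.character(covered), function(s) {
    b <- seen[[s]]; if (is.null(b)) 0L else length(b)
  }, 0L)
  data.frame(site = covered, bases = unname(bases), n_bases = unname(n),
             flag = ifelse(n == 0L, "missing",
                           ifelse(n > 2L, "too_many_bases", "")),
             stringsAsFactors = FALSE)
}

#' Extract cis phase constraints from positive reactions
#'
#' Every positive double-ARMS reaction asserts that its forward primer's
#' discriminating base and its reverse primer's discriminating base lie on
#' the same chromosome. Constraints are aggregated with a support count over
#' independent reactions.
#'
#' @inheritParams genotype_from_positives
#' @return data.frame of class `phase_graph`: `site_a < site_b`, `allele_a`,
#'   `allele_b`, `support`.
#' @export
phase_constraints <- function(positives, primers) {
  pos <- positives[positives$positive, , drop = FALSE]
  if (!nrow(pos)) {
    res <- data.frame(site_a = integer(0), site_b = integer(0),
                      allele_a = character(0), allele_b = character(0),
                      support = integer(0), stringsAsFactors = FALSE)
    class(res) <- c("phase_graph", "data.frame")
    return(res)
  }
  fi <- match(pos$fwd_label, primers$label)
  ri <- match(pos$rev_label, primers$label)
  single <- !grepl(",", primers$disc_bases)
  if (all(single[fi]) && all(single[ri])) {
    ## split primers: one discriminating base each — fully vectorized
    rows <- data.frame(site_a = primers$site[fi], site_b = primers$site[ri],
                       allele_a = primers$disc_bases[fi],
                       allele_b = primers$disc_bases[ri],
                       stringsAsFactors = FALSE)
  } else {
    rows <- do.call(rbind, lapply(seq_len(nrow(pos)), function(i) {
      expand.grid(site_a = primers$site[fi[i]], site_b = primers$site[ri[i]],
                  allele_a = strsplit(primers$disc_bases[fi[i]], ",")[[1]],
                  allele_b = strsplit(primers$disc_bases[ri[i]], ",")[[1]],
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
  }
  ## geometry guarantees fwd site < rev site
  agg <- stats::aggregate(list(support = rep(1L, nrow(rows))),
                          rows, FUN = sum)
  agg <- agg[order(agg$site_a, agg$site_b, agg$allele_a, agg$allele_b), ]
  rownames(agg) <- NULL
  class(agg) <- c("phase_graph", "data.frame")
  agg
}

## union-find with parity (offset to root); returns updated state or NULL on
## contradiction
.uf_find <- function(uf, x) {
  p <- 0L
  while (uf$parent[x] != x) {
    p <- xor(p, uf$parity[x])
    x <- uf$parent[x]
  }
  list(root = x, parity = p)
}

#' Assemble haplotypes from phase constraints
#'
#' Seeds at the smallest heterozygous site (its two bases, sorted, go to
#' haplotype 1 and 2; the labels are arbitrary, so results compare as
#' unordered pairs) and propagates phase along cis edges in decreasing
#' support order. Homozygous sites are copied to both haplotypes. Conflicting
#' edges between a pair of het sites are resolved by total-support majority;
#' a tie, a base set exceeding two, or a globally inconsistent edge set yields
#' status `"conflicted"`; het sites not connected to the seed's component
#' yield `"ambiguous"` with the disconnected blocks listed. Sites with no
#' positive coverage are carried as gaps (`-`).
#'
#' @param graph A `phase_graph` from [phase_constraints].
#' @param genotype_calls Output of [genotype_from_positives].
#' @param strict_conflicts When `TRUE`, any conflicting edge (not just ties)
#'   yields status `"conflicted"`.
#' @return List of class `decoded_result`: `genotype_calls`, `haplotypes`
#'   (list of 1 or 2 site-named base vectors), `status`
#'   (`ok`/`ambiguous`/`conflicted`), `diagnostics`.
#' @export
assemble_haplotypes <- function(graph, genotype_calls,
                                strict_conflicts = FALSE) {
  diagnostics <- list()
  gc <- genotype_calls
  result <- function(status, haps) {
    structure(list(genotype_calls = gc, haplotypes = haps, status = status,
                   diagnostics = diagnostics),
              class = "decoded_result")
  }
  if (any(gc$n_bases > 2L)) {
    diagnostics$too_many_bases <- gc$site[gc$n_bases > 2L]
    return(result("conflicted", list()))
  }
  if (any(gc$flag == "missing")) {
    diagnostics$missing_sites <- gc$site[gc$flag == "missing"]
  }
  base_list <- strsplit(gc$bases, ",")
  het <- which(gc$n_bases == 2L)
  ## start both haplotypes with hom bases and gaps
  hap1 <- vapply(seq_len(nrow(gc)), function(i) base_list[[i]][1L], "")
  names(hap1) <- gc$site
  hap2 <- hap1
  if (length(het) == 0L) {
    return(result("ok", list(hap1)))
  }
  het_sites <- gc$site[het]
  b1 <- vapply(base_list[het], `[`, "", 1L)  # sorted smaller base
  b2 <- vapply(base_list[het], `[`, "", 2L)
  names(b1) <- names(b2) <- het_sites

  ## per het-site-pair parity votes: "same" = the two smaller bases are cis
  g <- graph[graph$site_a %in% het_sites & graph$site_b %in% het_sites, ,
             drop = FALSE]
  edges <- NULL
  if (nrow(g)) {
    same <- (g$allele_a == b1[as.character(g$site_a)]) ==
      (g$allele_b == b1[as.character(g$site_b)])
    votes <- stats::aggregate(
      list(support_same = ifelse(same, g$support, 0L),
           support_anti = ifelse(same, 0L, g$support)),
      list(site_a = g$site_a, site_b = g$site_b), FUN = sum)
    conflicted_pairs <- votes[votes$support_same > 0 &
                                votes$support_anti > 0, , drop = FALSE]
    if (nrow(conflicted_pairs)) {
      diagnostics$conflicting_pairs <- conflicted_pairs
      if (strict_conflicts ||
          any(conflicted_pairs$support_same ==
                conflicted_pairs$support_anti)) {
        return(result("conflicted", list()))
      }
    }
    votes$same <- votes$support_same >= votes$support_anti
    votes$support <- abs(votes$support_same - votes$support_anti)
    edges <- votes[votes$support > 0, , drop = FALSE]
    edges <- edges[order(-edges$support), , drop = FALSE]
  }

  ## union-find with parity over het sites, edges in decreasing support order
  idx <- stats::setNames(seq_along(het_sites), het_sites)
  uf <- list(parent = seq_along(het_sites), parity = integer(length(het_sites)))
  for (i in seq_len(NROW(edges))) {
    a <- idx[[as.character(edges$site_a[i])]]
    b <- idx[[as.character(edges$site_b[i])]]
    want <- if (edges$same[i]) 0L else 1L
    fa <- .uf_find(uf, a); fb <- .uf_find(uf, b)
    if (fa$root == fb$root) {
      if (xor(fa$parity, fb$parity) != want) {
        diagnostics$inconsistent_edge <- edges[i, , drop = FALSE]
        return(result("conflicted", list()))
      }
    } else {
      uf$parent[fa$root] <- fb$root
      uf$parity[fa$root] <- xor(xor(fa$parity, fb$parity), want)
    }
  }
  finds <- lapply(seq_along(het_sites), function(i) .uf_find(uf, i))
  roots <- vapply(finds, `[[`, 0L, "root")
  seed_root <- roots[1L]  # seed = lexicographically smallest het site
  unreachable <- het_sites[roots != seed_root]
  if (length(unreachable)) {
    blocks <- split(het_sites, roots)
    diagnostics$ambiguous_blocks <- unname(blocks)
  }
  seed_parity <- finds[[1L]]$parity
  for (i in seq_along(het_sites)) {
    s <- as.character(het_sites[i])
    ## parity relative to seed; disconnected blocks get their own root's
    ## arbitrary orientation (status is ambiguous anyway)
    rel <- xor(finds[[i]]$parity, if (roots[i] == seed_root) seed_parity
               else 0L)
    hap1[s] <- if (rel == 0L) b1[s] else b2[s]
    hap2[s] <- if (rel == 0L) b2[s] else b1[s]
  }
  status <- if (length(unreachable)) "ambiguous" else "ok"
  result(status, list(hap1, hap2))
}

#' @export
print.decoded_result <- function(x, ...) {
  cat(sprintf("decoded_result: status %s, %d site(s), %d haplotype(s)\n",
              x$status, nrow(x$genotype_calls), length(x$haplotypes)))
  invisible(x)
}

#' Decode a bead readout into haplotypes
#'
#' Convenience pipeline: positivity + duplicate-bead QC calls, per-site
#' genotype extraction, cis-constraint aggregation, and haplotype assembly.
#'
#' @param readout A `reaction_readout`.
#' @param primers The `primer_panel` behind the readout.
#' @param rule A [positivity_rule].
#' @param layout Reaction layout; default reconstructs all geometrically
#'   legal reactions among each tube's bead classes.
#' @param max_amplicon_len See [enumerate_amplicons].
#' @return A `decoded_result` (see [assemble_haplotypes]) with the positive
#'   calls attached as attribute `positives`.
#' @export
decode_readout <- function(readout, primers, rule = positivity_rule(),
                           layout = NULL, max_amplicon_len = 3500) {
  if (is.null(layout)) {
    parts <- lapply(sort(unique(readout$tube)), function(tube) {
      members <- unique(readout$anchored_primer[readout$tube == tube])
      lt <- .legal_reactions(primers[primers$label %in% members, ,
                                     drop = FALSE], max_amplicon_len)
      if (nrow(lt)) lt$tube <- tube
      lt
    })
    layout <- do.call(rbind, parts[vapply(parts, NROW, 0L) > 0])
  }
  positives <- call_positive(readout, layout, rule)
  gc <- genotype_from_positives(positives, primers)
  graph <- phase_constraints(positives, primers)
  res <- assemble_haplotypes(graph, gc)
  attr(res, "positives") <- positives
  res
}

#' Exhaustive phase-enumeration oracle
#'
#' Independent check on the decoder: enumerate every phase configuration of
#' the heterozygous sites (2^(h-1); haplotype order is arbitrary), simulate
#' each configuration's zero-noise positive reaction set, and keep the
#' configurations whose set equals the observed one. The decoder must return
#' the unique survivor when there is one, and report ambiguity when several
#' survive.
#'
#' @param genotype_calls Output of [genotype_from_positives].
#' @param positives Output of [call_positive].
#' @param primers A `primer_panel`.
#' @param max_het Refuse instances with more heterozygous sites than this
#'   (combinatorial guard, default 12).
#' @return List of surviving haplotype pairs; each element is a list of two
#'   site-named base vectors.
#' @export
brute_force_oracle <- function(genotype_calls, positives, primers,
                               max_het = 12L) {
  gc <- genotype_calls[genotype_calls$flag != "missing", , drop = FALSE]
  if (any(gc$n_bases > 2L)) stop("oracle needs <= 2 bases per site")
  base_list <- strsplit(gc$bases, ",")
  het <- which(gc$n_bases == 2L)
  h <- length(het)
  if (h > max_het) stop("refusing ", h, " het sites (> ", max_het, ")")
  observed <- sort(paste(positives$fwd_label[positives$positive],
                         positives$rev_label[positives$positive],
                         sep = "|"))
  ## restrict to reactions over called (non-missing) sites
  lay <- positives
  lay$site_f <- .primer_site(primers, lay$fwd_label)
  lay$site_r <- .primer_site(primers, lay$rev_label)
  lay <- lay[lay$site_f %in% gc$site & lay$site_r %in% gc$site, ,
             drop = FALSE]
  fi <- match(lay$fwd_label, primers$label)
  ri <- match(lay$rev_label, primers$label)
  single <- !any(grepl(",", primers$disc_bases[c(fi, ri)]))
  bf1 <- primers$disc_bases[fi]
  br1 <- primers$disc_bases[ri]
  base_f <- strsplit(bf1, ",")
  base_r <- strsplit(br1, ",")
  sf <- as.character(lay$site_f); sr <- as.character(lay$site_r)

  hap_template <- vapply(base_list, `[`, "", 1L)
  names(hap_template) <- gc$site
  n_cfg <- if (h == 0L) 1L else 2L^(h - 1L)
  survivors <- list()
  for (cfg in seq_len(n_cfg) - 1L) {
    hap1 <- hap2 <- hap_template
    for (k in seq_len(h)) {
      s <- het[k]
      ## first het site fixed: configuration bits cover sites 2..h
      bit <- if (k == 1L) 0L else bitwAnd(bitwShiftR(cfg, k - 2L), 1L)
      hap1[s] <- base_list[[s]][1L + bit]
      hap2[s] <- base_list[[s]][2L - bit]
    }
    expected <- if (single) {
      (hap1[sf] == bf1 & hap1[sr] == br1) |
        (hap2[sf] == bf1 & hap2[sr] == br1)
    } else {
      vapply(seq_len(nrow(lay)), function(i) {
        (hap1[sf[i]] %in% base_f[[i]] && hap1[sr[i]] %in% base_r[[i]]) ||
          (hap2[sf[i]] %in% base_f[[i]] && hap2[sr[i]] %in% base_r[[i]])
      }, TRUE)
    }
    exp_keys <- sort(paste(lay$fwd_label[expected], lay$rev_label[expected],
                           sep = "|"))
    if (identical(exp_keys, observed)) {
      survivors[[length(survivors) + 1L]] <- list(hap1, hap2)
    }
  }
  ## collapse configurations that give the same unordered haplotype pair
  keys <- vapply(survivors, function(p) {
    paste(sort(c(paste(p[[1]], collapse = ""),
                 paste(p[[2]], collapse = ""))), collapse = "/")
  }, "")
  survivors[!duplicated(keys)]
}

#' Canonical key for an unordered haplotype pair
#'
#' @param haps List of one or two site-named base vectors (a `decoded_result`
#'   `haplotypes` element, or an oracle survivor).
#' @return Character scalar; equal keys mean equal unordered pairs.
#' @export
haplotype_pair_key <- function(haps) {
  if (length(haps) == 1L) haps <- c(haps, haps)
  paste(sort(c(paste(haps[[1]], collapse = ""),
               paste(haps[[2]], collapse = ""))), collapse = "/")
}
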