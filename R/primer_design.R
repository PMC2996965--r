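#' Primer design constraints
#'
#' Bundle of the tunable knobs for allele-specific (ARMS) primer design. The
#' melting-temperature window defaults to 55 +/- 3 degrees C, the window used
#' for the locus this package was developed on. Complementarity thresholds are
#' conservative defaults; the screens are configurable because acceptable
#' dimer lengths depend on cycling conditions.
#'
#' @param tm_target_c Target melting temperature, degrees C.
#' @param tm_tolerance_c Half-width of the acceptance window, degrees C.
#' @param min_len,max_len Primer length bounds (bases).
#' @param max_self_complement_run Longest tolerated self-complementary run.
#' @param max_pair_complement_run Longest tolerated run between two primers.
#' @param max_3prime_dimer_run Longest tolerated complementary run anchored at
#'   a 3' terminus (primer-dimer extension risk).
#' @param tm_method `"nn"` (nearest-neighbor, default) or `"wallace"`
#'   (2(A+T) + 4(G+C), exact integer arithmetic).
#' @param oligo_conc_m Total oligo concentration (mol/L) for the
#'   nearest-neighbor model.
#' @param na_conc_m Monovalent cation concentration (mol/L).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(tm_target_c = 55, tm_tolerance_c = 3,
                               min_len = 16L, max_len = 30L,
                               max_self_complement_run = 8L,
                               max_pair_complement_run = 8L,
                               max_3prime_dimer_run = 4L,
                               tm_method = c("nn", "wallace"),
                               oligo_conc_m = 2.5e-7, na_conc_m = 0.05) {
  tm_method <- match.arg(tm_method)
  stopifnot(tm_tolerance_c > 0, min_len >= 8L, max_len >= min_len,
            max_self_complement_run > 0, max_pair_complement_run > 0,
            max_3prime_dimer_run > 0, oligo_conc_m > 0, na_conc_m > 0)
  structure(
    list(tm_target_c = tm_target_c, tm_tolerance_c = tm_tolerance_c,
         min_len = as.integer(min_len), max_len = as.integer(max_len),
         max_self_complement_run = as.integer(max_self_complement_run),
         max_pair_complement_run = as.integer(max_pair_complement_run),
         max_3prime_dimer_run = as.integer(max_3prime_dimer_run),
         tm_method = tm_method, oligo_conc_m = oligo_conc_m,
         na_conc_m = na_conc_m),
    class = "design_constraints"
  )
}

#' Expand a degenerate sequence into concrete sequences
#'
#' Cartesian expansion over all IUPAC degenerate positions ("wobbles"), in
#' deterministic lexicographic order. The number of expansions is the product
#' of the per-position code cardinalities.
#'
#' @param sequence Character scalar over IUPAC codes, 5'->3'.
#' @param max_expansions Guard against combinatorial blow-up.
#' @return Character vector of concrete A/C/G/T sequences.
#' @examples
#' expand_degenerate("ARY")  # AAC AAT AGC AGT
#' @export
expand_degenerate <- function(sequence, max_expansions = 65536L) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% names(.bases_by_iupac))
  if (length(bad)) {
    stop("invalid IUPAC code at position(s) ", paste(bad, collapse = ", "),
         " of ", sequence)
  }
  alphabets <- .bases_by_iupac[chars]
  n <- prod(lengths(alphabets))
  if (n > max_expansions) stop("sequence too degenerate: ", n, " expansions")
  ## rightmost position varies fastest; per-position alphabets are sorted,
  ## so the resulting strings come out in lexicographic order
  grid <- expand.grid(rev(alphabets), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  apply(grid[, rev(seq_along(alphabets)), drop = FALSE], 1L, paste,
        collapse = "")
}

## SantaLucia (unified) nearest-neighbor parameters.
## dH in kcal/mol, dS in cal/(mol K); keys are 5'->3' dinucleotides.
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Estimate oligo melting temperature
#'
#' `"nn"` uses the unified nearest-neighbor thermodynamic model with duplex
#' initiation terms and a monovalent-salt entropy correction;
#' `"wallace"` is the classic 2(A+T) + 4(G+C) rule, useful when exact integer
#' arithmetic is wanted in tests.
#'
#' @param sequence Concrete A/C/G/T sequence, length >= 8.
#' @param method `"nn"` or `"wallace"`.
#' @param oligo_conc_m,na_conc_m Concentrations for the nearest-neighbor
#'   model (mol/L).
#' @return Melting temperature in degrees C.
#' @export
tm_estimate <- function(sequence, method = c("nn", "wallace"),
                        oligo_conc_m = 2.5e-7, na_conc_m = 0.05) {
  method <- match.arg(method)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T"))) {
    stop("tm_estimate needs a concrete A/C/G/T sequence")
  }
  n <- length(chars)
  if (n < 8L) stop("sequence too short for a Tm estimate (length ", n, " < 8)")
  gc <- sum(chars %in% c("G", "C"))
  if (method == "wallace") {
    return(2 * (n - gc) + 4 * gc)
  }
  dinucs <- paste0(chars[-n], chars[-1L])
  dh <- sum(.nn_dh[dinucs])
  ds <- sum(.nn_ds[dinucs])
  ## duplex initiation: terminal G.C adds (0.1, -2.8), terminal A.T (2.3, 4.1)
  for (term in chars[c(1L, n)]) {
    if (term %in% c("G", "C")) {
      dh <- dh + 0.1; ds <- ds - 2.8
    } else {
      dh <- dh + 2.3; ds <- ds + 4.1
    }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_conc_m)
  r_gas <- 1.987  # cal/(mol K)
  dh * 1000 / (ds + r_gas * log(oligo_conc_m / 4)) - 273.15
}

#' Melting-temperature summary over a degenerate primer
#'
#' A wobbled primer has no single Tm; this reports min/mean/max over the
#' concrete expansions. Design windows apply to the mean.
#'
#' @inheritParams tm_estimate
#' @return Named numeric vector `min`, `mean`, `max`, `n_expansions`.
#' @export
tm_degenerate <- function(sequence, method = c("nn", "wallace"),
                          oligo_conc_m = 2.5e-7, na_conc_m = 0.05) {
  method <- match.arg(method)
  tms <- vapply(expand_degenerate(sequence), tm_estimate, 0,
                method = method, oligo_conc_m = oligo_conc_m,
                na_conc_m = na_conc_m)
  c(min = min(tms), mean = mean(tms), max = max(tms),
    n_expansions = length(tms))
}

## pairable[x, y]: can IUPAC code x Watson-Crick pair with code y in some
## expansion of each
.iupac_pair_matrix <- local({
  codes <- names(.bases_by_iupac)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (x in codes) for (y in codes) m[x, y] <- .iupac_can_pair(x, y)
  m
})

## Longest antiparallel complementary run between p and q (IUPAC-aware: a run
## counts if SOME expansion pair realises it). Returns the run-length matrix
## D where D[i, j] is the complementary run ending at p[i] paired with q
## position n_q - j + 1.
.dimer_dp <- function(p_chars, q_chars) {
  r <- rev(q_chars)
  m <- .iupac_pair_matrix[p_chars, r, drop = FALSE]
  np <- length(p_chars); nq <- length(r)
  d <- matrix(0L, np, nq)
  d[1L, ] <- as.integer(m[1L, ])
  if (np > 1L) {
    for (i in 2L:np) {
      d[i, ] <- as.integer(m[i, ]) *
        (c(0L, d[i - 1L, -nq]) + 1L)
    }
  }
  d
}

#' Screen a primer (pair) for complementarity
#'
#' Detects internal/self complementarity and primer-primer dimers: the
#' longest antiparallel Watson-Crick run achievable by any pair of degenerate
#' expansions, plus runs anchored at either 3' terminus (the extension-prone
#' geometry). Fails when a run exceeds the configured thresholds.
#'
#' @param p,q Primer sequences (IUPAC, 5'->3'); `q = NULL` screens `p`
#'   against itself.
#' @param constraints A [design_constraints] object.
#' @return List of class `complementarity_report`: `pass`, `max_run`,
#'   `max_run_offset` (positions on p and q of the run's 3'-most base on p),
#'   `max_3prime_run`, `threshold_run`, `threshold_3prime`.
#' @export
complementarity_screen <- function(p, q = NULL,
                                   constraints = design_constraints()) {
  self <- is.null(q)
  if (self) q <- p
  pc <- strsplit(toupper(p), "")[[1]]
  qc <- strsplit(toupper(q), "")[[1]]
  d <- .dimer_dp(pc, qc)
  max_run <- max(d)
  idx <- which(d == max_run, arr.ind = TRUE)[1L, ]
  ## 3'-anchored runs: ending at p's 3' base, or at q's 3' base (symmetric DP)
  run_3p_p <- max(d[nrow(d), ])
  run_3p_q <- max(.dimer_dp(qc, pc)[length(qc), ])
  max_3p <- max(run_3p_p, run_3p_q)
  thr_run <- if (self) constraints$max_self_complement_run else
    constraints$max_pair_complement_run
  thr_3p <- constraints$max_3prime_dimer_run
  structure(
    list(pass = max_run <= thr_run && max_3p <= thr_3p,
         self = self,
         max_run = max_run,
         max_run_offset = c(p_end = unname(idx[1L]),
                            q_end = length(qc) - unname(idx[2L]) + 1L),
         max_3prime_run = max_3p,
         threshold_run = thr_run, threshold_3prime = thr_3p),
    class = "complementarity_report"
  )
}

#' @export
print.complementarity_report <- function(x, ...) {
  cat(sprintf("%s screen: %s (max run %d/%d, 3'-anchored %d/%d)\n",
              if (x$self) "self" else "pair",
              if (x$pass) "pass" else "FAIL",
              x$max_run, x$threshold_run,
              x$max_3prime_run, x$threshold_3prime))
  invisible(x)
}

## -- primer panel container ---------------------------------------------

#' Assemble a primer panel data.frame
#'
#' @param df data.frame with columns `label`, `orientation`, `sequence`,
#'   `ref_start`, `ref_end` (1-based inclusive; start > end allowed and
#'   conventional for reverse primers, which are written 5'->3' as synthesized).
#' @param strict Error on rows whose coordinate span disagrees with the
#'   sequence length; otherwise flag them in a `span_ok` column.
#' @return data.frame of class `primer_panel`, with derived columns `site`
#'   (reference position of the 3' discriminating base), `disc_bases`
#'   (comma-joined sense-strand bases the 3' terminus accepts), `fp_lo`,
#'   `fp_hi` (reference footprint), `span_ok`.
#' @export
primer_panel <- function(df, strict = TRUE) {
  need <- c("label", "orientation", "sequence", "ref_start", "ref_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing primer table column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$label)) {
    stop("duplicate primer labels: ",
         paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
  }
  if (!all(df$orientation %in% c("forward", "reverse"))) {
    stop("orientation must be 'forward' or 'reverse'")
  }
  df$sequence <- toupper(df$sequence)
  span <- abs(df$ref_end - df$ref_start) + 1L
  df$span_ok <- span == nchar(df$sequence)
  if (strict && !all(df$span_ok)) {
    stop("span/length mismatch in row(s): ",
         paste(df$label[!df$span_ok], collapse = ", "))
  }
  df$fp_lo <- pmin(df$ref_start, df$ref_end)
  df$fp_hi <- pmax(df$ref_start, df$ref_end)
  last_char <- substr(df$sequence, nchar(df$sequence), nchar(df$sequence))
  df$site <- ifelse(df$orientation == "forward", df$fp_hi, df$fp_lo)
  df$disc_bases <- vapply(seq_len(nrow(df)), function(i) {
    b <- iupac_bases(last_char[i])
    if (df$orientation[i] == "reverse") b <- unname(.complement_map[b])
    paste(sort(b), collapse = ",")
  }, "")
  class(df) <- c("primer_panel", "data.frame")
  df
}

#' Read / write the tab-separated primer-panel dialect
#'
#' Tab-separated, header row, `#` comments; columns `label`, `orientation`,
#' `sequence`, `ref_start`, `ref_end`. The coordinate/length invariant is
#' checked on load.
#'
#' @param path File path.
#' @param strict See [primer_panel].
#' @return `read_primer_table`: a `primer_panel`. `write_primer_table`: the
#'   path, invisibly.
#' @export
read_primer_table <- function(path, strict = TRUE) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  primer_panel(df, strict = strict)
}

#' @rdname read_primer_table
#' @param panel A `primer_panel`.
#' @export
write_primer_table <- function(panel, path) {
  stopifnot(inherits(panel, "primer_panel"))
  utils::write.table(
    panel[, c("label", "orientation", "sequence", "ref_start", "ref_end")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Design allele-specific primers at one polymorphic site
#'
#' One primer per base observed at the site; each primer's 3' terminus sits
#' exactly on the site and carries that base (ARMS discrimination). Interior
#' polymorphic positions are wobbled with IUPAC codes from the panel
#' consensus. Length is the shortest, within bounds, whose mean Tm over the
#' degenerate expansions falls in the design window; primers failing the
#' self-complementarity screen are dropped with a logged reason.
#'
#' @param panel An [allele_panel].
#' @param site 1-based alignment position; must be polymorphic in `panel`.
#' @param orientation `"forward"` or `"reverse"`.
#' @param constraints A [design_constraints].
#' @param strict When `TRUE` (the op contract) a site/base with no length in
#'   the Tm window yields no primer, and screen failures are dropped; when
#'   `FALSE` (pipeline mode) the closest-Tm length is used and screen
#'   failures kept, both flagged in the `flag` column.
#' @return A `primer_panel` (possibly 0 rows) with extra columns `tm_mean`
#'   and `flag`; attribute `diagnostics` lists dropped candidates and why.
#' @export
design_allele_specific_primers <- function(panel, site,
                                           orientation = c("forward",
                                                           "reverse"),
                                           constraints = design_constraints(),
                                           strict = TRUE) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(panel, "allele_panel"))
  sites <- find_polymorphic_sites(panel)
  row <- sites[sites$position == site, ]
  if (nrow(row) != 1L) stop("position ", site, " is not polymorphic")
  cons <- strsplit(consensus_iupac(panel), "")[[1]]
  bases <- strsplit(row$bases, ",")[[1]]
  len_range <- constraints$min_len:constraints$max_len
  out <- list()
  diagnostics <- list()
  for (b in bases) {
    cand <- NULL
    best <- NULL  # closest-to-target fallback
    for (len in len_range) {
      if (orientation == "forward") {
        lo <- site - len + 1L; hi <- site
        if (lo < 1L) next
        chars <- cons[lo:hi]
        chars[len] <- b
        seq5to3 <- paste(chars, collapse = "")
      } else {
        lo <- site; hi <- site + len - 1L
        if (hi > panel$alignment_length) next
        chars <- cons[lo:hi]
        chars[1L] <- b
        seq5to3 <- reverse_complement(paste(chars, collapse = ""))
      }
      tm <- tm_degenerate(seq5to3, method = constraints$tm_method,
                          oligo_conc_m = constraints$oligo_conc_m,
                          na_conc_m = constraints$na_conc_m)
      dev <- abs(tm[["mean"]] - constraints$tm_target_c)
      rec <- list(sequence = seq5to3, lo = lo, hi = hi, len = len,
                  tm_mean = tm[["mean"]], dev = dev)
      if (is.null(best) || dev < best$dev) best <- rec
      if (dev <= constraints$tm_tolerance_c) { cand <- rec; break }
    }
    flag <- ""
    if (is.null(cand)) {
      if (is.null(best)) {
        diagnostics[[length(diagnostics) + 1L]] <- list(
          site = site, base = b, orientation = orientation,
          reason = "no geometrically feasible length")
        next
      }
      if (strict) {
        diagnostics[[length(diagnostics) + 1L]] <- list(
          site = site, base = b, orientation = orientation,
          reason = sprintf("no length in [%d, %d] reaches Tm %.1f +/- %.1f (closest mean %.1f)",
                           constraints$min_len, constraints$max_len,
                           constraints$tm_target_c,
                           constraints$tm_tolerance_c, best$tm_mean))
        next
      }
      cand <- best
      flag <- "tm_out_of_window"
    }
    scr <- complementarity_screen(cand$sequence, constraints = constraints)
    if (!scr$pass) {
      if (strict) {
        diagnostics[[length(diagnostics) + 1L]] <- list(
          site = site, base = b, orientation = orientation,
          reason = sprintf("self-complementarity screen failed (run %d, 3' run %d)",
                           scr$max_run, scr$max_3prime_run))
        next
      }
      flag <- paste0(flag, if (nzchar(flag)) ";", "self_screen_failed")
    }
    label <- sprintf("%s%d%s", if (orientation == "forward") "F" else "R",
                     site, tolower(b))
    out[[length(out) + 1L]] <- data.frame(
      label = label, orientation = orientation, sequence = cand$sequence,
      ref_start = if (orientation == "forward") cand$lo else cand$hi,
      ref_end = if (orientation == "forward") cand$hi else cand$lo,
      tm_mean = cand$tm_mean, flag = flag, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(label = character(0), orientation = character(0),
               sequence = character(0), ref_start = integer(0),
               ref_end = integer(0), tm_mean = numeric(0),
               flag = character(0), stringsAsFactors = FALSE)
  res <- if (nrow(res)) primer_panel(res) else {
    class(res) <- c("primer_panel", "data.frame"); res
  }
  attr(res, "diagnostics") <- diagnostics
  res
}

#' Design a full allele-specific primer panel
#'
#' Runs [design_allele_specific_primers] at every polymorphic site in both
#' orientations (skipping orientations the alignment geometry cannot
#' support). With `strict = FALSE` (the default here) every site/base gets a
#' primer — out-of-window Tm picks are flagged rather than dropped — which is
#' what the simulation/decoding pipeline needs for complete genotype coverage.
#'
#' @inheritParams design_allele_specific_primers
#' @param sites Optional integer vector of positions (default: all
#'   polymorphic sites).
#' @return A `primer_panel` covering the requested sites; attribute
#'   `diagnostics` aggregates per-site design notes.
#' @export
design_panel_primers <- function(panel, constraints = design_constraints(),
                                 sites = NULL, strict = FALSE) {
  poly <- find_polymorphic_sites(panel)
  if (is.null(sites)) sites <- poly$position
  stopifnot(all(sites %in% poly$position))
  parts <- list()
  diagnostics <- list()
  for (s in sites) {
    for (orient in c("forward", "reverse")) {
      feasible <- if (orient == "forward") s >= constraints$min_len else
        s + constraints$min_len - 1L <= panel$alignment_length
      if (!feasible) next
      d <- design_allele_specific_primers(panel, s, orient, constraints,
                                          strict = strict)
      if (nrow(d)) parts[[length(parts) + 1L]] <- as.data.frame(d)
      diagnostics <- c(diagnostics, attr(d, "diagnostics"))
    }
  }
  if (!length(parts)) stop("no primers designable for the requested sites")
  res <- primer_panel(do.call(rbind, parts))
  attr(res, "diagnostics") <- diagnostics
  res
}

#' Packaged published primer panel
#'
#' Verbatim transcription of the published allele-specific primer table
#' (bold markup dropped). Loaded leniently: three printed rows carry a
#' span/length inconsistency in the source table and are flagged via
#' `span_ok = FALSE`.
#'
#' @return A `primer_panel`.
#' @export
table2_primers <- function() {
  path <- system.file("extdata", "table2_primers.tsv", package = "transcistor",
                      mustWork = TRUE)
  read_primer_table(path, strict = FALSE)
}
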