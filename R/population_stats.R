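#' Cohort allele-frequency table
#'
#' Aggregates per-individual allele calls (two chromosomes each; homozygotes
#' contribute the same allele twice) into a frequency table in the field's
#' usual dialect: chromosome counts plus percent frequencies to one decimal.
#' Individuals whose decode status is not `"ok"` are excluded and logged,
#' with `n` adjusted.
#'
#' @param calls data.frame with columns `individual`, `allele1`, `allele2`
#'   and optionally `status` (default `"ok"`).
#' @return data.frame of class `frequency_table`, sorted by decreasing
#'   count: `allele_name`, `chromosome_count`, `frequency_percent`;
#'   attributes `n_individuals`, `n_chromosomes`, `excluded`.
#' @export
frequency_table <- function(calls) {
  stopifnot(all(c("individual", "allele1", "allele2") %in% names(calls)))
  if (!"status" %in% names(calls)) calls$status <- "ok"
  excluded <- calls$individual[calls$status != "ok"]
  ok <- calls[calls$status == "ok", , drop = FALSE]
  if (!nrow(ok)) stop("no individuals with status 'ok'")
  chroms <- c(ok$allele1, ok$allele2)
  counts <- sort(table(chroms), decreasing = TRUE)
  n_chrom <- 2L * nrow(ok)
  out <- data.frame(
    allele_name = names(counts),
    chromosome_count = as.integer(counts),
    frequency_percent = round(100 * as.integer(counts) / n_chrom, 1L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_individuals") <- nrow(ok)
  attr(out, "n_chromosomes") <- n_chrom
  attr(out, "excluded") <- excluded
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Convert a published-style percent table to a frequency_table
#'
#' Re-derives integer chromosome counts from printed percent frequencies via
#' `round(f/100 * n_chromosomes)` — the convention under which a printed
#' 0.9% at n = 218 chromosomes means two carrier chromosomes and 0.5% means
#' one.
#'
#' @param df data.frame with `allele_accession` (or `allele_name`) and
#'   `frequency_percent`.
#' @param n_chromosomes Total chromosomes (2 x individuals).
#' @return A `frequency_table`.
#' @export
as_frequency_table <- function(df, n_chromosomes) {
  name_col <- intersect(c("allele_name", "allele_accession"), names(df))[1L]
  if (is.na(name_col)) stop("need an allele_name or allele_accession column")
  out <- data.frame(
    allele_name = df[[name_col]],
    chromosome_count = as.integer(round(df$frequency_percent / 100 *
                                          n_chromosomes)),
    frequency_percent = df$frequency_percent,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$chromosome_count, out$allele_name), ]
  rownames(out) <- NULL
  attr(out, "n_individuals") <- n_chromosomes / 2
  attr(out, "n_chromosomes") <- as.integer(n_chromosomes)
  attr(out, "excluded") <- character(0)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Number of alleles carried by exactly k chromosomes
#'
#' E.g. with `k = 1` this counts the singleton alleles seen in just one
#' chromosome of one animal.
#'
#' @param table A `frequency_table`.
#' @param k_chromosomes Chromosome count to match.
#' @return Integer.
#' @export
carriers_by_count <- function(table, k_chromosomes) {
  stopifnot(inherits(table, "frequency_table"))
  sum(table$chromosome_count == k_chromosomes)
}

#' Cumulative frequency of the k most common alleles
#'
#' @param table A `frequency_table`.
#' @param k How many top alleles to sum.
#' @return Percent (numeric).
#' @export
top_k_cumulative <- function(table, k) {
  stopifnot(inherits(table, "frequency_table"),
            k <= nrow(table))
  sum(sort(table$frequency_percent, decreasing = TRUE)[seq_len(k)])
}

#' Composite linkage disequilibrium from unphased genotypes
#'
#' The composite coefficient is computable without phase: with per-individual
#' allele dosages at two biallelic sites, counting genotype classes N (e.g.
#' N_AABB = both sites homozygous for the index alleles),
#' \deqn{\hat\Delta = \frac{1}{n}\left[2N_{AABB} + N_{AABb} + N_{AaBB} +
#'   \tfrac12 N_{AaBb}\right] - 2\hat p_A \hat p_B}
#' The correlation divides by
#' \eqn{\sqrt{(p_A(1-p_A)+\hat D_A)(p_B(1-p_B)+\hat D_B)}} where
#' \eqn{\hat D_A = \hat P_{AA} - \hat p_A^2} is the within-locus departure
#' from Hardy-Weinberg (`denominator = "composite"`, the coefficient's
#' standard form); `denominator = "simple"` omits the departure terms.
#'
#' @param dose_a,dose_b Integer vectors (0/1/2): per-individual copies of the
#'   index allele at each site.
#' @param denominator `"composite"` or `"simple"`.
#' @return List of class `ld_result`: `p_A`, `p_B`, `D`, `r`,
#'   `mode = "composite"`, `n`.
#' @export
composite_ld <- function(dose_a, dose_b,
                         denominator = c("composite", "simple")) {
  denominator <- match.arg(denominator)
  stopifnot(length(dose_a) == length(dose_b), length(dose_a) >= 2,
            all(dose_a %in% 0:2), all(dose_b %in% 0:2))
  n <- length(dose_a)
  p_a <- mean(dose_a) / 2
  p_b <- mean(dose_b) / 2
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    stop("monomorphic site: correlation undefined")
  }
  n_aabb <- sum(dose_a == 2 & dose_b == 2)
  n_aabh <- sum(dose_a == 2 & dose_b == 1)
  n_ahbb <- sum(dose_a == 1 & dose_b == 2)
  n_ahbh <- sum(dose_a == 1 & dose_b == 1)
  delta <- (2 * n_aabb + n_aabh + n_ahbb + 0.5 * n_ahbh) / n - 2 * p_a * p_b
  var_a <- p_a * (1 - p_a)
  var_b <- p_b * (1 - p_b)
  if (denominator == "composite") {
    d_a <- mean(dose_a == 2) - p_a^2
    d_b <- mean(dose_b == 2) - p_b^2
    var_a <- var_a + d_a
    var_b <- var_b + d_b
  }
  structure(list(p_A = p_a, p_B = p_b, p_AB = NA_real_, D = delta,
                 r = delta / sqrt(var_a * var_b), mode = "composite",
                 denominator = denominator, n = n),
            class = "ld_result")
}

#' Direct linkage disequilibrium from phased haplotypes
#'
#' With phase in hand, LD is the textbook haplotype-frequency quantity:
#' \eqn{D = p_{AB} - p_A p_B} and
#' \eqn{r = D / \sqrt{p_A(1-p_A)\,p_B(1-p_B)}}.
#'
#' @param hap_a,hap_b Logical vectors over chromosomes (one entry per
#'   chromosome, 2 per individual): does this chromosome carry the index
#'   allele at site A / site B?
#' @return List of class `ld_result` with `mode = "direct"` and the observed
#'   `p_AB`.
#' @export
direct_ld <- function(hap_a, hap_b) {
  stopifnot(is.logical(hap_a), is.logical(hap_b),
            length(hap_a) == length(hap_b), length(hap_a) >= 2)
  p_a <- mean(hap_a)
  p_b <- mean(hap_b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    stop("monomorphic site: correlation undefined")
  }
  p_ab <- mean(hap_a & hap_b)
  d <- p_ab - p_a * p_b
  structure(list(p_A = p_a, p_B = p_b, p_AB = p_ab, D = d,
                 r = d / sqrt(p_a * (1 - p_a) * p_b * (1 - p_b)),
                 mode = "direct", denominator = NA_character_,
                 n = length(hap_a) / 2),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("%s LD: p_A=%.4f p_B=%.4f%s D=%.4f r=%.4f (n=%g)\n",
              x$mode, x$p_A, x$p_B,
              if (!is.na(x$p_AB)) sprintf(" p_AB=%.4f", x$p_AB) else "",
              x$D, x$r, x$n))
  invisible(x)
}

#' Compare composite and direct LD on the same cohort
#'
#' Computes both estimators on the same individuals: the composite
#' coefficient from the genotypes obtained by collapsing phase, and the
#' direct coefficient from the phased chromosomes — the comparison phase
#' information makes possible. Also reports the modal two-site haplotype and
#' its frequency.
#'
#' @param hap1_a,hap1_b,hap2_a,hap2_b Logical vectors per individual: does
#'   haplotype 1 (resp. 2) carry the index allele at site A / B?
#' @param denominator Passed to [composite_ld].
#' @return List of class `ld_comparison`: `composite`, `direct`
#'   ([composite_ld]/[direct_ld] results), `modal_haplotype` (e.g. `"AB"`,
#'   index-allele presence coded A/a, B/b), `modal_frequency`.
#' @export
ld_compare <- function(hap1_a, hap1_b, hap2_a, hap2_b,
                       denominator = c("composite", "simple")) {
  n <- length(hap1_a)
  stopifnot(length(hap1_b) == n, length(hap2_a) == n, length(hap2_b) == n)
  comp <- composite_ld(hap1_a + hap2_a, hap1_b + hap2_b,
                       denominator = denominator)
  dir_ <- direct_ld(c(hap1_a, hap2_a), c(hap1_b, hap2_b))
  hap_class <- paste0(ifelse(c(hap1_a, hap2_a), "A", "a"),
                      ifelse(c(hap1_b, hap2_b), "B", "b"))
  tab <- sort(table(hap_class), decreasing = TRUE)
  structure(list(composite = comp, direct = dir_,
                 modal_haplotype = names(tab)[1L],
                 modal_frequency = as.numeric(tab[1L]) / (2 * n)),
            class = "ld_comparison")
}

#' @export
print.ld_comparison <- function(x, ...) {
  print(x$composite)
  print(x$direct)
  cat(sprintf("modal two-site haplotype %s at frequency %.3f\n",
              x$modal_haplotype, x$modal_frequency))
  invisible(x)
}
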