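#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide ambiguity codes. Keyed by the sorted, comma-free
## concatenation of the bases a code covers, e.g. "AG" -> "R".
.iupac_by_bases <- c(
  A = "A", C = "C", G = "G", T = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V",
  ACGT = "N"
)

.bases_by_iupac <- local({
  out <- strsplit(names(.iupac_by_bases), "")
  names(out) <- unname(.iupac_by_bases)
  out
})

.complement_map <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' IUPAC code covering a set of bases
#'
#' Returns the minimal IUPAC degeneracy code whose expansion is exactly the
#' given base set.
#'
#' @param bases Character vector of bases drawn from A/C/G/T (duplicates
#'   allowed and ignored).
#' @return Single character: the IUPAC code.
#' @examples
#' iupac_code(c("A", "G"))          # "R"
#' iupac_code(c("A", "G", "T"))     # "D"
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0L || !all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be a non-empty subset of A/C/G/T")
  }
  unname(.iupac_by_bases[[paste(bases, collapse = "")]])
}

#' Expand an IUPAC code to the bases it covers
#'
#' @param code Single IUPAC character (A/C/G/T or a degeneracy code).
#' @return Character vector of concrete bases, sorted.
#' @examples
#' iupac_bases("D")  # A G T
#' @export
iupac_bases <- function(code) {
  code <- toupper(code)
  if (length(code) != 1L || is.na(code) || !code %in% names(.bases_by_iupac)) {
    stop("not an IUPAC nucleotide code: ", deparse(code))
  }
  .bases_by_iupac[[code]]
}

#' Reverse complement of a (possibly degenerate) sequence
#'
#' Complements IUPAC codes correctly (R <-> Y, K <-> M, ...).
#'
#' @param x Character scalar, 5'->3' sequence over IUPAC codes.
#' @return Character scalar, the reverse complement 5'->3'.
#' @export
reverse_complement <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- which(!chars %in% names(.complement_map))
  if (length(bad)) {
    stop("invalid IUPAC character(s) at position(s) ",
         paste(bad, collapse = ", "))
  }
  paste(rev(unname(.complement_map[chars])), collapse = "")
}

## TRUE when some expansion of IUPAC code x is Watson-Crick complementary to
## some expansion of code y. Used by the degenerate-aware dimer screen.
.iupac_can_pair <- function(x, y) {
  bx <- .bases_by_iupac[[x]]
  by <- .bases_by_iupac[[y]]
  any(unname(.complement_map[bx]) %in% by)
}
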