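#' Construct an aligned allele panel
#'
#' An allele panel is the reference object for a polymorphic locus: a set of
#' named, equal-length, gap-free aligned sequences (e.g. the known exon 2
#' alleles of ovine MHC \emph{DRB1}). All coordinates are 1-based alignment
#' columns.
#'
#' @param sequences Character vector of upper-case A/C/G/T sequences, all the
#'   same length. Gaps and ambiguity codes are rejected: input must be a
#'   pre-aligned, gap-free exon alignment.
#' @param names Character vector of unique allele names (e.g. accessions).
#'   Defaults to `names(sequences)`.
#' @return An object of class `allele_panel`: a list with elements
#'   `sequences` (named character vector) and `alignment_length`.
#' @examples
#' p <- allele_panel(c(a1 = "ACGT", a2 = "ACCT"))
#' find_polymorphic_sites(p)
#' @export
allele_panel <- function(sequences, names = base::names(sequences)) {
  if (length(sequences) == 0L) stop("empty allele panel")
  if (is.null(names) || anyNA(names) || any(names == "")) {
    stop("every allele needs a name")
  }
  if (anyDuplicated(names)) {
    stop("duplicate allele names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  sequences <- toupper(as.character(sequences))
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    stop("alignment is ragged: sequence lengths ",
         paste(sort(len), collapse = ", "))
  }
  if (any(grepl("[^ACGT]", sequences))) {
    bad <- names[grepl("[^ACGT]", sequences)]
    stop("sequences must be gap-free A/C/G/T only; offending: ",
         paste(bad, collapse = ", "))
  }
  base::names(sequences) <- names
  structure(
    list(sequences = sequences, alignment_length = len),
    class = "allele_panel"
  )
}

#' @export
print.allele_panel <- function(x, ...) {
  cat(sprintf("allele_panel: %d alleles, alignment length %d\n",
              length(x$sequences), x$alignment_length))
  invisible(x)
}

#' @export
length.allele_panel <- function(x) length(x$sequences)

## Alignment as a character matrix, alleles x columns.
.panel_matrix <- function(panel) {
  do.call(rbind, strsplit(unname(panel$sequences), ""))
}

#' Read an allele panel from a FASTA alignment
#'
#' @param path FASTA file of equal-length, gap-free allele sequences.
#' @return An [allele_panel].
#' @export
read_allele_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  allele_panel(as.character(ss), names = names(ss))
}

#' Write an allele panel to FASTA
#'
#' @param panel An [allele_panel].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "allele_panel"))
  ss <- Biostrings::DNAStringSet(panel$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Locate polymorphic sites in an allele alignment
#'
#' Scans every alignment column and reports those where at least two distinct
#' bases occur across the panel's alleles. Most sites at a locus like this
#' are biallelic, but tri- and tetra-allelic columns occur and are reported
#' with the matching degeneracy code.
#'
#' @param panel An [allele_panel].
#' @return A data.frame with one row per polymorphic column, sorted by
#'   position: `position` (1-based), `n_bases`, `bases` (comma-joined, sorted)
#'   and `iupac` (minimal covering code).
#' @export
find_polymorphic_sites <- function(panel) {
  stopifnot(inherits(panel, "allele_panel"))
  m <- .panel_matrix(panel)
  per_col <- apply(m, 2L, function(col) sort(unique(col)), simplify = FALSE)
  poly <- which(lengths(per_col) >= 2L)
  data.frame(
    position = poly,
    n_bases = lengths(per_col)[poly],
    bases = vapply(per_col[poly], paste, "", collapse = ","),
    iupac = vapply(per_col[poly], iupac_code, ""),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' IUPAC consensus of an allele alignment
#'
#' Per-column minimal degeneracy code covering every base observed in the
#' panel; invariant columns keep their base. This is the degenerate consensus
#' against which allele-specific primers are designed.
#'
#' @param panel An [allele_panel].
#' @return Character scalar of length `alignment_length` over IUPAC codes.
#' @export
consensus_iupac <- function(panel) {
  stopifnot(inherits(panel, "allele_panel"))
  m <- .panel_matrix(panel)
  paste(apply(m, 2L, function(col) iupac_code(unique(col))), collapse = "")
}

#' Match an assembled haplotype against the known-allele panel
#'
#' Novelty at a locus like this overwhelmingly arises as new combinations of
#' known polymorphisms, so identity is defined over the panel's polymorphic
#' sites only: invariant columns carry no information. A haplotype matching
#' no known allele at those sites is reported `"novel"`.
#'
#' @param panel An [allele_panel].
#' @param haplotype Either a full-length sequence string, or a named character
#'   vector / list mapping polymorphic-site positions (names, 1-based) to
#'   bases. Must assign a base to every polymorphic site.
#' @param sites Optional precomputed [find_polymorphic_sites] result.
#' @return A list with `call` (allele name, `"novel"`, or `"error"`),
#'   `matches` (all matching allele names) and `message`.
#' @export
match_haplotype <- function(panel, haplotype, sites = NULL) {
  stopifnot(inherits(panel, "allele_panel"))
  if (is.null(sites)) sites <- find_polymorphic_sites(panel)
  pos <- sites$position
  if (length(pos) == 0L) {
    return(list(call = names(panel$sequences)[1L],
                matches = names(panel$sequences),
                message = "panel has no polymorphic sites"))
  }
  hap <- .haplotype_bases_at(haplotype, pos, panel$alignment_length)
  if (anyNA(hap)) {
    missing_pos <- pos[is.na(hap)]
    stop("haplotype missing base assignment at polymorphic position(s) ",
         paste(missing_pos, collapse = ", "))
  }
  m <- .panel_matrix(panel)[, pos, drop = FALSE]
  hits <- which(apply(m, 1L, function(row) all(row == hap)))
  if (length(hits) == 1L) {
    list(call = names(panel$sequences)[hits],
         matches = names(panel$sequences)[hits], message = "known allele")
  } else if (length(hits) == 0L) {
    list(call = "novel", matches = character(0),
         message = "no panel allele carries this combination of site bases")
  } else {
    list(call = "error", matches = names(panel$sequences)[hits],
         message = paste0("panel alleles not distinguishable at polymorphic ",
                          "sites: ",
                          paste(names(panel$sequences)[hits], collapse = ", ")))
  }
}

## Extract bases at `pos` from a haplotype given either as a full-length
## string or a position-named map. NA where unassigned.
.haplotype_bases_at <- function(haplotype, pos, alignment_length) {
  if (is.character(haplotype) && length(haplotype) == 1L &&
      is.null(names(haplotype))) {
    if (nchar(haplotype) != alignment_length) {
      stop("full-length haplotype must have alignment length ",
           alignment_length, ", got ", nchar(haplotype))
    }
    return(strsplit(toupper(haplotype), "")[[1]][pos])
  }
  map <- unlist(haplotype)
  if (is.null(names(map))) stop("site map haplotype must be position-named")
  out <- toupper(unname(map[as.character(pos)]))
  out[out == ""] <- NA_character_
  out
}

#' Packaged allele-frequency table for the study cohort
#'
#' Transcription of the published allele table for the 109-ram Scottish
#' Blackface cohort: 33 exon 2 alleles with percent frequencies and locus
#' nomenclature names. Frequencies are as printed (they sum to 100.3; the
#' printed values are rounded to one decimal).
#'
#' @return data.frame with columns `allele_accession`, `frequency_percent`,
#'   `number`, `ipd_name`.
#' @export
table1_alleles <- function() {
  path <- system.file("extdata", "table1_alleles.tsv", package = "transcistor",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric", "character",
                                   "character"))
}
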