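test_that("degenerate expansion is the cartesian product in lexicographic order", {
  expect_equal(expand_degenerate("ACGT"), "ACGT")
  expect_equal(expand_degenerate("ARY"), c("AAC", "AAT", "AGC", "AGT"))
  # published primer F1 carries R, M, R, Y: 2*2*2*2 expansions
  expect_length(expand_degenerate("GARMGAGTGTCRTTTCTY"), 16L)
  expect_error(expand_degenerate("ACXT"), "position\\(s\\) 3")

  # property: |expansion| equals the product of code cardinalities
  codes <- names(transcistor:::.bases_by_iupac)
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(codes, sample(3:8, 1), replace = TRUE), collapse = "")
    ex <- expand_degenerate(s)
    card <- prod(vapply(strsplit(s, "")[[1]],
                        function(c) length(iupac_bases(c)), 0L))
    expect_length(ex, card)
    expect_false(anyDuplicated(ex) > 0)
    expect_equal(ex, sort(ex))
  }
})

test_that("melting-temperature estimates behave physically", {
  # Wallace rule is exact integer arithmetic: 2(A+T) + 4(G+C)
  expect_equal(tm_estimate("ACGTACGTACGT", "wallace"), 36)
  expect_lt(tm_estimate(strrep("A", 16)), tm_estimate(strrep("G", 16)))
  expect_lt(tm_estimate(strrep("A", 16), "wallace"),
            tm_estimate(strrep("G", 16), "wallace"))
  # duplex symmetry: a sequence and its reverse complement share a Tm
  s <- "GATCGGATCGGATCGGAT"
  expect_equal(tm_estimate(s), tm_estimate(reverse_complement(s)),
               tolerance = 1e-12)
  expect_error(tm_estimate("ACGTACG"), "too short")
  expect_error(tm_estimate("ACGTRCGTAA"), "concrete")

  # Wallace Tm is monotone non-decreasing in GC count at fixed length
  set.seed(3)
  for (i in 1:10) {
    s <- sample(c("A", "C", "G", "T"), 18, replace = TRUE)
    j <- which(s %in% c("A", "T"))
    if (!length(j)) next
    s2 <- s
    s2[j[1]] <- "G"
    expect_gte(tm_estimate(paste(s2, collapse = ""), "wallace"),
               tm_estimate(paste(s, collapse = ""), "wallace"))
  }
})

test_that("allele-specific design puts each observed base at the 3' end", {
  toy <- toy_two_site()
  d <- design_allele_specific_primers(toy$panel, 20, "forward",
                                      strict = FALSE)
  expect_equal(nrow(d), 2L)
  expect_setequal(d$disc_bases, c("C", "T"))
  # primers differ only at the 3' terminal base
  n <- nchar(d$sequence)
  expect_equal(substr(d$sequence[1], 1, n[1] - 1),
               substr(d$sequence[2], 1, n[2] - 1))
  expect_error(design_allele_specific_primers(toy$panel, 21, "forward"),
               "not polymorphic")
})

test_that("multi-allelic sites get one primer per base and footprints match alleles", {
  loc <- small_locus()
  tri <- loc$sites[loc$sites$n_bases >= 3, ]
  expect_gt(nrow(tri), 0)   # the generator seeds multiallelic sites
  d <- design_allele_specific_primers(loc$panel, tri$position[1], "forward",
                                      strict = FALSE)
  expect_equal(nrow(d), tri$n_bases[1])
  expect_false(any(duplicated(d$disc_bases)))

  # every designed primer footprint exact-matches >= 1 panel allele
  primers <- loc$primers
  for (i in seq_len(nrow(primers))) {
    lo <- primers$fp_lo[i]; hi <- primers$fp_hi[i]
    probe <- if (primers$orientation[i] == "forward") primers$sequence[i]
             else reverse_complement(primers$sequence[i])
    hit <- any(vapply(loc$panel$sequences, function(s)
      substr(s, lo, hi) %in% expand_degenerate(probe), TRUE))
    expect_true(hit, label = paste("footprint match for", primers$label[i]))
  }
})

test_that("designed panels share no 3' base within a site/orientation", {
  primers <- small_locus()$primers
  key <- paste(primers$site, primers$orientation)
  for (k in unique(key)) {
    d <- primers$disc_bases[key == k]
    expect_false(any(duplicated(d)))
  }
})

test_that("complementarity screen flags dimers and passes inert pairs", {
  cons <- design_constraints(max_pair_complement_run = 8,
                             max_3prime_dimer_run = 4)
  p <- "GATCGGATCGGATCGGAT"
  r <- complementarity_screen(p, reverse_complement(p), cons)
  expect_false(r$pass)
  expect_equal(r$max_run, nchar(p))
  ok <- complementarity_screen(strrep("A", 18), strrep("A", 18), cons)
  expect_true(ok$pass)
  expect_equal(ok$max_run, 0L)
  # self screen on a hairpin-free homopolymer passes
  expect_true(complementarity_screen(strrep("C", 18),
                                     constraints = cons)$pass)
})

test_that("published primer table screens exhaustively", {
  t2 <- table2_primers()
  fwd <- t2$label[t2$orientation == "forward"]
  rev_ <- t2$label[t2$orientation == "reverse"]
  grid <- expand.grid(f = fwd, r = rev_, stringsAsFactors = FALSE)
  report <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sc <- complementarity_screen(
      t2$sequence[t2$label == grid$f[i]],
      t2$sequence[t2$label == grid$r[i]])
    data.frame(fwd = grid$f[i], rev = grid$r[i], pass = sc$pass,
               max_run = sc$max_run, stringsAsFactors = FALSE)
  }))
  expect_equal(nrow(report), length(fwd) * length(rev_))
  expect_true(all(report$max_run >= 0))
})

test_that("primer-table dialect round-trips and validates spans", {
  t2 <- table2_primers()
  expect_equal(nrow(t2), 18L)
  f1 <- t2[t2$label == "F1 c/t", ]
  expect_equal(nchar(f1$sequence), 18L)
  expect_equal(c(f1$ref_start, f1$ref_end), c(13L, 30L))
  r1 <- t2[t2$label == "R1 g/a/t", ]
  expect_equal(r1$orientation, "reverse")
  expect_gt(r1$ref_start, r1$ref_end)   # printed descending
  expect_equal(nchar(r1$sequence), 16L)
  # the three rows with a published span/length inconsistency are flagged
  expect_setequal(t2$label[!t2$span_ok], c("F4 ac", "F5 ct", "F6 a/t"))

  # strict load errors naming an offending row
  bad <- data.frame(label = "X", orientation = "forward",
                    sequence = "ACGTACGTACGT", ref_start = 1, ref_end = 10)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_primer_table(f), "X")
  unlink(f)

  # round trip on the consistent rows
  good <- t2[t2$span_ok, ]
  f <- tempfile(fileext = ".tsv")
  write_primer_table(good, f)
  back <- read_primer_table(f)
  expect_equal(back$sequence, good$sequence)
  expect_equal(back$ref_start, good$ref_start)
  expect_equal(back$ref_end, good$ref_end)
  unlink(f)
})
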