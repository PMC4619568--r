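test_that("kabat codes order lexicographically by number then insertion letter", {
  codes <- c("100B", "95", "100", "82C", "82", "9")
  expect_identical(kabat_sort(codes), c("9", "82", "82C", "95", "100", "100B"))
  expect_identical(kabat_number("82C"), 82L)
  expect_identical(kabat_insertion(c("82C", "82")), c("C", ""))
})

test_that("a sequence identical to the reference numbers without insertions and reconstructs", {
  for (chain in c("heavy", "lambda")) {
    ref <- ref_of(chain)
    nc <- number_chain(ref$seq, chain)
    expect_identical(nc$codes, ref$codes)
    expect_identical(paste(nc$residues, collapse = ""), ref$seq)
    expect_length(validate_numbering(nc), 0)
  }
})

test_that("loop insertions receive letter suffixes at the Kabat anchors", {
  # three extra residues in CDR H3 -> 100A, 100B, 100C; other codes unchanged
  seq <- insert_after_code(heavy_ref, "100", "GGG")
  nc <- number_chain(seq, "heavy")
  expect_true(all(c("100A", "100B", "100C") %in% nc$codes))
  expect_identical(setdiff(nc$codes, c("100A", "100B", "100C")), heavy_ref$codes)
  expect_identical(paste(nc$residues, collapse = ""), seq)
  # extended lambda L3 -> 95A, 95B (the positions the conserved-site analysis names)
  seql <- insert_after_code(lambda_ref, "95", "AS")
  ncl <- number_chain(seql, "lambda")
  expect_true(all(c("95A", "95B") %in% ncl$codes))
  expect_length(validate_numbering(ncl), 0)
})

test_that("deletions leave Kabat numbers absent, walking back from the anchor", {
  seq <- delete_codes(heavy_ref, c("99", "100"))
  nc <- number_chain(seq, "heavy")
  expect_false(any(c("99", "100") %in% nc$codes))
  expect_true(all(c("98", "101", "102") %in% nc$codes))
  expect_identical(paste(nc$residues, collapse = ""), seq)
})

test_that("numbering agrees with the flank-anchored enumeration oracle over loop edits", {
  cases <- list(
    list(chain = "heavy",  s = 31, e = 35, a = 35),
    list(chain = "heavy",  s = 50, e = 65, a = 52),
    list(chain = "heavy",  s = 95, e = 102, a = 100),
    list(chain = "lambda", s = 24, e = 34, a = 27),
    list(chain = "lambda", s = 89, e = 97, a = 95))
  set.seed(99)
  for (cs in cases) {
    ref <- ref_of(cs$chain)
    for (delta in -2:6) {   # up to reference length + 6
      if (delta == 0) next
      seq <- if (delta > 0) {
        ins <- paste(sample(c("G", "S", "A", "D", "Y"), delta, TRUE), collapse = "")
        insert_after_code(ref, as.character(cs$a), ins)
      } else {
        del <- as.character(seq(cs$a, by = -1, length.out = -delta))
        delete_codes(ref, del)
      }
      nc <- number_chain(seq, cs$chain)
      expected <- oracle_number_loop(seq, cs$chain, cs$s, cs$e, cs$a)
      expect_identical(nc$codes, expected,
                       label = sprintf("%s loop %d-%d delta %d", cs$chain, cs$s, cs$e, delta))
      expect_identical(paste(nc$residues, collapse = ""), seq)
    }
  }
})

test_that("numbering is deterministic and robust to point substitutions", {
  set.seed(7)
  for (rep in 1:10) {
    seq <- heavy_ref$seq
    for (k in 1:4) {
      i <- sample(nchar(seq), 1)
      substr(seq, i, i) <- sample(AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 1)
    }
    nc1 <- number_chain(seq, "heavy")
    nc2 <- number_chain(seq, "heavy")
    expect_identical(nc1$codes, nc2$codes)
    expect_identical(paste(nc1$residues, collapse = ""), seq)
    expect_length(validate_numbering(nc1), 0)
  }
})

test_that("framework-anchor insertions extend the 82-letter run", {
  seq <- insert_after_code(heavy_ref, "82C", "Q")
  nc <- number_chain(seq, "heavy")
  expect_true("82D" %in% nc$codes)
  expect_length(validate_numbering(nc), 0)
})

test_that("non-antibody input and out-of-range lengths are rejected", {
  expect_error(number_chain(strrep("AW", 55), "heavy"), "not an antibody")
  expect_error(number_chain(strrep("A", 40), "heavy"), "80-150")
  expect_error(number_chain(paste0(heavy_ref$seq, strrep("A", 60)), "heavy"), "80-150")
  expect_error(number_chain("EVQL*Z", "heavy"), "alphabet")
})

test_that("validate_numbering reports duplicated codes and non-anchor insertions", {
  nc <- number_chain(heavy_ref$seq, "heavy")
  bad <- nc
  bad$codes[10] <- bad$codes[9]        # duplicate code
  d <- validate_numbering(bad)
  expect_true(any(grepl(bad$codes[9], d)))
  bad2 <- nc
  bad2$codes[40] <- "40A"              # insertion letter away from any anchor
  d2 <- validate_numbering(bad2)
  expect_true(any(grepl("non-anchor", d2)))
  bad3 <- nc
  bad3$residues[1] <- "W"              # reconstruction broken
  expect_true(any(grepl("reconstruct", validate_numbering(bad3))))
})
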