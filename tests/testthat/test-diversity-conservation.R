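test_that("the default biophysical scheme is a seven-group partition of the 20 amino acids", {
  expect_length(builtin_scheme, 7)
  all_res <- unlist(builtin_scheme)
  expect_setequal(all_res, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(anyDuplicated(all_res), 0)
  # within-group identity and cross-group separation
  expect_identical(biophysical_group("D", builtin_scheme),
                   biophysical_group("E", builtin_scheme))
  expect_false(identical(biophysical_group("F", builtin_scheme),
                         biophysical_group("D", builtin_scheme)))
  expect_true(is.na(biophysical_group("X", builtin_scheme)))
})

test_that("variability is 100*(1 - modal/coverage) with the five-bin classification", {
  # 10 chains, modal residue count 4 at position 31 -> variability 60, bin 4
  seqs <- vapply(c("A","A","A","A","C","D","E","F","G","H"), function(r) {
    substitute_code(heavy_ref$seq, heavy_ref, "31", r)
  }, character(1))
  cs <- make_clone_set(heavy = unname(seqs))
  vp <- variability_profile(cs, "heavy")
  row <- vp[vp$code == "31", ]
  expect_equal(row$coverage, 10)
  expect_identical(row$modal, "A")
  expect_equal(row$variability, 60)
  expect_equal(row$bin, 4)
  # every untouched position is invariant -> variability 0, bin 1
  expect_true(all(vp$variability[vp$code != "31"] == 0))
  expect_true(all(vp$bin[vp$code != "31"] == 1))
  expect_true(all(vp$variability >= 0 & vp$variability <= 100))
})

test_that("bin edges are [0,10) [10,25) [25,50) [50,75) [75,100] and the floor flags sparse positions", {
  # 4 identical chains: coverage 4 < floor 5 -> flagged, not binned
  cs4 <- make_clone_set(heavy = rep(heavy_ref$seq, 4))
  vp4 <- variability_profile(cs4, "heavy")
  expect_true(all(vp4$insufficient))
  expect_true(all(is.na(vp4$bin)))
  # edge values: variability 75 must fall in bin 5, 10 in bin 2
  seqs <- vapply(c("A", "C", "D", rep("G", 1)), function(r) {
    substitute_code(heavy_ref$seq, heavy_ref, "31", r)
  }, character(1))
  cs <- make_clone_set(heavy = c(unname(seqs), heavy_ref$seq,
                                 rep(substitute_code(heavy_ref$seq, heavy_ref, "31", "A"), 3)))
  vp <- variability_profile(cs, "heavy")
  v31 <- vp[vp$code == "31", ]
  expect_equal(v31$variability, 50)
  expect_equal(v31$bin, 4)
})

test_that("consensus takes the modal residue with alphabetical tie-break", {
  one <- make_clone_set(heavy = heavy_ref$seq)
  expect_identical(unname(consensus(one, "heavy")[heavy_ref$codes]),
                   heavy_ref$residues)
  # 3 chains A,A,S at position 31 -> A; 2 chains A,S -> A by tie-break
  tri <- make_clone_set(heavy = c(
    substitute_code(heavy_ref$seq, heavy_ref, "31", "A"),
    substitute_code(heavy_ref$seq, heavy_ref, "31", "A"),
    substitute_code(heavy_ref$seq, heavy_ref, "31", "S")))
  expect_identical(unname(consensus(tri, "heavy")["31"]), "A")
  duo <- make_clone_set(heavy = c(
    substitute_code(heavy_ref$seq, heavy_ref, "31", "S"),
    substitute_code(heavy_ref$seq, heavy_ref, "31", "A")))
  expect_identical(unname(consensus(duo, "heavy")["31"]), "A")
})

test_that("conserved positions require presence in all chains and identity or group similarity", {
  cons <- consensus(make_clone_set(heavy = heavy_ref$seq), "heavy")
  # D62 -> E is a same-group (acidic) substitution: still conserved
  cs <- make_clone_set(heavy = c(heavy_ref$seq,
                                 substitute_code(heavy_ref$seq, heavy_ref, "62", "E")))
  cp <- conserved_positions(cs, cons, builtin_scheme, "heavy")
  expect_true("62" %in% cp)
  # one chain with K at that position breaks conservation (strict-all rule)
  cs2 <- make_clone_set(heavy = c(heavy_ref$seq, heavy_ref$seq,
                                  substitute_code(heavy_ref$seq, heavy_ref, "62", "K")))
  expect_false("62" %in% conserved_positions(cs2, cons, builtin_scheme, "heavy"))
  # positions absent from some chains are never conserved
  cs3 <- make_clone_set(heavy = c(heavy_ref$seq, delete_codes(heavy_ref, c("99", "100"))))
  cp3 <- conserved_positions(cs3, cons, builtin_scheme, "heavy")
  expect_false(any(c("99", "100") %in% cp3))
  expect_true("98" %in% cp3)
})

test_that("adding a clone never enlarges the conserved set (monotonicity)", {
  cons <- consensus(fixture_pre$clones, "heavy")
  heavy <- fixture_pre$clones[nzchar(fixture_pre$clones$heavy_seq), ]
  for (n in c(3, 6, 10)) {
    sub_small <- clone_set(as.data.frame(head(heavy, n)))
    sub_large <- clone_set(as.data.frame(head(heavy, n + 3)))
    cp_small <- conserved_positions(sub_small, cons, builtin_scheme, "heavy")
    cp_large <- conserved_positions(sub_large, cons, builtin_scheme, "heavy")
    expect_true(all(cp_large %in% cp_small))
  }
})

test_that("zero-variability positions matching the consensus are conserved", {
  numbered <- number_clone_set(fixture_post$clones, "heavy")
  vp <- variability_profile(fixture_post$clones, "heavy", numbered = numbered,
                            coverage_floor = 1)
  cons <- consensus(fixture_pre$clones, "heavy")
  cp <- conserved_positions(fixture_post$clones, cons, builtin_scheme, "heavy",
                            numbered = numbered)
  full_cov <- vp$code[vp$coverage == length(numbered)]
  agree <- vp$code[vp$variability == 0 & vp$code %in% full_cov &
                     vp$modal == cons[vp$code]]
  expect_true(all(agree %in% cp))
})

test_that("conservation_report is self-consistent and identical sets give identical pre/post", {
  rep <- conservation_report(fixture_pre$clones, fixture_pre$clones)
  expect_equal(rep$grand_total$pre, rep$grand_total$post)
  for (phase in c("pre", "post")) {
    for (chain in c("heavy", "lambda")) {
      s <- rep[[phase]][[chain]]
      fw <- sum(vapply(c("FW1","FW2","FW3","FW4"), function(r) length(s[[r]]), integer(1)))
      cdr <- sum(vapply(c("CDR1","CDR2","CDR3"), function(r) length(s[[r]]), integer(1)))
      expect_equal(s$total_fw, fw)
      expect_equal(s$total_cdr, cdr)
      expect_equal(s$total, fw + cdr)
    }
  }
  expect_equal(rep$grand_total$pre,
               rep$pre$heavy$total + rep$pre$lambda$total)
  df <- as.data.frame(rep)
  expect_true(all(df$n_conserved >= 0))
  expect_error(conservation_report(fixture_pre$clones[0, ], fixture_post$clones),
               "empty")
})

test_that("a post panel of identical clones conserves every covered consensus-matching position", {
  clone <- fixture_post$clones[1, , drop = FALSE]
  trio <- clone_set(data.frame(clone_id = c("a", "b", "c"),
                               phase = "post", target = "SQA",
                               heavy_seq = clone$heavy_seq,
                               light_seq = clone$light_seq,
                               stringsAsFactors = FALSE))
  nc <- number_chain(clone$heavy_seq, "heavy")
  self_cons <- setNames(nc$residues, nc$codes)
  cp <- conserved_positions(trio, self_cons, builtin_scheme, "heavy")
  expect_setequal(cp, nc$codes)   # grand total = number of covered positions
})
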