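test_that("synthetic_config validates weights, seeds and planted positions", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(1, heavy_mixture = c("1-1" = -1)), "weights")
  expect_error(synthetic_config(1, heavy_mixture = c("1-X" = 1)), "template")
  expect_error(synthetic_config(1, lambda_mixture = c("6-1" = 1)), "L1-L2-L3")
  expect_error(synthetic_config(1, l3_x_lengths = c("9" = 1)), "template lengths")
  expect_error(synthetic_config(1, planted_conserved = list(mode = "identical",
                                                            heavy = "999",
                                                            lambda = character(0))),
               "absent")
  cfg <- synthetic_config(1)
  expect_equal(sum(cfg$heavy_mixture), 1)
  expect_equal(sum(cfg$lambda_mixture), 1)
  expect_equal(sum(cfg$h3_lengths), 1)
})

test_that("zero mutation rates and a single combination reproduce the scaffold exactly", {
  cfg <- synthetic_config(5, n_pre_heavy = 4, n_pre_lambda = 0,
                          heavy_mixture = c("1-1" = 1), h3_lengths = c("8" = 1),
                          fw_rate = 0, cdr_rate = 0)
  pre <- generate_pre_library(cfg)
  expect_true(all(pre$clones$heavy_seq == heavy_ref$seq))
})

test_that("generation is seed-deterministic down to emitted FASTA bytes", {
  cfg <- synthetic_config(17, n_pre_heavy = 6, n_pre_lambda = 5)
  a <- generate_pre_library(cfg)
  b <- generate_pre_library(cfg)
  expect_identical(a$clones$heavy_seq, b$clones$heavy_seq)
  expect_identical(a$clones$light_seq, b$clones$light_seq)
  dir <- withr::local_tempdir()
  fa1 <- file.path(dir, "a.fasta"); fa2 <- file.path(dir, "b.fasta")
  write_repertoire(a$clones, fa1, file.path(dir, "a.tsv"))
  write_repertoire(b$clones, fa2, file.path(dir, "b.tsv"))
  expect_identical(readLines(fa1), readLines(fa2))
  # a different seed changes the draw
  c2 <- generate_pre_library(synthetic_config(18, n_pre_heavy = 6, n_pre_lambda = 5))
  expect_false(identical(a$clones$heavy_seq, c2$clones$heavy_seq))
})

test_that("the classifier recovers generated canonical labels and CDR lengths exactly per clone", {
  truth <- fixture_pre$truth$clones
  for (chain in c("heavy", "lambda")) {
    numbered <- number_clone_set(fixture_pre$clones, chain)
    expect_length(attr(numbered, "failures"), 0)
    for (id in names(numbered)) {
      nc <- numbered[[id]]
      ra <- annotate_regions(nc)
      ca <- assign_canonical(nc, ra, builtin_templates)
      expect_identical(paste(ca$labels, collapse = "-"), truth[[id]]$combo,
                       label = paste("combo of", id))
      expect_equal(ra$cdr_lengths, truth[[id]]$cdr_lengths,
                   label = paste("CDR lengths of", id))
    }
  }
})

test_that("selection replicates founders, assigns targets, and respects founder limits", {
  post <- fixture_post
  expect_true(all(post$clones$phase == "post"))
  expect_true(all(post$clones$target == "SQA"))
  expect_equal(nrow(post$clones), 4 * 2)   # 4 founders x 2 copies
  expect_length(post$truth$founders, 4)
  # copies are byte-identical to their founder emission
  base <- sub("\\.2$", "", post$clones$clone_id)
  for (b in unique(base)) {
    rows <- post$clones[base == b, ]
    expect_true(all(rows$heavy_seq == rows$heavy_seq[1]))
  }
  cfg_big <- synthetic_config(3, n_pre_heavy = 3, n_pre_lambda = 3,
                              post_panels = list(list(target = "SQA", n_clones = 5)))
  small <- generate_pre_library(cfg_big)
  expect_error(simulate_selection(small$clones, cfg_big, small$truth), "founders")
  cfg0 <- synthetic_config(3, n_pre_heavy = 3, n_pre_lambda = 3,
                           post_panels = list())
  expect_warning(out0 <- simulate_selection(small$clones, cfg0, small$truth),
                 "size 0")
  expect_null(out0$clones)
})

test_that("planted conserved positions in identical mode are recovered by the conservation analysis", {
  for (chain in c("heavy", "lambda")) {
    planted <- fixture_cfg$planted_conserved[[chain]]
    cons <- consensus(fixture_pre$clones, chain)
    cp <- conserved_positions(fixture_post$clones, cons, builtin_scheme, chain)
    expect_true(all(planted %in% cp),
                label = paste(chain, "planted positions all conserved"))
  }
})

test_that("group-conserving planting exercises the biophysical-similarity branch", {
  cfg <- synthetic_config(
    77, library_id = "grp", n_pre_heavy = 12, n_pre_lambda = 10,
    fw_rate = 0, cdr_rate = 0.1,
    post_panels = list(list(target = "COP", n_clones = 5)), post_copies = 1,
    planted_conserved = list(mode = "group", heavy = "62", lambda = character(0)))
  pre <- generate_pre_library(cfg)
  post <- simulate_selection(pre$clones, cfg, truth = pre$truth)
  cons <- consensus(pre$clones, "heavy")
  cp <- conserved_positions(post$clones, cons, builtin_scheme, "heavy")
  expect_true("62" %in% cp)   # conserved under the seven-group rule
  numbered <- number_clone_set(post$clones, "heavy")
  res62 <- vapply(numbered, function(nc) nc$residues[match("62", nc$codes)],
                  character(1))
  # acidic group membership, not necessarily identity
  expect_true(all(res62 %in% c("D", "E")))
})
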