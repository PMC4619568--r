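test_that("split_scfv locates the linker exactly and concatenation round-trips", {
  scfv <- paste0(heavy_ref$seq, scfv_linker(), lambda_ref$seq)
  p <- split_scfv(scfv)
  expect_identical(p$heavy_seq, heavy_ref$seq)
  expect_identical(p$light_seq, lambda_ref$seq)
  expect_identical(p$linker_seq, scfv_linker())
  expect_equal(p$linker_length, 15)
  expect_true(p$exact)
  expect_identical(paste0(p$heavy_seq, p$linker_seq, p$light_seq), scfv)
})

test_that("split_scfv tolerates a single linker mutation (fuzzy match) but rejects unrelated sequences", {
  lk <- scfv_linker()
  substr(lk, 7, 7) <- "W"   # 14/15 identity = 93% > 80%
  p <- split_scfv(paste0(heavy_ref$seq, lk, lambda_ref$seq))
  expect_false(p$exact)
  expect_identical(p$heavy_seq, heavy_ref$seq)
  expect_identical(p$light_seq, lambda_ref$seq)
  # no 15-mer window at >= 80% identity anywhere
  expect_error(split_scfv(paste(rep("AW", 150), collapse = "")), "linker not found")
  # two exact linker copies are ambiguous
  dbl <- paste0(heavy_ref$seq, scfv_linker(), lambda_ref$seq,
                scfv_linker(), lambda_ref$seq)
  expect_error(split_scfv(dbl), "ambiguous")
})

test_that("clone_set enforces its invariants", {
  df <- data.frame(clone_id = c("a", "b"), heavy_seq = heavy_ref$seq,
                   stringsAsFactors = FALSE)
  cs <- clone_set(df)
  expect_s3_class(cs, "clone_set")
  expect_identical(cs$phase, c("pre", "pre"))
  expect_error(clone_set(data.frame(clone_id = c("a", "a"), heavy_seq = "ACD")),
               "duplicate")
  expect_error(clone_set(data.frame(clone_id = "a", heavy_seq = "ACGU1")),
               "alphabet")
  expect_error(clone_set(data.frame(clone_id = "a", heavy_seq = "ACD",
                                    phase = "post", target = "")),
               "target")
})

test_that("read_repertoire splits scFv records, rejects bad alphabets, and round-trips", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "r.fasta")
  tsv <- file.path(dir, "r.tsv")
  cs0 <- rbind(
    data.frame(clone_id = "scfv1", library_id = "L1", phase = "post",
               target = "SQA", heavy_seq = heavy_ref$seq,
               light_seq = lambda_ref$seq, light_isotype = "lambda"),
    data.frame(clone_id = "h1", library_id = "L1", phase = "pre", target = "",
               heavy_seq = heavy_ref$seq, light_seq = "",
               light_isotype = "lambda"))
  cs0 <- clone_set(cs0)
  write_repertoire(cs0, fa, tsv)
  cs1 <- read_repertoire(fa, tsv)
  plain <- function(cs) {
    df <- as.data.frame(cs)[order(cs$clone_id), ]
    attr(df, "provenance") <- NULL
    rownames(df) <- NULL
    df
  }
  expect_identical(plain(cs1), plain(cs0))
  # a second write/read reproduces every field byte-for-byte
  fa2 <- file.path(dir, "r2.fasta"); tsv2 <- file.path(dir, "r2.tsv")
  write_repertoire(cs1, fa2, tsv2)
  cs2 <- read_repertoire(fa2, tsv2)
  expect_identical(plain(cs2), plain(cs1))
})

test_that("read_repertoire rejects nucleotide-alphabet records but keeps the rest", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "mixed.fasta")
  writeLines(c(">good", heavy_ref$seq, ">nuc", strrep("ACGTU", 20)), fa)
  expect_warning(cs <- read_repertoire(fa), "alphabet")
  expect_identical(cs$clone_id, "good")
  # duplicate record ids are an error
  writeLines(c(">a", heavy_ref$seq, ">a", heavy_ref$seq), fa)
  expect_error(read_repertoire(fa), "duplicate")
})

test_that("write_report renders TSV with one-decimal percents and JSON round-trips values", {
  dir <- withr::local_tempdir()
  tab <- length_frequency_table(fixture_pre$clones, "H3")
  tsv <- file.path(dir, "t.tsv")
  write_report(tab, tsv)
  back <- read.delim(tsv, colClasses = "character")
  expect_identical(names(back), c("category", "count", "percent"))
  expect_true(all(grepl("^[0-9]+\\.[0-9]$", back$percent)))
  expect_equal(as.numeric(back$percent), round(tab$percent, 1))
  js <- file.path(dir, "t.json")
  write_report(tab, js, "json")
  back2 <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back2$count, tab$count)
  expect_equal(back2$percent, tab$percent, tolerance = 1e-12)
  expect_warning(write_report(data.frame(), file.path(dir, "e.tsv")), "empty")
})
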