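# Shared fixtures and independent oracles, built in code at test time.

heavy_ref <- kabat_reference("heavy")
lambda_ref <- kabat_reference("lambda")
builtin_templates <- load_templates()
builtin_scheme <- load_biophysical_scheme()

ref_of <- function(chain) if (chain == "heavy") heavy_ref else lambda_ref

# insert residues immediately after a reference Kabat code
insert_after_code <- function(ref, code, insert) {
  i <- match(code, ref$codes)
  stopifnot(!is.na(i))
  paste0(substr(ref$seq, 1, i), insert, substr(ref$seq, i + 1, nchar(ref$seq)))
}

# delete the residues at the given reference Kabat codes
delete_codes <- function(ref, codes) {
  keep <- !(ref$codes %in% codes)
  paste(ref$residues[keep], collapse = "")
}

# substitute the residue at a reference Kabat code
substitute_code <- function(seq, ref, code, res) {
  i <- match(code, ref$codes)
  stopifnot(!is.na(i))
  substr(seq, i, i) <- res
  seq
}

# Independent Kabat-numbering oracle for sequences that differ from the
# reference only inside one variable-loop window: the loop is located by
# exact framework flank matching (no alignment), and its codes are
# enumerated directly from the Kabat insertion/deletion rules (letters after
# the anchor; deletions walking back from the anchor).
oracle_number_loop <- function(seq, chain, s, e, a) {
  ref <- ref_of(chain)
  base <- kabat_number(ref$codes)
  pre_idx <- which(base < s)
  post_idx <- which(base > e)
  prefix <- paste(ref$residues[pre_idx], collapse = "")
  suffix <- paste(ref$residues[post_idx], collapse = "")
  stopifnot(startsWith(seq, prefix), endsWith(seq, suffix))
  k <- nchar(seq) - nchar(prefix) - nchar(suffix)
  m <- e - s + 1
  loop_codes <- if (k >= m) {
    c(as.character(s:a), if (k > m) paste0(a, LETTERS[seq_len(k - m)]),
      if (a < e) as.character((a + 1):e))
  } else {
    del <- c(a:s, if (a < e) (a + 1):e)[seq_len(m - k)]
    as.character(sort(setdiff(s:e, del)))
  }
  c(ref$codes[pre_idx], loop_codes, ref$codes[post_idx])
}

# Independent canonical-classification oracle: plain scan over all templates.
oracle_assign <- function(nc, templates) {
  loops <- if (nc$chain_type == "heavy") c("H1", "H2") else c("L1", "L2", "L3")
  res <- setNames(nc$residues, nc$codes)
  out <- character(0)
  for (lp in loops) {
    tl <- Filter(function(t) t$chain == nc$chain_type && t$loop == lp, templates)
    w <- tl[[1]]$window
    len <- sum(kabat_number(nc$codes) >= kabat_number(w[1]) &
                 kabat_number(nc$codes) <= kabat_number(w[2]))
    same_len <- Filter(function(t) t$length == len, tl)
    if (length(same_len) == 0) {
      out[lp] <- "X"
      next
    }
    hit <- character(0)
    for (t in same_len) {
      ok <- all(vapply(t$keys, function(kk) {
        r <- res[kk$code]
        !is.na(r) && r %in% kk$allowed
      }, logical(1)))
      if (ok) hit <- c(hit, t$class)
    }
    out[lp] <- if (length(hit) == 1) hit else if (length(hit) == 0) "unmatched" else "AMBIG"
  }
  out
}

# small shared synthetic library with planted conserved positions
fixture_planted_heavy <- c("5", "12", "38", "45", "70", "80", "86", "105")
fixture_planted_lambda <- c("7", "15", "40", "61", "73", "86", "100")
fixture_cfg <- synthetic_config(
  seed = 421, library_id = "fix", n_pre_heavy = 25, n_pre_lambda = 20,
  post_panels = list(list(target = "SQA", n_clones = 4)),
  post_copies = 2,
  planted_conserved = list(mode = "identical",
                           heavy = fixture_planted_heavy,
                           lambda = fixture_planted_lambda))
fixture_pre <- generate_pre_library(fixture_cfg)
fixture_post <- simulate_selection(fixture_pre$clones, fixture_cfg,
                                   truth = fixture_pre$truth)

# tiny hand-made clone set helper
make_clone_set <- function(heavy = character(0), lambda = character(0),
                           phase = "pre", target = "") {
  n <- max(length(heavy), length(lambda))
  rows <- data.frame(
    clone_id = sprintf("c%02d", seq_len(n)),
    phase = phase, target = target,
    heavy_seq = if (length(heavy)) heavy else "",
    light_seq = if (length(lambda)) lambda else "",
    stringsAsFactors = FALSE)
  clone_set(rows)
}
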