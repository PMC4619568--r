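kabat_anchors <- function(chain_type) {
  switch(chain_type, heavy = c(35L, 52L, 82L, 100L), lambda = c(27L, 95L, 106L))
}

# variable-length loop windows (Kabat code space) with their insertion anchor;
# fr_anchor marks the framework position whose insertion letters simply extend
kabat_windows <- function(chain_type) {
  if (chain_type == "heavy") {
    list(windows = list(c(s = 31L, e = 35L, a = 35L),
                        c(s = 50L, e = 65L, a = 52L),
                        c(s = 95L, e = 102L, a = 100L)),
         fr_anchor = 82L)
  } else {
    list(windows = list(c(s = 24L, e = 34L, a = 27L),
                        c(s = 89L, e = 97L, a = 95L)),
         fr_anchor = 106L)
  }
}

#' Load a Kabat reference profile
#'
#' Reference profiles are plain-text, two-column files (Kabat code, residue)
#' with `#` comments; the built-in profiles are synthetic consensus-like sheep
#' VH and V-lambda sequences and can be replaced by the user.
#'
#' @param chain_type `"heavy"` or `"lambda"`.
#' @param path path to a profile file, or `NULL` for the built-in profile.
#' @return a list with `chain_type`, `codes`, `residues` and `seq`.
#' @export
kabat_reference <- function(chain_type = c("heavy", "lambda"), path = NULL) {
  chain_type <- match.arg(chain_type)
  key <- paste0("ref_", chain_type, "_", path %||% "builtin")
  if (!is.null(.panrep_cache[[key]])) return(.panrep_cache[[key]])
  if (is.null(path)) {
    path <- panrep_extdata(paste0("kabat_reference_", chain_type, ".txt"))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  codes <- vapply(parts, `[`, character(1), 1)
  residues <- toupper(vapply(parts, `[`, character(1), 2))
  if (!all(kabat_valid(codes))) stop("malformed Kabat codes in ", path)
  if (!all(residues %in% AA_STANDARD)) stop("non-standard residues in ", path)
  if (is.unsorted(kabat_key(codes), strictly = TRUE)) {
    stop("reference codes must be strictly increasing in ", path)
  }
  ref <- list(chain_type = chain_type, codes = codes, residues = residues,
              seq = paste(residues, collapse = ""))
  .panrep_cache[[key]] <- ref
  ref
}

align_to_reference <- function(seq, ref, gap_opening, gap_extension) {
  if (is.null(.panrep_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .panrep_cache$blosum62 <- e$BLOSUM62
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(seq),
    subject = Biostrings::AAString(ref$seq),
    substitutionMatrix = .panrep_cache$blosum62,
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global")
  p <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  qmap <- integer(0)
  qi <- 0L
  si <- 0L
  for (k in seq_along(p)) {
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-") {
      qi <- qi + 1L
      qmap[qi] <- if (s[k] != "-") si else NA_integer_
    }
  }
  list(qmap = qmap, score = Biostrings::score(pa))
}

# codes for a window of k residues: base codes s..e, insertion letters after
# anchor a; deletions removed walking back from the anchor (then forward)
window_codes <- function(s, e, a, k, max_letters = 26L) {
  m <- e - s + 1L
  if (k == 0L) return(character(0))
  if (k >= m) {
    n_ins <- k - m
    if (n_ins > max_letters) {
      stop("loop too long: ", n_ins, " insertions needed at anchor ", a)
    }
    c(as.character(s:a),
      if (n_ins > 0) paste0(a, LETTERS[seq_len(n_ins)]),
      if (a < e) as.character((a + 1L):e))
  } else {
    d <- m - k
    del_order <- c(a:s, if (a < e) (a + 1L):e)
    keep <- setdiff(s:e, del_order[seq_len(d)])
    as.character(sort(keep))
  }
}

#' Assign Kabat codes to a variable-domain sequence
#'
#' Globally aligns the sequence against an embedded, position-annotated
#' reference profile for the chain type (affine gaps, BLOSUM62).
#' Reference-matched residues inherit the reference's Kabat number; insertions
#' relative to the reference receive letter suffixes at the scheme's permitted
#' anchors (heavy: 35, 52, 82, 100; lambda: 27, 95, 106), placed leftmost
#' within the variable-loop window so numbering is deterministic; deletions
#' leave Kabat numbers absent.
#'
#' @param seq amino-acid sequence (80--150 residues, standard alphabet plus X).
#' @param chain_type `"heavy"` or `"lambda"`.
#' @param reference optional profile from [kabat_reference()].
#' @param gap_opening,gap_extension affine gap penalties.
#' @param score_floor minimum alignment score below which the input is
#'   rejected as not an antibody variable domain.
#' @return an object of class `numbered_chain`: list with `chain_type`,
#'   `codes`, `residues`, `seq` and `alignment_score`. Joining `residues`
#'   reconstructs `seq` exactly.
#' @examples
#' ref <- kabat_reference("heavy")
#' nc <- number_chain(ref$seq, "heavy")
#' tail(nc$codes)
#' @export
number_chain <- function(seq, chain_type = c("heavy", "lambda"), reference = NULL,
                         gap_opening = 10, gap_extension = 1, score_floor = 50) {
  chain_type <- match.arg(chain_type)
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (!valid_aa_seq(seq)) stop("non-amino-acid alphabet in input sequence")
  n <- nchar(seq)
  if (n < 80 || n > 150) {
    stop("sequence length ", n, " outside the variable-domain range 80-150")
  }
  ref <- reference %||% kabat_reference(chain_type)
  al <- align_to_reference(seq, ref, gap_opening, gap_extension)
  if (al$score < score_floor) {
    stop("not an antibody variable domain: alignment score ",
         round(al$score, 1), " below floor ", score_floor)
  }
  qmap <- al$qmap
  residues <- strsplit(seq, "")[[1]]
  codes <- rep(NA_character_, n)
  matched <- !is.na(qmap)
  codes[matched] <- ref$codes[qmap[matched]]
  base <- ifelse(matched, kabat_number(codes), NA_integer_)

  win <- kabat_windows(chain_type)
  in_window <- function(b, w) !is.na(b) && b >= w["s"] && b <= w["e"]
  window_of <- function(b) {
    for (wi in seq_along(win$windows)) {
      if (in_window(b, win$windows[[wi]])) return(wi)
    }
    NA_integer_
  }

  # attribute each residue to a window (0 = framework)
  assignment <- integer(n)
  for (i in seq_len(n)) {
    if (matched[i]) {
      w <- window_of(base[i])
      assignment[i] <- if (is.na(w)) 0L else w
    }
  }
  # insertion runs: attach to the preceding matched residue's window, else the
  # following one's (leftmost placement), else a framework anchor
  runs <- rle(!matched)
  idx <- 1L
  fr_runs <- list()
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    if (runs$values[r]) {
      run_idx <- idx:(idx + len - 1L)
      prev_i <- idx - 1L
      next_i <- idx + len
      prev_b <- if (prev_i >= 1L) base[prev_i] else NA_integer_
      next_b <- if (next_i <= n) base[next_i] else NA_integer_
      w <- window_of(prev_b)
      if (is.na(w)) w <- window_of(next_b)
      if (!is.na(w)) {
        assignment[run_idx] <- w
      } else if (!is.na(prev_b) && prev_b == win$fr_anchor) {
        fr_runs[[length(fr_runs) + 1]] <- list(idx = run_idx, prev = prev_i)
      } else {
        at <- if (!is.na(prev_b)) codes[prev_i] else "the sequence start"
        stop("insertion after Kabat position ", at,
             " falls outside any insertion anchor window")
      }
    }
    idx <- idx + len
  }

  # renumber every variable-loop window deterministically from its length
  for (wi in seq_along(win$windows)) {
    w <- win$windows[[wi]]
    members <- which(assignment == wi)
    if (length(members) == 0) next
    if (any(diff(members) != 1L)) {
      stop("residues of the Kabat ", w["s"], "-", w["e"],
           " window are not contiguous after alignment")
    }
    codes[members] <- window_codes(w["s"], w["e"], w["a"], length(members))
  }

  # framework-anchor insertions (heavy 82, lambda 106): extend the letter run
  for (fr in fr_runs) {
    prev_code <- codes[fr$prev]
    last_ins <- kabat_insertion(prev_code)
    start_rank <- if (last_ins == "") 0L else match(last_ins, LETTERS)
    if (start_rank + length(fr$idx) > 26L) stop("too many insertions at anchor ", win$fr_anchor)
    codes[fr$idx] <- paste0(win$fr_anchor, LETTERS[start_rank + seq_along(fr$idx)])
  }

  if (anyNA(codes)) stop("internal error: unassigned Kabat codes")
  if (is.unsorted(kabat_key(codes), strictly = TRUE)) {
    stop("numbering failed: Kabat codes are not strictly increasing")
  }
  structure(list(chain_type = chain_type, codes = codes, residues = residues,
                 seq = seq, alignment_score = al$score),
            class = "numbered_chain")
}

#' @export
print.numbered_chain <- function(x, ...) {
  cat(sprintf("numbered_chain (%s): %d residues, Kabat %s-%s, alignment score %.1f\n",
              x$chain_type, length(x$codes), x$codes[1],
              x$codes[length(x$codes)], x$alignment_score))
  invisible(x)
}

#' Diagnostic checks on a numbered chain
#'
#' Verifies strict Kabat-code ordering, absence of duplicates, insertion
#' letters only at the scheme's anchors, and exact reconstruction of the input
#' sequence from the residues.
#'
#' @param nc a [number_chain()] result.
#' @return a character vector of diagnostics; empty iff the numbering is valid.
#' @export
validate_numbering <- function(nc) {
  stopifnot(inherits(nc, "numbered_chain"))
  out <- character(0)
  dup <- unique(nc$codes[duplicated(nc$codes)])
  if (length(dup)) out <- c(out, paste("duplicated code(s):", paste(dup, collapse = ", ")))
  if (is.unsorted(kabat_key(nc$codes))) {
    out <- c(out, "codes are not in increasing Kabat order")
  }
  ins <- kabat_insertion(nc$codes) != ""
  bad <- ins & !(kabat_number(nc$codes) %in% kabat_anchors(nc$chain_type))
  if (any(bad)) {
    out <- c(out, paste("insertion letter at non-anchor position(s):",
                        paste(nc$codes[bad], collapse = ", ")))
  }
  if (paste(nc$residues, collapse = "") != nc$seq) {
    out <- c(out, "residues do not reconstruct the input sequence")
  }
  out
}
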