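#' Load a biophysical amino-acid grouping scheme
#'
#' The scheme partitions the 20 standard amino acids into exactly seven
#' groups; it is the similarity rule used to decide whether a substitution is
#' conservative. The default groups are aliphatic (AVLI), aromatic (FWY),
#' polar-neutral (STNQ), acidic (DE), basic (KRH), sulfur-containing (CM) and
#' conformational (GP).
#'
#' @param path path to a YAML file with a `groups` mapping, or `"builtin"`.
#' @return an object of class `biophysical_scheme`: a named list of residue
#'   character vectors.
#' @export
load_biophysical_scheme <- function(path = "builtin") {
  if (identical(path, "builtin")) path <- panrep_extdata("biophysical_groups.yaml")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$groups)) stop("scheme file has no 'groups' entry")
  groups <- lapply(raw$groups, function(x) strsplit(toupper(x), "")[[1]])
  all_res <- unlist(groups, use.names = FALSE)
  if (length(groups) != 7) stop("scheme must have exactly seven groups")
  if (anyDuplicated(all_res)) stop("scheme groups overlap")
  if (!setequal(all_res, AA_STANDARD)) {
    stop("scheme must cover all 20 standard amino acids exactly once")
  }
  structure(groups, class = "biophysical_scheme")
}

#' Biophysical group of an amino acid
#'
#' @param aa one-letter amino-acid codes.
#' @param scheme a [load_biophysical_scheme()] result.
#' @return the group id containing each residue; `NA` for `X` or any
#'   non-standard letter (the "ungroupable" sentinel).
#' @examples
#' sch <- load_biophysical_scheme()
#' biophysical_group(c("D", "E", "F"), sch)
#' @export
biophysical_group <- function(aa, scheme = load_biophysical_scheme()) {
  stopifnot(inherits(scheme, "biophysical_scheme"))
  lut <- setNames(rep(names(scheme), lengths(scheme)), unlist(scheme))
  unname(lut[toupper(aa)])
}

same_group <- function(a, b, scheme) {
  ga <- biophysical_group(a, scheme)
  gb <- biophysical_group(b, scheme)
  !is.na(ga) & !is.na(gb) & ga == gb
}

#' Number every chain of a clone set
#'
#' Convenience wrapper that Kabat-numbers the requested chain of each clone,
#' returning a list keyed by clone id; clones lacking that chain are skipped
#' and numbering failures are collected rather than raised.
#'
#' @param cs a [clone_set()].
#' @param chain `"heavy"` or `"lambda"`.
#' @param ... passed to [number_chain()].
#' @return a list of `numbered_chain` objects named by clone id, with the
#'   character vector of failed clone ids as attribute `"failures"`.
#' @export
number_clone_set <- function(cs, chain = c("heavy", "lambda"), ...) {
  stopifnot(inherits(cs, "clone_set"))
  chain <- match.arg(chain)
  col <- if (chain == "heavy") "heavy_seq" else "light_seq"
  has <- nzchar(cs[[col]])
  out <- list()
  failures <- character(0)
  for (i in which(has)) {
    nc <- tryCatch(number_chain(cs[[col]][i], chain, ...), error = function(e) e)
    if (inherits(nc, "error")) {
      failures <- c(failures, cs$clone_id[i])
    } else {
      out[[cs$clone_id[i]]] <- nc
    }
  }
  attr(out, "failures") <- failures
  out
}

position_residue_matrix <- function(numbered) {
  if (length(numbered) == 0) stop("no numbered chains")
  codes <- kabat_sort(unique(unlist(lapply(numbered, `[[`, "codes"))))
  mat <- matrix(NA_character_, nrow = length(codes), ncol = length(numbered),
                dimnames = list(codes, names(numbered)))
  for (j in seq_along(numbered)) {
    nc <- numbered[[j]]
    mat[nc$codes, j] <- nc$residues
  }
  mat
}

modal_residue <- function(res) {
  tab <- sort(table(res), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  sort(top)[1]   # alphabetical tie-break
}

#' Per-position amino-acid variability of a repertoire
#'
#' For every Kabat position carried by at least one chain, computes coverage
#' (chains bearing a residue there), the modal residue, variability defined as
#' `100 * (1 - modal_count / coverage)` (percent), and a five-bin variability
#' class under the configured edges. Positions covered by fewer chains than
#' `coverage_floor` are flagged `insufficient` and not binned. Region and
#' framework-vs-CDR summaries report the percentage of binned positions
#' falling in each bin.
#'
#' @param cs a [clone_set()].
#' @param chain `"heavy"` or `"lambda"`.
#' @param bin_edges increasing interior edges of the five bins; the default
#'   `c(10, 25, 50, 75)` yields bins `[0,10) [10,25) [25,50) [50,75) [75,100]`.
#' @param coverage_floor minimum coverage for a position to be binned.
#' @param numbered optional precomputed [number_clone_set()] result.
#' @return an object of class `variability_profile`: a data frame with
#'   columns `code`, `region`, `coverage`, `modal`, `variability`, `bin`,
#'   `insufficient`, with attributes `region_summary` and `fw_cdr_summary`.
#' @export
variability_profile <- function(cs, chain = c("heavy", "lambda"),
                                bin_edges = c(10, 25, 50, 75),
                                coverage_floor = 5, numbered = NULL) {
  chain <- match.arg(chain)
  stopifnot(length(bin_edges) == 4, !is.unsorted(bin_edges, strictly = TRUE))
  if (nrow(cs) == 0) stop("empty clone set")
  numbered <- numbered %||% number_clone_set(cs, chain)
  mat <- position_residue_matrix(numbered)
  codes <- rownames(mat)
  coverage <- apply(mat, 1, function(r) sum(!is.na(r)))
  modal <- apply(mat, 1, function(r) modal_residue(r[!is.na(r)]))
  modal_n <- vapply(seq_along(codes), function(i) {
    sum(mat[i, ] == modal[i], na.rm = TRUE)
  }, numeric(1))
  variability <- 100 * (1 - modal_n / coverage)
  insufficient <- coverage < coverage_floor
  bin <- findInterval(variability, bin_edges) + 1L
  bin[insufficient] <- NA_integer_
  df <- data.frame(code = codes, region = region_of_codes(codes, chain),
                   coverage = coverage, modal = modal,
                   variability = variability, bin = bin,
                   insufficient = insufficient, row.names = NULL,
                   stringsAsFactors = FALSE)
  bin_pct <- function(rows) {
    b <- df$bin[rows & !df$insufficient]
    if (length(b) == 0) return(setNames(rep(NA_real_, 5), paste0("bin", 1:5)))
    setNames(100 * tabulate(b, 5) / length(b), paste0("bin", 1:5))
  }
  regions <- levels(df$region)
  region_summary <- cbind(data.frame(region = regions),
                          do.call(rbind, lapply(regions, function(r) bin_pct(df$region == r))))
  fw_cdr_summary <- cbind(data.frame(region = c("FW", "CDR")),
                          rbind(bin_pct(grepl("^FW", df$region)),
                                bin_pct(grepl("^CDR", df$region))))
  structure(df, chain_type = chain, bin_edges = bin_edges,
            coverage_floor = coverage_floor, region_summary = region_summary,
            fw_cdr_summary = fw_cdr_summary,
            class = c("variability_profile", "data.frame"))
}

#' Consensus residues of a repertoire
#'
#' Modal residue at every covered Kabat position; ties are broken by
#' alphabetical order of the residue.
#'
#' @inheritParams variability_profile
#' @return a named character vector, Kabat code -> consensus residue.
#' @export
consensus <- function(cs, chain = c("heavy", "lambda"), numbered = NULL) {
  chain <- match.arg(chain)
  if (nrow(cs) == 0) stop("empty clone set")
  numbered <- numbered %||% number_clone_set(cs, chain)
  mat <- position_residue_matrix(numbered)
  vapply(rownames(mat), function(code) {
    r <- mat[code, ]
    modal_residue(r[!is.na(r)])
  }, character(1))
}

#' Conserved positions of a test repertoire against a reference consensus
#'
#' A position is conserved iff every test-set chain bears a residue there and
#' each such residue either equals the reference residue or shares its
#' biophysical group ("similar bio-physical characteristics"). With
#' `mode = "any"` a residue instead conserves the position if it equals, or
#' shares a group with, any reference-set residue observed at that position
#' (`pre_residues` must then be supplied). Positions absent from the reference
#' are excluded with a warning.
#'
#' @param test_set a [clone_set()] (typically the post-selection clones).
#' @param reference_consensus named residue vector from [consensus()] on the
#'   pre-selection set.
#' @param scheme a [load_biophysical_scheme()] result.
#' @param chain `"heavy"` or `"lambda"`.
#' @param numbered optional precomputed numbering of `test_set`.
#' @param mode `"consensus"` (default) or `"any"`.
#' @param pre_residues for `mode = "any"`: named list, Kabat code -> character
#'   vector of residues observed in the reference set.
#' @return a character vector of conserved Kabat codes, in Kabat order.
#' @export
conserved_positions <- function(test_set, reference_consensus,
                                scheme = load_biophysical_scheme(),
                                chain = c("heavy", "lambda"), numbered = NULL,
                                mode = c("consensus", "any"),
                                pre_residues = NULL) {
  chain <- match.arg(chain)
  mode <- match.arg(mode)
  if (mode == "any" && is.null(pre_residues)) {
    stop("mode = 'any' requires pre_residues")
  }
  numbered <- numbered %||% number_clone_set(test_set, chain)
  if (length(numbered) == 0) stop("no ", chain, " chains in the test set")
  mat <- position_residue_matrix(numbered)
  extra <- setdiff(rownames(mat), names(reference_consensus))
  if (length(extra)) {
    warning("position(s) absent from the reference consensus excluded: ",
            paste(extra, collapse = ", "))
  }
  codes <- intersect(rownames(mat), names(reference_consensus))
  ok <- vapply(codes, function(code) {
    res <- mat[code, ]
    if (anyNA(res)) return(FALSE)     # a site cannot be unchanged where absent
    if (mode == "consensus") {
      ref <- reference_consensus[[code]]
      all(res == ref | same_group(res, ref, scheme))
    } else {
      refs <- pre_residues[[code]]
      if (is.null(refs)) return(FALSE)
      all(vapply(res, function(r) {
        any(r == refs | same_group(rep(r, length(refs)), refs, scheme))
      }, logical(1)))
    }
  }, logical(1))
  kabat_sort(codes[ok])
}

region_counts <- function(codes, chain) {
  regions <- levels(region_of_codes(character(0), chain))
  split_codes <- split(codes, region_of_codes(codes, chain))
  lapply(setNames(regions, regions), function(r) {
    kabat_sort(split_codes[[r]] %||% character(0))
  })
}

#' Conserved-site comparison of pre- and post-selection repertoires
#'
#' Computes, per chain and per region, the positions conserved within the
#' pre-selection set (each pre chain matching the pre consensus exactly or by
#' biophysical group) and the positions of the post-selection set conserved
#' relative to the same pre-selection consensus, together with framework, CDR,
#' per-chain and grand totals. All totals are sums of the corresponding
#' per-region lists.
#'
#' @param pre,post [clone_set()] objects; both must carry the requested chains.
#' @param scheme a [load_biophysical_scheme()] result.
#' @param chains chains to analyze.
#' @param mode conservation rule, see [conserved_positions()].
#' @return an object of class `conservation_report`: nested list
#'   `$pre`/`$post` -> chain -> list of per-region code vectors plus
#'   `total_fw`, `total_cdr`, `total`; and `$grand_total` with pre/post sums.
#' @export
conservation_report <- function(pre, post, scheme = load_biophysical_scheme(),
                                chains = c("heavy", "lambda"),
                                mode = c("consensus", "any")) {
  mode <- match.arg(mode)
  if (nrow(pre) == 0 || nrow(post) == 0) stop("empty pre or post clone set")
  out <- list(pre = list(), post = list())
  for (chain in chains) {
    pre_num <- number_clone_set(pre, chain)
    post_num <- number_clone_set(post, chain)
    if (length(pre_num) == 0 || length(post_num) == 0) {
      stop("chain '", chain, "' is missing from the pre or post set")
    }
    pre_mat <- position_residue_matrix(pre_num)
    cons <- vapply(rownames(pre_mat), function(code) {
      r <- pre_mat[code, ]
      modal_residue(r[!is.na(r)])
    }, character(1))
    pre_res <- lapply(setNames(rownames(pre_mat), rownames(pre_mat)),
                      function(code) unique(pre_mat[code, !is.na(pre_mat[code, ])]))
    cp_pre <- conserved_positions(pre, cons, scheme, chain, numbered = pre_num,
                                  mode = mode, pre_residues = pre_res)
    cp_post <- conserved_positions(post, cons, scheme, chain, numbered = post_num,
                                   mode = mode, pre_residues = pre_res)
    summarize <- function(codes) {
      by_region <- region_counts(codes, chain)
      fw <- unlist(by_region[grepl("^FW", names(by_region))], use.names = FALSE)
      cdr <- unlist(by_region[grepl("^CDR", names(by_region))], use.names = FALSE)
      c(by_region, list(total_fw = length(fw), total_cdr = length(cdr),
                        total = length(fw) + length(cdr)))
    }
    out$pre[[chain]] <- summarize(cp_pre)
    out$post[[chain]] <- summarize(cp_post)
  }
  out$grand_total <- list(
    pre = sum(vapply(out$pre, `[[`, numeric(1), "total")),
    post = sum(vapply(out$post, `[[`, numeric(1), "total")))
  structure(out, chains = chains, mode = mode, class = "conservation_report")
}

#' @export
as.data.frame.conservation_report <- function(x, ...) {
  rows <- list()
  for (phase in c("pre", "post")) {
    for (chain in names(x[[phase]])) {
      s <- x[[phase]][[chain]]
      for (region in c("FW1", "FW2", "FW3", "FW4", "CDR1", "CDR2", "CDR3")) {
        codes <- s[[region]]
        rows[[length(rows) + 1]] <- data.frame(
          phase = phase, chain = chain, region = region,
          n_conserved = length(codes),
          positions = paste(codes, collapse = ","),
          stringsAsFactors = FALSE)
      }
      for (tot in c("total_fw", "total_cdr", "total")) {
        rows[[length(rows) + 1]] <- data.frame(
          phase = phase, chain = chain, region = tot,
          n_conserved = s[[tot]], positions = "", stringsAsFactors = FALSE)
      }
    }
  }
  rows[[length(rows) + 1]] <- data.frame(
    phase = "pre", chain = "all", region = "grand_total",
    n_conserved = x$grand_total$pre, positions = "", stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    phase = "post", chain = "all", region = "grand_total",
    n_conserved = x$grand_total$post, positions = "", stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("conservation_report: %d conserved positions pre-selection, %d post-selection\n",
              x$grand_total$pre, x$grand_total$post))
  for (chain in names(x$post)) {
    cat(sprintf("  %s: pre FW %d / CDR %d; post FW %d / CDR %d\n", chain,
                x$pre[[chain]]$total_fw, x$pre[[chain]]$total_cdr,
                x$post[[chain]]$total_fw, x$post[[chain]]$total_cdr))
  }
  invisible(x)
}
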