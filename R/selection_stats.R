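new_frequency_table <- function(categories, grouping = list()) {
  tab <- table(categories)
  n <- sum(tab)
  df <- data.frame(category = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$percent <- 100 * df$count / n
  # descending count, ties by category
  df <- df[order(-df$count, df$category), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_total = n, grouping = grouping,
            class = c("frequency_table", "data.frame"))
}

#' @export
print.frequency_table <- function(x, ...) {
  g <- attr(x, "grouping")
  if (length(g)) cat(paste(names(g), unlist(g), sep = "=", collapse = ", "), "\n")
  df <- as.data.frame(x)
  df$percent <- format_percent(df$percent)
  print(df, row.names = FALSE)
  cat("n =", attr(x, "n_total"), "\n")
  invisible(x)
}

#' CDR length frequency table
#'
#' Tabulates the Kabat CDR length of one loop across a clone set, as counts
#' and percentages of the clones analyzed. With `dedupe = TRUE` identical
#' amino-acid sequences are collapsed first (the convention for post-selection
#' clone panels, where the same binder is often isolated repeatedly).
#'
#' @param cs a [clone_set()].
#' @param cdr one of `"H1"`, `"H2"`, `"H3"`, `"L1"`, `"L2"`, `"L3"`.
#' @param dedupe collapse identical sequences before counting.
#' @param numbered optional precomputed [number_clone_set()] result for the
#'   relevant chain.
#' @return a `frequency_table` data frame (`category`, `count`, `percent`)
#'   sorted by descending count, with attributes `n_total` and `grouping`.
#' @export
length_frequency_table <- function(cs, cdr, dedupe = FALSE, numbered = NULL) {
  stopifnot(cdr %in% c("H1", "H2", "H3", "L1", "L2", "L3"))
  chain <- if (startsWith(cdr, "H")) "heavy" else "lambda"
  col <- if (chain == "heavy") "heavy_seq" else "light_seq"
  cs_use <- cs[nzchar(cs[[col]]), , drop = FALSE]
  if (nrow(cs_use) == 0) stop("no clones with a ", chain, " chain")
  if (dedupe) {
    keep <- !duplicated(paste(cs_use$heavy_seq, cs_use$light_seq))
    cs_use <- cs_use[keep, , drop = FALSE]
    numbered <- NULL
  }
  numbered <- numbered %||% number_clone_set(
    clone_set(as.data.frame(cs_use)), chain)
  numbered <- numbered[names(numbered) %in% cs_use$clone_id]
  if (length(numbered) == 0) stop("no ", chain, " chains numbered successfully")
  which_cdr <- paste0("CDR", substr(cdr, 2, 2))
  lens <- vapply(numbered, function(nc) {
    cdr_length(annotate_regions(nc), which_cdr)
  }, integer(1))
  new_frequency_table(lens, grouping = list(cdr = cdr, dedupe = dedupe))
}

#' Canonical combination frequency table
#'
#' Tabulates heavy-chain `"h1-h2"` or light-chain `"l1-l2-l3"` canonical
#' combination strings across a clone set. `"X"` and `"unmatched"` labels
#' propagate as their own categories.
#'
#' @param cs a [clone_set()].
#' @param which `"heavy_pair"` or `"light_triple"`.
#' @param templates a [load_templates()] set.
#' @param collapse_unmatched report key-residue failures as `"X"` (the
#'   convention that conflates non-classified loops with unknown lengths).
#' @param dedupe collapse identical sequences before counting.
#' @return a `frequency_table`, as for [length_frequency_table()].
#' @export
canonical_frequency_table <- function(cs, which = c("heavy_pair", "light_triple"),
                                      templates = load_templates(),
                                      collapse_unmatched = FALSE,
                                      dedupe = FALSE) {
  which <- match.arg(which)
  chain <- if (which == "heavy_pair") "heavy" else "lambda"
  col <- if (chain == "heavy") "heavy_seq" else "light_seq"
  cs_use <- cs[nzchar(cs[[col]]), , drop = FALSE]
  if (nrow(cs_use) == 0) stop("no clones with a ", chain, " chain")
  if (dedupe) {
    cs_use <- cs_use[!duplicated(paste(cs_use$heavy_seq, cs_use$light_seq)), ,
                     drop = FALSE]
  }
  numbered <- number_clone_set(clone_set(as.data.frame(cs_use)), chain)
  if (length(numbered) == 0) stop("no ", chain, " chains numbered successfully")
  combos <- vapply(numbered, function(nc) {
    ca <- assign_canonical(nc, annotate_regions(nc), templates,
                           collapse_unmatched = collapse_unmatched)
    paste(ca$labels, collapse = "-")
  }, character(1))
  new_frequency_table(combos, grouping = list(which = which, dedupe = dedupe))
}

#' Chi-square goodness-of-fit test against a uniform null
#'
#' Tests whether category counts are compatible with equal representation:
#' the statistic is `sum((obs - exp)^2 / exp)` with `exp = total / k`, and the
#' p-value is the upper tail of the chi-square distribution with `k - 1`
#' degrees of freedom. The null is uniform over the observed categories.
#'
#' @param counts non-negative integer counts, length >= 2, positive total.
#' @return an object of class `gof_result`: `statistic`, `df`, `p_value`, `k`.
#' @examples
#' chi_square_gof(c(8, 1, 1))
#' @export
chi_square_gof <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  k <- length(counts)
  if (k < 2) stop("at least two categories are required")
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  expd <- total / k
  statistic <- sum((counts - expd)^2 / expd)
  structure(list(statistic = statistic, df = k - 1L,
                 p_value = pchisq(statistic, df = k - 1, lower.tail = FALSE),
                 k = k),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-square goodness of fit: X2 = %.4g, df = %d, p = %.4g (k = %d)\n",
              x$statistic, x$df, x$p_value, x$k))
  invisible(x)
}

#' Pre/post selection enrichment comparison
#'
#' Joins a pre-selection and a post-selection frequency table over the same
#' grouping and reports, per category, the pre and post percentages and the
#' fold-change of the percentage (post / pre, from unrounded values).
#' Categories absent pre-selection are flagged `novel` with an undefined
#' (`NA`) fold-change.
#'
#' @param pre_table,post_table `frequency_table` objects with the same
#'   grouping key.
#' @return a data frame with columns `category`, `pre_count`, `pre_percent`,
#'   `post_count`, `post_percent`, `fold_change`, `novel`.
#' @export
pre_post_enrichment <- function(pre_table, post_table) {
  stopifnot(inherits(pre_table, "frequency_table"),
            inherits(post_table, "frequency_table"))
  gp <- attr(pre_table, "grouping")
  gq <- attr(post_table, "grouping")
  if (!identical(gp[setdiff(names(gp), "dedupe")], gq[setdiff(names(gq), "dedupe")])) {
    stop("pre and post tables have different grouping keys")
  }
  cats <- sort(union(pre_table$category, post_table$category))
  pre_i <- match(cats, pre_table$category)
  post_i <- match(cats, post_table$category)
  df <- data.frame(
    category = cats,
    pre_count = ifelse(is.na(pre_i), 0L, pre_table$count[pre_i]),
    pre_percent = ifelse(is.na(pre_i), 0, pre_table$percent[pre_i]),
    post_count = ifelse(is.na(post_i), 0L, post_table$count[post_i]),
    post_percent = ifelse(is.na(post_i), 0, post_table$percent[post_i]),
    stringsAsFactors = FALSE)
  df$novel <- df$pre_count == 0 & df$post_count > 0
  df$fold_change <- ifelse(df$pre_percent > 0, df$post_percent / df$pre_percent,
                           NA_real_)
  df[order(-df$post_percent, df$category), , drop = FALSE]
}
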