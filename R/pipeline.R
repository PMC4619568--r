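prepare_out_dir <- function(out_dir, overwrite) {
  if (dir.exists(out_dir)) {
    if (!overwrite && length(list.files(out_dir)) > 0) {
      stop("output directory ", out_dir,
           " is non-empty; use overwrite = TRUE or a fresh directory")
    }
  } else {
    dir.create(out_dir, recursive = TRUE)
  }
  out_dir
}

profile_one_chain <- function(cs, chain, templates, bin_edges, coverage_floor) {
  numbered <- number_clone_set(cs, chain)
  failures <- attr(numbered, "failures")
  n_attempted <- length(numbered) + length(failures)
  if (n_attempted == 0) return(NULL)
  if (length(failures) > 0.2 * n_attempted) {
    stop(length(failures), "/", n_attempted, " ", chain,
         " chains failed Kabat numbering: ", paste(failures, collapse = ", "))
  }
  cdrs <- if (chain == "heavy") c("H1", "H2", "H3") else c("L1", "L2", "L3")
  cdr_tables <- lapply(setNames(cdrs, cdrs), function(cdr) {
    length_frequency_table(cs, cdr, numbered = numbered)
  })
  which <- if (chain == "heavy") "heavy_pair" else "light_triple"
  canon <- canonical_frequency_table(cs, which, templates = templates)
  assignments <- do.call(rbind, lapply(names(numbered), function(id) {
    nc <- numbered[[id]]
    ca <- assign_canonical(nc, annotate_regions(nc), templates)
    data.frame(clone_id = id, chain = chain,
               combination = paste(ca$labels, collapse = "-"),
               t(ca$labels), stringsAsFactors = FALSE)
  }))
  vp <- variability_profile(cs, chain, bin_edges = bin_edges,
                            coverage_floor = coverage_floor, numbered = numbered)
  list(numbered = numbered, failures = failures, cdr_tables = cdr_tables,
       canonical_table = canon, assignments = assignments, variability = vp)
}

#' Profile a repertoire: numbering, regions, canonical classes, variability
#'
#' Runs the full single-repertoire pipeline on a FASTA + metadata input and
#' writes `cdr_lengths.tsv`, `canonical.tsv`, `canonical_assignments.tsv` and
#' `variability.tsv` into `out_dir`. Per-sequence numbering failures are
#' tallied and reported; more than 20 percent failures on a chain aborts the
#' run.
#'
#' @param fasta_path,metadata_path repertoire input, see [read_repertoire()].
#' @param out_dir report directory (must be empty unless `overwrite`).
#' @param templates canonical templates ([load_templates()]).
#' @param bin_edges,coverage_floor see [variability_profile()].
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, a list with per-chain profile bundles and the paths
#'   written.
#' @export
run_profile <- function(fasta_path, metadata_path = NULL, out_dir,
                        templates = load_templates(),
                        bin_edges = c(10, 25, 50, 75), coverage_floor = 5,
                        overwrite = FALSE) {
  out_dir <- prepare_out_dir(out_dir, overwrite)
  cs <- read_repertoire(fasta_path, metadata_path)
  bundles <- list()
  for (chain in c("heavy", "lambda")) {
    b <- profile_one_chain(cs, chain, templates, bin_edges, coverage_floor)
    if (!is.null(b)) bundles[[chain]] <- b
  }
  if (length(bundles) == 0) stop("no chains could be profiled")
  cdr_rows <- do.call(rbind, unlist(lapply(names(bundles), function(chain) {
    lapply(names(bundles[[chain]]$cdr_tables), function(cdr) {
      t <- bundles[[chain]]$cdr_tables[[cdr]]
      data.frame(chain = chain, cdr = cdr, length = t$category,
                 count = t$count, percent = t$percent, stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  canon_rows <- do.call(rbind, lapply(names(bundles), function(chain) {
    t <- bundles[[chain]]$canonical_table
    data.frame(chain = chain, combination = t$category, count = t$count,
               percent = t$percent, stringsAsFactors = FALSE)
  }))
  paths <- c(cdr_lengths = file.path(out_dir, "cdr_lengths.tsv"),
             canonical = file.path(out_dir, "canonical.tsv"),
             assignments = file.path(out_dir, "canonical_assignments.tsv"),
             variability = file.path(out_dir, "variability.tsv"))
  write_report(cdr_rows, paths["cdr_lengths"])
  write_report(canon_rows, paths["canonical"])
  assign_rows <- do.call(rbind, lapply(bundles, function(b) {
    df <- b$assignments
    df[, intersect(c("clone_id", "chain", "combination"), names(df))]
  }))
  write_report(assign_rows, paths["assignments"])
  var_rows <- do.call(rbind, lapply(names(bundles), function(chain) {
    cbind(chain = chain, as.data.frame(bundles[[chain]]$variability))
  }))
  write_report(var_rows, paths["variability"])
  n_fail <- sum(vapply(bundles, function(b) length(b$failures), integer(1)))
  message(sprintf("profiled %d clones (%d numbering failures); reports in %s",
                  nrow(cs), n_fail, out_dir))
  invisible(list(clones = cs, bundles = bundles, paths = paths))
}

#' Compare pre- and post-selection repertoires
#'
#' Computes the conserved-site report, the pre/post enrichment tables for
#' CDR lengths and canonical combinations, and chi-square goodness-of-fit
#' tests for canonical-class uniformity, writing `conservation.json`,
#' `conservation.tsv`, `enrichment_*.tsv` and `chi_square.tsv` into
#' `out_dir`. A summary line prints the pre and post conserved grand totals.
#'
#' @param pre_fasta,pre_metadata,post_fasta,post_metadata repertoire inputs.
#' @param out_dir report directory.
#' @param templates canonical templates.
#' @param scheme biophysical scheme.
#' @param mode conservation rule, see [conserved_positions()].
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, a list with the [conservation_report()], enrichment
#'   tables and chi-square results.
#' @export
run_compare <- function(pre_fasta, pre_metadata = NULL, post_fasta,
                        post_metadata = NULL, out_dir,
                        templates = load_templates(),
                        scheme = load_biophysical_scheme(),
                        mode = c("consensus", "any"), overwrite = FALSE) {
  mode <- match.arg(mode)
  out_dir <- prepare_out_dir(out_dir, overwrite)
  pre <- read_repertoire(pre_fasta, pre_metadata)
  post <- read_repertoire(post_fasta, post_metadata)
  for (chain in c("heavy", "lambda")) {
    col <- if (chain == "heavy") "heavy_seq" else "light_seq"
    if (any(nzchar(pre[[col]])) != any(nzchar(post[[col]]))) {
      stop("chain '", chain, "' present in only one of the pre/post sets")
    }
  }
  rep_cons <- conservation_report(pre, post, scheme = scheme, mode = mode)
  write_report(rep_cons, file.path(out_dir, "conservation.json"), "json")
  write_report(rep_cons, file.path(out_dir, "conservation.tsv"), "tsv")
  enrichment <- list()
  gof <- list()
  for (which in c("heavy_pair", "light_triple")) {
    pre_t <- canonical_frequency_table(pre, which, templates = templates)
    post_t <- canonical_frequency_table(post, which, templates = templates,
                                        dedupe = TRUE)
    enr <- pre_post_enrichment(pre_t, post_t)
    enrichment[[which]] <- enr
    write_report(enr, file.path(out_dir, paste0("enrichment_", which, ".tsv")))
    gof[[which]] <- chi_square_gof(pre_t$count)
  }
  gof_df <- do.call(rbind, lapply(names(gof), function(w) {
    g <- gof[[w]]
    data.frame(grouping = w, statistic = g$statistic, df = g$df,
               p_value = g$p_value, k = g$k, stringsAsFactors = FALSE)
  }))
  write_report(gof_df, file.path(out_dir, "chi_square.tsv"))
  message(sprintf("conserved positions: pre %d, post %d; reports in %s",
                  rep_cons$grand_total$pre, rep_cons$grand_total$post, out_dir))
  invisible(list(conservation = rep_cons, enrichment = enrichment,
                 chi_square = gof, paths = out_dir))
}

#' Generate a synthetic study dataset on disk
#'
#' Emulates the configured study design (default: the built-in three-library
#' design) and writes, per library, pre- and post-selection FASTA + metadata
#' TSV, a ground-truth JSON, and an echo of the configuration used.
#'
#' @param out_dir output directory.
#' @param seed mandatory integer seed.
#' @param config_path study design YAML, or `NULL` for the built-in design.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, the [emulate_study_design()] result with file paths.
#' @export
run_simulate <- function(out_dir, seed, config_path = NULL, overwrite = FALSE) {
  if (missing(seed) || is.null(seed)) stop("an explicit integer seed is required")
  out_dir <- prepare_out_dir(out_dir, overwrite)
  libs <- emulate_study_design(seed, config_path)
  paths <- list()
  for (id in names(libs)) {
    lib <- libs[[id]]
    p <- list(
      pre_fasta = file.path(out_dir, paste0(id, "_pre.fasta")),
      pre_meta = file.path(out_dir, paste0(id, "_pre.tsv")),
      post_fasta = file.path(out_dir, paste0(id, "_post.fasta")),
      post_meta = file.path(out_dir, paste0(id, "_post.tsv")),
      truth = file.path(out_dir, paste0(id, "_ground_truth.json")))
    write_repertoire(lib$pre, p$pre_fasta, p$pre_meta, linker = lib$config$linker)
    write_repertoire(lib$post, p$post_fasta, p$post_meta, linker = lib$config$linker)
    jsonlite::write_json(list(pre = lib$truth_pre, post = lib$truth_post),
                         p$truth, auto_unbox = TRUE, pretty = TRUE)
    paths[[id]] <- p
  }
  cfg_echo <- file.path(out_dir, "config_echo.yaml")
  file.copy(config_path %||% panrep_extdata("table1_emulation.yaml"), cfg_echo)
  message(sprintf("simulated %d libraries (seed %d) into %s",
                  length(libs), as.integer(seed), out_dir))
  invisible(list(libraries = libs, paths = paths))
}
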