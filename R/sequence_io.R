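#' The scFv inter-domain linker
#'
#' The 15-residue peptide joining VH and V-lambda in the scFv constructs this
#' package parses.
#'
#' @return a character scalar, `"EGKSSGASGESKVDD"`.
#' @export
scfv_linker <- function() "EGKSSGASGESKVDD"

valid_aa_seq <- function(seq) {
  nzchar(seq) && grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seq)
}

#' Construct a clone set
#'
#' A clone set is the unit all repertoire statistics operate on: a data frame
#' of clones (one row each) with library/phase/target metadata and the heavy
#' and/or light chain sequence, plus a free-text provenance attribute.
#'
#' @param clones data frame with columns `clone_id`, `library_id`, `phase`
#'   (`"pre"` or `"post"`), `target`, `heavy_seq`, `light_seq`,
#'   `light_isotype` (`"lambda"` or `"kappa"`). Missing metadata columns are
#'   filled with defaults (`phase = "pre"`, empty target, lambda isotype).
#' @param provenance free-text description of where the clones came from.
#' @return an object of class `clone_set` (a validated data frame).
#' @details Sequences may contain the 20 standard one-letter codes plus `X`.
#'   `phase = "post"` requires a non-empty `target`; clone ids must be unique.
#'   Single-chain clones leave the absent chain as `""`.
#' @export
clone_set <- function(clones, provenance = "") {
  stopifnot(is.data.frame(clones))
  defaults <- list(library_id = "lib", phase = "pre", target = "",
                   heavy_seq = "", light_seq = "", light_isotype = "lambda")
  if (is.null(clones$clone_id)) stop("clone_id column is required")
  for (col in names(defaults)) {
    if (is.null(clones[[col]])) clones[[col]] <- defaults[[col]]
  }
  clones <- clones[, c("clone_id", "library_id", "phase", "target",
                       "heavy_seq", "light_seq", "light_isotype")]
  clones[] <- lapply(clones, as.character)
  if (anyDuplicated(clones$clone_id)) {
    stop("duplicate clone ids: ",
         paste(unique(clones$clone_id[duplicated(clones$clone_id)]), collapse = ", "))
  }
  if (!all(clones$phase %in% c("pre", "post"))) stop("phase must be 'pre' or 'post'")
  if (!all(clones$light_isotype %in% c("lambda", "kappa"))) {
    stop("light_isotype must be 'lambda' or 'kappa'")
  }
  bad_target <- clones$phase == "post" & !nzchar(clones$target)
  if (any(bad_target)) {
    stop("post-selection clones must carry a target: ",
         paste(clones$clone_id[bad_target], collapse = ", "))
  }
  for (col in c("heavy_seq", "light_seq")) {
    bad <- nzchar(clones[[col]]) & !vapply(clones[[col]], valid_aa_seq, logical(1))
  if (any(bad)) {
      stop("non-amino-acid alphabet in ", col, " of clone(s): ",
           paste(clones$clone_id[bad], collapse = ", "))
    }
  }
  empty <- !nzchar(clones$heavy_seq) & !nzchar(clones$light_seq)
  if (any(empty)) stop("clones with no sequence: ",
                       paste(clones$clone_id[empty], collapse = ", "))
  structure(clones, provenance = provenance,
            class = c("clone_set", "data.frame"))
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("clone_set: %d clones (%d pre, %d post); %d with heavy, %d with light chains\n",
              nrow(x), sum(x$phase == "pre"), sum(x$phase == "post"),
              sum(nzchar(x$heavy_seq)), sum(nzchar(x$light_seq))))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("provenance:", prov, "\n")
  invisible(x)
}

#' Split an scFv construct into VH, linker and VL
#'
#' Locates the 15-residue linker by exact match, or failing that by the
#' leftmost best-scoring ungapped 15-residue window with at least
#' `min_identity` identity, and splits the construct into the heavy-chain
#' prefix and light-chain suffix.
#'
#' @param seq amino-acid sequence of the full construct (length > 200).
#' @param linker linker peptide to search for.
#' @param min_identity minimum fractional identity for a fuzzy linker match.
#' @return a list with `heavy_seq`, `linker_seq`, `light_seq`,
#'   `linker_length` (residues) and `exact` (`FALSE` when the match was fuzzy).
#' @examples
#' s <- paste0(strrep("A", 110), scfv_linker(), strrep("G", 100))
#' split_scfv(s)$linker_length
#' @export
split_scfv <- function(seq, linker = scfv_linker(), min_identity = 0.8) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) <= 200) stop("sequence too short to be an scFv construct (<= 200 aa)")
  k <- nchar(linker)
  hits <- gregexpr(linker, seq, fixed = TRUE)[[1]]
  exact <- TRUE
  if (hits[1] == -1L) {
    exact <- FALSE
    chars <- strsplit(seq, "")[[1]]
    lchars <- strsplit(linker, "")[[1]]
    n <- length(chars) - k + 1
    ident <- vapply(seq_len(n), function(i) {
      mean(chars[i:(i + k - 1)] == lchars)
    }, numeric(1))
    if (max(ident) < min_identity) {
      stop("linker not found: no ", k, "-residue window with >= ",
           round(100 * min_identity), "% identity to ", linker)
    }
    hits <- which(ident == max(ident))[1]   # leftmost best window
  } else if (length(hits) > 1) {
    stop("ambiguous construct: linker matches at ", length(hits), " positions")
  }
  start <- hits[1]
  list(heavy_seq = substr(seq, 1, start - 1),
       linker_seq = substr(seq, start, start + k - 1),
       light_seq = substr(seq, start + k, nchar(seq)),
       linker_length = k,
       exact = exact)
}

#' Read a repertoire from FASTA plus optional metadata
#'
#' Reads amino-acid FASTA records and an optional tab-separated metadata
#' sidecar keyed by `clone_id`. Records typed `scfv` in the metadata (or
#' untyped records longer than 200 residues) are split at the linker into
#' heavy and light chains; records typed `heavy` or `lambda` populate a single
#' chain. Records with a non-amino-acid alphabet are rejected with a warning;
#' records lacking metadata default to `phase = "pre"` with an empty target
#' (also warned).
#'
#' @param fasta_path path to the FASTA file.
#' @param metadata_path path to a TSV with columns `clone_id`, `library_id`,
#'   `phase`, `target`, `light_isotype` and optionally `chain`
#'   (`heavy`/`lambda`/`scfv`), or `NULL`.
#' @param linker linker peptide used for scFv splitting.
#' @return a [clone_set()].
#' @export
read_repertoire <- function(fasta_path, metadata_path = NULL, linker = scfv_linker()) {
  recs <- Biostrings::readAAStringSet(fasta_path)
  if (length(recs) == 0) stop("no FASTA records in ", fasta_path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- read.delim(metadata_path, colClasses = "character")
    if (is.null(meta$clone_id)) stop("metadata must have a clone_id column")
  }
  rows <- list()
  for (i in seq_along(recs)) {
    seq <- as.character(recs[[i]])
    id <- ids[i]
    if (!valid_aa_seq(seq)) {
      warning("record '", id, "' rejected: non-amino-acid alphabet")
      next
    }
    m <- if (!is.null(meta) && id %in% meta$clone_id) {
      as.list(meta[match(id, meta$clone_id), ])
    } else {
      if (!is.null(meta)) {
        warning("record '", id, "' has no metadata row; defaulting to phase=pre")
      }
      list()
    }
    chain <- m$chain %||% if (nchar(seq) > 200) "scfv" else "heavy"
    heavy <- light <- ""
    if (chain == "scfv") {
      parts <- split_scfv(seq, linker = linker)
      heavy <- parts$heavy_seq
      light <- parts$light_seq
    } else if (chain == "heavy") {
      heavy <- seq
    } else if (chain %in% c("lambda", "kappa", "light")) {
      light <- seq
    } else {
      stop("unknown chain type '", chain, "' for record '", id, "'")
    }
    rows[[length(rows) + 1]] <- data.frame(
      clone_id = id,
      library_id = m$library_id %||% "lib",
      phase = m$phase %||% "pre",
      target = m$target %||% "",
      heavy_seq = heavy, light_seq = light,
      light_isotype = m$light_isotype %||% "lambda",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no usable records in ", fasta_path)
  clone_set(do.call(rbind, rows),
            provenance = paste("read from", fasta_path))
}

#' Write a repertoire to FASTA plus metadata
#'
#' Clones with both chains are written as scFv constructs (heavy + linker +
#' light); single-chain clones as bare chains. The metadata TSV mirrors the
#' columns [read_repertoire()] consumes.
#'
#' @param cs a [clone_set()].
#' @param fasta_path,metadata_path output paths.
#' @param linker linker peptide inserted between paired chains.
#' @return invisibly, the paths written.
#' @export
write_repertoire <- function(cs, fasta_path, metadata_path, linker = scfv_linker()) {
  stopifnot(inherits(cs, "clone_set"))
  both <- nzchar(cs$heavy_seq) & nzchar(cs$light_seq)
  seqs <- ifelse(both, paste0(cs$heavy_seq, linker, cs$light_seq),
                 ifelse(nzchar(cs$heavy_seq), cs$heavy_seq, cs$light_seq))
  chain <- ifelse(both, "scfv", ifelse(nzchar(cs$heavy_seq), "heavy", cs$light_isotype))
  set <- Biostrings::AAStringSet(setNames(seqs, cs$clone_id))
  Biostrings::writeXStringSet(set, fasta_path)
  meta <- data.frame(clone_id = cs$clone_id, library_id = cs$library_id,
                     phase = cs$phase, target = cs$target,
                     light_isotype = cs$light_isotype, chain = chain,
                     stringsAsFactors = FALSE)
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, metadata = metadata_path))
}

format_percent <- function(x) formatC(x, format = "f", digits = 1)

#' Write a tabular or structured report
#'
#' Data frames (frequency tables, enrichment tables, variability profiles) are
#' written as TSV with a deterministic column order and percentages rendered
#' with one decimal place, or as JSON. Conservation reports are written as
#' JSON (per-region position lists) or as a TSV mirroring their tabular form.
#'
#' @param table a data frame or a [conservation_report()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_report <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(table, "conservation_report")) {
    if (format == "json") {
      jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, pretty = TRUE)
    } else {
      df <- as.data.frame(table)
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(path))
  }
  df <- as.data.frame(table)
  if (nrow(df) == 0) warning("writing empty table to ", path)
  if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    out <- df
    pct_cols <- grep("percent|variability", names(out))
    for (j in pct_cols) out[[j]] <- format_percent(out[[j]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
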