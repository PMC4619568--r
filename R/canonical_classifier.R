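#' Load canonical-structure templates
#'
#' Templates are declarative YAML records `{chain, loop, class, window,
#' length, keys}`: a Chothia-style loop window expressed in Kabat codes, the
#' loop residue count the class requires, and key residues with their allowed
#' amino-acid sets. The built-in set covers heavy H1 classes 1-3, H2 classes
#' 1-4, lambda L1 classes 2/3/5/6, L2 class 1 and L3 classes 4/5.
#'
#' @param path path to a template YAML file, or `"builtin"`.
#' @return an object of class `canonical_templates` (list of template records).
#' @examples
#' tpl <- load_templates()
#' template_length(tpl, "lambda", "L1", "6")
#' @export
load_templates <- function(path = "builtin") {
  if (identical(path, "builtin")) path <- panrep_extdata("canonical_templates.yaml")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$templates)) stop("template file has no 'templates' entry")
  tpls <- lapply(raw$templates, function(t) {
    for (f in c("chain", "loop", "class", "window", "length", "keys")) {
      if (is.null(t[[f]])) stop("template missing field '", f, "'")
    }
    if (!t$chain %in% c("heavy", "lambda")) stop("unknown template chain: ", t$chain)
    if (length(t$window) != 2 || !all(kabat_valid(unlist(t$window)))) {
      stop("malformed window in template ", t$chain, "/", t$loop, "/", t$class)
    }
    if (t$length < 1) stop("template loop_length must be >= 1")
    keys <- lapply(t$keys, function(k) {
      if (is.null(k$code) || is.null(k$allowed) || !nzchar(k$allowed)) {
        stop("malformed key-residue spec in template ", t$chain, "/", t$loop,
             "/", t$class)
      }
      list(code = as.character(k$code),
           allowed = strsplit(toupper(k$allowed), "")[[1]])
    })
    list(chain = t$chain, loop = t$loop, class = as.character(t$class),
         window = as.character(unlist(t$window)), length = as.integer(t$length),
         keys = keys)
  })
  ids <- vapply(tpls, function(t) paste(t$chain, t$loop, t$class), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate (chain, loop, class) template(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = "; "))
  }
  # all templates of one loop must agree on the measurement window
  for (lp in unique(vapply(tpls, `[[`, character(1), "loop"))) {
    wins <- unique(vapply(tpls[vapply(tpls, `[[`, character(1), "loop") == lp],
                          function(t) paste(t$window, collapse = "-"), character(1)))
    if (length(wins) > 1) stop("templates of loop ", lp, " disagree on the window")
  }
  structure(tpls, class = "canonical_templates")
}

#' @export
print.canonical_templates <- function(x, ...) {
  cat("canonical_templates:", length(x), "templates\n")
  for (t in x) {
    cat(sprintf("  %s %s class %s: window %s-%s, length %d, %d key(s)\n",
                t$chain, t$loop, t$class, t$window[1], t$window[2],
                t$length, length(t$keys)))
  }
  invisible(x)
}

#' @rdname load_templates
#' @param templates a `canonical_templates` object.
#' @param chain,loop,class template coordinates.
#' @return `template_length()`: the loop residue count of one template.
#' @export
template_length <- function(templates, chain, loop, class) {
  for (t in templates) {
    if (t$chain == chain && t$loop == loop && t$class == as.character(class)) {
      return(t$length)
    }
  }
  stop("no template for ", chain, "/", loop, "/", class)
}

loops_for_chain <- function(chain_type) {
  if (chain_type == "heavy") c("H1", "H2") else c("L1", "L2", "L3")
}

loop_window <- function(templates, chain_type, loop) {
  for (t in templates) if (t$chain == chain_type && t$loop == loop) return(t$window)
  stop("no templates for loop ", loop, " of chain ", chain_type)
}

measure_loop_length <- function(nc, window) {
  s <- kabat_number(window[1])
  e <- kabat_number(window[2])
  base <- kabat_number(nc$codes)
  sum(base >= s & base <= e)
}

#' Assign canonical classes to the CDR loops of a chain
#'
#' Strict Chothia SDR template matching: for each loop the Chothia-style loop
#' length is measured over the template window; if no template of that loop
#' has the observed length the loop is labelled `"X"` (no canonical class of
#' that length is known); otherwise the unique length-compatible template
#' whose key residues all match gives the class, and a single violated key
#' residue disqualifies a template. Length-compatible templates all violated
#' yield `"unmatched"` (optionally collapsed into `"X"`, the convention used
#' when non-classified loops are not reported separately). CDR H3 is never
#' classified.
#'
#' @param nc a [number_chain()] result.
#' @param ra the matching [annotate_regions()] result (retained for the loop
#'   length bookkeeping recorded in the evidence).
#' @param templates a [load_templates()] set.
#' @param collapse_unmatched if `TRUE`, report `"unmatched"` loops as `"X"`.
#' @return an object of class `canonical_assignment`: `labels` (named by
#'   loop), `lengths` (observed loop lengths over the template windows) and
#'   `evidence` (per loop: candidates considered and key-residue violations).
#' @export
assign_canonical <- function(nc, ra, templates = load_templates(),
                             collapse_unmatched = FALSE) {
  stopifnot(inherits(nc, "numbered_chain"), inherits(ra, "region_annotation"))
  loops <- loops_for_chain(nc$chain_type)
  labels <- character(0)
  lengths <- integer(0)
  evidence <- list()
  code_res <- setNames(nc$residues, nc$codes)
  for (lp in loops) {
    window <- loop_window(templates, nc$chain_type, lp)
    len <- measure_loop_length(nc, window)
    cands <- Filter(function(t) t$chain == nc$chain_type && t$loop == lp &&
                      t$length == len, templates)
    ev <- list(observed_length = len, candidates = character(0),
               violations = list())
    if (length(cands) == 0) {
      label <- "X"
    } else {
      matched <- character(0)
      for (t in cands) {
        ev$candidates <- c(ev$candidates, t$class)
        viol <- list()
        for (k in t$keys) {
          res <- unname(code_res[k$code])
          if (is.na(res) || !(res %in% k$allowed)) {
            viol[[length(viol) + 1]] <- list(code = k$code,
                                             residue = if (is.na(res)) "-" else res,
                                             allowed = paste(k$allowed, collapse = ""))
          }
        }
        if (length(viol) == 0) {
          matched <- c(matched, t$class)
        } else {
          ev$violations[[t$class]] <- viol
        }
      }
      if (length(matched) > 1) {
        stop("ambiguous template set for ", nc$chain_type, " ", lp,
             " at length ", len, ": classes ", paste(matched, collapse = ", "),
             " all match")
      }
      label <- if (length(matched) == 1) matched else "unmatched"
    }
    if (collapse_unmatched && label == "unmatched") label <- "X"
    labels[lp] <- label
    lengths[lp] <- len
    evidence[[lp]] <- ev
  }
  structure(list(chain_type = nc$chain_type, labels = labels,
                 lengths = lengths, evidence = evidence),
            class = "canonical_assignment")
}

#' @export
print.canonical_assignment <- function(x, ...) {
  cat(sprintf("canonical_assignment (%s): %s\n", x$chain_type,
              paste(names(x$labels), x$labels, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Canonical combination strings
#'
#' Joins per-loop class labels into the combination strings used to tabulate
#' repertoires: `"h1-h2"` for the heavy chain and `"l1-l2-l3"` for the light
#' chain (e.g. `"1-1"` and `"6-1-X"`). `"unmatched"` labels propagate into the
#' combination and are counted as their own category.
#'
#' @param ca_heavy,ca_light [assign_canonical()] results for the two chains.
#' @return a list with `heavy` and `light` combination strings (an element is
#'   `NA` when the corresponding assignment is `NULL`).
#' @export
canonical_combination <- function(ca_heavy = NULL, ca_light = NULL) {
  comb <- function(ca) {
    if (is.null(ca)) return(NA_character_)
    stopifnot(inherits(ca, "canonical_assignment"))
    paste(ca$labels, collapse = "-")
  }
  list(heavy = comb(ca_heavy), light = comb(ca_light))
}
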