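normalize_weights <- function(w, what) {
  if (is.null(w) || length(w) == 0) stop("empty weight vector for ", what)
  w <- unlist(w)
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights for ", what)
  w / sum(w)
}

#' Configuration of one synthetic library
#'
#' Bundles everything the generator needs to emulate one immunized-sheep
#' scFv library: pre-selection chain counts, canonical-combination mixtures
#' for heavy (`"h1-h2"`) and lambda (`"l1-l2-l3"`) chains, a CDR-H3 Kabat
#' length distribution, the loop-length distribution used when a combination
#' carries an `"X"` L3 label, per-region substitution rates, and the
#' post-selection panel design with optionally planted conserved positions.
#' Mixture and length values are weights and are normalized to probabilities.
#'
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @param library_id library name used in clone ids.
#' @param n_pre_heavy,n_pre_lambda pre-selection chain counts.
#' @param heavy_mixture,lambda_mixture named weights over canonical
#'   combination strings; lambda combinations may carry `"X"` as the L3 label.
#' @param h3_lengths named weights over Kabat CDR-H3 lengths.
#' @param l3_x_lengths named weights over L3 loop lengths drawn for `"X"`
#'   combinations; every length must be absent from the L3 template set.
#' @param fw_rate,cdr_rate per-site substitution probabilities in framework
#'   and CDR positions.
#' @param post_panels list of `list(target =, n_clones =)` panels.
#' @param post_copies copies emitted per post-selection founder.
#' @param planted_conserved `list(mode = "identical"|"group", heavy = codes,
#'   lambda = codes)`: positions overwritten in every post clone with the
#'   pre-selection consensus residue (or a residue from its biophysical
#'   group).
#' @param templates a [load_templates()] set used to size the canonical loops.
#' @param linker scFv linker peptide.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed, library_id = "lib1",
                             n_pre_heavy = 110, n_pre_lambda = 80,
                             heavy_mixture = c("1-1" = 97.3, "2-4" = 1, "1-4" = 1),
                             lambda_mixture = c("6-1-X" = 51.3, "2-1-5" = 11.2,
                                                "6-1-5" = 11.2, "2-1-X" = 10),
                             h3_lengths = c("14" = 14.5, "13" = 11.8,
                                            "12" = 10, "11" = 8.18),
                             l3_x_lengths = c("10" = 62.5, "12" = 10, "13" = 14),
                             fw_rate = 0.01, cdr_rate = 0.15,
                             post_panels = list(list(target = "SQA", n_clones = 6),
                                                list(target = "POR", n_clones = 3)),
                             post_copies = 2,
                             planted_conserved = list(mode = "identical",
                                                      heavy = character(0),
                                                      lambda = character(0)),
                             templates = load_templates(),
                             linker = scfv_linker()) {
  if (missing(seed) || is.null(seed)) stop("an explicit integer seed is required")
  seed <- as.integer(seed)
  stopifnot(n_pre_heavy >= 0, n_pre_lambda >= 0)
  heavy_mixture <- normalize_weights(heavy_mixture, "heavy_mixture")
  lambda_mixture <- normalize_weights(lambda_mixture, "lambda_mixture")
  h3_lengths <- normalize_weights(h3_lengths, "h3_lengths")
  l3_x_lengths <- normalize_weights(l3_x_lengths, "l3_x_lengths")
  # every non-X class in a mixture must exist in the template set
  for (combo in names(heavy_mixture)) {
    cls <- strsplit(combo, "-")[[1]]
    if (length(cls) != 2 || any(cls == "X")) {
      stop("heavy combination '", combo, "' must be two template classes")
    }
    template_length(templates, "heavy", "H1", cls[1])
    template_length(templates, "heavy", "H2", cls[2])
  }
  for (combo in names(lambda_mixture)) {
    cls <- strsplit(combo, "-")[[1]]
    if (length(cls) != 3 || any(cls[1:2] == "X")) {
      stop("lambda combination '", combo,
           "' must be L1-L2-L3 with template classes for L1 and L2")
    }
    template_length(templates, "lambda", "L1", cls[1])
    template_length(templates, "lambda", "L2", cls[2])
    if (cls[3] != "X") template_length(templates, "lambda", "L3", cls[3])
  }
  l3_tpl_lens <- vapply(Filter(function(t) t$chain == "lambda" && t$loop == "L3",
                               templates), `[[`, integer(1), "length")
  bad <- intersect(as.integer(names(l3_x_lengths)), l3_tpl_lens)
  if (length(bad)) {
    stop("l3_x_lengths contain template lengths (not class X): ",
         paste(bad, collapse = ", "))
  }
  planted_conserved$mode <- match.arg(planted_conserved$mode %||% "identical",
                                      c("identical", "group"))
  for (chain in c("heavy", "lambda")) {
    codes <- planted_conserved[[chain]] %||% character(0)
    ref <- kabat_reference(chain)
    if (!all(codes %in% ref$codes)) {
      stop("planted conserved codes absent from the ", chain, " reference: ",
           paste(setdiff(codes, ref$codes), collapse = ", "))
    }
    planted_conserved[[chain]] <- codes
  }
  if (post_copies < 1) stop("post_copies must be >= 1")
  for (p in post_panels) {
    if (is.null(p$target) || !nzchar(p$target) || is.null(p$n_clones)) {
      stop("each post panel needs a target and n_clones")
    }
  }
  structure(list(seed = seed, library_id = library_id,
                 n_pre_heavy = as.integer(n_pre_heavy),
                 n_pre_lambda = as.integer(n_pre_lambda),
                 heavy_mixture = heavy_mixture, lambda_mixture = lambda_mixture,
                 h3_lengths = h3_lengths, l3_x_lengths = l3_x_lengths,
                 fw_rate = fw_rate, cdr_rate = cdr_rate,
                 post_panels = post_panels, post_copies = as.integer(post_copies),
                 planted_conserved = planted_conserved,
                 templates = templates, linker = linker),
            class = "synthetic_config")
}

template_keys_map <- function(templates, chain, classes) {
  # classes: named by loop, "X" entries contribute no keys
  out <- list()
  for (lp in names(classes)) {
    cl <- classes[[lp]]
    if (cl == "X") next
    for (t in templates) {
      if (t$chain == chain && t$loop == lp && t$class == cl) {
        for (k in t$keys) out[[k$code]] <- k$allowed
      }
    }
  }
  out
}

# construct a chain from the reference with its variable loops resized to the
# target Kabat CDR residue counts; inserted positions get random residues
build_synthetic_chain <- function(chain_type, cdr_counts) {
  ref <- kabat_reference(chain_type)
  win <- kabat_windows(chain_type)
  codes <- ref$codes
  residues <- ref$residues
  # heavy windows map to CDR1..CDR3 in order; lambda windows to CDR1, CDR3
  cdr_ids <- if (chain_type == "heavy") c("CDR1", "CDR2", "CDR3") else c("CDR1", "CDR3")
  for (wi in seq_along(win$windows)) {
    w <- win$windows[[wi]]
    k <- cdr_counts[[cdr_ids[wi]]]
    new_codes <- window_codes(w["s"], w["e"], w["a"], k)
    ref_idx <- match(new_codes, ref$codes)
    new_res <- ref$residues[ref_idx]
    nas <- is.na(ref_idx)
    if (any(nas)) new_res[nas] <- sample(AA_STANDARD, sum(nas), replace = TRUE)
    inside <- kabat_number(codes) >= w["s"] & kabat_number(codes) <= w["e"]
    codes <- c(codes[!inside], new_codes)
    residues <- c(residues[!inside], new_res)
    ord <- kabat_order(codes)
    codes <- codes[ord]
    residues <- residues[ord]
  }
  list(codes = codes, residues = residues)
}

mutate_chain <- function(codes, residues, chain_type, fw_rate, cdr_rate, key_map) {
  region <- region_of_codes(codes, chain_type)
  rate <- ifelse(grepl("^CDR", region), cdr_rate, fw_rate)
  hit <- which(runif(length(codes)) < rate)
  n_mut <- 0L
  for (i in hit) {
    allowed <- key_map[[codes[i]]]
    pool <- if (!is.null(allowed)) setdiff(allowed, residues[i])
            else setdiff(AA_STANDARD, residues[i])
    if (length(pool)) {
      residues[i] <- sample(pool, 1)
      n_mut <- n_mut + 1L
    }
  }
  list(residues = residues, n_mut = n_mut)
}

sample_category <- function(prob_vec) {
  sample(names(prob_vec), 1, prob = prob_vec)
}

generate_one_chain <- function(cfg, chain_type) {
  tpl <- cfg$templates
  if (chain_type == "heavy") {
    combo <- sample_category(cfg$heavy_mixture)
    cls <- strsplit(combo, "-")[[1]]
    classes <- c(H1 = cls[1], H2 = cls[2])
    h3 <- as.integer(sample_category(cfg$h3_lengths))
    cdr_counts <- list(
      CDR1 = template_length(tpl, "heavy", "H1", cls[1]) - 5L,  # window 26-35 spans FW 26-30
      CDR2 = 16L + (template_length(tpl, "heavy", "H2", cls[2]) - 9L),
      CDR3 = h3)
  } else {
    combo <- sample_category(cfg$lambda_mixture)
    cls <- strsplit(combo, "-")[[1]]
    classes <- c(L1 = cls[1], L2 = cls[2], L3 = cls[3])
    l3 <- if (cls[3] == "X") as.integer(sample_category(cfg$l3_x_lengths))
          else template_length(tpl, "lambda", "L3", cls[3])
    cdr_counts <- list(
      CDR1 = template_length(tpl, "lambda", "L1", cls[1]),
      CDR2 = template_length(tpl, "lambda", "L2", cls[2]),
      CDR3 = l3)
  }
  built <- build_synthetic_chain(chain_type, cdr_counts)
  keys <- template_keys_map(cfg$templates, chain_type, classes)
  mut <- mutate_chain(built$codes, built$residues, chain_type,
                      cfg$fw_rate, cfg$cdr_rate, keys)
  list(seq = paste(mut$residues, collapse = ""), combo = combo,
       classes = classes, cdr_lengths = unlist(cdr_counts), n_mut = mut$n_mut)
}

#' Generate a synthetic pre-selection library
#'
#' Draws each chain by sampling a canonical combination from the configured
#' mixture, resizing the reference scaffold's loops to the class lengths
#' (CDR H3, and the L3 length of `"X"` combinations, from their own length
#' distributions), and applying per-site substitutions at the region rates;
#' canonical key residues only ever mutate within their allowed sets, so
#' planted class labels survive mutation. Heavy and lambda pre-selection
#' chains are generated unpaired, mirroring independently sequenced chain
#' pools.
#'
#' @param cfg a [synthetic_config()].
#' @return a list with `clones` (a [clone_set()]) and `truth` (per-clone
#'   ground truth: combination, classes, CDR lengths, mutation count).
#' @export
generate_pre_library <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  rows <- list()
  truth <- list()
  for (i in seq_len(cfg$n_pre_heavy)) {
    g <- generate_one_chain(cfg, "heavy")
    id <- sprintf("%s-preH-%03d", cfg$library_id, i)
    rows[[length(rows) + 1]] <- data.frame(
      clone_id = id, library_id = cfg$library_id, phase = "pre", target = "",
      heavy_seq = g$seq, light_seq = "", light_isotype = "lambda",
      stringsAsFactors = FALSE)
    truth[[id]] <- g[c("combo", "classes", "cdr_lengths", "n_mut")]
    truth[[id]]$chain <- "heavy"
  }
  for (i in seq_len(cfg$n_pre_lambda)) {
    g <- generate_one_chain(cfg, "lambda")
    id <- sprintf("%s-preL-%03d", cfg$library_id, i)
    rows[[length(rows) + 1]] <- data.frame(
      clone_id = id, library_id = cfg$library_id, phase = "pre", target = "",
      heavy_seq = "", light_seq = g$seq, light_isotype = "lambda",
      stringsAsFactors = FALSE)
    truth[[id]] <- g[c("combo", "classes", "cdr_lengths", "n_mut")]
    truth[[id]]$chain <- "lambda"
  }
  if (length(rows) == 0) stop("config generates no pre-selection chains")
  clones <- clone_set(do.call(rbind, rows),
                      provenance = sprintf("synthetic pre-selection library %s (seed %d)",
                                           cfg$library_id, cfg$seed))
  list(clones = clones, truth = list(clones = truth,
                                     planted_conserved = cfg$planted_conserved))
}

#' Simulate phage-display selection from a pre-selection library
#'
#' Samples post-selection founder clones from the pre-selection pool (biased
#' toward scaffold-faithful chains: sampling weight halves per accumulated
#' substitution when ground truth is supplied), pairs a heavy with a lambda
#' founder per clone, overwrites the planted conserved positions with the
#' pre-selection consensus residue (mode `"identical"`) or a residue from its
#' biophysical group (mode `"group"`), and replicates each founder
#' `post_copies` times without further mutation.
#'
#' @param pre the pre-selection [clone_set()].
#' @param cfg the [synthetic_config()].
#' @param truth optional ground truth from [generate_pre_library()] (enables
#'   faithfulness weighting and class inheritance).
#' @param scheme biophysical scheme used for mode `"group"`.
#' @return a list with `clones` (post [clone_set()]) and `truth` (founder
#'   map, planted positions, inherited classes).
#' @export
simulate_selection <- function(pre, cfg, truth = NULL,
                               scheme = load_biophysical_scheme()) {
  stopifnot(inherits(pre, "clone_set"), inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  n_post <- sum(vapply(cfg$post_panels, `[[`, numeric(1), "n_clones"))
  if (n_post == 0) {
    warning("post panel of size 0 requested; returning an empty selection")
    return(list(clones = NULL, truth = list(founders = character(0),
                                            planted_conserved = cfg$planted_conserved)))
  }
  heavy_ids <- pre$clone_id[nzchar(pre$heavy_seq)]
  lambda_ids <- pre$clone_id[nzchar(pre$light_seq)]
  if (n_post > length(heavy_ids) || n_post > length(lambda_ids)) {
    stop("n_post_clones (", n_post, ") exceeds the distinct founders available")
  }
  weight_of <- function(ids) {
    if (is.null(truth)) return(rep(1, length(ids)))
    vapply(ids, function(id) 2^-(truth$clones[[id]]$n_mut %||% 0), numeric(1))
  }
  founders_h <- sample(heavy_ids, n_post, prob = weight_of(heavy_ids))
  founders_l <- sample(lambda_ids, n_post, prob = weight_of(lambda_ids))

  pre_num_h <- number_clone_set(pre, "heavy")
  pre_num_l <- number_clone_set(pre, "lambda")
  cons <- list(heavy = consensus(pre, "heavy", numbered = pre_num_h),
               lambda = consensus(pre, "lambda", numbered = pre_num_l))

  plant <- function(nc, chain) {
    planted <- cfg$planted_conserved[[chain]]
    for (code in planted) {
      i <- match(code, nc$codes)
      if (is.na(i)) {
        warning("planted position ", code, " absent from a ", chain, " founder")
        next
      }
      ref_res <- cons[[chain]][[code]]
      if (is.null(ref_res) || is.na(ref_res)) next
      nc$residues[i] <- if (cfg$planted_conserved$mode == "identical") ref_res
                        else sample(scheme[[biophysical_group(ref_res, scheme)]], 1)
    }
    paste(nc$residues, collapse = "")
  }

  targets <- unlist(lapply(cfg$post_panels, function(p) rep(p$target, p$n_clones)))
  rows <- list()
  founder_map <- list()
  per_target_idx <- list()
  for (f in seq_len(n_post)) {
    tgt <- targets[f]
    per_target_idx[[tgt]] <- (per_target_idx[[tgt]] %||% 0L) + 1L
    hseq <- plant(pre_num_h[[founders_h[f]]], "heavy")
    lseq <- plant(pre_num_l[[founders_l[f]]], "lambda")
    base_id <- sprintf("%s-%s-%d", cfg$library_id, tgt, per_target_idx[[tgt]])
    for (cp in seq_len(cfg$post_copies)) {
      id <- if (cp == 1) base_id else sprintf("%s.%d", base_id, cp)
      rows[[length(rows) + 1]] <- data.frame(
        clone_id = id, library_id = cfg$library_id, phase = "post",
        target = tgt, heavy_seq = hseq, light_seq = lseq,
        light_isotype = "lambda", stringsAsFactors = FALSE)
    }
    founder_map[[base_id]] <- list(
      heavy_founder = founders_h[f], lambda_founder = founders_l[f],
      heavy_combo = truth$clones[[founders_h[f]]]$combo,
      lambda_combo = truth$clones[[founders_l[f]]]$combo)
  }
  clones <- clone_set(do.call(rbind, rows),
                      provenance = sprintf("synthetic post-selection panel %s (seed %d)",
                                           cfg$library_id, cfg$seed))
  list(clones = clones,
       truth = list(founders = founder_map,
                    planted_conserved = cfg$planted_conserved))
}

#' Emulate the full three-library study design
#'
#' Reads a study-design YAML (defaults to the built-in three-library design:
#' 110+80, 77+30 and 196+95 pre-selection heavy+lambda chains with post
#' panels of 6/3, 8 and 6 clones) and generates every library's pre- and
#' post-selection clone sets with ground truth.
#'
#' @param seed integer master seed; library i uses `seed + i - 1`.
#' @param config_path YAML design file, or `NULL` for the built-in design.
#' @param templates a [load_templates()] set.
#' @return a named list of libraries, each `list(config, pre, post,
#'   truth_pre, truth_post)`.
#' @export
emulate_study_design <- function(seed, config_path = NULL,
                                 templates = load_templates()) {
  if (missing(seed) || is.null(seed)) stop("an explicit integer seed is required")
  path <- config_path %||% panrep_extdata("table1_emulation.yaml")
  design <- yaml::read_yaml(path)
  out <- list()
  for (i in seq_along(design$libraries)) {
    lib <- design$libraries[[i]]
    cfg <- synthetic_config(
      seed = as.integer(seed) + i - 1L,
      library_id = lib$id,
      n_pre_heavy = lib$n_pre_heavy, n_pre_lambda = lib$n_pre_lambda,
      heavy_mixture = unlist(lib$heavy_mixture),
      lambda_mixture = unlist(lib$lambda_mixture),
      h3_lengths = unlist(lib$h3_lengths),
      l3_x_lengths = unlist(lib$l3_x_lengths),
      fw_rate = design$mutation_rates$fw %||% 0.01,
      cdr_rate = design$mutation_rates$cdr %||% 0.15,
      post_panels = lib$post_panels,
      post_copies = design$post_copies %||% 2,
      planted_conserved = list(
        mode = if (identical(design$planted_conserved$mode, "identical"))
                 "identical" else "group",
        heavy = as.character(design$planted_conserved$heavy %||% character(0)),
        lambda = as.character(design$planted_conserved$lambda %||% character(0))),
      templates = templates,
      linker = design$linker %||% scfv_linker())
    pre <- generate_pre_library(cfg)
    post <- simulate_selection(pre$clones, cfg, truth = pre$truth)
    out[[lib$id]] <- list(config = cfg, pre = pre$clones, post = post$clones,
                          truth_pre = pre$truth, truth_post = post$truth)
  }
  out
}
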