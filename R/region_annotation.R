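#' Kabat framework/CDR boundary table
#'
#' Hard-coded Kabat region boundaries, exposed for audit: heavy CDR1 31-35,
#' CDR2 50-65, CDR3 95-102; lambda CDR1 24-34, CDR2 50-56, CDR3 89-97.
#' Codes carrying insertion letters belong to the region of their base number.
#'
#' @param chain_type `"heavy"` or `"lambda"`.
#' @return a data frame with columns `region`, `start`, `end`.
#' @export
kabat_region_boundaries <- function(chain_type = c("heavy", "lambda")) {
  chain_type <- match.arg(chain_type)
  if (chain_type == "heavy") {
    data.frame(region = c("FW1", "CDR1", "FW2", "CDR2", "FW3", "CDR3", "FW4"),
               start = c(1L, 31L, 36L, 50L, 66L, 95L, 103L),
               end = c(30L, 35L, 49L, 65L, 94L, 102L, 113L))
  } else {
    data.frame(region = c("FW1", "CDR1", "FW2", "CDR2", "FW3", "CDR3", "FW4"),
               start = c(1L, 24L, 35L, 50L, 57L, 89L, 98L),
               end = c(23L, 34L, 49L, 56L, 88L, 97L, 109L))
  }
}

region_of_codes <- function(codes, chain_type) {
  bounds <- kabat_region_boundaries(chain_type)
  base <- kabat_number(codes)
  idx <- findInterval(base, bounds$start)
  idx[idx < 1L] <- 1L          # codes before FW1 start (none in practice)
  factor(bounds$region[idx], levels = bounds$region)
}

#' Partition a numbered chain into framework and CDR regions
#'
#' Assigns every residue to exactly one of FW1-FW4 / CDR1-CDR3 under the Kabat
#' boundaries and records the residue count of each CDR. Regions the chain
#' does not reach are annotated empty with a warning.
#'
#' @param nc a [number_chain()] result.
#' @return an object of class `region_annotation`: list with `chain_type`,
#'   `codes`, `residues`, `region` (factor, one level per residue),
#'   `region_map` (region -> data frame of code/residue) and `cdr_lengths`.
#' @export
annotate_regions <- function(nc) {
  stopifnot(inherits(nc, "numbered_chain"))
  region <- region_of_codes(nc$codes, nc$chain_type)
  region_map <- lapply(split(seq_along(nc$codes), region), function(i) {
    data.frame(code = nc$codes[i], residue = nc$residues[i],
               stringsAsFactors = FALSE)
  })
  empty <- names(region_map)[vapply(region_map, nrow, integer(1)) == 0]
  if (length(empty)) {
    warning("chain has no residues in region(s): ", paste(empty, collapse = ", "))
  }
  cdrs <- c("CDR1", "CDR2", "CDR3")
  cdr_lengths <- vapply(region_map[cdrs], nrow, integer(1))
  structure(list(chain_type = nc$chain_type, codes = nc$codes,
                 residues = nc$residues, region = region,
                 region_map = region_map, cdr_lengths = cdr_lengths),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("region_annotation (%s): CDR lengths %s\n", x$chain_type,
              paste(names(x$cdr_lengths), x$cdr_lengths, sep = "=", collapse = ", ")))
  invisible(x)
}

#' CDR residue count
#'
#' Number of residues actually present in a CDR (absent Kabat numbers do not
#' count; insertion-lettered codes do).
#'
#' @param ra a [annotate_regions()] result.
#' @param cdr `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @return an integer count.
#' @export
cdr_length <- function(ra, cdr = c("CDR1", "CDR2", "CDR3")) {
  stopifnot(inherits(ra, "region_annotation"))
  cdr <- match.arg(cdr)
  unname(ra$cdr_lengths[[cdr]])
}
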