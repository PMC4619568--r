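#' Kabat position codes
#'
#' A Kabat code is a positive integer position optionally followed by a single
#' uppercase insertion letter (e.g. `"82C"`, `"95A"`). Codes order
#' lexicographically by (number, insertion letter) with the bare number
#' sorting before `"A"`.
#'
#' @param codes character vector of Kabat codes.
#' @return `kabat_number()` the integer part; `kabat_insertion()` the insertion
#'   letter (`""` when absent); `kabat_order()` an ordering permutation;
#'   `kabat_sort()` the sorted codes.
#' @examples
#' kabat_sort(c("100B", "95", "100", "82C", "82"))
#' @export
kabat_number <- function(codes) {
  as.integer(sub("([0-9]+)[A-Z]?$", "\\1", codes))
}

#' @rdname kabat_number
#' @export
kabat_insertion <- function(codes) {
  sub("^[0-9]+", "", codes)
}

kabat_valid <- function(codes) {
  grepl("^[0-9]+[A-Z]?$", codes)
}

# numeric sort key: number * 27 + insertion rank ("" = 0, A = 1, ...)
kabat_key <- function(codes) {
  ins <- kabat_insertion(codes)
  rank <- ifelse(ins == "", 0L, match(ins, LETTERS))
  kabat_number(codes) * 27 + rank
}

#' @rdname kabat_number
#' @export
kabat_order <- function(codes) {
  order(kabat_key(codes))
}

#' @rdname kabat_number
#' @export
kabat_sort <- function(codes) {
  codes[kabat_order(codes)]
}
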