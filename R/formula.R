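#' Parse a chemical formula in Hill notation
#'
#' Turns a formula string such as `"C6H12O6"` or `"C10H12N5O13P3"` into a
#' named numeric vector of element counts. An empty string denotes an
#' element-free pseudo-species (photons, electron carriers) and parses to an
#' empty vector; `NA` means the composition is unknown.
#'
#' Counts may be non-integer (lumped pseudo-compounds). Isotope markers and
#' R-groups are not supported and yield `NA` (unknown composition).
#'
#' @param x character vector of formula strings.
#' @return A list of named numeric vectors, one per input; `NA` entries of `x`
#'   give `NULL` elements.
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(x) {
  lapply(x, function(f) {
    if (is.na(f)) return(NULL)
    f <- trimws(f)
    if (f == "") return(setNames(numeric(0), character(0)))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f) || length(toks) == 0) {
      return(NULL) # unparseable -> unknown composition
    }
    el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
    ct <- sub("^[A-Z][a-z]?", "", toks)
    ct <- ifelse(ct == "", 1, suppressWarnings(as.numeric(ct)))
    if (anyNA(ct)) return(NULL)
    tapply(ct, el, sum)[unique(el)]
  })
}

# count of one element across a vector of formulas (NA where unknown)
element_count <- function(formulas, element) {
  vapply(parse_formula(formulas), function(p) {
    if (is.null(p)) return(NA_real_)
    if (element %in% names(p)) p[[element]] else 0
  }, numeric(1))
}
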