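#' Component catalog
#'
#' A catalog of the elementary components that make up the complex
#' interventions of a network. Every treatment in a component network
#' meta-analysis is a combination (set) of catalog components, and the
#' catalog order fixes the column order of all design matrices, so results
#' are reproducible across runs.
#'
#' Codes are case-insensitive on input and stored lower-case.
#'
#' @param codes character vector of short component identifiers
#'   (e.g. \code{"wl"}, \code{"pl"}, \code{"ftf"}).
#' @param descriptions optional character vector of free-text descriptions,
#'   same length as \code{codes}.
#' @return an object of class \code{component_catalog}: a character vector of
#'   normalized codes with an optional \code{descriptions} attribute.
#' @examples
#' cat6 <- component_catalog(c("c1", "c2", "c3", "c4", "c5", "c6"))
#' @export
component_catalog <- function(codes, descriptions = NULL) {
  if (length(codes) == 0L) stop("catalog must contain at least one component code")
  codes <- tolower(trimws(as.character(codes)))
  if (any(!nzchar(codes))) stop("catalog codes must be non-empty")
  if (anyDuplicated(codes)) {
    stop("duplicated component code(s) in catalog: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  if (!is.null(descriptions) && length(descriptions) != length(codes)) {
    stop("descriptions must match codes in length")
  }
  structure(codes, descriptions = descriptions, class = "component_catalog")
}

#' @export
print.component_catalog <- function(x, ...) {
  cat("Component catalog (", length(x), " components):\n  ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Parse a treatment-combination label
#'
#' Treatment labels are \code{"+"}-separated component codes, e.g.
#' \code{"pl + ftf + pe + ps + ive"}. Whitespace around codes is ignored and
#' codes are matched case-insensitively against the catalog. The returned
#' combination is in canonical (catalog) order.
#'
#' @param label a single character string.
#' @param catalog a \code{\link{component_catalog}}.
#' @return an object of class \code{treatment_combination}: a character
#'   vector of member codes in catalog order.
#' @examples
#' cat12 <- component_catalog(c("wl", "pl", "ftf", "pe", "ps", "br", "mr",
#'                              "ive", "ine", "vre", "cr", "w3"))
#' parse_combination("pl + ftf + pe + ps + ive", cat12)
#' @export
parse_combination <- function(label, catalog) {
  stopifnot(inherits(catalog, "component_catalog"), length(label) == 1L)
  label <- trimws(as.character(label))
  if (!nzchar(label)) stop("combination label is empty")
  toks <- tolower(trimws(strsplit(label, "+", fixed = TRUE)[[1L]]))
  if (any(!nzchar(toks))) stop("empty component token in label '", label, "'")
  unknown <- setdiff(toks, unclass(catalog))
  if (length(unknown)) {
    stop("unknown component code(s) in '", label, "': ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(toks)) {
    stop("duplicated component code(s) in '", label, "': ",
         paste(unique(toks[duplicated(toks)]), collapse = ", "))
  }
  members <- unclass(catalog)[unclass(catalog) %in% toks]
  structure(members, class = "treatment_combination")
}

#' Canonical label of a treatment combination
#'
#' @param combo a \code{treatment_combination} (or character vector of codes
#'   already in canonical order).
#' @return the canonical \code{" + "}-joined label.
#' @export
combination_label <- function(combo) {
  paste(unclass(combo), collapse = " + ")
}

#' @export
print.treatment_combination <- function(x, ...) {
  cat("<", combination_label(x), ">\n", sep = "")
  invisible(x)
}

#' @export
format.treatment_combination <- function(x, ...) combination_label(x)

# Internal: accept either a label string or a parsed combination.
as_combination <- function(x, catalog) {
  if (inherits(x, "treatment_combination")) return(x)
  parse_combination(x, catalog)
}
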