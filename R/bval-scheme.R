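#' Diffusion-weighting scheme (b values and NEX)
#'
#' A `bvalue_scheme` records the diffusion-weighting protocol of a multi-b
#' DWI acquisition: the b values in s/mm\eqn{^2} and the number of
#' excitations (NEX) averaged at each b. The default scheme is the 12-b
#' breast protocol used throughout this package: b = 0, 10, 20, 30, 50, 70,
#' 100, 150, 200, 400, 800, 1000 s/mm\eqn{^2} with NEX
#' 1, 3, 3, 3, 3, 2, 2, 2, 2, 3, 5, 6.
#'
#' @param b_values Numeric vector of b values in s/mm\eqn{^2}, strictly
#'   increasing, starting at 0.
#' @param nex Positive integer vector of excitation counts, one per b value
#'   (recycled if length 1).
#'
#' @return An object of class `bvalue_scheme`: a list with elements
#'   `b_values` and `nex`.
#' @examples
#' sch <- default_scheme()
#' sch$b_values
#' @export
bvalue_scheme <- function(b_values, nex = 1L) {
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2L) {
    abort("`b_values` must contain at least two b values.")
  }
  if (b_values[1L] != 0) {
    abort("The first b value must be 0 (the unweighted acquisition).")
  }
  if (any(diff(b_values) <= 0)) {
    abort("`b_values` must be strictly increasing.")
  }
  if (length(nex) == 1L) nex <- rep(nex, length(b_values))
  nex <- as.integer(nex)
  if (length(nex) != length(b_values) || any(is.na(nex)) || any(nex < 1L)) {
    abort("`nex` must supply one integer >= 1 per b value.")
  }
  structure(list(b_values = b_values, nex = nex), class = "bvalue_scheme")
}

#' @rdname bvalue_scheme
#' @export
default_scheme <- function() {
  bvalue_scheme(
    b_values = c(0, 10, 20, 30, 50, 70, 100, 150, 200, 400, 800, 1000),
    nex      = c(1L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 3L, 5L, 6L)
  )
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("<bvalue_scheme> ", length(x$b_values), " b values (s/mm^2)\n", sep = "")
  print(data.frame(b = x$b_values, nex = x$nex), row.names = FALSE)
  invisible(x)
}

#' @export
length.bvalue_scheme <- function(x) length(x$b_values)

#' Read and write FSL-style bval files
#'
#' A bval file holds one whitespace-separated line of b values. Because the
#' bval dialect has no slot for excitation counts, the NEX vector travels in
#' a YAML sidecar with a single `nex` entry.
#'
#' @param path Path to the bval text file.
#' @param nex_path Optional path to the YAML sidecar holding `nex:`; when
#'   missing on read, NEX defaults to 1 everywhere.
#' @param scheme A [bvalue_scheme].
#' @return `read_bval()` returns a [bvalue_scheme]; the writers return the
#'   primary path invisibly.
#' @export
read_bval <- function(path, nex_path = NULL) {
  b <- scan(path, what = numeric(), quiet = TRUE)
  nex <- 1L
  if (!is.null(nex_path) && file.exists(nex_path)) {
    side <- yaml::read_yaml(nex_path)
    if (!is.null(side$nex)) nex <- as.integer(side$nex)
  }
  bvalue_scheme(b, nex)
}

#' @rdname read_bval
#' @export
write_bval <- function(scheme, path, nex_path = NULL) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  writeLines(paste(format(scheme$b_values, trim = TRUE), collapse = " "), path)
  if (!is.null(nex_path)) {
    yaml::write_yaml(list(nex = scheme$nex), nex_path)
  }
  invisible(path)
}
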