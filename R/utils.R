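#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages so that
#' e.g. 10.455 renders as 10.46. R's own \code{round()} rounds half to even,
#' which disagrees with how identification rates are conventionally tabulated.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return \code{x} rounded half away from zero to \code{digits} places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Ingroup specimen ids of a dataset
#'
#' @param dataset a \code{barcode_dataset}.
#' @return character vector of specimen ids not listed as outgroup.
#' @export
ingroup_ids <- function(dataset) {
  stopifnot(inherits(dataset, "barcode_dataset"))
  setdiff(dataset$records$specimen_id, dataset$outgroup_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer draws from an inclusive range; safe when lo == hi
.rint <- function(n, lo, hi) {
  if (lo > hi) stop("invalid range [", lo, ", ", hi, "]")
  if (lo == hi) return(rep.int(as.integer(lo), n))
  sample(seq.int(lo, hi), n, replace = TRUE)
}
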