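#' Min-max normalization to [-1, 1]
#'
#' Column-wise affine map onto [-1, 1] by per-column minimum and maximum,
#' the scaling under which the network's error goals are defined.  The
#' parameters are fitted once (on training data) and applied or inverted
#' elsewhere, so test data never influence the scaling.
#'
#' @param x numeric matrix (or data.frame of numeric columns).
#' @return an object of class `minmax` holding per-column `min` and `max`.
#' @export
minmax_fit <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  bad <- !(hi > lo)
  if (any(bad))
    stop("constant column(s) cannot be normalized: ",
         paste(colnames(x)[bad] %||% which(bad), collapse = ", "))
  structure(list(min = lo, max = hi), class = "minmax")
}

#' @rdname minmax_fit
#' @param nm a fitted `minmax` object.
#' @export
minmax_apply <- function(nm, x) {
  x <- as.matrix(x)
  stopifnot(inherits(nm, "minmax"), ncol(x) == length(nm$min))
  sweep(sweep(x, 2L, (nm$min + nm$max) / 2), 2L, (nm$max - nm$min) / 2, "/")
}

#' @rdname minmax_fit
#' @export
minmax_invert <- function(nm, x) {
  x <- as.matrix(x)
  stopifnot(inherits(nm, "minmax"), ncol(x) == length(nm$min))
  sweep(sweep(x, 2L, (nm$max - nm$min) / 2, "*"), 2L, (nm$min + nm$max) / 2, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
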