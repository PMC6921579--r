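# Grayscale morphology with a disc structuring element, used for the
# background estimate (morphological opening, the flat-disc equivalent of
# rolling-ball background subtraction). The disc is decomposed into its
# horizontal chords; each chord min/max is a centred running window
# computed with sparse-table doubling (O(log width) shifted pmin/pmax
# passes), and the chord results are folded over the disc rows. Pixels
# outside the image are ignored (in-bounds semantics), so a spatially
# uniform image is a fixed point of both erosion and dilation.

# Running min/max over a centred window of half-width l along columns.
# The matrix is padded with l neutral columns per side; start-anchored
# windows of length 2l+1 on the padded matrix are centred windows on the
# original. Doubling builds op over spans of length p (largest power of
# two <= 2l+1); two overlapping spans cover the full window.
lineFilter <- function(m, l, op) {
  if (l <= 0L) return(m)
  fill <- if (identical(op, pmin)) Inf else -Inf
  n <- ncol(m)
  L <- 2L * l + 1L
  pad <- matrix(fill, nrow(m), l)
  g <- cbind(pad, m, pad)
  p <- 1L
  while (2L * p <= L) {
    g <- op(g, colShift(g, p, fill))
    p <- 2L * p
  }
  W <- op(g, colShift(g, L - p, fill))
  W[, seq_len(n), drop = FALSE]
}

discFilter <- function(m, r, op) {
  if (r <= 0L) return(m)
  fill <- if (identical(op, pmin)) Inf else -Inf
  dys <- -r:r
  lxs <- as.integer(floor(sqrt(r^2 - dys^2) + 1e-9))
  cache <- new.env(parent = emptyenv())
  out <- NULL
  for (i in seq_along(dys)) {
    key <- as.character(lxs[i])
    if (is.null(cache[[key]])) cache[[key]] <- lineFilter(m, lxs[i], op)
    shifted <- rowShift(cache[[key]], dys[i], fill)
    out <- if (is.null(out)) shifted else op(out, shifted)
  }
  out
}

#' Grayscale erosion, dilation and opening with a disc
#'
#' Flat grayscale morphology over a disc of radius \code{r} pixels.
#' Border pixels use only the in-bounds part of the disc, so constant
#' images are unchanged.
#'
#' @param m numeric matrix.
#' @param r integer disc radius in pixels.
#' @return a matrix of the same dimensions.
#' @export
erodeDisc <- function(m, r) discFilter(m, as.integer(r), pmin)

#' @rdname erodeDisc
#' @export
dilateDisc <- function(m, r) discFilter(m, as.integer(r), pmax)

#' @rdname erodeDisc
#' @export
openDisc <- function(m, r) dilateDisc(erodeDisc(m, r), r)
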