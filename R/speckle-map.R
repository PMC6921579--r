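# Generalized differences: per-pixel sum of absolute grey-level
# differences over all frame pairs of a burst. Computed via the sorted
# value identity sum_{k<l} |a_k - a_l| = sum_j (2j - 1 - T) a_(j),
# which is O(T log T) per pixel instead of O(T^2).

#' Generalized differences activity map
#'
#' Reduces a frame burst to a single 2D map of dynamic-speckle activity.
#' For each pixel p, the generalized differences are
#' \deqn{GD(p) = \sum_{k < l} |I_k(p) - I_l(p)|}
#' over all T(T-1)/2 frame pairs. With the default \code{"mean_pair"}
#' normalization the sum is divided by the number of pairs, keeping values
#' on the grey-level scale so that grey-level detection thresholds remain
#' meaningful; \code{"sum"} returns the raw sum. Identical frames give an
#' exactly zero map and the result is invariant to frame order.
#'
#' @param stack a \linkS4class{FrameStack} (T >= 2 frames).
#' @param normalization \code{"mean_pair"} (default) or \code{"sum"}.
#' @return an \linkS4class{ActivityMap}.
#' @examples
#' fr <- array(rep(c(10, 50), each = 16), dim = c(4, 4, 2))
#' st <- new("FrameStack", frames = fr, stepIndex = 0L, bitDepth = 8L)
#' range(activityValues(generalizedDifferences(st)))  # 40 everywhere
#' @export
generalizedDifferences <- function(stack,
                                   normalization = c("mean_pair", "sum")) {
  stopifnot(is(stack, "FrameStack"))
  normalization <- match.arg(normalization)
  d <- dim(stack@frames)
  nT <- d[3]
  if (nT < 2L) stop("insufficient frames: generalized differences need T >= 2")
  m <- matrix(stack@frames, d[1] * d[2], nT)
  srt <- rowSort(m)
  wts <- 2 * seq_len(nT) - 1 - nT
  gd <- as.vector(srt %*% wts)
  if (normalization == "mean_pair") gd <- gd / (nT * (nT - 1) / 2)
  # exact-zero guard: identical frames must give exactly 0
  gd[gd < 0] <- 0
  new("ActivityMap", values = matrix(gd, d[1], d[2]),
      stepIndex = stack@stepIndex, normalization = normalization)
}
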