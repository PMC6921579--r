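# Internal helpers: structured logging, boundary-index arithmetic and
# shifted matrix views shared by the filtering code.

#' Structured log line
#'
#' Emits a structured log line (module, sample, step, message) via
#' \code{message()}. Silent unless \code{options(bspim.verbose = TRUE)}.
#'
#' @param module character module name.
#' @param msg character message.
#' @param sampleId optional sample identifier.
#' @param step optional step index.
#' @export
bspimLog <- function(module, msg, sampleId = NULL, step = NULL) {
  if (!isTRUE(getOption("bspim.verbose", FALSE))) return(invisible(NULL))
  parts <- sprintf("[bspim][%s]", module)
  if (!is.null(sampleId)) parts <- paste0(parts, sprintf(" sample=%s", sampleId))
  if (!is.null(step)) parts <- paste0(parts, sprintf(" step=%s", step))
  message(paste0(parts, " ", msg))
  invisible(NULL)
}

# Symmetric (edge-duplicating) reflection of out-of-range indices into 1..n.
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j < n, j, 2L * n - 1L - j) + 1L)
}

# Shift matrix rows by s (out[i, ] = m[i + s, ]), filling with `fill`.
rowShift <- function(m, s, fill) {
  n <- nrow(m)
  out <- matrix(fill, n, ncol(m))
  if (s >= n || -s >= n) return(out)
  if (s >= 0) out[seq_len(n - s), ] <- m[(s + 1L):n, , drop = FALSE]
  else out[(1L - s):n, ] <- m[seq_len(n + s), , drop = FALSE]
  out
}

# Shift matrix columns by s (out[, j] = m[, j + s]), filling with `fill`.
colShift <- function(m, s, fill) {
  n <- ncol(m)
  out <- matrix(fill, nrow(m), n)
  if (s >= n || -s >= n) return(out)
  if (s >= 0) out[, seq_len(n - s)] <- m[, (s + 1L):n, drop = FALSE]
  else out[, (1L - s):n] <- m[, seq_len(n + s), drop = FALSE]
  out
}

# Row-wise sort of a numeric matrix (ascending within each row).
rowSort <- function(m) {
  if (nrow(m) == 0L) return(m)
  matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
}

# djb2 string hash, used for config provenance stamps.
stringHash <- function(x) {
  v <- utf8ToInt(x)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 4294967296
  sprintf("%08x", h)
}
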