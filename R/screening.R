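# Time-course screening: per-replicate normalization of total biospeckle
# intensity to its pre-treatment value, and two-sided paired/unpaired
# t-tests across treatments, trophic groups and time points. Raw p-values
# are reported without multiple-testing correction.

#' Normalize a screening time course to pre-treatment levels
#'
#' Expresses each replicate's total biospeckle intensity at every time
#' point as a percentage of its own pre-treatment (time 0) value:
#' \code{percent = 100 * mu_t / mu_0}. Replicates whose pre-treatment
#' value is zero or missing have no defined percentage; they are excluded
#' from the output with a warning, never silently dropped.
#'
#' @param records data.frame with columns \code{replicate_id},
#'   \code{group}, \code{treatment}, \code{time_point_h} and \code{mu}.
#' @param baselineTime the pre-treatment time point (default 0).
#' @return the input rows of replicates with a positive baseline, with a
#'   \code{percent_of_pretreatment} column added.
#' @export
normalizeTimecourse <- function(records, baselineTime = 0) {
  stopifnot(is.data.frame(records),
            all(c("replicate_id", "group", "treatment", "time_point_h",
                  "mu") %in% names(records)))
  if (any(records$mu < 0, na.rm = TRUE)) stop("mu values must be >= 0")
  keyOf <- function(d) paste(d$group, d$treatment, d$replicate_id, sep = "\r")
  base <- records[records$time_point_h == baselineTime, ]
  mu0 <- stats::setNames(base$mu, keyOf(base))
  k <- keyOf(records)
  m0 <- mu0[k]
  bad <- is.na(m0) | m0 <= 0
  if (any(bad)) {
    badReps <- unique(records$replicate_id[bad])
    warning("replicate(s) with zero or missing pre-treatment mu excluded: ",
            paste(badReps, collapse = ", "))
    bspimLog("screening", sprintf("excluded %d record(s) without baseline",
                                  sum(bad)))
  }
  out <- records[!bad, , drop = FALSE]
  out$percent_of_pretreatment <- 100 * out$mu / m0[!bad]
  rownames(out) <- NULL
  out
}

comparisonRow <- function(label, test, n, t, p, meanA, meanB, seA, seB) {
  data.frame(comparison = label, test = test, n = n,
             t_statistic = t, p_value = p,
             mean_before = meanA, mean_after = meanB,
             se_before = seA, se_after = seB,
             stringsAsFactors = FALSE)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Paired t-test on total biospeckle intensity
#'
#' Two-sided paired t-test of after vs before, one pair per replicate.
#' When the paired differences have zero variance the usual statistic is
#' undefined: a zero mean difference is reported as t = 0, p = 1, and a
#' non-zero mean difference as the limit t = +/-Inf, p = 0 with a warning.
#'
#' @param before,after numeric vectors of equal length (n >= 2).
#' @param label comparison label carried into the result.
#' @return a one-row data.frame: comparison, test, n, t_statistic,
#'   p_value, means and standard errors of both sides.
#' @export
pairedTTest <- function(before, after, label = "after_vs_before") {
  if (length(before) != length(after))
    stop("paired t-test needs equal-length vectors")
  n <- length(before)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  d <- after - before
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(comparisonRow(label, "paired_t", n, 0, 1, mean(before),
                           mean(after), sem(before), sem(after)))
    warning("zero variance of paired differences with non-zero mean; ",
            "p reported as the 0 limit")
    return(comparisonRow(label, "paired_t", n, sign(mean(d)) * Inf, 0,
                         mean(before), mean(after), sem(before), sem(after)))
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  comparisonRow(label, "paired_t", n, unname(ht$statistic), ht$p.value,
                mean(before), mean(after), sem(before), sem(after))
}

#' Unpaired two-sample t-test
#'
#' Two-sided two-sample t-test, equal-variance by default (\code{welch =
#' TRUE} for the Welch correction). Degenerate zero-variance inputs are
#' handled as in \code{\link{pairedTTest}}.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param welch logical, use the Welch unequal-variance test.
#' @param label comparison label.
#' @return a one-row data.frame as for \code{\link{pairedTTest}}.
#' @export
unpairedTTest <- function(a, b, welch = FALSE, label = "b_vs_a") {
  if (length(a) < 2 || length(b) < 2)
    stop("unpaired t-test needs at least 2 observations per side")
  n <- length(a) + length(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(comparisonRow(label, "unpaired_t", n, 0, 1, mean(a), mean(b),
                           sem(a), sem(b)))
    warning("zero variance in both groups with different means; ",
            "p reported as the 0 limit")
    return(comparisonRow(label, "unpaired_t", n,
                         sign(mean(b) - mean(a)) * Inf, 0,
                         mean(a), mean(b), sem(a), sem(b)))
  }
  ht <- stats::t.test(b, a, var.equal = !welch)
  comparisonRow(label, "unpaired_t", n, unname(ht$statistic), ht$p.value,
                mean(a), mean(b), sem(a), sem(b))
}

#' Screening report across groups, treatments and time points
#'
#' Builds the time-course screening summary: per group x treatment x time
#' point, the replicate count, mean and standard error of the
#' percent-of-pretreatment total biospeckle intensity, plus a paired
#' t-test of the raw intensities at each post-treatment time against the
#' pre-treatment scan (replicates paired with themselves). Cells with a
#' single replicate are reported with n = 1 and no test. Row order is
#' deterministic (sorted by group, treatment, time), so the report is a
#' pure function of its input records.
#'
#' @param records data.frame as for \code{\link{normalizeTimecourse}}.
#' @param baselineTime pre-treatment time point (default 0).
#' @return list with elements \code{summary} and \code{comparisons}
#'   (data.frames).
#' @export
screeningReport <- function(records, baselineTime = 0) {
  norm <- normalizeTimecourse(records, baselineTime)
  norm <- norm[order(norm$group, norm$treatment, norm$time_point_h,
                     norm$replicate_id), ]
  cell <- interaction(norm$group, norm$treatment, norm$time_point_h,
                      drop = TRUE, lex.order = TRUE)
  summ <- do.call(rbind, lapply(split(norm, cell), function(d) data.frame(
    group = d$group[1], treatment = d$treatment[1],
    time_point_h = d$time_point_h[1], n = nrow(d),
    mean_percent = mean(d$percent_of_pretreatment),
    se_percent = if (nrow(d) > 1) sem(d$percent_of_pretreatment) else NA_real_,
    mean_mu = mean(d$mu),
    se_mu = if (nrow(d) > 1) sem(d$mu) else NA_real_,
    stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  summ <- summ[order(summ$group, summ$treatment, summ$time_point_h), ]
  rownames(summ) <- NULL

  comps <- list()
  series <- interaction(norm$group, norm$treatment, drop = TRUE,
                        lex.order = TRUE)
  for (s in levels(series)) {
    d <- norm[series == s, ]
    timePts <- sort(unique(d$time_point_h))
    for (tp in setdiff(timePts, baselineTime)) {
      b <- d[d$time_point_h == baselineTime, ]
      a <- d[d$time_point_h == tp, ]
      common <- intersect(b$replicate_id, a$replicate_id)
      label <- sprintf("%s:%s:%gh_vs_%gh", d$group[1], d$treatment[1],
                       tp, baselineTime)
      if (length(common) < 2) {
        bspimLog("screening", sprintf(
          "cell %s has %d paired replicate(s); no test", label,
          length(common)))
        comps[[length(comps) + 1L]] <- comparisonRow(
          label, "paired_t", length(common), NA_real_, NA_real_,
          if (nrow(b)) mean(b$mu) else NA_real_,
          if (nrow(a)) mean(a$mu) else NA_real_, NA_real_, NA_real_)
      } else {
        bv <- b$mu[match(common, b$replicate_id)]
        av <- a$mu[match(common, a$replicate_id)]
        comps[[length(comps) + 1L]] <- pairedTTest(bv, av, label)
      }
    }
  }
  comparisons <- if (length(comps)) do.call(rbind, comps) else
    comparisonRow(character(0), character(0), integer(0), numeric(0),
                  numeric(0), numeric(0), numeric(0), numeric(0),
                  numeric(0))[0, ]
  rownames(comparisons) <- NULL
  list(summary = summ, comparisons = comparisons)
}

#' Correlation of biospeckle volume with biospeckle intensity
#'
#' Convenience wrapper around the standard linear regression and Pearson
#' correlation of per-object biospeckle volume (voxel count) against
#' biospeckle intensity (mean grey value).
#'
#' @param nVoxels numeric vector of object voxel counts.
#' @param meanIntensity numeric vector of object mean intensities.
#' @return list with slope, intercept, r_squared, pearson_r, p_value, n.
#' @export
volumeIntensityCorrelation <- function(nVoxels, meanIntensity) {
  stopifnot(length(nVoxels) == length(meanIntensity), length(nVoxels) >= 3)
  fit <- stats::lm(meanIntensity ~ nVoxels)
  ct <- stats::cor.test(nVoxels, meanIntensity)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       pearson_r = unname(ct$estimate),
       p_value = ct$p.value,
       n = length(nVoxels))
}
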