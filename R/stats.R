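# Repeatability and agreement statistics for tract-segment profiles of
# the effective MR radius and RISH features: test-retest variability,
# between-subject coefficient of variation, Lin's concordance
# correlation, paired comparisons, and segment-wise aggregation.

#' Average voxel values within labelled segments
#'
#' @param voxel_values Numeric vector (or array) of voxel metrics.
#' @param labels Integer labels aligned with `voxel_values`; 0 or NA
#'   labels are ignored.
#' @return Data frame with `segment`, `mean` and `n` (voxels averaged;
#'   NaN/NA voxels are excluded). Empty segments give NaN with a warning.
#' @export
segment_aggregate <- function(voxel_values, labels) {
  v <- as.numeric(voxel_values); l <- as.integer(labels)
  if (length(v) != length(l))
    stop("values and labels have different lengths")
  keep <- !is.na(l) & l > 0
  v <- v[keep]; l <- l[keep]
  segs <- sort(unique(l))
  ok <- is.finite(v)
  m <- vapply(segs, function(s) {
    idx <- l == s & ok
    if (!any(idx)) NaN else mean(v[idx])
  }, numeric(1))
  n <- vapply(segs, function(s) sum(l == s & ok), numeric(1))
  if (any(n == 0)) warning("empty segment(s): mean reported as NaN")
  data.frame(segment = segs, mean = m, n = n)
}

#' Test-retest variability (TRV)
#'
#' \deqn{\mathrm{TRV} = \frac{1}{N}\sum_{i=1}^N \sqrt{\pi/2}\,
#'   \frac{2|a_i - b_i|}{a_i + b_i} \times 100,}
#' the scaled mean absolute relative difference between paired repeated
#' measurements, in percent. Scale-invariant; pairs with a + b = 0 are
#' excluded with a warning.
#'
#' @param a,b Paired test and retest measurements.
#' @return TRV in percent.
#' @examples
#' trv(c(1, 2), c(1, 2))   # 0
#' trv(1, 2)               # sqrt(pi/2) * 2/3 * 100
#' @export
trv <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  s <- a + b
  bad <- s == 0
  if (any(bad)) {
    warning("pairs with a + b = 0 excluded from TRV")
    a <- a[!bad]; b <- b[!bad]; s <- s[!bad]
  }
  if (!length(a)) return(NaN)
  mean(sqrt(pi / 2) * 2 * abs(a - b) / s) * 100
}

#' Between-subject coefficient of variation
#'
#' 100 times the (sample, N-1 denominator) standard deviation across
#' subjects divided by the subject-averaged value.
#'
#' @param values Metric values across subjects (N >= 2).
#' @return CoV in percent (warning if the mean is not positive).
#' @export
cov_percent <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m <= 0) warning("mean is not positive; CoV is ill-defined")
  100 * sd(values) / m
}

#' Lin's concordance correlation coefficient and coefficient of accuracy
#'
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' measures agreement of paired measurements; the coefficient of
#' accuracy \eqn{C_b = \rho_c / \rho} (Pearson's \eqn{\rho}) isolates
#' the systematic location/scale component.
#'
#' @param x,y Paired measurements (N >= 3, nonzero variances).
#' @return List with `rho_c`, `accuracy` (C_b) and `pearson`.
#' @export
lins_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance: concordance undefined")
  sxy <- cov(x, y)
  rho_c <- 2 * sxy / (var(x) + var(y) + (mean(x) - mean(y))^2)
  pearson <- cor(x, y)
  list(rho_c = rho_c, accuracy = rho_c / pearson, pearson = pearson)
}

#' Paired two-sided comparison
#'
#' Standard paired two-sided t-test with a degenerate-data guard.
#'
#' @param x,y Paired measurements.
#' @param alpha Significance level (default 0.05).
#' @return List with `t`, `p`, `significant`, `degenerate`.
#' @export
paired_comparison <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, significant = FALSE, degenerate = FALSE))
    warning("constant nonzero paired differences: p undefined")
    return(list(t = NA_real_, p = NA_real_, significant = NA,
                degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, degenerate = FALSE)
}

#' Segment-profile repeatability report
#'
#' Computes, per tract segment, the TRV across subjects between two
#' sessions, the between-subject CoV of the session-averaged metric, and
#' a paired test between conditions; plus Lin's concordance across the
#' whole profile.
#'
#' @param profile Data frame with columns `subject`, `session` (two
#'   levels), `segment`, `metric`.
#' @param alpha Significance level for the per-segment paired test.
#' @return List with `per_segment` (data frame: segment, trv, cov,
#'   n_subjects) and `concordance` (Lin's CCC between session-mean
#'   profiles).
#' @export
profile_stats <- function(profile, alpha = 0.05) {
  need <- c("subject", "session", "segment", "metric")
  if (!all(need %in% names(profile)))
    stop("profile must have columns ", paste(need, collapse = ", "))
  sess <- sort(unique(profile$session))
  if (length(sess) != 2) stop("exactly two sessions expected")
  segs <- sort(unique(profile$segment))
  per <- lapply(segs, function(sg) {
    sub <- profile[profile$segment == sg, ]
    w <- reshape(sub[, c("subject", "session", "metric")],
                 idvar = "subject", timevar = "session",
                 direction = "wide")
    a <- w[[paste0("metric.", sess[1])]]
    b <- w[[paste0("metric.", sess[2])]]
    ok <- is.finite(a) & is.finite(b)
    data.frame(segment = sg,
               trv = if (any(ok)) trv(a[ok], b[ok]) else NaN,
               cov = if (sum(ok) >= 2) cov_percent((a[ok] + b[ok]) / 2)
                     else NaN,
               n_subjects = sum(ok))
  })
  per <- do.call(rbind, per)
  m1 <- tapply(profile$metric[profile$session == sess[1]],
               profile$segment[profile$session == sess[1]], mean)
  m2 <- tapply(profile$metric[profile$session == sess[2]],
               profile$segment[profile$session == sess[2]], mean)
  conc <- lins_ccc(as.numeric(m1), as.numeric(m2))
  list(per_segment = per, concordance = conc)
}

#' @importFrom stats cov reshape
NULL
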