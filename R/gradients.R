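#' @useDynLib axonradius, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim optimize rnorm runif sd var cor t.test
#'   pt qt integrate uniroot coef predict
#' @importFrom graphics plot lines points legend abline
NULL

# Gyromagnetic ratio of 1H in the package's internal unit system
# (rad ms^-1 per mT/m per... such that gamma * g[mT/m] * delta[ms] is in
# rad/um). Equals 2.6752e8 rad s^-1 T^-1.
GAMMA_H <- 2.6752e-4

#' Pulsed-gradient spin-echo (PGSE) condition
#'
#' A single rectangular-lobe PGSE diffusion encoding: gradient amplitude
#' `g` (mT/m), pulse duration `delta` (ms), pulse separation `Delta` (ms),
#' and a unit gradient direction.
#'
#' @param g Gradient amplitude in mT/m (non-negative).
#' @param delta Pulse duration \eqn{\delta} in ms (0 < delta <= Delta).
#' @param Delta Pulse separation \eqn{\Delta} in ms.
#' @param direction Unit 3-vector; defaults to the z axis.
#' @return An object of class `pgse` with fields `g`, `delta`, `Delta`,
#'   `direction` and the derived `b` (ms/um^2).
#' @examples
#' pgse(273, 15, 30)  # the strongest shell of a Connectom-style protocol
#' @export
pgse <- function(g, delta, Delta, direction = c(0, 0, 1)) {
  stopifnot(is.numeric(g), length(g) == 1L, g >= 0)
  if (!(delta > 0 && delta <= Delta))
    stop("require 0 < delta <= Delta")
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-8) {
    if (nrm == 0) stop("direction must be a nonzero vector")
    direction <- direction / nrm
  }
  obj <- structure(
    list(g = g, delta = delta, Delta = Delta, direction = direction),
    class = "pgse")
  obj$b <- compute_bvalue(obj)
  obj
}

#' @export
print.pgse <- function(x, ...) {
  cat(sprintf("PGSE: g = %.1f mT/m, delta = %.1f ms, Delta = %.1f ms, b = %.3f ms/um^2\n",
              x$g, x$delta, x$Delta, x$b))
  invisible(x)
}

#' b-value of a PGSE condition
#'
#' Computes \eqn{b = (\gamma g \delta)^2 (\Delta - \delta/3)} in ms/um^2.
#'
#' @param grad A [pgse()] object.
#' @return b-value in ms/um^2.
#' @examples
#' compute_bvalue(pgse(273, 15, 30))  # ~30 ms/um^2
#' @export
compute_bvalue <- function(grad) {
  stopifnot(inherits(grad, "pgse"))
  (GAMMA_H * grad$g * grad$delta)^2 * (grad$Delta - grad$delta / 3)
}

#' Gradient amplitude achieving a target b-value
#'
#' Inverts the PGSE b-value relation at fixed pulse timings.
#'
#' @param b Target b-value (ms/um^2).
#' @param delta,Delta Pulse duration and separation (ms).
#' @return Gradient amplitude in mT/m.
#' @export
g_for_bvalue <- function(b, delta, Delta) {
  stopifnot(b >= 0, delta > 0, delta <= Delta)
  sqrt(b / (Delta - delta / 3)) / (GAMMA_H * delta)
}

#' Read an FSL-style gradient table
#'
#' Reads `bval` (one row of b-values, in s/mm^2 or ms/um^2) and `bvec`
#' (three rows of direction components). b-values larger than 500 are
#' assumed to be in s/mm^2 and are converted to ms/um^2. Non-unit
#' direction rows are normalized with a warning (zero rows, used for b=0
#' volumes, are kept as zeros).
#'
#' @param bval_file,bvec_file Paths to the text files.
#' @return List with `bval` (length N, ms/um^2) and `bvec` (N x 3).
#' @export
read_bval_bvec <- function(bval_file, bvec_file) {
  bval <- scan(bval_file, quiet = TRUE)
  bvec <- as.matrix(read.table(bvec_file))
  if (nrow(bvec) == 3L) bvec <- t(bvec)
  dimnames(bvec) <- NULL
  if (nrow(bvec) != length(bval))
    stop("bval and bvec describe different numbers of volumes")
  if (max(bval) > 500) bval <- bval / 1000  # s/mm^2 -> ms/um^2
  nrm <- sqrt(rowSums(bvec^2))
  bad <- which(nrm > 0 & abs(nrm - 1) > 1e-3)
  if (length(bad)) {
    warning(sprintf("%d non-unit bvec rows normalized", length(bad)))
    bvec[bad, ] <- bvec[bad, ] / nrm[bad]
  }
  list(bval = bval, bvec = bvec)
}

#' Write an FSL-style gradient table
#'
#' @param bval Vector of b-values (ms/um^2); written as s/mm^2.
#' @param bvec N x 3 matrix of directions.
#' @param bval_file,bvec_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_bval_bvec <- function(bval, bvec, bval_file, bvec_file) {
  cat(paste(format(bval * 1000, trim = TRUE), collapse = " "), "\n",
      file = bval_file)
  write.table(format(t(bvec), digits = 8), bvec_file,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(bval_file, bvec_file))
}

#' Group diffusion volumes into b-shells
#'
#' Nonzero b-values are clustered: consecutive (sorted) values whose gap
#' is at most `tol` ms/um^2 belong to one shell, whose nominal b is the
#' cluster mean rounded to the nearest 0.1 ms/um^2. Volumes with b below
#' `b0_max` are treated as b = 0.
#'
#' @param bval Vector of b-values (ms/um^2).
#' @param tol Grouping tolerance (ms/um^2); default 0.25, so e.g. 29.9
#'   and 30.1 fall in one shell.
#' @param b0_max Threshold below which a volume counts as b = 0.
#' @return List with `shell_b` (sorted nonzero shell b-values), `index`
#'   (per-volume shell id, 0 for b0) and `b0` (logical mask).
#' @export
group_shells <- function(bval, tol = 0.25, b0_max = 0.05) {
  b0 <- bval < b0_max
  index <- integer(length(bval))
  vals <- sort(unique(bval[!b0]))
  if (!length(vals))
    return(list(shell_b = numeric(0), index = index, b0 = b0))
  cl <- cumsum(c(1, diff(vals) > tol))
  shell_b <- round(as.numeric(tapply(vals, cl, mean)) / 0.1) * 0.1
  for (i in seq_along(vals)) index[!b0 & bval == vals[i]] <- cl[i]
  list(shell_b = shell_b, index = index, b0 = b0)
}
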