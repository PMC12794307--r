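# Spherical-harmonic decomposition of shelled dMRI data and extraction of
# the rotationally invariant features the radius estimators consume:
# the spherical mean (ell = 0) and spherical variance (ell = 2).

#' One shell of diffusion-weighted measurements
#'
#' @param b Shell b-value (ms/um^2).
#' @param grad A [pgse()] object with the shell's pulse parameters.
#' @param directions N x 3 matrix of unit gradient directions.
#' @param signals N non-negative signal magnitudes.
#' @param sigma Noise standard deviation (same units as `signals`).
#' @return Object of class `shell_data`.
#' @export
shell_data <- function(b, grad, directions, signals, sigma = 0) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3L, nrow(directions) == length(signals),
            all(signals >= 0), sigma >= 0, inherits(grad, "pgse"))
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) directions <- directions / nrm
  structure(list(b = b, grad = grad, directions = directions,
                 signals = as.numeric(signals), sigma = sigma),
            class = "shell_data")
}

# Cartesian unit vectors -> (theta polar, phi azimuth)
.cart2sph <- function(dirs) {
  z <- pmin(1, pmax(-1, dirs[, 3]))
  list(theta = acos(z), phi = atan2(dirs[, 2], dirs[, 1]))
}

#' Real even-order spherical harmonic design matrix
#'
#' Orthonormal real SH basis (even orders only, as dMRI signals are
#' antipodally symmetric). Column order: l = 0; then for each even l,
#' m = -l..-1 (sine terms), 0, 1..l (cosine terms).
#'
#' @param directions N x 3 unit vectors.
#' @param Lmax Maximum (even) order; default 6.
#' @return N x M design matrix with attribute `l` giving each column's order.
#' @export
sh_design <- function(directions, Lmax = 6) {
  directions <- as.matrix(directions)
  ang <- .cart2sph(directions)
  ct <- cos(ang$theta)
  ls <- seq(0, Lmax, by = 2)
  cols <- list(); lidx <- integer(0)
  for (l in ls) {
    P <- pracma::legendre(l, ct)           # (l+1) x N, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    blk <- matrix(0, nrow = length(ct), ncol = 2 * l + 1)
    # m = 0
    n0 <- sqrt((2 * l + 1) / (4 * pi))
    blk[, l + 1] <- n0 * P[1, ]
    if (l > 0) for (m in 1:l) {
      nm <- sqrt((2 * l + 1) / (2 * pi) *
                   exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      blk[, l + 1 + m] <- nm * P[m + 1, ] * cos(m * ang$phi)
      blk[, l + 1 - m] <- nm * P[m + 1, ] * sin(m * ang$phi)
    }
    cols[[length(cols) + 1]] <- blk
    lidx <- c(lidx, rep(l, 2 * l + 1))
  }
  out <- do.call(cbind, cols)
  attr(out, "l") <- lidx
  out
}

# Rician negative log-likelihood and gradient in coefficient space.
.rician_nll <- function(coeffs, B, m, sigma) {
  mu <- pmax(as.numeric(B %*% coeffs), 1e-12)
  z <- m * mu / sigma^2
  logI0 <- log(besselI(z, 0, expon.scaled = TRUE)) + z
  -sum(log(pmax(m, 1e-12)) - 2 * log(sigma) -
         (m^2 + mu^2) / (2 * sigma^2) + logI0)
}

.rician_nll_grad <- function(coeffs, B, m, sigma) {
  mu <- pmax(as.numeric(B %*% coeffs), 1e-12)
  z <- m * mu / sigma^2
  ratio <- besselI(z, 1, expon.scaled = TRUE) /
    besselI(z, 0, expon.scaled = TRUE)
  dmu <- mu / sigma^2 - (m / sigma^2) * ratio
  as.numeric(crossprod(B, dmu))
}

#' Fit spherical harmonic coefficients to one shell
#'
#' Ordinary least squares, or maximum likelihood under a Rician noise
#' model with known sigma (initialized from OLS). ML is the appropriate
#' estimator for magnitude MR data at low SNR, where OLS inherits the
#' Rician bias of the magnitudes.
#'
#' @param shell A [shell_data()] object.
#' @param Lmax Maximum even SH order (default 6).
#' @param method `"ml"` (default; requires `shell$sigma > 0`) or `"ols"`.
#' @return Numeric coefficient vector with attributes `l` (order per
#'   coefficient) and `converged`.
#' @export
fit_sh_ml <- function(shell, Lmax = 6, method = c("ml", "ols")) {
  method <- match.arg(method)
  B <- sh_design(shell$directions, Lmax)
  if (nrow(B) < ncol(B))
    stop("fewer directions than SH coefficients at this Lmax")
  qr_B <- qr(B)
  if (qr_B$rank < ncol(B))
    stop("rank-deficient SH design: degenerate direction set")
  ols <- qr.coef(qr_B, shell$signals)
  conv <- TRUE
  if (method == "ml") {
    if (shell$sigma <= 0)
      stop("Rician ML requires a positive noise level sigma")
    fit <- optim(ols, .rician_nll, .rician_nll_grad,
                 B = B, m = shell$signals, sigma = shell$sigma,
                 method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    if (fit$convergence == 0) {
      coeffs <- fit$par
    } else {
      warning("Rician ML did not converge; falling back to OLS")
      coeffs <- ols
      conv <- FALSE
    }
  } else coeffs <- ols
  attr(coeffs, "l") <- attr(B, "l")
  attr(coeffs, "converged") <- conv
  coeffs
}

#' RISH features from SH coefficients
#'
#' The order-l RISH feature is defined here as
#' \eqn{S_\ell = \|c_\ell\| / \sqrt{4\pi(2\ell+1)}}, normalized by the
#' non-diffusion-weighted reference signal. With this scale, the ell = 0
#' feature equals the spherical mean of the normalized signal, and the
#' same convention is used by [sv_forward()], making forward and inverse
#' models consistent.
#'
#' @param sh_coeffs Coefficients from [fit_sh_ml()] (attribute `l` required).
#' @param s0_ref Non-diffusion-weighted reference signal (> 0).
#' @param b Optional shell b-value carried through for bookkeeping.
#' @return Object of class `rish_features`: list with `sm`, `sv`,
#'   `sh_coeffs`, `s0_ref`, `b`.
#' @export
rish_features <- function(sh_coeffs, s0_ref, b = NA_real_) {
  if (s0_ref <= 0) stop("s0_ref must be positive")
  l <- attr(sh_coeffs, "l")
  if (is.null(l)) stop("sh_coeffs lacks the 'l' attribute")
  nrm <- function(ord) {
    idx <- which(l == ord)
    if (!length(idx)) return(0)
    sqrt(sum(sh_coeffs[idx]^2)) / sqrt(4 * pi * (2 * ord + 1))
  }
  structure(list(sm = nrm(0) / s0_ref, sv = nrm(2) / s0_ref,
                 sh_coeffs = sh_coeffs, s0_ref = s0_ref, b = b),
            class = "rish_features")
}

#' @export
print.rish_features <- function(x, ...) {
  cat(sprintf("RISH features (b = %.3g ms/um^2): SM = %.5g, SV = %.5g\n",
              x$b, x$sm, x$sv))
  invisible(x)
}

#' Shell signals to RISH features in one step
#'
#' @param shell A [shell_data()] object.
#' @param s0_ref b = 0 reference signal.
#' @param Lmax Maximum even SH order.
#' @param method SH fit method; defaults to Rician ML when
#'   `shell$sigma > 0`, OLS otherwise.
#' @return A [rish_features()] object.
#' @export
shell_features <- function(shell, s0_ref, Lmax = 6,
                           method = if (shell$sigma > 0) "ml" else "ols") {
  coeffs <- fit_sh_ml(shell, Lmax = Lmax, method = method)
  rish_features(coeffs, s0_ref, b = shell$b)
}

#' Noise-induced bias of the spherical variance
#'
#' The SV is the Euclidean norm of five noisy ell = 2 coefficients, so
#' under additive coefficient noise it follows a noncentral chi law with
#' 5 degrees of freedom and its expectation exceeds the true value.
#' This probe estimates that expectation by Monte Carlo.
#'
#' @param sv_true True SV (norm of the noiseless coefficient vector).
#' @param sigma_coeff Coefficient noise standard deviation.
#' @param n_repeats Monte Carlo repeats (>= 1000 recommended).
#' @param seed RNG seed.
#' @return Mean of the noisy SV over repeats.
#' @export
sv_bias_probe <- function(sv_true, sigma_coeff, n_repeats = 1e4, seed = 1) {
  stopifnot(sv_true >= 0, sigma_coeff >= 0)
  if (sigma_coeff == 0) return(sv_true)
  set.seed(seed)
  eps <- matrix(rnorm(5 * n_repeats, sd = sigma_coeff), ncol = 5)
  eps[, 1] <- eps[, 1] + sv_true
  mean(sqrt(rowSums(eps^2)))
}

# Uniformly random rotation matrix (for invariance tests and seeded
# direction-set rotations).
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qrd <- qr(M)
  Q <- qr.Q(qrd)
  Q * sign(det(Q))  # proper rotation
}
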