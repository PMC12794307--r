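# Closed-form restricted-diffusion signal models for cylinders:
# Neumann long-pulse limit, Van Gelderen Gaussian-phase series, the
# directional axon kernel, and the spherical-mean / spherical-variance
# forward models that the two-shell estimators invert exactly.

#' Tissue parameter set for the single-compartment axon model
#'
#' @param f Intracellular signal fraction, in \[0, 1\].
#' @param Dpar Intracellular parallel diffusivity \eqn{D_{c\parallel}}
#'   (um^2/ms); must not exceed `D0`.
#' @param p2 Intracellular coherence index (the \eqn{\ell = 2} Legendre
#'   moment of the fiber ODF), in \[0, 1\].
#' @param D0 Intrinsic axoplasm diffusivity (um^2/ms); default 2.5.
#' @param r Cylinder radius (um).
#' @return Object of class `tissue_params`.
#' @examples
#' tissue_params(f = 0.6, Dpar = 2.2, p2 = 0.7, r = 3)
#' @export
tissue_params <- function(f = 1, Dpar = 2.5, p2 = 0.7, D0 = 2.5, r = 3) {
  stopifnot(f >= 0, f <= 1, Dpar >= 0, p2 >= 0, p2 <= 1, r >= 0)
  if (D0 <= 0) stop("D0 must be positive")
  if (Dpar > D0 + 1e-12) stop("Dpar must not exceed D0")
  structure(list(f = f, Dpar = Dpar, p2 = p2, D0 = D0, r = r),
            class = "tissue_params")
}

#' Attenuation constant of the Neumann cylinder model
#'
#' \eqn{\kappa = 7 \gamma^2 g^2 \delta / (48 D_0)} in um^-4, so that the
#' perpendicular log-attenuation of a cylinder of radius r (um) is
#' \eqn{-\kappa r^4} in the long-pulse regime.
#'
#' @param g Gradient amplitude (mT/m).
#' @param delta Pulse duration (ms).
#' @param D0 Intrinsic diffusivity (um^2/ms).
#' @return kappa in um^-4 (vectorized over `g`).
#' @examples
#' kappa(273, 15, 2.5)
#' @export
kappa <- function(g, delta, D0 = 2.5) {
  if (any(D0 <= 0)) stop("D0 must be positive")
  stopifnot(all(g >= 0), all(delta > 0))
  7 * (GAMMA_H * g)^2 * delta / (48 * D0)
}

#' Neumann perpendicular cylinder attenuation
#'
#' Long-pulse limit of restricted diffusion perpendicular to an
#' impermeable cylinder: \eqn{S_\perp = \exp(-\kappa r^4)}. Valid when
#' \eqn{\delta \gg r^2 / D_0}; the returned value carries a `regime_ok`
#' attribute that is FALSE when \eqn{\delta < 10 r^2 / D_0}.
#'
#' @param r Cylinder radius (um); vectorized.
#' @param grad A [pgse()] object.
#' @param D0 Intrinsic diffusivity (um^2/ms).
#' @return Signal fraction in (0, 1\] with attribute `regime_ok`.
#' @export
neumann_perp <- function(r, grad, D0 = 2.5) {
  stopifnot(inherits(grad, "pgse"))
  k <- kappa(grad$g, grad$delta, D0)
  out <- exp(-k * r^4)
  attr(out, "regime_ok") <- grad$delta >= 10 * r^2 / D0
  out
}

# First 10 roots of J1'(x) = 0 (derivative of the order-1 Bessel function),
# refined to machine precision at build time of this file.
.j1prime_roots <- c(
  1.8411837813406593, 5.3314427735250325, 8.5363163663462858,
  11.7060049025920873, 14.8635886339090417, 18.0155278626818097,
  21.1643698591888536, 24.3113268572108284, 27.4570505710592133,
  30.6019229726691239)

#' Van Gelderen perpendicular cylinder attenuation
#'
#' Gaussian-phase-approximation PGSE attenuation for diffusion
#' perpendicular to an impermeable cylinder, as a series over roots
#' \eqn{\beta_m} of \eqn{J_1'}. Converges to the Neumann value as
#' \eqn{\delta D_0 / r^2 \to \infty}.
#'
#' @param r Cylinder radius (um); vectorized.
#' @param grad A [pgse()] object.
#' @param D0 Intrinsic diffusivity (um^2/ms).
#' @param n_terms Number of Bessel-root terms (default 10, max 10).
#' @return Signal fraction in (0, 1\]; attribute `converged` is FALSE if
#'   the last retained term exceeds 1e-9 on the exponent.
#' @export
vangelderen_perp <- function(r, grad, D0 = 2.5, n_terms = 10) {
  stopifnot(inherits(grad, "pgse"), n_terms >= 1)
  n_terms <- min(n_terms, length(.j1prime_roots))
  g <- grad$g; delta <- grad$delta; Delta <- grad$Delta
  out <- numeric(length(r))
  conv <- TRUE
  for (i in seq_along(r)) {
    ri <- r[i]
    if (ri <= 0 || g == 0) { out[i] <- 1; next }
    am2 <- (.j1prime_roots[seq_len(n_terms)] / ri)^2  # alpha_m^2, um^-2
    dam <- D0 * am2
    num <- 2 * dam * delta - 2 +
      2 * exp(-dam * delta) + 2 * exp(-dam * Delta) -
      exp(-dam * (Delta - delta)) - exp(-dam * (Delta + delta))
    den <- D0^2 * am2^3 * (am2 * ri^2 - 1)
    terms <- 2 * (GAMMA_H * g)^2 * num / den
    if (terms[n_terms] > 1e-9) conv <- FALSE
    out[i] <- exp(-sum(terms))
  }
  attr(out, "converged") <- conv
  out
}

.perp_model <- function(model = c("neumann", "vangelderen")) {
  model <- match.arg(model)
  if (model == "neumann") neumann_perp else vangelderen_perp
}

#' Directional signal of a dispersed-free axon segment
#'
#' The single-orientation kernel
#' \eqn{K(\xi) = f \exp(-b D_{c\parallel} \xi^2)\, S_\perp(r \mid g\sin\psi, \delta)}
#' with \eqn{\xi = \cos\psi} the cosine between gradient direction and
#' cylinder axis. This is the exact kernel used to synthesize signals
#' numerically (no erf approximation).
#'
#' @param grad A [pgse()] object (its `b` is used).
#' @param cos_psi Cosine(s) of the gradient-to-axis angle, in \[-1, 1\].
#' @param params A [tissue_params()] object.
#' @param model Perpendicular model, `"neumann"` or `"vangelderen"`.
#' @return Signal value(s), same length as `cos_psi`.
#' @export
axon_kernel <- function(grad, cos_psi, params, model = "neumann") {
  stopifnot(inherits(grad, "pgse"), inherits(params, "tissue_params"))
  if (any(abs(cos_psi) > 1 + 1e-12)) stop("cos_psi outside [-1, 1]")
  cos_psi <- pmin(1, pmax(-1, cos_psi))
  perp <- .perp_model(model)
  # Gaussian-phase attenuations have log-signal proportional to g^2, so
  # perp(g sin(psi)) = perp(g)^(sin(psi)^2) exactly for both models.
  log_perp <- log(as.numeric(perp(params$r, grad, params$D0)))
  sin2 <- pmax(0, 1 - cos_psi^2)
  params$f * exp(-grad$b * params$Dpar * cos_psi^2 + log_perp * sin2)
}

#' Spherical-mean forward model
#'
#' High-b spherical mean of the axon kernel:
#' \eqn{\bar S(b) = \beta\, S_\perp(r \mid g, \delta) / \sqrt{b}} with
#' \eqn{\beta = f \sqrt{\pi / (4 D_{c\parallel})}}. Uses the
#' \eqn{\mathrm{erf}(\sqrt{b D_{c\parallel}}) \approx 1} approximation;
#' the result carries attribute `erf_ok`, FALSE when
#' \eqn{b D_{c\parallel} < 6}.
#'
#' @inheritParams axon_kernel
#' @return Normalized spherical-mean signal.
#' @export
sm_forward <- function(grad, params, model = "neumann") {
  stopifnot(inherits(grad, "pgse"), inherits(params, "tissue_params"))
  b <- grad$b
  if (b <= 0) stop("b must be positive")
  perp <- .perp_model(model)
  beta <- params$f * sqrt(pi / (4 * params$Dpar))
  out <- beta * as.numeric(perp(params$r, grad, params$D0)) / sqrt(b)
  attr(out, "erf_ok") <- b * params$Dpar >= 6
  out
}

#' Spherical-variance forward model
#'
#' High-b second-order rotational invariant of the Watson-dispersed axon
#' kernel:
#' \deqn{\bar S_\sigma(b) = p_2\, \gamma'\, (2 b D_{c\parallel} - 3)\,
#'   S_\perp(r \mid g, \delta) / b^{3/2},\qquad
#'   \gamma' = f \sqrt{\pi} / (8 D_{c\parallel}^{3/2}),}
#' the exact \eqn{\ell = 2} Legendre projection of the kernel (reported as
#' a magnitude; the raw projection is negative for
#' \eqn{b D_{c\parallel} > 3/2}). This expression is the exact algebraic
#' counterpart of the two-shell inversion in [loglinear_radius_sv()].
#'
#' @inheritParams axon_kernel
#' @return Normalized spherical-variance signal (magnitude).
#' @export
sv_forward <- function(grad, params, model = "neumann") {
  stopifnot(inherits(grad, "pgse"), inherits(params, "tissue_params"))
  b <- grad$b
  if (b <= 0) stop("b must be positive")
  if (params$Dpar <= 0) stop("Dpar must be positive for the SV model")
  x <- b * params$Dpar
  if (x <= 3 / 2)
    stop("b * Dpar <= 3/2: outside the SV model regime (factor sign change)")
  perp <- .perp_model(model)
  gam <- params$f * sqrt(pi) / (8 * params$Dpar^1.5)
  out <- params$p2 * gam * (2 * x - 3) *
    as.numeric(perp(params$r, grad, params$D0)) / b^1.5
  attr(out, "erf_ok") <- x >= 6
  out
}

# ---- Watson orientation distribution helpers ------------------------------

# p2 = <P2> of a Watson distribution with concentration k (axially
# symmetric, density on the sphere proportional to exp(k * (u.z)^2)).
watson_p2 <- function(k) {
  vapply(k, function(kk) {
    if (abs(kk) < 1e-12) return(0)
    num <- integrate(function(x) (3 * x^2 - 1) / 2 * exp(kk * x^2), 0, 1,
                     rel.tol = 1e-10)$value
    den <- integrate(function(x) exp(kk * x^2), 0, 1, rel.tol = 1e-10)$value
    num / den
  }, numeric(1))
}

# Concentration achieving a target p2 in [0, ~0.995].
watson_kappa_from_p2 <- function(p2) {
  stopifnot(p2 >= 0, p2 <= 1)
  if (p2 == 0) return(0)
  if (p2 > watson_p2(700))
    stop("p2 outside the attainable Watson range")
  uniroot(function(k) watson_p2(k) - p2, c(0, 700), tol = 1e-10)$root
}
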