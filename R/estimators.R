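# Two-shell closed-form (log-linear) and nonlinear least-squares
# estimators of the effective MR radius from spherical-mean and
# spherical-variance features, plus the fixed-diffusivity sensitivity
# sweep. The log-linear forms are the exact algebraic inverses of
# sm_forward() / sv_forward().

.radius_estimate <- function(r4, dpar_used, d0_used, flags = character(0)) {
  r <- if (is.na(r4)) NA_real_ else max(r4, 0)^0.25
  if (!is.na(r4) && r4 < 0) flags <- c(flags, "negative_r4")
  structure(list(r4 = r4, r = r, dpar_used = dpar_used, d0_used = d0_used,
                 flags = flags),
            class = "radius_estimate")
}

#' @export
print.radius_estimate <- function(x, ...) {
  cat(sprintf("effective MR radius: r = %.4f um (r^4 = %.4g um^4)\n",
              x$r, x$r4))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.check_two_shells <- function(f1, f2, grads, D0) {
  stopifnot(inherits(f1, "rish_features"), inherits(f2, "rish_features"),
            length(grads) == 2L, D0 > 0)
  k1 <- kappa(grads[[1]]$g, grads[[1]]$delta, D0)
  k2 <- kappa(grads[[2]]$g, grads[[2]]$delta, D0)
  if (abs(k2 - k1) < 1e-12)
    stop("kappa identical across shells: degenerate two-shell design")
  list(k1 = k1, k2 = k2, b1 = f1$b, b2 = f2$b)
}

#' Log-linear two-shell radius estimate from the spherical mean
#'
#' Closed-form inversion of the spherical-mean model at two high-b
#' shells:
#' \deqn{r^4 = \log\!\frac{\sqrt{b_1}\,\bar S(b_1)}{\sqrt{b_2}\,\bar S(b_2)}
#'   \; / \; (\kappa_2 - \kappa_1).}
#' The prefactor (intracellular fraction, parallel diffusivity) cancels
#' in the ratio, so no biophysical fit is needed.
#'
#' @param f1,f2 [rish_features()] of the two shells (their `b` is used).
#' @param grads List of the two [pgse()] objects (same order).
#' @param D0 Intrinsic diffusivity (um^2/ms), default 2.5.
#' @return A `radius_estimate` (fields `r4`, `r`, `flags`).
#' @export
loglinear_radius_sm <- function(f1, f2, grads, D0 = 2.5) {
  ks <- .check_two_shells(f1, f2, grads, D0)
  if (!is.finite(f1$sm) || !is.finite(f2$sm) || f1$sm <= 0 || f2$sm <= 0)
    return(.radius_estimate(NaN, NA_real_, D0, "invalid_sm"))
  r4 <- log((sqrt(ks$b1) * f1$sm) / (sqrt(ks$b2) * f2$sm)) / (ks$k2 - ks$k1)
  .radius_estimate(r4, NA_real_, D0)
}

#' Log-linear two-shell radius estimate from the spherical variance
#'
#' Closed-form inversion of the spherical-variance model at two shells:
#' \deqn{r^4 = \big[\log(b_1^{3/2} (2 b_2 D_{c\parallel} - 3)\,
#'   \bar S_\sigma(b_1)) - \log(b_2^{3/2} (2 b_1 D_{c\parallel} - 3)\,
#'   \bar S_\sigma(b_2))\big] / (\kappa_2 - \kappa_1).}
#' The p2 and intracellular-fraction prefactors cancel; the parallel
#' diffusivity must be supplied (e.g. from a standard-model fit).
#'
#' @inheritParams loglinear_radius_sm
#' @param Dpar Intracellular parallel diffusivity (um^2/ms).
#' @return A `radius_estimate`.
#' @export
loglinear_radius_sv <- function(f1, f2, grads, D0 = 2.5, Dpar) {
  ks <- .check_two_shells(f1, f2, grads, D0)
  if (Dpar <= 0) stop("Dpar must be positive")
  if (ks$b1 * Dpar <= 1.5 || ks$b2 * Dpar <= 1.5)
    stop("b * Dpar <= 3/2 on a shell: outside the SV model regime")
  if (!is.finite(f1$sv) || !is.finite(f2$sv) || f1$sv <= 0 || f2$sv <= 0)
    return(.radius_estimate(NaN, Dpar, D0, "invalid_sv"))
  num <- log(ks$b1^1.5 * (2 * ks$b2 * Dpar - 3) * f1$sv) -
    log(ks$b2^1.5 * (2 * ks$b1 * Dpar - 3) * f2$sv)
  .radius_estimate(num / (ks$k2 - ks$k1), Dpar, D0)
}

# Forward feature value at radius r for one shell, without prefactor.
.shape_fun <- function(order, model, grad, D0, Dpar) {
  perp <- .perp_model(model)
  b <- grad$b
  if (order == "sm") {
    function(r) as.numeric(perp(r, grad, D0)) / sqrt(b)
  } else {
    function(r) (2 * b * Dpar - 3) * as.numeric(perp(r, grad, D0)) / b^1.5
  }
}

#' Nonlinear least-squares radius estimate
#'
#' Fits (prefactor, r) of the spherical-mean or spherical-variance
#' forward model to features of two or more shells by least squares,
#' with the prefactor profiled out analytically. The radius is bounded
#' to \[0, 10\] um and located by bracketed 1-D optimization started
#' from several subintervals. With `model = "vangelderen"` this is the
#' reference estimator against which the Neumann-based log-linear form
#' is compared.
#'
#' @param features List of [rish_features()], one per shell.
#' @param grads List of [pgse()] objects, same order.
#' @param D0 Intrinsic diffusivity (um^2/ms).
#' @param Dpar Parallel diffusivity (needed for `order = "sv"`).
#' @param model `"neumann"` or `"vangelderen"`.
#' @param order `"sm"` or `"sv"`.
#' @return A `radius_estimate`.
#' @export
nonlinear_radius <- function(features, grads, D0 = 2.5, Dpar = NULL,
                             model = c("neumann", "vangelderen"),
                             order = c("sm", "sv")) {
  model <- match.arg(model); order <- match.arg(order)
  stopifnot(length(features) >= 2L, length(features) == length(grads))
  if (order == "sv" && (is.null(Dpar) || Dpar <= 0))
    stop("order = 'sv' requires a positive Dpar")
  y <- vapply(features, function(f) f[[order]], numeric(1))
  if (any(!is.finite(y)) || any(y <= 0))
    return(.radius_estimate(NaN, if (is.null(Dpar)) NA_real_ else Dpar,
                            D0, paste0("invalid_", order)))
  shapes <- lapply(grads, .shape_fun, order = order, model = model,
                   D0 = D0, Dpar = Dpar)
  sse <- function(r) {
    m <- vapply(shapes, function(s) s(r), numeric(1))
    a <- sum(y * m) / sum(m * m)  # profiled prefactor
    sum((y - a * m)^2)
  }
  # multi-start over subintervals of the bounded range
  brackets <- list(c(0, 1.5), c(1.5, 4), c(4, 10))
  cand <- lapply(brackets, function(br)
    optimize(sse, interval = br, tol = 1e-10))
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "objective"))]]
  r <- best$minimum
  # refine around the winner
  lo <- max(0, r - 0.05); hi <- min(10, r + 0.05)
  r <- optimize(sse, interval = c(lo, hi), tol = 1e-12)$minimum
  flags <- character(0)
  if (r > 10 - 1e-6) flags <- "upper_bound"
  if (r < 1e-6) r <- 0
  .radius_estimate(r^4, if (is.null(Dpar)) NA_real_ else Dpar, D0, flags)
}

#' Sensitivity of the SM-SV radius difference to the fixed diffusivities
#'
#' Re-estimates the SM- and SV-derived radii of supplied two-shell
#' feature pairs over grids of assumed D0 and parallel diffusivity, and
#' returns the mean difference r_SM - r_SV per grid cell.
#'
#' @param sm_pairs,sv_pairs N x 2 matrices of spherical-mean and
#'   spherical-variance values at the two shells (columns = shells).
#' @param grads List of the two [pgse()] objects.
#' @param b Length-2 vector of the shell b-values (ms/um^2).
#' @param D0_grid,Dpar_grid Strictly positive grids (um^2/ms).
#' @return Matrix (length(D0_grid) x length(Dpar_grid)) of mean
#'   r_SM - r_SV (um), with dimnames giving the grid values.
#' @export
diffusivity_sweep <- function(sm_pairs, sv_pairs, grads, b,
                              D0_grid, Dpar_grid) {
  sm_pairs <- as.matrix(sm_pairs); sv_pairs <- as.matrix(sv_pairs)
  if (nrow(sm_pairs) == 0L) stop("empty input")
  stopifnot(ncol(sm_pairs) == 2L, ncol(sv_pairs) == 2L,
            all(D0_grid > 0), all(Dpar_grid > 0), length(b) == 2L)
  out <- matrix(NA_real_, length(D0_grid), length(Dpar_grid),
                dimnames = list(D0 = format(D0_grid),
                                Dpar = format(Dpar_grid)))
  for (i in seq_along(D0_grid)) for (j in seq_along(Dpar_grid)) {
    d0 <- D0_grid[i]; dp <- Dpar_grid[j]
    diffs <- vapply(seq_len(nrow(sm_pairs)), function(v) {
      f1 <- structure(list(sm = sm_pairs[v, 1], sv = sv_pairs[v, 1],
                           b = b[1]), class = "rish_features")
      f2 <- structure(list(sm = sm_pairs[v, 2], sv = sv_pairs[v, 2],
                           b = b[2]), class = "rish_features")
      rsm <- loglinear_radius_sm(f1, f2, grads, D0 = d0)
      rsv <- loglinear_radius_sv(f1, f2, grads, D0 = d0, Dpar = dp)
      rsm$r - rsv$r
    }, numeric(1))
    out[i, j] <- mean(diffs, na.rm = TRUE)
  }
  out
}

# ---- The user-facing model fit -------------------------------------------

#' Fit the effective MR radius to multi-shell RISH features
#'
#' The central fitting function of the package. Given per-shell RISH
#' features of high-b data (minimally two shells, e.g. b = 6 and
#' 30 ms/um^2), estimates the effective MR radius from the spherical
#' mean and, optionally, the spherical variance, using the closed-form
#' log-linear estimator or a nonlinear least-squares fit.
#'
#' With more than two shells and `method = "loglinear"`, r^4 is obtained
#' by linear regression of the log-transformed feature on kappa.
#'
#' @param features List of [rish_features()], one per shell; each must
#'   carry its b-value.
#' @param grads List of [pgse()] objects, one per shell, same order.
#' @param d0 Assumed intrinsic diffusivity D0 (um^2/ms), default 2.5.
#' @param dpar Assumed parallel diffusivity (um^2/ms); required for the
#'   spherical-variance path.
#' @param order Character vector among `"sm"`, `"sv"`.
#' @param method `"loglinear"` (closed form) or `"nonlinear"`.
#' @param model Perpendicular attenuation model for the nonlinear
#'   method: `"neumann"` or `"vangelderen"`.
#' @return Object of class `radius_fit` with methods `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' prot <- connectom_protocol()
#' tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = 3)
#' idx <- match(c(6, 30), vapply(prot$shells, `[[`, 0, "b"))
#' feats <- lapply(prot$shells[idx], function(s) {
#'   structure(list(sm = as.numeric(sm_forward(s$grad, tp)),
#'                  sv = as.numeric(sv_forward(s$grad, tp)), b = s$b),
#'             class = "rish_features")
#' })
#' grads <- lapply(prot$shells[idx], `[[`, "grad")
#' fit <- fit_radius(feats, grads, dpar = 2.2)
#' coef(fit)
#' @export
fit_radius <- function(features, grads, d0 = 2.5, dpar = NULL,
                       order = c("sm", "sv"),
                       method = c("loglinear", "nonlinear"),
                       model = c("neumann", "vangelderen")) {
  method <- match.arg(method); model <- match.arg(model)
  order <- match.arg(order, c("sm", "sv"), several.ok = TRUE)
  stopifnot(length(features) >= 2L, length(features) == length(grads))
  bs <- vapply(features, `[[`, numeric(1), "b")
  ord <- order(bs)
  features <- features[ord]; grads <- grads[ord]; bs <- bs[ord]
  if ("sv" %in% order && is.null(dpar))
    stop("the spherical-variance path requires 'dpar'")
  est <- list()
  for (o in order) {
    if (method == "nonlinear") {
      est[[o]] <- nonlinear_radius(features, grads, D0 = d0, Dpar = dpar,
                                   model = model, order = o)
    } else if (length(features) == 2L) {
      est[[o]] <- if (o == "sm")
        loglinear_radius_sm(features[[1]], features[[2]], grads, D0 = d0)
      else
        loglinear_radius_sv(features[[1]], features[[2]], grads,
                            D0 = d0, Dpar = dpar)
    } else {
      est[[o]] <- .loglinear_multishell(features, grads, d0, dpar, o)
    }
  }
  structure(list(estimates = est, features = features, grads = grads,
                 d0 = d0, dpar = dpar, method = method, model = model,
                 call = match.call()),
            class = "radius_fit")
}

# Weighted linear regression of the log feature on kappa for > 2 shells.
.loglinear_multishell <- function(features, grads, d0, dpar, order) {
  ks <- vapply(grads, function(g) kappa(g$g, g$delta, d0), numeric(1))
  bs <- vapply(features, `[[`, numeric(1), "b")
  y <- vapply(seq_along(features), function(i) {
    f <- features[[i]][[order]]
    if (!is.finite(f) || f <= 0) return(NA_real_)
    if (order == "sm") log(sqrt(bs[i]) * f)
    else log(bs[i]^1.5 * f / (2 * bs[i] * dpar - 3))
  }, numeric(1))
  if (any(is.na(y)))
    return(.radius_estimate(NaN, if (is.null(dpar)) NA_real_ else dpar,
                            d0, paste0("invalid_", order)))
  fit <- stats::lm.fit(cbind(1, -ks), y)
  .radius_estimate(unname(fit$coefficients[2]),
                   if (is.null(dpar)) NA_real_ else dpar, d0)
}

#' @export
print.radius_fit <- function(x, ...) {
  cat("Effective MR radius fit (", x$method, ", ", x$model, " model)\n",
      sep = "")
  bs <- vapply(x$features, `[[`, numeric(1), "b")
  cat("shells: b =", paste(format(bs), collapse = ", "), "ms/um^2\n")
  for (o in names(x$estimates)) {
    e <- x$estimates[[o]]
    cat(sprintf("  r_%s = %.4f um%s\n", o, e$r,
                if (length(e$flags))
                  paste0("  [", paste(e$flags, collapse = ", "), "]")
                else ""))
  }
  invisible(x)
}

#' @export
coef.radius_fit <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "r")
}

#' @export
summary.radius_fit <- function(object, ...) {
  bs <- vapply(object$features, `[[`, numeric(1), "b")
  ks <- vapply(object$grads, function(g) kappa(g$g, g$delta, object$d0),
               numeric(1))
  tab <- data.frame(
    b = bs, kappa = ks,
    sm = vapply(object$features, `[[`, numeric(1), "sm"),
    sv = vapply(object$features, `[[`, numeric(1), "sv"))
  res <- list(fit = object, shells = tab,
              r = coef(object),
              r4 = vapply(object$estimates, `[[`, numeric(1), "r4"),
              flags = lapply(object$estimates, `[[`, "flags"))
  class(res) <- "summary.radius_fit"
  res
}

#' @export
print.summary.radius_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-shell features:\n")
  print(x$shells, row.names = FALSE)
  cat("\nr^4 (um^4):", paste(format(x$r4, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Predict forward feature values from a radius fit
#'
#' Evaluates the fitted forward model (with the prefactor implied by the
#' first shell's feature) at new PGSE conditions.
#'
#' @param object A `radius_fit`.
#' @param grads List of [pgse()] objects to predict at; defaults to the
#'   fitted shells.
#' @param order `"sm"` or `"sv"`.
#' @param ... Unused.
#' @return Numeric vector of predicted feature values.
#' @export
predict.radius_fit <- function(object, grads = object$grads,
                               order = names(object$estimates)[1], ...) {
  e <- object$estimates[[order]]
  if (is.null(e)) stop("order '", order, "' was not fitted")
  shape1 <- .shape_fun(order, object$model, object$grads[[1]],
                       object$d0, object$dpar)
  a <- object$features[[1]][[order]] / shape1(e$r)
  vapply(grads, function(g) {
    a * .shape_fun(order, object$model, g, object$d0, object$dpar)(e$r)
  }, numeric(1))
}

#' @export
residuals.radius_fit <- function(object, order = names(object$estimates)[1],
                                 ...) {
  obs <- vapply(object$features, `[[`, numeric(1), order)
  obs - predict(object, order = order)
}

#' Log-linear diagnostic plot of a radius fit
#'
#' Plots the log-transformed feature against kappa; under the Neumann
#' model the points fall on a line with slope -r^4.
#'
#' @param x A `radius_fit`.
#' @param order `"sm"` or `"sv"`.
#' @param ... Passed to [plot()].
#' @export
plot.radius_fit <- function(x, order = names(x$estimates)[1], ...) {
  ks <- vapply(x$grads, function(g) kappa(g$g, g$delta, x$d0), numeric(1))
  bs <- vapply(x$features, `[[`, numeric(1), "b")
  y <- vapply(seq_along(x$features), function(i) {
    f <- x$features[[i]][[order]]
    if (order == "sm") log(sqrt(bs[i]) * f)
    else log(bs[i]^1.5 * f / (2 * bs[i] * x$dpar - 3))
  }, numeric(1))
  plot(ks, y, xlab = expression(kappa ~ (um^-4)),
       ylab = sprintf("log-transformed %s feature", toupper(order)), ...)
  e <- x$estimates[[order]]
  abline(a = y[1] + ks[1] * e$r4, b = -e$r4, lty = 2)
  invisible(x)
}
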