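# Synthetic multi-shell acquisition generator: the five-shell Connectom
# protocol, deterministic uniform direction sets, and voxel/phantom
# synthesis with Rician noise.

#' Deterministic uniform directions on the sphere
#'
#' Spherical-Fibonacci point set, optionally antipodally symmetrized to
#' the upper hemisphere (gradient polarity is irrelevant for diffusion
#' encoding) and optionally rotated by a seeded random rotation.
#'
#' @param n Number of directions.
#' @param seed If non-NULL, the set is rotated by a random rotation drawn
#'   under this seed (same seed, same set).
#' @param hemisphere Flip points to the z >= 0 hemisphere (default TRUE).
#' @return n x 3 matrix of unit vectors.
#' @export
uniform_directions <- function(n, seed = NULL, hemisphere = TRUE) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- golden * (seq_len(n) - 1)
  dirs <- cbind(rho * cos(phi), rho * sin(phi), z, deparse.level = 0)
  if (!is.null(seed)) {
    set.seed(seed)
    dirs <- dirs %*% t(random_rotation())
  }
  if (hemisphere) {
    flip <- dirs[, 3] < 0
    dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  }
  dirs
}

#' The five-shell high-gradient acquisition protocol
#'
#' b = 0.5, 1, 2.5, 6 and 30 ms/um^2 with 30, 30, 30, 120 and 240
#' uniformly distributed directions, pulse timings Delta/delta = 30/15 ms
#' and per-shell gradient amplitudes back-computed from the b-values
#' (273 mT/m at the strongest shell), plus 23 b = 0 volumes.
#'
#' @param delta,Delta Pulse timings in ms.
#' @param n_b0 Number of non-diffusion-weighted volumes.
#' @return Object of class `protocol`: list of `shells` (each with `b`,
#'   `n`, `grad`, `directions`) and `n_b0`.
#' @export
connectom_protocol <- function(delta = 15, Delta = 30, n_b0 = 23) {
  bs <- c(0.5, 1, 2.5, 6, 30)
  nd <- c(30, 30, 30, 120, 240)
  shells <- lapply(seq_along(bs), function(i) {
    g <- g_for_bvalue(bs[i], delta, Delta)
    list(b = bs[i], n = nd[i], grad = pgse(g, delta, Delta),
         directions = uniform_directions(nd[i]))
  })
  structure(list(shells = shells, n_b0 = n_b0), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("Multi-shell PGSE protocol,", x$n_b0, "b0 volumes\n")
  for (s in x$shells)
    cat(sprintf("  b = %4.1f ms/um^2: %3d directions, g = %6.1f mT/m\n",
                s$b, s$n, s$grad$g))
  invisible(x)
}

#' Add Rician noise to magnitudes
#'
#' \eqn{|s + n_1 + i n_2|} with independent Gaussian channels of
#' standard deviation `sigma`.
#'
#' @param signal Noiseless magnitudes.
#' @param sigma Noise standard deviation.
#' @return Noisy magnitudes of the same length.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
}

#' Synthesize one voxel's multi-shell data
#'
#' Per shell, mixes a Watson-dispersed restricted-cylinder axon
#' compartment with an optional isotropic glia-like compartment, then
#' applies Rician noise with sigma = 1/SNR (signals normalized so the
#' noiseless b = 0 signal is 1). The glia compartment is either ideal
#' "dot" restriction (unit signal at every b; the limiting case of a
#' fully restricted sphere) or externally supplied per-direction signals,
#' e.g. from the Monte Carlo simulator.
#'
#' @param params A [tissue_params()] for the axon compartment (`f` is
#'   ignored; the compartment is normalized and weighted by 1 - fg).
#' @param fg Glia signal fraction in \[0, 1).
#' @param protocol A [connectom_protocol()]-style protocol.
#' @param snr Signal-to-noise ratio at b = 0 (Inf for noiseless).
#' @param seed RNG seed for the noise.
#' @param glia_signals Optional list (one per shell) of per-direction
#'   glia signals; default NULL = dot compartment.
#' @param axis Axon bundle orientation.
#' @return List with `shells` (list of [shell_data()]), `b0` (noisy b = 0
#'   magnitudes), `sigma`, and `truth` (generative parameters).
#' @export
synthesize_voxel <- function(params, fg = 0, protocol = connectom_protocol(),
                             snr = Inf, seed = 1, glia_signals = NULL,
                             axis = c(0, 0, 1)) {
  stopifnot(fg >= 0, fg < 1, snr > 0)
  sigma <- if (is.finite(snr)) 1 / snr else 0
  set.seed(seed)
  shells <- vector("list", length(protocol$shells))
  for (i in seq_along(protocol$shells)) {
    sh <- protocol$shells[[i]]
    ax <- dispersed_cylinder_signal(params, sh$grad, sh$directions,
                                    axis = axis)
    gl <- if (is.null(glia_signals)) rep(1, sh$n) else glia_signals[[i]]
    sig <- (1 - fg) * ax / params$f + fg * gl
    noisy <- add_rician_noise(sig, sigma)
    shells[[i]] <- shell_data(sh$b, sh$grad, sh$directions, noisy,
                              sigma = sigma)
  }
  b0 <- add_rician_noise(rep(1, protocol$n_b0), sigma)
  list(shells = shells, b0 = b0, sigma = sigma,
       truth = list(params = params, fg = fg, snr = snr, axis = axis))
}

#' Synthesize a phantom volume and write it as NIfTI + bval/bvec
#'
#' A grid phantom spanning cylinder radius along x and glia (dot)
#' signal fraction along y, replicated along z with independent noise.
#' Writes `<prefix>_dwi.nii.gz`, `<prefix>.bval`, `<prefix>.bvec` and a
#' JSON ground-truth sidecar `<prefix>_truth.json`.
#'
#' @param prefix Output path prefix.
#' @param dim Grid dimensions, default c(10, 10, 3).
#' @param r_range Radius range spanned along x (um).
#' @param fg_range Glia-fraction range spanned along y.
#' @param params Base [tissue_params()]; `r` is overridden per voxel.
#' @param protocol Acquisition protocol.
#' @param snr SNR at b = 0.
#' @param seed RNG seed.
#' @return Invisibly, a list with the written paths and the ground truth.
#' @export
synth_phantom <- function(prefix, dim = c(10, 10, 3), r_range = c(1, 5),
                          fg_range = c(0, 0.5),
                          params = tissue_params(f = 1, Dpar = 2.2,
                                                 p2 = 0.7, r = 3),
                          protocol = connectom_protocol(), snr = 50,
                          seed = 1) {
  rs <- seq(r_range[1], r_range[2], length.out = dim[1])
  fgs <- seq(fg_range[1], fg_range[2], length.out = dim[2])
  shells <- protocol$shells
  nvol <- protocol$n_b0 + sum(vapply(shells, `[[`, numeric(1), "n"))
  sigma <- if (is.finite(snr)) 1 / snr else 0
  # noiseless per-direction axon signals cached per unique radius
  cache <- lapply(rs, function(r) {
    p <- params; p$r <- r
    lapply(shells, function(sh)
      dispersed_cylinder_signal(p, sh$grad, sh$directions) / params$f)
  })
  vol <- array(0, c(dim, nvol))
  set.seed(seed)
  for (ix in seq_len(dim[1])) for (iy in seq_len(dim[2]))
    for (iz in seq_len(dim[3])) {
      sig <- rep(1, protocol$n_b0)
      for (k in seq_along(shells)) {
        ax <- cache[[ix]][[k]]
        sig <- c(sig, (1 - fgs[iy]) * ax + fgs[iy])
      }
      vol[ix, iy, iz, ] <- add_rician_noise(sig, sigma)
    }
  bval <- c(rep(0, protocol$n_b0),
            unlist(lapply(shells, function(sh) rep(sh$b, sh$n))))
  bvec <- rbind(matrix(0, protocol$n_b0, 3),
                do.call(rbind, lapply(shells, `[[`, "directions")))
  dwi_file <- paste0(prefix, "_dwi.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), dwi_file)
  write_bval_bvec(bval, bvec, paste0(prefix, ".bval"),
                  paste0(prefix, ".bvec"))
  truth <- list(r = rs, fg = fgs, dim = dim, snr = snr, seed = seed,
                sigma = sigma, Dpar = params$Dpar, D0 = params$D0,
                p2 = params$p2, delta = shells[[1]]$grad$delta,
                Delta = shells[[1]]$grad$Delta)
  jsonlite::write_json(truth, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dwi = dwi_file, bval = paste0(prefix, ".bval"),
                 bvec = paste0(prefix, ".bvec"),
                 truth_file = paste0(prefix, "_truth.json"),
                 truth = truth))
}
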