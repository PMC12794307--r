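# Monte Carlo spin-walker simulation of restricted diffusion in axon and
# glia substrates, PGSE signal synthesis from the walks, and the analytic
# dispersed-cylinder (Watson ODF) axon compartment used in the glia
# signal-fraction mixture experiment.

# orthonormal basis whose third column is `axis` (local z)
.frame_for_axis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cbind(e1, e2, axis, deparse.level = 0)
}

#' Substrate geometries for the Monte Carlo simulator
#'
#' Constructors for the impermeable geometries the walkers diffuse in:
#' free space, a sphere, a cylinder (infinite, or finite with reflecting
#' caps), and a parametric glia cell (soma sphere plus isotropically
#' oriented cylindrical processes).
#'
#' @param radius Radius in um.
#' @param length Cylinder length in um (`Inf` for an unbounded axon-like
#'   cylinder).
#' @param axis Cylinder axis (unit 3-vector).
#' @return An object of class `substrate`.
#' @export
substrate_sphere <- function(radius) {
  stopifnot(radius > 0)
  structure(list(kind = "sphere", radius = radius), class = "substrate")
}

#' @rdname substrate_sphere
#' @export
substrate_cylinder <- function(radius, length = Inf, axis = c(0, 0, 1)) {
  stopifnot(radius > 0, length > 0)
  structure(list(kind = "cylinder", radius = radius, length = length,
                 axis = axis / sqrt(sum(axis^2)),
                 frame = .frame_for_axis(axis)),
            class = "substrate")
}

#' @rdname substrate_sphere
#' @export
substrate_free <- function() {
  structure(list(kind = "free"), class = "substrate")
}

#' @rdname substrate_sphere
#' @param radii Vector of cylinder radii (um), one per cylinder.
#' @param axes Matrix of unit axes (one row per cylinder), or NULL to
#'   draw an isotropic deterministic set.
#' @param n_cylinders Number of cylinders when `axes` is NULL.
#' @details `substrate_dispersed_cylinders()` models a set of
#'   independent, unbounded, isotropically oriented impermeable
#'   cylinders (fully dispersed thick processes). Walkers are assigned
#'   to cylinders proportional to their cross-sectional area and never
#'   exchange between them.
#' @export
substrate_dispersed_cylinders <- function(radii, axes = NULL,
                                          n_cylinders = length(radii),
                                          seed = 1) {
  if (length(radii) == 1L) radii <- rep(radii, n_cylinders)
  stopifnot(all(radii > 0), n_cylinders == length(radii))
  if (is.null(axes))
    axes <- uniform_directions(n_cylinders, seed = seed,
                               hemisphere = FALSE)
  axes <- matrix(axes, ncol = 3)
  stopifnot(nrow(axes) == length(radii))
  structure(list(kind = "cylinders", radii = radii, axes = axes),
            class = "substrate")
}

#' @rdname substrate_sphere
#' @param soma_radius Soma sphere radius (um); 0 omits the soma
#'   ("process-only" glia).
#' @param n_processes Number of cylindrical processes.
#' @param process_radius Range (min, max) of process radii (um).
#' @param process_length Process length (um).
#' @param seed Seed for the process orientations and radii.
#' @export
substrate_glia <- function(soma_radius = 5, n_processes = 20,
                           process_radius = c(1, 2), process_length = 30,
                           seed = 1) {
  stopifnot(soma_radius >= 0, n_processes >= 0, process_length > 0)
  set.seed(seed)
  prims <- NULL
  if (soma_radius > 0)
    prims <- rbind(prims, c(0, 0, 0, 0, soma_radius, 0, 0, 0, 1))
  if (n_processes > 0) {
    dirs <- uniform_directions(n_processes, seed = seed,
                               hemisphere = FALSE)
    radii <- runif(n_processes, process_radius[1],
                   max(process_radius))
    H <- process_length / 2
    # processes extend radially outward, rooted at (or near) the soma
    root <- max(soma_radius - 1, 0)
    for (k in seq_len(n_processes)) {
      ctr <- dirs[k, ] * (root + H)
      prims <- rbind(prims, c(1, ctr, radii[k], H, dirs[k, ]))
    }
  }
  if (is.null(prims)) stop("glia substrate needs a soma or processes")
  structure(list(kind = "glia", prims = prims, soma_radius = soma_radius,
                 n_processes = n_processes), class = "substrate")
}

.prim_volume <- function(row) {
  if (row[1] < 0.5) 4 / 3 * pi * row[5]^3 else 2 * row[6] * pi * row[5]^2
}

#' Containment test for a substrate
#'
#' @param substrate A `substrate` object.
#' @param points N x 3 matrix of positions (um).
#' @return Logical vector: is each point inside the geometry?
#' @export
contains <- function(substrate, points) {
  points <- matrix(points, ncol = 3)
  switch(substrate$kind,
    free = rep(TRUE, nrow(points)),
    sphere = rowSums(points^2) <= substrate$radius^2,
    cylinder = {
      loc <- points %*% substrate$frame
      ok <- loc[, 1]^2 + loc[, 2]^2 <= substrate$radius^2
      if (is.finite(substrate$length))
        ok <- ok & abs(loc[, 3]) <= substrate$length / 2
      ok
    },
    cylinders = {
      out <- rep(FALSE, nrow(points))
      for (k in seq_along(substrate$radii)) {
        u <- substrate$axes[k, ]
        t <- as.numeric(points %*% u)
        out <- out | (rowSums(points^2) - t^2 <= substrate$radii[k]^2)
      }
      out
    },
    glia = {
      out <- rep(FALSE, nrow(points))
      for (k in seq_len(nrow(substrate$prims))) {
        row <- substrate$prims[k, ]
        q <- sweep(points, 2, row[2:4])
        if (row[1] < 0.5) {
          out <- out | rowSums(q^2) <= row[5]^2
        } else {
          t <- as.numeric(q %*% row[7:9])
          r2 <- rowSums(q^2) - t^2
          out <- out | (abs(t) <= row[6] & r2 <= row[5]^2)
        }
      }
      out
    })
}

#' Seed walkers uniformly inside a substrate
#'
#' Rejection sampling of uniform positions within the geometry;
#' deterministic given the seed. For union (glia) substrates, a primitive
#' is chosen proportional to its volume and the draw is accepted with
#' probability 1/k when the point lies in k primitives, which yields an
#' exactly uniform density over the union.
#'
#' @param substrate A `substrate` object.
#' @param n Number of walkers.
#' @param seed RNG seed.
#' @return Object of class `walker_ensemble` with `positions` (n x 3, um).
#' @export
seed_walkers <- function(substrate, n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  pos <- switch(substrate$kind,
    free = matrix(0, n, 3),
    sphere = {
      R <- substrate$radius
      out <- matrix(NA_real_, n, 3); got <- 0L; tries <- 0L
      while (got < n) {
        m <- 2L * (n - got)
        cand <- matrix(runif(3 * m, -R, R), ncol = 3)
        keep <- cand[rowSums(cand^2) <= R^2, , drop = FALSE]
        take <- min(nrow(keep), n - got)
        if (take > 0) out[got + seq_len(take), ] <- keep[seq_len(take), ]
        got <- got + take; tries <- tries + m
        if (tries > 1e4 * n) stop("seeding acceptance rate too low")
      }
      out
    },
    cylinder = {
      R <- substrate$radius
      H <- if (is.finite(substrate$length)) substrate$length / 2 else 0
      out <- matrix(NA_real_, n, 3); got <- 0L
      while (got < n) {
        m <- 2L * (n - got)
        xy <- matrix(runif(2 * m, -R, R), ncol = 2)
        keep <- xy[rowSums(xy^2) <= R^2, , drop = FALSE]
        take <- min(nrow(keep), n - got)
        if (take > 0)
          out[got + seq_len(take), 1:2] <- keep[seq_len(take), ]
        got <- got + take
      }
      out[, 3] <- if (H > 0) runif(n, -H, H) else 0
      out %*% t(substrate$frame)
    },
    cylinders = {
      w <- substrate$radii^2
      assign <- sample.int(length(w), n, replace = TRUE, prob = w)
      out <- matrix(0, n, 3)
      for (k in unique(assign)) {
        idx <- which(assign == k)
        R <- substrate$radii[k]
        got <- 0L; loc <- matrix(NA_real_, length(idx), 2)
        while (got < length(idx)) {
          m <- 2L * (length(idx) - got)
          xy <- matrix(runif(2 * m, -R, R), ncol = 2)
          keep <- xy[rowSums(xy^2) <= R^2, , drop = FALSE]
          take <- min(nrow(keep), length(idx) - got)
          if (take > 0) loc[got + seq_len(take), ] <- keep[seq_len(take), ]
          got <- got + take
        }
        fr <- .frame_for_axis(substrate$axes[k, ])
        out[idx, ] <- cbind(loc, 0) %*% t(fr)
      }
      attr(out, "assign") <- assign
      out
    },
    glia = {
      prims <- substrate$prims
      vols <- apply(prims, 1, .prim_volume)
      out <- matrix(NA_real_, n, 3); got <- 0L; tries <- 0L
      while (got < n) {
        k <- sample.int(nrow(prims), 1, prob = vols)
        row <- prims[k, ]
        p <- if (row[1] < 0.5) {
          repeat {
            cand <- runif(3, -row[5], row[5])
            if (sum(cand^2) <= row[5]^2) break
          }
          row[2:4] + cand
        } else {
          repeat {
            xy <- runif(2, -row[5], row[5])
            if (sum(xy^2) <= row[5]^2) break
          }
          fr <- .frame_for_axis(row[7:9])
          row[2:4] + fr %*% c(xy, runif(1, -row[6], row[6]))
        }
        # uniform over the union: accept with probability 1/#containing
        ncover <- sum(vapply(seq_len(nrow(prims)), function(j) {
          q <- as.numeric(p) - prims[j, 2:4]
          if (prims[j, 1] < 0.5) sum(q^2) <= prims[j, 5]^2
          else {
            t <- sum(q * prims[j, 7:9])
            abs(t) <= prims[j, 6] && sum(q^2) - t^2 <= prims[j, 5]^2
          }
        }, logical(1)))
        tries <- tries + 1L
        if (runif(1) <= 1 / ncover) {
          got <- got + 1L
          out[got, ] <- p
        }
        if (tries > 1e4 * n) stop("seeding acceptance rate too low")
      }
      out
    })
  structure(list(positions = pos, substrate = substrate, n = n,
                 seed = seed), class = "walker_ensemble")
}

#' Run the fixed-step random walk
#'
#' Propagates walkers with fixed-length, uniformly oriented off-lattice
#' steps; the time step is tied to the step length by
#' \eqn{dt = \mathrm{step}^2 / (6 D_0)}. Membrane collisions are handled
#' by specular reflection of the residual step. When PGSE pulse timings
#' are supplied, the walk accumulates the time-integrated positions over
#' the two gradient lobes, from which [pgse_signal()] computes phases for
#' any gradient amplitude and direction.
#'
#' @param ensemble A [seed_walkers()] ensemble.
#' @param D0 Diffusivity (um^2/ms), default 2.5.
#' @param duration Walk duration (ms); must cover `Delta + delta` when a
#'   pulse is given.
#' @param step Step length (um), default 0.40.
#' @param pulse Optional [pgse()] (its `delta`, `Delta` set the lobes).
#' @param record_every Record positions every this many steps (0 = none).
#' @param seed RNG seed for the step directions.
#' @return Object of class `mc_walk`: final `positions`, phase integrals
#'   `dX` (n x 3, um ms, first minus second lobe), `dt`, `n_steps`,
#'   optional `trajectory` (frames x walkers x 3).
#' @export
walk <- function(ensemble, D0 = 2.5, duration = NULL, step = 0.40,
                 pulse = NULL, record_every = 0, seed = 1) {
  stopifnot(inherits(ensemble, "walker_ensemble"), step > 0, D0 > 0)
  substrate <- ensemble$substrate
  dt <- step^2 / (6 * D0)
  if (!is.null(pulse)) {
    stopifnot(inherits(pulse, "pgse"))
    if (is.null(duration)) duration <- pulse$Delta + pulse$delta
    if (duration < pulse$Delta + pulse$delta - 1e-9)
      stop("duration must cover Delta + delta")
    n_delta <- round(pulse$delta / dt)
    i_Delta <- round(pulse$Delta / dt)
  } else {
    if (is.null(duration)) stop("duration required without a pulse")
    n_delta <- 0L; i_Delta <- 0L
  }
  n_steps <- round(duration / dt)
  if (substrate$kind == "cylinders") {
    assign <- attr(ensemble$positions, "assign")
    dX <- matrix(0, ensemble$n, 3)
    positions <- matrix(0, ensemble$n, 3)
    set.seed(seed)
    for (k in unique(assign)) {
      idx <- which(assign == k)
      fr <- .frame_for_axis(substrate$axes[k, ])
      pos0 <- ensemble$positions[idx, , drop = FALSE] %*% fr
      res <- mc_walk_cpp(pos0, 2L, substrate$radii[k], 0,
                         matrix(0, 0, 9), step, as.integer(n_steps),
                         as.integer(n_delta), as.integer(i_Delta), 0L)
      dX[idx, ] <- ((res$X1 - res$X2) %*% t(fr)) * dt
      positions[idx, ] <- res$positions %*% t(fr)
    }
    return(structure(list(positions = positions, dX = dX, dt = dt,
                          step = step, n_steps = n_steps,
                          substrate = substrate, pulse = pulse,
                          n = ensemble$n), class = "mc_walk"))
  }
  if (substrate$kind == "cylinder" || substrate$kind == "sphere") {
    feat <- substrate$radius
    if (step > feat / 2)
      warning("step length exceeds half the smallest geometric feature")
  }
  # local-frame transform for oriented cylinders
  rot <- diag(3)
  if (substrate$kind == "cylinder") rot <- substrate$frame
  pos0 <- ensemble$positions %*% rot     # global -> local
  geom <- switch(substrate$kind,
    free = list(type = 0L, R = 0, H = 0, prims = matrix(0, 0, 9)),
    sphere = list(type = 1L, R = substrate$radius, H = 0,
                  prims = matrix(0, 0, 9)),
    cylinder = if (is.finite(substrate$length))
      list(type = 3L, R = substrate$radius, H = substrate$length / 2,
           prims = matrix(0, 0, 9))
    else list(type = 2L, R = substrate$radius, H = 0,
              prims = matrix(0, 0, 9)),
    glia = list(type = 4L, R = 0, H = 0, prims = substrate$prims))
  set.seed(seed)
  res <- mc_walk_cpp(pos0, geom$type, geom$R, geom$H, geom$prims,
                     step, as.integer(n_steps), as.integer(n_delta),
                     as.integer(i_Delta), as.integer(record_every))
  dX <- ((res$X1 - res$X2) %*% t(rot)) * dt   # back to global, um*ms
  positions <- res$positions %*% t(rot)
  out <- list(positions = positions, dX = dX, dt = dt, step = step,
              n_steps = n_steps, substrate = substrate,
              pulse = pulse, n = ensemble$n)
  if (record_every > 0) {
    tr <- res$trajectory
    if (!identical(rot, diag(3))) {
      d <- dim(tr)
      flat <- matrix(tr, ncol = 3)
      tr <- array(flat %*% t(rot), dim = d)
    }
    out$trajectory <- tr
    out$record_dt <- record_every * dt
  }
  structure(out, class = "mc_walk")
}

#' PGSE signal from a completed walk
#'
#' Computes per-direction signals \eqn{S = \langle \cos\phi \rangle} with
#' \eqn{\phi = \gamma g\, d \cdot (X_1 - X_2)}, where \eqn{X_{1,2}} are
#' the walk's time-integrated positions over the two rectangular gradient
#' lobes. The walk must have been run with a `pulse`.
#'
#' @param walk_res An [walk()] result.
#' @param g Gradient amplitude (mT/m).
#' @param directions N x 3 matrix of unit gradient directions.
#' @return Signal vector (length N) with attribute `se`, the per-direction
#'   Monte Carlo standard error.
#' @export
pgse_signal <- function(walk_res, g, directions) {
  stopifnot(inherits(walk_res, "mc_walk"))
  if (is.null(walk_res$pulse))
    stop("walk was run without PGSE pulse timings")
  directions <- matrix(directions, ncol = 3)
  if (g == 0) {
    out <- rep(1, nrow(directions))
    attr(out, "se") <- rep(0, nrow(directions))
    return(out)
  }
  phase <- GAMMA_H * g * (walk_res$dX %*% t(directions))  # n x N, rad
  cosphi <- cos(phase)
  out <- colMeans(cosphi)
  attr(out, "se") <- apply(cosphi, 2, sd) / sqrt(nrow(cosphi))
  out
}

#' Analytic signal of Watson-dispersed restricted cylinders
#'
#' Orientation average of the axon kernel over a Watson ODF whose
#' concentration is matched so that its second Legendre moment equals
#' `params$p2`. This is the axon compartment of the glia-mixture
#' experiment.
#'
#' @param params A [tissue_params()] (uses `r`, `f`, `Dpar`, `p2`, `D0`).
#' @param grad A [pgse()] object for the shell.
#' @param directions N x 3 unit gradient directions.
#' @param axis Mean fiber orientation.
#' @param model Perpendicular model.
#' @param n_odf Size of the spherical quadrature grid for the ODF average.
#' @return Per-direction signal vector.
#' @export
dispersed_cylinder_signal <- function(params, grad, directions,
                                      axis = c(0, 0, 1), model = "neumann",
                                      n_odf = 2000) {
  stopifnot(inherits(params, "tissue_params"), inherits(grad, "pgse"))
  directions <- matrix(directions, ncol = 3)
  axis <- axis / sqrt(sum(axis^2))
  if (params$p2 >= 1) {  # delta ODF: single-orientation kernel
    return(axon_kernel(grad, as.numeric(directions %*% axis), params,
                       model = model))
  }
  k <- watson_kappa_from_p2(params$p2)
  grid <- uniform_directions(n_odf, hemisphere = FALSE)
  w <- exp(k * as.numeric(grid %*% axis)^2)
  w <- w / sum(w)
  xi <- directions %*% t(grid)                     # N x n_odf
  perp <- .perp_model(model)
  log_perp <- log(as.numeric(perp(params$r, grad, params$D0)))
  K <- params$f * exp(-grad$b * params$Dpar * xi^2 +
                        log_perp * (1 - xi^2))
  as.numeric(K %*% w)
}

#' Glia signal-fraction mixture experiment
#'
#' Reproduces the simulation design probing how glia contributions bias
#' the effective MR radius: an analytic Watson-dispersed axon bundle
#' (p2 = 0.7 by default) is mixed, per direction, with Monte Carlo
#' signals from glia substrates at a grid of glia signal fractions; the
#' spherical-mean and spherical-variance radius estimators are then
#' applied to each mixture.
#'
#' @param glia_substrates Named list of `substrate` objects.
#' @param fractions Glia signal fractions in \[0, 1).
#' @param protocol A [connectom_protocol()]-style protocol.
#' @param shells The two b-values used for estimation (default 6 and 30).
#' @param axon Tissue parameters of the axon compartment. The default is
#'   a p2 = 0.7 Watson-dispersed bundle of r = 1 um cylinders with
#'   Dpar = D0 = 2.5 um^2/ms: axons thin relative to glial processes, the
#'   regime in which glia can confound the radius estimate.
#' @param n_walkers Monte Carlo walkers per substrate.
#' @param step Walker step length (um).
#' @param seed Base RNG seed.
#' @return Data frame with columns `substrate`, `fraction`, `r_sm`,
#'   `r_sv`, `sm1`, `sm2`, `sv1`, `sv2`.
#' @export
glia_mixture_experiment <- function(glia_substrates,
                                    fractions = seq(0, 0.5, by = 0.1),
                                    protocol = connectom_protocol(),
                                    shells = c(6, 30),
                                    axon = tissue_params(f = 1, Dpar = 2.5,
                                                         p2 = 0.7, D0 = 2.5,
                                                         r = 1),
                                    n_walkers = 2000, step = 0.40,
                                    seed = 1) {
  stopifnot(all(fractions >= 0), all(fractions < 1))
  bs <- vapply(protocol$shells, `[[`, numeric(1), "b")
  idx <- match(shells, bs)
  if (any(is.na(idx))) stop("requested shells not in the protocol")
  sh <- protocol$shells[idx]
  grads <- lapply(sh, `[[`, "grad")
  pulse <- grads[[1]]
  out <- NULL
  for (s in seq_along(glia_substrates)) {
    sub <- glia_substrates[[s]]
    nm <- names(glia_substrates)[s]
    if (is.null(nm) || nm == "") nm <- paste0("substrate", s)
    ens <- seed_walkers(sub, n_walkers, seed = seed + 1000 * s)
    wk <- walk(ens, D0 = axon$D0, step = step, pulse = pulse,
               seed = seed + 1000 * s + 1)
    glia_sig <- lapply(seq_along(sh), function(i)
      as.numeric(pgse_signal(wk, sh[[i]]$grad$g, sh[[i]]$directions)))
    axon_sig <- lapply(seq_along(sh), function(i)
      dispersed_cylinder_signal(axon, sh[[i]]$grad, sh[[i]]$directions))
    for (fg in fractions) {
      feats <- lapply(seq_along(sh), function(i) {
        sig <- (1 - fg) * axon_sig[[i]] + fg * glia_sig[[i]]
        sd <- shell_data(sh[[i]]$b, sh[[i]]$grad, sh[[i]]$directions,
                         pmax(sig, 0), sigma = 0)
        shell_features(sd, s0_ref = 1)
      })
      fit <- fit_radius(feats, grads, d0 = axon$D0, dpar = axon$Dpar)
      out <- rbind(out, data.frame(
        substrate = nm, fraction = fg,
        r_sm = fit$estimates$sm$r, r_sv = fit$estimates$sv$r,
        sm1 = feats[[1]]$sm, sm2 = feats[[2]]$sm,
        sv1 = feats[[1]]$sv, sv2 = feats[[2]]$sv))
    }
  }
  rownames(out) <- NULL
  out
}

#' Average glia-mixture bias curves over substrate realizations
#'
#' Pools the per-shell features of a [glia_mixture_experiment()] result
#' across substrates (e.g. independent realizations of a glia geometry,
#' analogous to averaging over a sample of reconstructed cells) and
#' re-estimates the radii from the averaged features.
#'
#' @param res Result data frame of [glia_mixture_experiment()].
#' @param grads List of the two [pgse()] objects used.
#' @param d0,dpar Diffusivities assumed by the estimators (um^2/ms).
#' @return Data frame with `fraction`, `r_sm`, `r_sv`, `r4_sm`, `r4_sv`,
#'   `n` (substrates pooled).
#' @export
average_bias_curves <- function(res, grads, d0 = 2.5, dpar = 2.5) {
  fr <- sort(unique(res$fraction))
  out <- lapply(fr, function(f) {
    sub <- res[res$fraction == f, ]
    f1 <- structure(list(sm = mean(sub$sm1), sv = mean(sub$sv1), b = 6),
                    class = "rish_features")
    f2 <- structure(list(sm = mean(sub$sm2), sv = mean(sub$sv2), b = 30),
                    class = "rish_features")
    esm <- loglinear_radius_sm(f1, f2, grads, D0 = d0)
    esv <- loglinear_radius_sv(f1, f2, grads, D0 = d0, Dpar = dpar)
    data.frame(fraction = f, r_sm = esm$r, r_sv = esv$r,
               r4_sm = esm$r4, r4_sv = esv$r4, n = nrow(sub))
  })
  do.call(rbind, out)
}

#' Read an SWC neuron morphology as a substrate
#'
#' Minimal SWC reader: each child-parent pair becomes a finite cylinder
#' (radius = mean of the two node radii), and soma nodes (type 1) become
#' spheres. Intended for neuromorpho-style reconstructions.
#'
#' @param path Path to an SWC text file.
#' @return A glia-kind `substrate`.
#' @export
read_swc <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius",
                                  "parent"))
  prims <- NULL
  nodes <- tab[order(tab$id), ]
  rownames(nodes) <- as.character(nodes$id)
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    if (nd$type == 1) {
      prims <- rbind(prims, c(0, nd$x, nd$y, nd$z, nd$radius, 0, 0, 0, 1))
    }
    if (nd$parent > 0) {
      pa <- nodes[as.character(nd$parent), ]
      d <- c(nd$x - pa$x, nd$y - pa$y, nd$z - pa$z)
      len <- sqrt(sum(d^2))
      if (len < 1e-9) next
      prims <- rbind(prims, c(1, (nd$x + pa$x) / 2, (nd$y + pa$y) / 2,
                              (nd$z + pa$z) / 2,
                              mean(c(nd$radius, pa$radius)), len / 2,
                              d / len))
    }
  }
  if (is.null(prims)) stop("no usable segments in SWC file")
  structure(list(kind = "glia", prims = prims), class = "substrate")
}
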