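# File-level pipeline functions behind the command-line front end:
# phantom synthesis, RISH feature volumes, radius maps, the glia mixture
# simulation table, and segment-profile statistics. All take file paths
# in and write standard formats out (NIfTI, bval/bvec, TSV, JSON).

.read_sigma <- function(sigma, dim3) {
  if (is.character(sigma)) {
    arr <- as.array(RNifti::readNifti(sigma))
    if (!all(dim(arr)[1:3] == dim3)) stop("sigma map grid mismatch")
    arr
  } else {
    array(as.numeric(sigma), dim3)
  }
}

# Per-voxel RISH features of selected shells of a 4-D DWI array.
.volume_features <- function(dwi, bval, bvec, sigma, shells = NULL,
                             delta = 15, Delta = 30, Lmax = 6,
                             tol = 0.25) {
  dims <- dim(dwi)
  grp <- group_shells(bval, tol = tol)
  if (is.null(shells)) shells <- grp$shell_b
  sel <- vapply(shells, function(b) {
    j <- which.min(abs(grp$shell_b - b))
    if (abs(grp$shell_b[j] - b) > tol) NA_integer_ else j
  }, integer(1))
  if (any(is.na(sel)))
    stop("requested shells not present in bval: ",
         paste(shells[is.na(sel)], collapse = ", "))
  if (!any(grp$b0)) stop("no b = 0 volumes for normalization")
  s0 <- apply(dwi[, , , grp$b0, drop = FALSE], 1:3, mean)
  sig <- .read_sigma(sigma, dims[1:3])
  grads <- lapply(grp$shell_b[sel], function(b)
    pgse(g_for_bvalue(b, delta, Delta), delta, Delta))
  sm <- sv <- lapply(sel, function(i) array(NA_real_, dims[1:3]))
  mask <- s0 > 0
  for (j in seq_along(sel)) {
    vols <- which(grp$index == sel[j])
    dirs <- bvec[vols, , drop = FALSE]
    b <- grp$shell_b[sel[j]]
    for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2]))
      for (iz in seq_len(dims[3])) {
        if (!mask[ix, iy, iz]) next
        sdat <- shell_data(b, grads[[j]], dirs, dwi[ix, iy, iz, vols],
                           sigma = sig[ix, iy, iz])
        ft <- shell_features(sdat, s0_ref = s0[ix, iy, iz], Lmax = Lmax)
        sm[[j]][ix, iy, iz] <- ft$sm
        sv[[j]][ix, iy, iz] <- ft$sv
      }
  }
  list(b = grp$shell_b[sel], grads = grads, sm = sm, sv = sv,
       mask = mask, s0 = s0)
}

.echo_config <- function(path, config) {
  config$axonradius_version <-
    as.character(utils::packageVersion("axonradius"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' Write a synthetic phantom acquisition
#'
#' @param out_prefix Output path prefix.
#' @param dim Grid dimensions.
#' @param snr SNR at b = 0.
#' @param seed RNG seed.
#' @param ... Passed to [synth_phantom()].
#' @return Invisibly, the written paths.
#' @export
run_synth <- function(out_prefix, dim = c(10, 10, 3), snr = 50, seed = 1,
                      ...) {
  res <- synth_phantom(out_prefix, dim = dim, snr = snr, seed = seed, ...)
  .echo_config(paste0(out_prefix, "_config.json"),
               list(command = "synth", dim = dim, snr = snr, seed = seed))
  invisible(res)
}

#' Compute SM/SV RISH volumes from a DWI dataset
#'
#' Reads a 4-D NIfTI plus FSL bval/bvec, groups volumes into shells
#' (b rounded to the nearest 0.1 ms/um^2), fits even-order spherical
#' harmonics per voxel and shell (Rician ML when sigma > 0) and writes
#' per-shell normalized SM and SV volumes.
#'
#' @param dwi,bval,bvec Input file paths.
#' @param sigma Noise level: scalar or path to a NIfTI map.
#' @param out_prefix Output prefix; writes
#'   `<prefix>_sm_b<b>.nii.gz` / `<prefix>_sv_b<b>.nii.gz`.
#' @param shells b-values to process (default: all nonzero shells).
#' @param delta,Delta Pulse timings (ms) of the acquisition.
#' @param Lmax Maximum even SH order.
#' @return Invisibly, the feature list (per-shell arrays `sm`, `sv`).
#' @export
run_rish <- function(dwi, bval, bvec, sigma, out_prefix, shells = NULL,
                     delta = 15, Delta = 30, Lmax = 6) {
  if (missing(sigma) || is.null(sigma))
    stop("a noise level is required: pass a scalar sigma or a NIfTI map ",
         "(estimate it during preprocessing, e.g. via MPPCA)")
  img <- RNifti::readNifti(dwi)
  tab <- read_bval_bvec(bval, bvec)
  ft <- .volume_features(as.array(img), tab$bval, tab$bvec, sigma,
                         shells = shells, delta = delta, Delta = Delta,
                         Lmax = Lmax)
  for (j in seq_along(ft$b)) {
    btag <- gsub("\\.", "p", format(ft$b[j]))
    RNifti::writeNifti(RNifti::asNifti(ft$sm[[j]], reference = img),
                       sprintf("%s_sm_b%s.nii.gz", out_prefix, btag))
    RNifti::writeNifti(RNifti::asNifti(ft$sv[[j]], reference = img),
                       sprintf("%s_sv_b%s.nii.gz", out_prefix, btag))
  }
  .echo_config(paste0(out_prefix, "_rish_config.json"),
               list(command = "rish", dwi = dwi, shells = ft$b,
                    delta = delta, Delta = Delta, Lmax = Lmax))
  invisible(ft)
}

#' Map the effective MR radius from a DWI dataset
#'
#' End-to-end voxel-wise estimation: RISH features at the two high-b
#' shells, then the closed-form log-linear SM and SV radius estimators.
#' Writes `<prefix>_r_sm.nii.gz`, `<prefix>_r_sv.nii.gz` and
#' `<prefix>_flags.nii.gz` (bit 1: negative r^4 on the SM path, bit 2:
#' on the SV path, bit 4: invalid input features).
#'
#' @inheritParams run_rish
#' @param dpar Parallel diffusivity: scalar or NIfTI map path (um^2/ms).
#' @param d0 Intrinsic diffusivity (um^2/ms).
#' @param shells The two b-values to use (default c(6, 30)).
#' @param order Estimation paths, subset of c("sm", "sv").
#' @return Invisibly, list of the output arrays.
#' @export
run_estimate <- function(dwi, bval, bvec, sigma, out_prefix, dpar = NULL,
                         d0 = 2.5, shells = c(6, 30),
                         order = c("sm", "sv"), delta = 15, Delta = 30,
                         Lmax = 6) {
  order <- match.arg(order, c("sm", "sv"), several.ok = TRUE)
  if (length(shells) < 2) stop("need two shells for the two-shell estimator")
  if ("sv" %in% order && is.null(dpar))
    stop("the SV path requires dpar (scalar or map)")
  img <- RNifti::readNifti(dwi)
  tab <- read_bval_bvec(bval, bvec)
  arr <- as.array(img)
  ft <- .volume_features(arr, tab$bval, tab$bvec, sigma, shells = shells,
                         delta = delta, Delta = Delta, Lmax = Lmax)
  dims <- dim(arr)[1:3]
  dpar_map <- if (!is.null(dpar)) .read_sigma(dpar, dims)
  r_sm <- r_sv <- array(NA_real_, dims)
  flags <- array(0L, dims)
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2]))
    for (iz in seq_len(dims[3])) {
      if (!ft$mask[ix, iy, iz]) next
      feats <- lapply(seq_along(ft$b), function(j)
        structure(list(sm = ft$sm[[j]][ix, iy, iz],
                       sv = ft$sv[[j]][ix, iy, iz], b = ft$b[j]),
                  class = "rish_features"))
      fit <- fit_radius(feats, ft$grads, d0 = d0,
                        dpar = if (is.null(dpar_map)) NULL
                               else dpar_map[ix, iy, iz],
                        order = order)
      fl <- 0L
      if ("sm" %in% order) {
        e <- fit$estimates$sm
        r_sm[ix, iy, iz] <- e$r
        if ("negative_r4" %in% e$flags) fl <- fl + 1L
        if ("invalid_sm" %in% e$flags) fl <- fl + 4L
      }
      if ("sv" %in% order) {
        e <- fit$estimates$sv
        r_sv[ix, iy, iz] <- e$r
        if ("negative_r4" %in% e$flags) fl <- fl + 2L
        if ("invalid_sv" %in% e$flags) fl <- fl + 4L
      }
      flags[ix, iy, iz] <- fl
    }
  if ("sm" %in% order)
    RNifti::writeNifti(RNifti::asNifti(r_sm, reference = img),
                       paste0(out_prefix, "_r_sm.nii.gz"))
  if ("sv" %in% order)
    RNifti::writeNifti(RNifti::asNifti(r_sv, reference = img),
                       paste0(out_prefix, "_r_sv.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(flags, reference = img),
                     paste0(out_prefix, "_flags.nii.gz"))
  .echo_config(paste0(out_prefix, "_estimate_config.json"),
               list(command = "estimate", dwi = dwi, shells = shells,
                    d0 = d0, dpar = if (is.character(dpar)) dpar
                                    else dpar,
                    order = order, delta = delta, Delta = Delta))
  invisible(list(r_sm = r_sm, r_sv = r_sv, flags = flags))
}

#' Run the glia signal-fraction simulation and write a bias table
#'
#' Runs [glia_mixture_experiment()] over sphere-only, process-only and
#' full (soma + processes) glia substrates and writes a TSV with columns
#' `substrate`, `fraction`, `r_sm`, `r_sv`, `se` (first-order Monte
#' Carlo standard error of the SM radius propagated from the shell
#' signals).
#'
#' @param out_tsv Output TSV path.
#' @param fractions Glia signal-fraction grid.
#' @param n_walkers Walkers per substrate.
#' @param seed RNG seed.
#' @param substrates Named list of substrates; defaults to the three
#'   canonical cases.
#' @param ... Passed to [glia_mixture_experiment()].
#' @return Invisibly, the result data frame.
#' @export
run_simulate <- function(out_tsv, fractions = seq(0, 0.5, by = 0.1),
                         n_walkers = 2000, seed = 1, substrates = NULL,
                         ...) {
  if (is.null(substrates)) {
    set.seed(seed)
    substrates <- list(
      soma = substrate_sphere(5),
      processes = substrate_dispersed_cylinders(runif(20, 1, 2),
                                                seed = seed),
      glia = substrate_glia(seed = seed))
  }
  res <- glia_mixture_experiment(substrates, fractions = fractions,
                                 n_walkers = n_walkers, seed = seed, ...)
  # delta-method SE of r_sm from the relative MC error of the two SMs
  bs <- c(6, 30)
  prot <- connectom_protocol()
  idx <- match(bs, vapply(prot$shells, `[[`, numeric(1), "b"))
  k1 <- kappa(prot$shells[[idx[1]]]$grad$g, 15)
  k2 <- kappa(prot$shells[[idx[2]]]$grad$g, 15)
  rel <- 1 / sqrt(n_walkers)  # per-signal relative error scale
  r4se <- sqrt(2) * rel / (k2 - k1)
  res$se <- ifelse(res$r_sm > 0, r4se / (4 * res$r_sm^3), NA_real_)
  write.table(res, out_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  .echo_config(paste0(out_tsv, ".json"),
               list(command = "simulate", fractions = fractions,
                    n_walkers = n_walkers, seed = seed))
  invisible(res)
}

#' Compute a repeatability report from a profile TSV
#'
#' Input columns: `subject`, `session`, `segment`, `metric` (e.g. the
#' segment-averaged effective MR radius of each subject and session).
#' Writes per-segment TRV/CoV as TSV and a JSON summary including Lin's
#' concordance between the session-mean profiles.
#'
#' @param profile_tsv Input TSV path.
#' @param out_prefix Output prefix (`<prefix>_segments.tsv`,
#'   `<prefix>_summary.json`).
#' @param alpha Significance level.
#' @return Invisibly, the [profile_stats()] result.
#' @export
run_stats <- function(profile_tsv, out_prefix, alpha = 0.05) {
  profile <- read.table(profile_tsv, header = TRUE, sep = "\t")
  res <- profile_stats(profile, alpha = alpha)
  write.table(res$per_segment, paste0(out_prefix, "_segments.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  summary <- list(
    mean_trv = mean(res$per_segment$trv, na.rm = TRUE),
    mean_cov = mean(res$per_segment$cov, na.rm = TRUE),
    ccc = res$concordance$rho_c,
    accuracy = res$concordance$accuracy,
    pearson = res$concordance$pearson,
    command = "stats", alpha = alpha)
  .echo_config(paste0(out_prefix, "_summary.json"), summary)
  invisible(res)
}

#' @importFrom utils read.table write.table
NULL
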