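test_that("walker seeding is uniform, contained and deterministic", {
  sph <- substrate_sphere(4)
  ens <- seed_walkers(sph, 4000, seed = 1)
  expect_true(all(contains(sph, ens$positions)))
  # uniform ball: E||x|| = 3R/4, sd = R sqrt(3/80)
  nrm <- sqrt(rowSums(ens$positions^2))
  se <- 4 * sqrt(3 / 80) / sqrt(4000)
  expect_lt(abs(mean(nrm) - 3) , 3 * se)
  expect_identical(seed_walkers(sph, 100, seed = 7)$positions,
                   seed_walkers(sph, 100, seed = 7)$positions)
  cyl <- substrate_cylinder(2, length = 20, axis = c(1, 1, 0))
  expect_true(all(contains(cyl, seed_walkers(cyl, 500, 2)$positions)))
  gl <- substrate_glia(seed = 3)
  expect_true(all(contains(gl, seed_walkers(gl, 500, 3)$positions)))
})

test_that("free diffusion obeys the Einstein relation", {
  ens <- seed_walkers(substrate_free(), 1500, seed = 2)
  wk <- walk(ens, D0 = 2.5, duration = 8, seed = 3, record_every = 125)
  # fixed-length steps: MSD after k steps is exactly k * step^2 on average
  tr <- wk$trajectory
  times <- (seq_len(dim(tr)[1]) - 1) * wk$record_dt
  for (i in c(3, dim(tr)[1])) {
    disp2 <- rowSums((tr[i, , ] - tr[1, , ])^2)
    se <- sd(disp2) / sqrt(length(disp2))
    expect_lt(abs(mean(disp2) - 6 * 2.5 * times[i]), 3 * se)
  }
})

test_that("restricted diffusion in a cylinder saturates transversally", {
  cyl <- substrate_cylinder(3)
  ens <- seed_walkers(cyl, 1200, seed = 4)
  wk <- walk(ens, D0 = 2.5, duration = 40, seed = 5, record_every = 500)
  tr <- wk$trajectory
  expect_true(all(contains(cyl, wk$positions)))
  nf <- dim(tr)[1]
  dz <- tr[nf, , 3] - tr[1, , 3]
  t_end <- (nf - 1) * wk$record_dt
  se_z <- var(dz) * sqrt(2 / (length(dz) - 1))
  expect_lt(abs(var(dz) - 2 * 2.5 * t_end), 4 * se_z)  # free along axis
  # transverse displacement variance saturates near r^2/2 per coordinate
  dx <- tr[nf, , 1] - tr[1, , 1]
  expect_equal(var(dx), 9 / 2, tolerance = 0.15)
})

test_that("zero-duration walks leave positions unchanged", {
  ens <- seed_walkers(substrate_sphere(3), 50, seed = 6)
  wk <- walk(ens, duration = 1e-9, seed = 7)
  expect_equal(wk$positions, ens$positions)
})

test_that("free-diffusion PGSE signal matches the closed form", {
  ens <- seed_walkers(substrate_free(), 4000, seed = 8)
  p <- pgse(g_for_bvalue(1, 15, 30), 15, 30)
  wk <- walk(ens, D0 = 2.5, pulse = p, seed = 9)
  s <- pgse_signal(wk, p$g, diag(3))
  for (i in 1:3)
    expect_lt(abs(s[i] - exp(-1 * 2.5)), 3 * attr(s, "se")[i])
  s0 <- pgse_signal(wk, 0, diag(3))
  expect_equal(as.numeric(s0), rep(1, 3))
})

test_that("perpendicular cylinder signal matches Van Gelderen", {
  cyl <- substrate_cylinder(3)
  ens <- seed_walkers(cyl, 4000, seed = 10)
  p <- pgse(273, 15, 30)
  wk <- walk(ens, D0 = 2.5, pulse = p, seed = 11)
  s <- pgse_signal(wk, 273, matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE))
  vg <- as.numeric(vangelderen_perp(3, p, 2.5))
  for (i in 1:2) expect_lt(abs(s[i] - vg), 3 * attr(s, "se")[i])
})

test_that("signals are invariant under joint substrate/gradient rotation", {
  set.seed(12)
  R <- axonradius:::random_rotation()
  dirs <- uniform_directions(20)
  p <- pgse(200, 15, 30)
  sub1 <- substrate_cylinder(3, axis = c(0, 0, 1))
  # rotate the substrate's full frame so identical local trajectories
  # describe the same physical walk in both poses
  sub2 <- sub1
  sub2$axis <- as.numeric(R %*% sub1$axis)
  sub2$frame <- R %*% sub1$frame
  ens1 <- seed_walkers(sub1, 800, seed = 12)
  ens2 <- seed_walkers(sub2, 800, seed = 12)
  s1 <- as.numeric(pgse_signal(walk(ens1, pulse = p, seed = 13), 200, dirs))
  s2 <- as.numeric(pgse_signal(walk(ens2, pulse = p, seed = 13), 200,
                               dirs %*% t(R)))
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("walks are bit-reproducible under fixed seeds", {
  gl <- substrate_glia(seed = 1)
  ens <- seed_walkers(gl, 300, seed = 14)
  w1 <- walk(ens, pulse = pgse(273, 15, 30), seed = 15)
  w2 <- walk(ens, pulse = pgse(273, 15, 30), seed = 15)
  expect_identical(w1$positions, w2$positions)
  expect_identical(w1$dX, w2$dX)
  expect_true(all(contains(gl, w1$positions)))
})

test_that("spherical substrates produce negligible spherical variance", {
  sph <- substrate_sphere(5)
  ens <- seed_walkers(sph, 3000, seed = 16)
  prot <- connectom_protocol()
  sh <- prot$shells[[4]]
  wk <- walk(ens, pulse = sh$grad, seed = 17)
  s <- pgse_signal(wk, sh$grad$g, sh$directions)
  ft <- shell_features(shell_data(sh$b, sh$grad, sh$directions,
                                  pmax(as.numeric(s), 0), 0), 1)
  # noise floor of the l=2 norm from the per-direction MC error
  floor <- mean(attr(s, "se")) / sqrt(4 * pi * 5) * sqrt(5)
  expect_lt(ft$sv, 3 * max(floor, 1e-4))
})

test_that("dispersed-cylinder signal has the ODF limit behaviors", {
  g <- high_b_shells()[[1]]$grad
  dirs <- uniform_directions(40)
  iso <- tissue_params(f = 0.7, Dpar = 2.2, p2 = 0, r = 2)
  s_iso <- dispersed_cylinder_signal(iso, g, dirs)
  expect_lt(diff(range(s_iso)) / mean(s_iso), 0.02)
  coh <- tissue_params(f = 0.7, Dpar = 2.2, p2 = 1, r = 2)
  s_coh <- dispersed_cylinder_signal(coh, g, dirs)
  expect_equal(s_coh, axon_kernel(g, dirs[, 3], coh), tolerance = 1e-12)
})

test_that("dispersed-cylinder spherical mean matches the forward model", {
  sh <- high_b_shells()
  tp <- tissue_params(f = 0.8, Dpar = 2.5, p2 = 0.7, r = 3)
  for (s in sh) {   # bDpar = 15 and 75
    sig <- dispersed_cylinder_signal(tp, s$grad, s$directions)
    expect_equal(mean(sig), as.numeric(sm_forward(s$grad, tp)),
                 tolerance = 0.02)
  }
})

test_that("glia mixture experiment is unbiased at zero glia fraction", {
  res <- glia_mixture_experiment(list(soma = substrate_sphere(5)),
                                 fractions = 0, n_walkers = 10, seed = 1)
  expect_equal(res$r_sm, 1, tolerance = 0.02)
  expect_equal(res$r_sv, 1, tolerance = 0.05)
  expect_named(res, c("substrate", "fraction", "r_sm", "r_sv",
                      "sm1", "sm2", "sv1", "sv2"))
})

test_that("SWC morphologies load as containing substrates", {
  swc <- file.path(tempdir(), "toy.swc")
  writeLines(c("# toy neuron",
               "1 1 0 0 0 4 -1",
               "2 3 8 0 0 1 1",
               "3 3 16 0 0 1 2"), swc)
  sub <- read_swc(swc)
  expect_s3_class(sub, "substrate")
  expect_true(contains(sub, matrix(c(0, 0, 0), 1)))       # soma center
  expect_true(contains(sub, matrix(c(12, 0.5, 0), 1)))    # along process
  expect_false(contains(sub, matrix(c(12, 3, 0), 1)))     # off process
  ens <- seed_walkers(sub, 200, seed = 18)
  expect_true(all(contains(sub, ens$positions)))
})
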