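test_that("two-shell log-linear estimators invert the forward models", {
  grads <- high_b_grads()
  for (r in c(0, 1, 3, 4.5)) for (dpar in c(1.8, 2.5)) {
    tp <- tissue_params(f = 0.65, Dpar = dpar, p2 = 0.7, r = r)
    ft <- forward_features(tp)
    rsm <- loglinear_radius_sm(ft[[1]], ft[[2]], grads)
    expect_equal(rsm$r4, r^4, tolerance = 1e-9)
    if (r > 0) {
      rsv <- loglinear_radius_sv(ft[[1]], ft[[2]], grads, Dpar = dpar)
      expect_equal(rsv$r4, r^4, tolerance = 1e-9)
    }
  }
})

test_that("estimates are invariant to overall signal scaling", {
  grads <- high_b_grads()
  tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = 3)
  ft <- forward_features(tp)
  for (c_scale in c(0.1, 7)) {
    fs <- lapply(ft, function(f) {
      f$sm <- f$sm * c_scale; f$sv <- f$sv * c_scale; f
    })
    expect_equal(loglinear_radius_sm(fs[[1]], fs[[2]], grads)$r4, 81,
                 tolerance = 1e-9)
    expect_equal(loglinear_radius_sv(fs[[1]], fs[[2]], grads,
                                     Dpar = 2.2)$r4, 81, tolerance = 1e-9)
  }
})

test_that("SV estimate is independent of p2 and f", {
  grads <- high_b_grads()
  res <- lapply(list(c(0.9, 0.3), c(0.2, 0.9)), function(pf) {
    tp <- tissue_params(f = pf[1], Dpar = 2.2, p2 = pf[2], r = 3)
    ft <- forward_features(tp)
    loglinear_radius_sv(ft[[1]], ft[[2]], grads, Dpar = 2.2)$r4
  })
  expect_equal(res[[1]], res[[2]], tolerance = 1e-12)
})

test_that("noise can push r^4 negative, which is flagged and clipped", {
  grads <- high_b_grads()
  tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = 0.5)
  ft <- forward_features(tp)
  # perturb the high-b SM upward so the apparent decay is slower than a stick
  ft[[2]]$sm <- ft[[2]]$sm * 1.05
  est <- loglinear_radius_sm(ft[[1]], ft[[2]], grads)
  expect_lt(est$r4, 0)
  expect_equal(est$r, 0)
  expect_true("negative_r4" %in% est$flags)
  ft[[2]]$sm <- -1
  est2 <- loglinear_radius_sm(ft[[1]], ft[[2]], grads)
  expect_true(is.nan(est2$r4))
  expect_true("invalid_sm" %in% est2$flags)
})

test_that("degenerate designs and regime violations are rejected", {
  tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = 3)
  ft <- forward_features(tp)
  same <- list(high_b_grads()[[1]], high_b_grads()[[1]])
  expect_error(loglinear_radius_sm(ft[[1]], ft[[2]], same), "degenerate")
  expect_error(loglinear_radius_sv(ft[[1]], ft[[2]], high_b_grads(),
                                   Dpar = 0.1), "regime")
})

test_that("nonlinear estimator matches log-linear on same-model data", {
  grads <- high_b_grads()
  for (r in c(1, 3)) {
    tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = r)
    ft <- forward_features(tp)
    nl_sm <- nonlinear_radius(ft, grads, model = "neumann", order = "sm")
    expect_equal(nl_sm$r, r, tolerance = 1e-6)
    nl_sv <- nonlinear_radius(ft, grads, Dpar = 2.2, model = "neumann",
                              order = "sv")
    expect_equal(nl_sv$r, r, tolerance = 1e-6)
  }
})

test_that("Van Gelderen nonlinear estimator recovers its own data exactly", {
  grads <- high_b_grads()
  tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = 3)
  ft <- forward_features(tp, model = "vangelderen")
  nl <- nonlinear_radius(ft, grads, model = "vangelderen", order = "sm")
  expect_equal(nl$r, 3, tolerance = 1e-6)
})

test_that("Neumann inversion of Van Gelderen data stays within 5%", {
  grads <- high_b_grads()
  for (r in c(1, 2, 3)) {
    tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = r)
    ft <- forward_features(tp, model = "vangelderen")
    ll <- loglinear_radius_sm(ft[[1]], ft[[2]], grads)
    expect_lt(abs(ll$r - r) / r, 0.05)
  }
})

test_that("more than two shells are combined by log-linear regression", {
  prot <- connectom_protocol()
  sh <- prot$shells[3:5]     # b = 2.5, 6, 30
  grads <- lapply(sh, `[[`, "grad")
  tp <- tissue_params(f = 0.65, Dpar = 2.5, p2 = 0.7, r = 3)
  ft <- forward_features(tp, shells = sh)
  fit <- fit_radius(ft, grads, dpar = 2.5)
  expect_equal(unname(coef(fit)[["sm"]]), 3, tolerance = 1e-8)
  expect_equal(unname(coef(fit)[["sv"]]), 3, tolerance = 1e-8)
})

test_that("noisy SM inversion is accurate in the median", {
  grads <- high_b_grads()
  shells <- high_b_shells()
  tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = 3)
  clean <- lapply(shells, function(s)
    dispersed_cylinder_signal(tp, s$grad, s$directions))
  set.seed(19)
  r_hat <- replicate(300, {
    # SNR 50 on the shell signal (signal / sigma = 50)
    ft <- lapply(seq_along(shells), function(i) {
      s <- shells[[i]]
      sigma <- mean(clean[[i]]) / 50
      noisy <- add_rician_noise(clean[[i]], sigma)
      shell_features(shell_data(s$b, s$grad, s$directions, noisy, sigma),
                     1, method = "ols")
    })
    loglinear_radius_sm(ft[[1]], ft[[2]], grads)$r
  })
  expect_lt(abs(median(r_hat) - 3) / 3, 0.05)
})

test_that("fit_radius object supports the standard methods", {
  grads <- high_b_grads()
  tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = 3)
  ft <- forward_features(tp)
  fit <- fit_radius(ft, grads, dpar = 2.2)
  expect_s3_class(fit, "radius_fit")
  expect_equal(unname(coef(fit)), c(3, 3), tolerance = 1e-9)
  expect_output(print(fit), "r_sm")
  expect_output(print(summary(fit)), "Per-shell")
  # predictions reproduce the fitted shells' features
  expect_equal(predict(fit, order = "sm"),
               vapply(ft, `[[`, numeric(1), "sm"), tolerance = 1e-9)
  expect_equal(max(abs(residuals(fit, order = "sv"))), 0, tolerance = 1e-9)
  pdf(NULL); plot(fit); dev.off()
})

test_that("diffusivity sweep is driven by Dpar far more than by D0", {
  shells <- high_b_shells()
  tp <- tissue_params(f = 0.65, Dpar = 2.2, p2 = 0.7, r = 3)
  ft <- forward_features(tp)
  sm_pairs <- matrix(c(ft[[1]]$sm, ft[[2]]$sm), 1)
  sv_pairs <- matrix(c(ft[[1]]$sv, ft[[2]]$sv), 1)
  D0g <- c(2.0, 2.5, 3.0); Dpg <- c(1.6, 2.2, 2.8)
  sw <- diffusivity_sweep(sm_pairs, sv_pairs, high_b_grads(), c(6, 30),
                          D0g, Dpg)
  # self-consistent cell: assumed Dpar equals the generative one
  expect_equal(sw["2.5", "2.2"], 0, tolerance = 1e-9)
  # SV radius decreases as assumed Dpar increases -> difference increases
  expect_true(all(apply(sw, 1, diff) > 0))
  # Dpar dominates the difference relative to D0
  dpar_span <- max(abs(sw[2, 3] - sw[2, 1]))
  d0_span <- max(abs(sw[3, 2] - sw[1, 2]))
  expect_gt(dpar_span, 5 * d0_span)
  expect_error(diffusivity_sweep(sm_pairs[0, , drop = FALSE],
                                 sv_pairs[0, , drop = FALSE],
                                 high_b_grads(), c(6, 30), D0g, Dpg),
               "empty")
})
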