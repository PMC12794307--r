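test_that("constant signals load only the l=0 coefficient", {
  dirs <- uniform_directions(60)
  sd0 <- shell_data(6, pgse(122, 15, 30), dirs, rep(2, 60), sigma = 0)
  cf <- fit_sh_ml(sd0, Lmax = 6, method = "ols")
  l <- attr(cf, "l")
  expect_lt(max(abs(cf[l > 0])), 1e-8 * abs(cf[l == 0]))
})

test_that("the l=0 RISH feature equals the spherical mean", {
  # S0 convention: norm / sqrt(4 pi) reproduces the plain average of the
  # signal over a uniform direction set
  g <- high_b_grads()[[1]]
  tp <- tissue_params(f = 0.7, Dpar = 2.2, p2 = 0.7, r = 3)
  dirs <- uniform_directions(90)
  sig <- dispersed_cylinder_signal(tp, g, dirs)
  sd0 <- shell_data(6, g, dirs, sig, sigma = 0)
  ft <- shell_features(sd0, s0_ref = 1)
  expect_equal(ft$sm, mean(sig), tolerance = 0.01)
})

test_that("RISH features are invariant to direction-frame rotation", {
  g <- high_b_grads()[[2]]
  tp <- tissue_params(f = 0.7, Dpar = 2.2, p2 = 0.7, r = 3)
  dirs <- uniform_directions(120)
  sig <- dispersed_cylinder_signal(tp, g, dirs, axis = c(0.3, -0.2, 0.93))
  f0 <- shell_features(shell_data(30, g, dirs, sig, 0), 1)
  set.seed(42)
  for (i in 1:3) {
    R <- axonradius:::random_rotation()
    # rotating directions and substrate together = evaluating the same
    # physical signal in a rotated frame
    sig_r <- dispersed_cylinder_signal(tp, g, dirs %*% t(R),
                                       axis = as.numeric(R %*% c(0.3, -0.2, 0.93)))
    fr <- shell_features(shell_data(30, g, dirs %*% t(R), sig_r, 0), 1)
    expect_lt(abs(fr$sm - f0$sm) / f0$sm, 0.005)
    expect_lt(abs(fr$sv - f0$sv) / f0$sv, 0.005)
  }
})

test_that("isotropic signals give zero spherical variance", {
  g <- high_b_grads()[[1]]
  dirs <- uniform_directions(60)
  ft <- shell_features(shell_data(6, g, dirs, rep(0.5, 60), 0), 1)
  expect_lt(ft$sv, 1e-10)
})

test_that("ML and OLS coefficients agree at high SNR", {
  g <- high_b_grads()[[1]]
  tp <- tissue_params(f = 0.7, Dpar = 2.2, p2 = 0.7, r = 3)
  dirs <- uniform_directions(90)
  sig <- dispersed_cylinder_signal(tp, g, dirs)
  set.seed(7)
  noisy <- add_rician_noise(sig, max(sig) / 200)
  shell <- shell_data(6, g, dirs, noisy, sigma = max(sig) / 200)
  ml <- fit_sh_ml(shell, method = "ml")
  ols <- fit_sh_ml(shell, method = "ols")
  expect_lt(abs(ml[1] - ols[1]) / abs(ols[1]), 0.01)
})

test_that("Rician ML reduces the low-SNR bias of the mean coefficient", {
  # signals from a known SH representation at SNR 5: OLS inherits the
  # Rician floor, ML with known sigma corrects most of it
  g <- high_b_grads()[[1]]
  dirs <- uniform_directions(90)
  tp <- tissue_params(f = 0.7, Dpar = 2.2, p2 = 0.7, r = 3)
  B <- sh_design(dirs, 4)
  c_true <- qr.coef(qr(B), dispersed_cylinder_signal(tp, g, dirs))
  clean <- pmax(as.numeric(B %*% c_true), 0)
  sigma <- mean(clean) / 5
  set.seed(11)
  reps <- 200
  err_ml <- err_ols <- numeric(reps)
  for (i in seq_len(reps)) {
    noisy <- add_rician_noise(clean, sigma)
    sh <- shell_data(6, g, dirs, noisy, sigma = sigma)
    err_ml[i] <- fit_sh_ml(sh, Lmax = 4, method = "ml")[1] - c_true[1]
    err_ols[i] <- fit_sh_ml(sh, Lmax = 4, method = "ols")[1] - c_true[1]
  }
  expect_gt(mean(err_ols), 0)              # positive Rician bias
  expect_lt(abs(mean(err_ml)), abs(mean(err_ols)))
})

test_that("SV noise bias follows the noncentral-chi expectation", {
  expect_equal(sv_bias_probe(0.4, 0, 100), 0.4)
  # central chi(5) mean for sv_true = 0
  sigma <- 0.03
  chi5_mean <- sigma * sqrt(2) * gamma(3) / gamma(2.5)
  expect_equal(sv_bias_probe(0, sigma, 2e4, seed = 3), chi5_mean,
               tolerance = 0.01)
  # bias strictly positive and decreasing as sv_true/sigma grows
  bias <- vapply(c(0, 0.05, 0.1, 0.2, 0.4),
                 function(sv) sv_bias_probe(sv, sigma, 2e4, seed = 4) - sv,
                 numeric(1))
  expect_true(all(bias > 0))
  expect_true(all(diff(bias) < 0))
})

test_that("SH fitting validates its inputs", {
  dirs <- uniform_directions(10)
  sd0 <- shell_data(6, pgse(122, 15, 30), dirs, rep(1, 10), sigma = 0)
  expect_error(fit_sh_ml(sd0, Lmax = 6), "fewer directions")
  # degenerate set: all directions identical
  degen <- matrix(rep(c(0, 0, 1), each = 40), ncol = 3)
  sd1 <- shell_data(6, pgse(122, 15, 30), degen, rep(1, 40), sigma = 0)
  expect_error(fit_sh_ml(sd1, Lmax = 6), "rank")
  cf <- fit_sh_ml(shell_data(6, pgse(122, 15, 30), uniform_directions(60),
                             rep(1, 60), sigma = 0), method = "ols")
  expect_error(rish_features(cf, s0_ref = 0), "positive")
  expect_error(fit_sh_ml(shell_data(6, pgse(122, 15, 30),
                                    uniform_directions(60), rep(1, 60),
                                    sigma = 0), method = "ml"),
               "sigma")
})
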