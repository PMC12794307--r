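test_that("kappa follows its closed form and scaling laws", {
  expect_equal(kappa(0, 15), 0)
  expect_equal(kappa(200, 15) / kappa(100, 15), 4, tolerance = 1e-12)
  expect_equal(kappa(100, 30) / kappa(100, 15), 2, tolerance = 1e-12)
  expect_error(kappa(100, 15, D0 = 0))
  expect_error(kappa(100, 15, D0 = -1))
})

test_that("kappa * r^4 equals -log(neumann_perp) to machine precision", {
  grads <- list(pgse(273, 15, 30), pgse(122, 15, 30), pgse(35, 10, 40))
  for (g in grads) for (r in c(0.5, 1, 3, 5)) for (D0 in c(1.5, 2.5)) {
    x <- kappa(g$g, g$delta, D0) * r^4
    # absolute agreement at machine precision of exp(); the relative
    # error of log(exp(-x)) grows as eps/x for small exponents
    expect_lt(abs(x + log(as.numeric(neumann_perp(r, g, D0)))),
              1e-12 * max(1, x))
  }
})

test_that("perpendicular attenuations lie in (0,1] and decrease with r", {
  g <- pgse(273, 15, 30)
  r <- seq(0, 6, by = 0.5)
  for (f in list(neumann_perp, vangelderen_perp)) {
    s <- as.numeric(f(r, g, 2.5))
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(diff(s) <= 0))
    expect_equal(s[1], 1)
  }
})

test_that("Neumann regime flag reflects the long-pulse condition", {
  g <- pgse(273, 15, 30)
  expect_true(attr(neumann_perp(1, g, 2.5), "regime_ok"))   # 10 r^2/D0 = 4
  expect_false(attr(neumann_perp(3, g, 2.5), "regime_ok"))  # 10 r^2/D0 = 36
})

test_that("Van Gelderen converges to Neumann in the long-pulse limit", {
  g <- pgse(273, 15, 30)
  # r = 1 um: delta D0 / r^2 = 37.5 >> 1
  vg <- as.numeric(vangelderen_perp(1, g, 2.5))
  nm <- as.numeric(neumann_perp(1, g, 2.5))
  expect_lt(abs(vg - nm) / nm, 0.01)
  # smaller radii get even closer
  vg2 <- as.numeric(vangelderen_perp(0.5, g, 2.5))
  nm2 <- as.numeric(neumann_perp(0.5, g, 2.5))
  expect_lt(abs(vg2 - nm2) / nm2, abs(vg - nm) / nm)
  expect_true(attr(vangelderen_perp(1, g, 2.5), "converged"))
})

test_that("axon kernel has the stick limits", {
  g <- high_b_grads()[[2]]
  tp0 <- tissue_params(f = 0.6, Dpar = 2.2, p2 = 0.7, r = 0)
  expect_equal(axon_kernel(g, 0, tp0), 0.6, tolerance = 1e-12)
  expect_equal(axon_kernel(g, 1, tp0), 0.6 * exp(-g$b * 2.2),
               tolerance = 1e-12)
})

test_that("sm_forward matches numerical spherical mean of the kernel", {
  g <- high_b_grads()[[2]]  # b = 30, bDpar = 75
  for (r in c(0.5, 2, 3)) {
    tp <- tissue_params(f = 0.7, Dpar = 2.5, p2 = 0.7, r = r)
    num <- integrate(function(x) axon_kernel(g, x, tp), 0, 1,
                     rel.tol = 1e-10)$value
    expect_equal(as.numeric(sm_forward(g, tp)), num, tolerance = 0.01)
  }
})

test_that("sv_forward matches the numerical l=2 projection of the kernel", {
  for (g in high_b_grads()) {  # bDpar = 13.2 and 66
    for (r in c(1, 3)) {
      tp <- tissue_params(f = 0.7, Dpar = 2.2, p2 = 0.6, r = r)
      k2 <- integrate(function(x) (3 * x^2 - 1) / 2 * axon_kernel(g, x, tp),
                      0, 1, rel.tol = 1e-10)$value
      expect_equal(as.numeric(sv_forward(g, tp)), tp$p2 * abs(k2),
                   tolerance = 0.02)
    }
  }
})

test_that("forward-model shell ratios cancel the ODF/fraction prefactors", {
  shells <- high_b_shells()
  ratio <- function(fun, tp)
    as.numeric(fun(shells[[1]]$grad, tp)) /
    as.numeric(fun(shells[[2]]$grad, tp))
  base <- tissue_params(f = 0.7, Dpar = 2.0, p2 = 0.5, r = 3)
  alt_f <- tissue_params(f = 0.2, Dpar = 2.0, p2 = 0.9, r = 3)
  expect_equal(ratio(sm_forward, base), ratio(sm_forward, alt_f),
               tolerance = 1e-12)
  expect_equal(ratio(sv_forward, base), ratio(sv_forward, alt_f),
               tolerance = 1e-12)
  # SM ratio is also independent of Dpar
  alt_d <- tissue_params(f = 0.7, Dpar = 1.5, p2 = 0.5, r = 3)
  expect_equal(ratio(sm_forward, base), ratio(sm_forward, alt_d),
               tolerance = 1e-12)
})

test_that("sv_forward rejects the out-of-regime factor sign change", {
  tp <- tissue_params(f = 0.7, Dpar = 2.0, p2 = 0.5, r = 3)
  low_b <- pgse(g_for_bvalue(0.5, 15, 30), 15, 30)  # bDpar = 1 < 3/2
  expect_error(sv_forward(low_b, tp), "regime")
  expect_error(sm_forward(pgse(0, 15, 30), tp))
})

test_that("Watson concentration inversion reproduces the target p2", {
  for (p2 in c(0.1, 0.3, 0.7, 0.9)) {
    k <- axonradius:::watson_kappa_from_p2(p2)
    expect_equal(axonradius:::watson_p2(k), p2, tolerance = 1e-8)
  }
  expect_equal(axonradius:::watson_kappa_from_p2(0), 0)
  expect_error(axonradius:::watson_kappa_from_p2(0.9999), "attainable")
})
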