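test_that("electron transport has the right limits and theta->0 form", {
  kp <- kinetic_params()
  expect_identical(electron_transport(0, kp), 0)
  expect_equal(electron_transport(1e9, kp), kp$jmax, tolerance = 1e-4)
  expect_true(all(electron_transport(c(10, 100, 1000), kp) <= kp$jmax))
  ## theta -> 0 degenerates to the rectangular hyperbola
  kp0 <- kinetic_params(theta = 0)
  i <- c(5, 50, 500, 5000)
  x <- kp0$s_factor * kp0$y2ll * i
  expect_equal(electron_transport(i, kp0), x * kp0$jmax / (x + kp0$jmax),
               tolerance = 1e-12)
  ## quadratic-root oracle at small positive theta approaches the same
  kp_eps <- kinetic_params(theta = 1e-6)
  expect_equal(electron_transport(i, kp_eps), electron_transport(i, kp0),
               tolerance = 1e-4)
})

test_that("net rate hits the compensation point and the Rubisco ceiling", {
  kp <- kinetic_params()
  expect_equal(net_rate(kp$gamma_star, 150, kp), -kp$rd, tolerance = 1e-12)
  expect_equal(net_rate(1e9, 1e12, kp), kp$vcmax - kp$rd, tolerance = 1e-3)
  expect_identical(net_rate(0, 100, kp), -kp$rd)
})

test_that("net rate matches an independently coded FvCB evaluation", {
  kp <- kinetic_params()
  set.seed(99)
  cc <- runif(200, 1, 2000)
  j <- runif(200, 0, 300)
  ## independent formulation: explicit branch selection instead of pmin
  oracle <- vapply(seq_along(cc), function(i) {
    wc <- kp$vcmax * cc[i] / (cc[i] + kp$kc * (1 + kp$o2 / kp$ko))
    wj <- j[i] * cc[i] / (4 * cc[i] + 8 * kp$gamma_star)
    w <- if (wc < wj) wc else wj
    w * (1 - kp$gamma_star / cc[i]) - kp$rd
  }, numeric(1))
  expect_equal(net_rate(cc, j, kp), oracle, tolerance = 1e-12)
})

test_that("assimilation is monotone in Cc and in J", {
  kp <- kinetic_params()
  cc <- seq(5, 2000, by = 5)
  a1 <- net_rate(cc, 120, kp)
  expect_true(all(diff(a1) > -1e-12))
  j <- seq(0, 250, by = 1)
  a2 <- net_rate(400, j, kp)
  expect_true(all(diff(a2) > -1e-12))
  ## min-limitation: never above either single-limitation curve
  kco <- kp$kc * (1 + kp$o2 / kp$ko)
  above <- cc > kp$gamma_star   # min-rule bounds apply above compensation
  wc_only <- (1 - kp$gamma_star / cc) * kp$vcmax * cc / (cc + kco) - kp$rd
  wj_only <- (1 - kp$gamma_star / cc) * 120 * cc /
    (4 * cc + 8 * kp$gamma_star) - kp$rd
  expect_true(all(a1[above] <= wc_only[above] + 1e-12))
  expect_true(all(a1[above] <= wj_only[above] + 1e-12))
})

test_that("kinetics distribute and re-integrate to the leaf-area values", {
  v <- tiny_volume()
  kp <- kinetic_params()
  kin <- distribute_kinetics(v, kp)
  vc_back <- kin$vcmax_vol * sum(kin$chloro_mask) * kin$vox_vol /
    kin$leaf_area
  rd_back <- kin$rd_vol * sum(kin$resp_mask) * kin$vox_vol / kin$leaf_area
  expect_equal(vc_back, kp$vcmax, tolerance = 1e-9)
  expect_equal(rd_back, kp$rd, tolerance = 1e-9)
  ## doubling chloroplast volume halves the density
  kin2 <- distribute_kinetics(v, kinetic_params(vcmax = 2 * kp$vcmax))
  expect_equal(kin2$vcmax_vol, 2 * kin$vcmax_vol, tolerance = 1e-12)
  ## zero respiration
  kin0 <- distribute_kinetics(v, kinetic_params(rd = 0))
  expect_identical(kin0$rd_vol, 0)
  ## no chloroplasts is an error
  lab <- array(leaf_labels()[["mc_cytosol"]], c(4, 4, 4))
  expect_error(distribute_kinetics(as_labelled_volume(lab, 1), kp),
               "no chloroplast")
})

test_that("PhiPSII limits: low light gives Y(II)LL, high light decays", {
  kp <- kinetic_params()
  alpha <- kp$absorptance
  ## low-light series limit of the hyperbola: J ~ s y2ll alpha Q
  q <- c(1, 2, 5)
  j <- electron_transport(alpha * q, kp)
  phi <- phi_psii(j, q, kp)
  expect_equal(phi, rep(kp$y2ll, 3), tolerance = 1e-3)
  ## PhiPSII non-increasing in Q, tending to 0
  qs <- c(10, 100, 500, 1000, 2000, 5000, 1e5)
  phis <- phi_psii(electron_transport(alpha * qs, kp), qs, kp)
  expect_true(all(diff(phis) < 1e-12))
  expect_lt(phis[length(phis)], 0.01)
  ## zero incident light is undefined
  expect_error(phi_psii(10, 0, kp), "must be > 0")
})
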