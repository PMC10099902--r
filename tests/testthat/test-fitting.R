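test_that("forward curves hit the dark and compensation limits", {
  kp <- kinetic_params()
  pr <- measurement_protocol(aci_ci = c(kp$gamma_star, 100, 300, 700, 1500),
                             aq_q = c(1e-6, 100, 500, 2000))
  ds <- forward_curves(kp, pr)
  ## C_i at the compensation point
  expect_equal(ds$a_n[ds$curve == "aci"][1], -kp$rd, tolerance = 1e-9)
  ## vanishing light
  expect_equal(ds$a_n[ds$curve == "aq"][1], -kp$rd, tolerance = 1e-6)
  ## doubling vcmax doubles A + Rd in the Rubisco-limited region
  kp2 <- kinetic_params(vcmax = 2 * kp$vcmax, jmax = 1e6)
  kp1 <- kinetic_params(vcmax = kp$vcmax, jmax = 1e6)
  p2 <- forward_curves(kp2, measurement_protocol())
  p1 <- forward_curves(kp1, measurement_protocol())
  low <- p1$curve == "aci" & p1$x <= 150
  expect_equal((p2$a_n[low] + kp2$rd) / (p1$a_n[low] + kp1$rd),
               rep(2, sum(low)), tolerance = 1e-9)
})

test_that("synthetic datasets are seeded and unbiased", {
  kp <- kinetic_params()
  ds0 <- synth_dataset(kp, noise_sd = c(0, 0), seed = 1)
  expect_equal(ds0$a_n, forward_curves(kp)$a_n, tolerance = 1e-12)
  d1 <- synth_dataset(kp, seed = 7)
  d2 <- synth_dataset(kp, seed = 7)
  expect_identical(d1$a_n, d2$a_n)
  expect_false(identical(d1$a_n, synth_dataset(kp, seed = 8)$a_n))
  ## Monte-Carlo mean of one point within 3 SE of the clean value
  sd_a <- 0.5; n <- 1000
  vals <- vapply(seq_len(n), function(s) {
    synth_dataset(kp, noise_sd = c(sd_a, 0), seed = s)$a_n[1]
  }, numeric(1))
  clean <- forward_curves(kp)$a_n[1]
  expect_lt(abs(mean(vals) - clean), 3 * sd_a / sqrt(n))
})

test_that("gas-exchange CSV round-trips", {
  ds <- synth_dataset(kinetic_params(), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_gas_exchange(ds, path)
  back <- read_gas_exchange(path)
  expect_equal(back$a_n, ds$a_n, tolerance = 1e-12)
  expect_equal(back$curve, ds$curve)
})

test_that("noise-free recovery is within 5 percent for every parameter", {
  kp <- kinetic_params(vcmax = 123, jmax = 187, rd = 1.1, y2ll = 0.74,
                       s_factor = 0.9)
  ds <- forward_curves(kp)
  fit <- fit_parameters(ds, ga_config(seed = 5), base_kp = kp)
  truth <- c(kp$vcmax, kp$jmax, kp$rd, kp$y2ll, kp$s_factor)
  expect_true(all(abs(fit$estimates / truth - 1) < 0.05))
})

test_that("GA objective never increases across generations", {
  ds <- synth_dataset(kinetic_params(), seed = 3)
  fit <- fit_parameters(ds, ga_config(generations = 60, seed = 2))
  expect_true(all(diff(fit$trace) <= 1e-9))
})

test_that("noise-free fits agree across GA seeds within 1 percent", {
  ds <- forward_curves(kinetic_params())
  ests <- vapply(1:5, function(s) {
    fit_parameters(ds, ga_config(seed = s))$estimates
  }, numeric(5))
  spread <- apply(ests, 1, function(r) diff(range(r)) / mean(r))
  expect_true(all(spread < 0.01))
})

test_that("noisy recovery stays within 15 percent in the median", {
  kp <- kinetic_params()
  truth <- c(kp$vcmax, kp$jmax, kp$rd, kp$y2ll, kp$s_factor)
  rel_err <- sapply(1:20, function(s) {
    ds <- synth_dataset(kp, noise_sd = c(0.5, 0.005), seed = 100 + s)
    fit <- fit_parameters(ds, ga_config(population = 60, generations = 80,
                                        seed = s))
    abs(fit$estimates / truth - 1)
  })
  ## median over seeds, per parameter; rd is small in absolute terms so a
  ## 0.5-unit noise floor dominates it -- judge the four scale parameters
  med <- apply(rel_err, 1, median)
  expect_true(all(med[c("vcmax", "jmax", "y2ll", "s_factor")] < 0.15))
})

test_that("one-dimensional fit matches a golden-section oracle", {
  kp <- kinetic_params()
  ds <- forward_curves(kp)
  eps <- 1e-9
  bounds <- list(vcmax = c(50, 300),
                 jmax = kp$jmax + c(-eps, eps),
                 rd = kp$rd + c(-eps, eps),
                 y2ll = kp$y2ll + c(-eps, eps),
                 s_factor = kp$s_factor + c(-eps, eps))
  fit <- fit_parameters(ds, ga_config(bounds = bounds, seed = 1,
                                      generations = 120))
  ## golden-section search on the same 1D objective
  obj1d <- function(v) {
    th <- matrix(c(v, kp$jmax, kp$rd, kp$y2ll, kp$s_factor), 1)
    eleaf:::fit_objective(th, ds, kp, fit$weights["w_a"],
                          fit$weights["w_phi"])
  }
  gold <- optimize(obj1d, c(50, 300), tol = 1e-10)
  expect_lt(abs(fit$estimates["vcmax"] - gold$minimum) / gold$minimum, 1e-3)
})

test_that("datasets without low-Ci points carry an identifiability warning", {
  kp <- kinetic_params()
  pr <- measurement_protocol(aci_ci = c(400, 500, 700, 900, 1200, 1500))
  ds <- forward_curves(kp, pr)
  fit <- fit_parameters(ds, ga_config(generations = 10, seed = 1))
  expect_match(fit$warnings, "below 300")
})
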