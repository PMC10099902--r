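test_that("the factor grouping partitions the parameter set", {
  g <- factor_grouping()
  expect_length(g, 9L)
  expect_silent(eleaf:::validate_grouping(g))
  ## breaking the partition is detected
  g2 <- g; g2$F3 <- c("porosity", "wall_thickness")
  expect_error(eleaf:::validate_grouping(g2), "twice")
  g3 <- g; g3$F6 <- NULL
  expect_error(eleaf:::validate_grouping(g3), "not a partition")
})

test_that("substituting identical values changes nothing, all groups give
           the full alternative model", {
  a <- anatomy_preset("aCO2"); e <- anatomy_preset("eCO2")
  ka <- kinetics_preset("aCO2"); ke <- kinetics_preset("eCO2")
  same <- substitute_groups(a, a, ka, ka, "F5")
  expect_identical(unclass(same$anatomy), unclass(a))
  allsub <- substitute_groups(a, e, ka, ke, names(factor_grouping()))
  expect_identical(unclass(allsub$anatomy), unclass(e))
  expect_identical(allsub$kinetics, ke)
  expect_error(substitute_groups(a, e, ka, ke, "F10"), "unknown group")
})

test_that("matched-seed substitution of nothing gives exactly zero delta", {
  conds <- data.frame(ci = 280, q = 1000)
  a <- anatomy_preset("aCO2"); ka <- kinetics_preset("aCO2")
  fs <- factor_substitution(a, a, ka, ka, "F3", conds, n_replicates = 1,
                            seed = 3, n_rays = 4000)
  expect_identical(max(abs(fs$delta_a)), 0)
})

test_that("partition identity: all-group substitution equals the full
           alternative run", {
  conds <- data.frame(ci = 700, q = 1200)
  a <- anatomy_preset("aCO2"); e <- anatomy_preset("eCO2")
  ka <- kinetics_preset("aCO2"); ke <- kinetics_preset("eCO2")
  fs <- factor_substitution(a, e, ka, ke, "all", conds, n_replicates = 1,
                            seed = 2, n_rays = 4000)
  direct <- eleaf:::run_condition_grid(e, ke, conds, 1, 2, n_rays = 4000)
  expect_identical(fs$a_subst, direct$a_n)
})

test_that("a 1x1 response surface equals a single coupled solve", {
  sf <- response_surface(anatomy_preset("aCO2"), kinetic_params(),
                         ci_grid = 280, q_grid = 2000, n_replicates = 1,
                         seed = 1, n_rays = 8000)
  ## identical seeds by hand: geometry seed 1, tracer seed 1002
  v <- pack_mesophyll(anatomy_preset("aCO2"), 1, 2)
  f <- trace_light(v, optical_props(), light_source(2000), n_rays = 8000,
                   seed = 1002)
  st <- solve_coupled(v, transport_params(ci_boundary = 280), f,
                      kinetic_params())
  expect_equal(sf$a_n, st$a_net_leaf, tolerance = 1e-9)
  expect_false(any(is.na(sf$a_n)))
})

test_that("anova flags behave at the trivial ends", {
  r <- anova_significance(c(1, 1, 1), c(1, 1, 1))
  expect_false(r$significant)
  expect_equal(r$p_value, 1)
  r2 <- anova_significance(c(0, 0.001, -0.001), c(5, 5.001, 4.999))
  expect_true(r2$significant)
  expect_error(anova_significance(1, c(2, 3)), ">= 2 replicates")
})

test_that("anova type-I error rate is 5 percent under the null", {
  n_sim <- 10000
  set.seed(1234)
  flags <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    flags[i] <- anova_significance(rnorm(5), rnorm(5))$significant
  }
  expect_lt(abs(mean(flags) - 0.05), 0.01)
})

test_that("sweep control cell is exactly zero and infeasible values are
           reported", {
  p <- anatomy_preset("aCO2")
  conds <- data.frame(ci = 280, q = 1000)
  sw <- sweep_anatomy(p, kinetic_params(), "porosity",
                      values = c(0.0, p$porosity), conds,
                      n_replicates = 1, seed = 1, n_rays = 4000)
  ctrl <- sw[sw$value == p$porosity, ]
  expect_identical(ctrl$delta_a, 0)
  expect_false(isTRUE(ctrl$significant))
  bad <- sw[sw$value == 0, ]
  expect_false(any(bad$feasible))
  expect_match(bad$reason[1], "infeasible")
})
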