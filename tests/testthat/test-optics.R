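test_that("fresnel closed forms hold", {
  ## normal incidence air -> glass-like
  expect_equal(fresnel_interface(0, 1, 1.5)$reflectance, 0.04,
               tolerance = 1e-12)
  ## matched media: no reflection, ray undeviated
  f <- fresnel_interface(0.7, 1.353, 1.353)
  expect_equal(f$reflectance, 0, tolerance = 1e-12)
  expect_equal(f$refraction_angle, 0.7, tolerance = 1e-12)
  ## beyond the critical angle: total internal reflection
  crit <- asin(1.0 / 1.5)
  f2 <- fresnel_interface(crit + 0.05, 1.5, 1.0)
  expect_identical(f2$reflectance, 1)
  expect_true(is.na(f2$refraction_angle))
})

test_that("no absorber means no absorption and R + T = 1", {
  v <- tiny_volume()
  op0 <- optical_props(k_chl = 0)
  f <- trace_light(v, op0, light_source(1000), n_rays = 20000, seed = 3)
  expect_identical(sum(f$absorbed_frac), 0)
  expect_equal(unname(f$totals["reflected"] + f$totals["transmitted"] +
                        f$totals["lost"]), 1, tolerance = 1e-12)
})

test_that("homogeneous slab follows Beer-Lambert within 3 SE", {
  ## chloroplast slab with matched refractive indices everywhere: the only
  ## interaction is absorption, so T = exp(-k L)
  lbl <- leaf_labels()
  n_z <- 40L; h <- 1
  lab <- array(lbl[["mc_chloroplast"]], c(10, 10, n_z))
  chl_area <- 300
  v <- as_labelled_volume(lab, voxel_size = h,
                          params = anatomy_params(chlorophyll_per_area =
                                                    chl_area))
  op <- optical_props(n_air = 1, n_liquid = 1, n_wall = 1, k_chl = 0.005)
  f <- trace_light(v, op, light_source(1000), n_rays = 1e5, seed = 11)
  ## volumetric absorption coefficient from the chlorophyll bookkeeping
  conc <- chl_area / (n_z * h * 1e-6)          # umol m-3
  k_um <- 0.005 * conc * 1e-6                  # um^-1
  t_expect <- exp(-k_um * n_z * h)
  se <- max(f$se["transmitted"], 1e-6)
  expect_lt(abs(f$totals[["transmitted"]] - t_expect), 3 * se + 1e-4)
  expect_identical(f$totals[["reflected"]], 0)  # matched indices everywhere
})

test_that("energy is conserved within 3 SE and SE shrinks like 1/sqrt(n)", {
  v <- tiny_volume()
  op <- optical_props()
  ses <- vapply(c(1e3, 1e4, 1e5), function(n) {
    f <- trace_light(v, op, light_source(500), n_rays = n, seed = 5)
    tot <- sum(f$totals)
    se <- sqrt(sum(f$se^2))
    expect_lt(abs(tot - 1), max(3 * se, 1e-9))
    se
  }, numeric(1))
  ## SE ratio across decades should be near sqrt(10) = 3.16
  expect_gt(ses[1] / ses[2], 1.8)
  expect_gt(ses[2] / ses[3], 1.8)
})

test_that("absorbed flux scales exactly linearly with incident PPFD", {
  v <- tiny_volume()
  op <- optical_props()
  f1 <- trace_light(v, op, light_source(700), n_rays = 5000, seed = 9)
  f2 <- trace_light(v, op, light_source(1400), n_rays = 5000, seed = 9)
  expect_identical(f1$absorbed_frac, f2$absorbed_frac)
  expect_equal(f2$absorbed, 2 * f1$absorbed, tolerance = 1e-12)
})

test_that("absorption happens only in chloroplast voxels", {
  v <- tiny_volume()
  f <- tiny_light()
  chl <- v$label %in% c(leaf_labels()[["mc_chloroplast"]],
                        leaf_labels()[["bs_chloroplast"]])
  expect_true(all(f$absorbed_frac[!chl] == 0))
})

test_that("light is absorbed preferentially in the adaxial half", {
  v <- tiny_volume()
  f <- tiny_light()
  d <- v$dims
  zmid <- d[3] %/% 2
  chl <- v$label %in% c(3L, 7L)
  dim(chl) <- d
  top <- mean(f$absorbed[, , 1:zmid][chl[, , 1:zmid]])
  bot <- mean(f$absorbed[, , (zmid + 1):d[3]][chl[, , (zmid + 1):d[3]]])
  expect_gt(top, bot)
})

test_that("per-cell absorbed flux conserves the leaf total", {
  v <- tiny_volume()
  f <- tiny_light()
  pc <- absorbed_per_chloroplast(f, v)
  expect_equal(sum(pc$absorbed_fraction), sum(f$absorbed_frac),
               tolerance = 1e-12)
  expect_equal(sum(pc$absorbed_fraction), unname(f$totals["absorbed"]),
               tolerance = 1e-12)
  ## zero field gives all zeros
  f0 <- trace_light(v, optical_props(k_chl = 0), light_source(100),
                    n_rays = 2000, seed = 2)
  pc0 <- absorbed_per_chloroplast(f0, v)
  expect_true(all(pc0$absorbed_fraction == 0))
})

test_that("tracing is reproducible for a fixed seed", {
  v <- tiny_volume()
  op <- optical_props()
  f1 <- trace_light(v, op, light_source(1000), n_rays = 3000, seed = 42)
  f2 <- trace_light(v, op, light_source(1000), n_rays = 3000, seed = 42)
  expect_identical(f1$absorbed_frac, f2$absorbed_frac)
  expect_identical(f1$totals, f2$totals)
})
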