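test_that("template with zero lobe amplitude is an ellipsoid", {
  tpl <- build_cell_template(5, 30, 18, 24, 0.15, 0.4, lobe_amplitude = 0)
  a <- 15; b <- 9; c <- 12
  expect_equal(tpl$volume, 4 / 3 * pi * a * b * c, tolerance = 1e-6)
  ## Thomsen approximation for the ellipsoid surface
  p <- 1.6075
  s_approx <- 4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
  expect_equal(tpl$surface_area, s_approx, tolerance = 0.01)
})

test_that("surface area increases with lobe number at equal volume", {
  tpls <- lapply(c(4, 6, 8, 10), function(n) {
    build_cell_template(n, 30, 14, 16, 0.15, 0.4)
  })
  vols <- vapply(tpls, `[[`, numeric(1), "volume")
  expect_equal(max(vols) / min(vols), 1, tolerance = 1e-12) # volume free of n
  areas <- vapply(tpls, `[[`, numeric(1), "surface_area")
  expect_true(all(diff(areas) > 0))
})

test_that("surface area never decreases with lobe amplitude at fixed volume", {
  shape <- vapply(seq(0, 0.6, by = 0.1), function(a) {
    tpl <- build_cell_template(7, 30, 14, 16, 0.15, 0.4, lobe_amplitude = a)
    tpl$surface_area / tpl$volume^(2 / 3)   # dimensionless shape factor
  }, numeric(1))
  expect_true(all(diff(shape) > -1e-9))
})

test_that("cross-section has exactly lobe_number lobes", {
  for (n in c(4, 7, 10)) {
    th <- seq(0, 2 * pi, length.out = 3601)[-3601]
    r <- eleaf:::lobed_radius(th, n, 0.35)
    ## strict local maxima on the periodic profile
    rp <- c(r[length(r)], r, r[1])
    n_max <- sum(r > rp[seq_along(r)] & r > rp[seq_along(r) + 2])
    expect_equal(n_max, n)
  }
})

test_that("zero plastid fraction gives an empty chloroplast band", {
  tpl <- build_cell_template(6, 30, 14, 16, 0.15, 0)
  expect_identical(tpl$band_thickness, 0)
})

test_that("infeasible plastid fraction is rejected explicitly", {
  ## flat plate-like cell: the band the fraction demands exceeds the
  ## half-width
  expect_error(build_cell_template(3, 40, 6, 40, 2.0, 0.9),
               "infeasible plastid fraction")
})

test_that("packing meets porosity, S_mes and plastid-fraction targets", {
  for (cond in c("aCO2", "eCO2")) {
    p <- anatomy_preset(cond)
    v <- pack_mesophyll(p, seed = 11, voxel_size = 2)
    m <- measure_anatomy(v)
    expect_lt(abs(m$porosity_measured - p$porosity), 0.02)
    expect_lt(abs(m$smes_measured / p$smes_fraction - 1), 0.05)
    expect_lt(abs(m$plastid_fraction_measured - p$mc_plastid_fraction), 0.02)
    expect_true(v$achieved$targets_met)
  }
})

test_that("voxel labels partition the grid", {
  v <- tiny_volume()
  expect_true(all(v$label %in% leaf_labels()))
  tab <- table(v$label)
  expect_identical(as.integer(sum(tab)), as.integer(prod(v$dims)))
})

test_that("airspace is connected to both epidermal surfaces", {
  v <- tiny_volume()
  lab <- v$label; d <- v$dims
  air <- lab == 0L
  epi <- lab == leaf_labels()[["epidermis"]]
  seeds <- array(FALSE, d)
  for (z in 2:(d[3] - 1)) {
    seeds[, , z] <- air[, , z] & (epi[, , z - 1] | epi[, , z + 1])
  }
  expect_gt(sum(seeds), 0)
  visited <- seeds
  repeat {
    g <- visited
    g <- g | visited[c(2:d[1], 1), , ] | visited[c(d[1], 1:(d[1] - 1)), , ]
    g <- g | visited[, c(2:d[2], 1), ] | visited[, c(d[2], 1:(d[2] - 1)), ]
    g[, , 1:(d[3] - 1)] <- g[, , 1:(d[3] - 1)] | visited[, , 2:d[3]]
    g[, , 2:d[3]] <- g[, , 2:d[3]] | visited[, , 1:(d[3] - 1)]
    g <- g & air
    if (identical(g, visited)) break
    visited <- g
  }
  ## the vast majority of airspace must be reachable by gas from outside
  expect_gt(sum(visited) / sum(air), 0.85)
})

test_that("identical (params, seed) give bit-identical volumes", {
  v1 <- pack_mesophyll(anatomy_preset("aCO2"), seed = 5, voxel_size = 2)
  v2 <- pack_mesophyll(anatomy_preset("aCO2"), seed = 5, voxel_size = 2)
  expect_identical(v1$label, v2$label)
  expect_identical(v1$cell, v2$cell)
  expect_identical(v1$provenance, v2$provenance)
})

test_that("porosity zero is rejected as infeasible", {
  p <- anatomy_preset("aCO2")
  p$porosity <- 0
  expect_error(pack_mesophyll(p, 1, 2), "infeasible")
})

test_that("measure_anatomy closed forms on hand-built volumes", {
  lbl <- leaf_labels()
  ## all-airspace mesophyll: porosity 1
  lab <- array(lbl[["airspace"]], c(6, 4, 10))
  lab[, , 1] <- lbl[["epidermis"]]; lab[, , 10] <- lbl[["epidermis"]]
  ## a single fully exposed cuboid cell
  lab[3:4, 2:3, 4:6] <- lbl[["mc_cytosol"]]
  v <- as_labelled_volume(lab, voxel_size = 1)
  m <- measure_anatomy(v)
  n_cell <- 2 * 2 * 3
  n_air <- sum(lab == 0)
  expect_equal(m$porosity_measured, n_air / (n_air + n_cell))
  expect_equal(m$smes_measured, 1)   # every boundary face touches air
  expect_equal(m$cell_count, 1L)
})

test_that("measure_anatomy rejects an empty mesophyll region", {
  lab <- array(leaf_labels()[["epidermis"]], c(4, 4, 4))
  v <- as_labelled_volume(lab, voxel_size = 1)
  expect_error(measure_anatomy(v), "empty mesophyll")
})

test_that("replicates are distinct but all within target tolerances", {
  p <- anatomy_preset("aCO2")
  vols <- generate_replicates(p, n = 3, base_seed = 21, voxel_size = 2)
  expect_length(vols, 3L)
  for (v in vols) {
    m <- measure_anatomy(v)
    expect_lt(abs(m$porosity_measured - p$porosity), 0.02)
  }
  expect_false(identical(vols[[1]]$label, vols[[2]]$label))
  expect_false(identical(vols[[2]]$label, vols[[3]]$label))
  ## n = 1 equals a plain pack_mesophyll call
  v1 <- generate_replicates(p, 1, base_seed = 21, voxel_size = 2)[[1]]
  expect_identical(v1$label,
                   pack_mesophyll(p, 21, voxel_size = 2)$label)
  ## duplicated seeds are a contract violation
  expect_error(generate_replicates(p, 3, 1, 2, seeds = c(4, 4, 5)),
               "distinct")
})
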