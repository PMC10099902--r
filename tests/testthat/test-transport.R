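test_that("ca_reaction equilibrium and signs", {
  tp <- transport_params()
  c0 <- 0.012
  expect_equal(ca_reaction(c0, tp$equilibrium_ratio * c0, tp), 0,
               tolerance = 1e-15)
  expect_gt(ca_reaction(c0, 0, tp), 0)
  expect_lt(ca_reaction(0, 0.01, tp), 0)
  expect_error(ca_reaction(-1, 0, tp), ">= 0")
})

test_that("closed box relaxes to CA equilibrium conserving carbon", {
  skip_if_not_installed("deSolve")
  tp <- transport_params(k_hydration = 50)
  keq <- tp$equilibrium_ratio
  ode_fn <- function(t, y, parms) {
    r <- ca_reaction(y[1], y[2], tp)
    list(c(-r, r))
  }
  y0 <- c(c = 0.02, b = 0.001)
  sol <- deSolve::ode(y0, seq(0, 2, by = 0.01), ode_fn, NULL)
  total <- rowSums(sol[, c("c", "b")])
  expect_equal(max(abs(total - sum(y0))), 0, tolerance = 1e-8)
  final <- sol[nrow(sol), ]
  expect_equal(unname(final["b"] / final["c"]), keq, tolerance = 1e-4)
})

test_that("interior rows of the uniform-medium operator sum to zero", {
  ## all-airspace column, no reactions: pure discrete Laplacian + Dirichlet
  lbl <- leaf_labels()
  lab <- array(lbl[["airspace"]], c(4, 4, 12))
  lab[, , 1] <- lbl[["epidermis"]]; lab[, , 12] <- lbl[["epidermis"]]
  v <- as_labelled_volume(lab, 2)
  ts <- assemble_system(v, transport_params())
  rs <- Matrix::rowSums(ts$A)
  interior <- setdiff(seq_len(ts$nc), ts$dir_idx)
  expect_equal(max(abs(rs[interior])), 0, tolerance = 1e-18)
})

test_that("scaled operator is symmetric positive definite", {
  ## small random mixed-phase grid; the diagonal similarity transform with
  ## the Henry/equilibrium weights must symmetrise the operator
  lbl <- leaf_labels()
  set.seed(4)
  lab <- array(sample(c(lbl[["airspace"]], lbl[["mc_cytosol"]],
                        lbl[["mc_chloroplast"]]), 4 * 4 * 10, replace = TRUE),
               c(4, 4, 10))
  lab[, , 1] <- lbl[["epidermis"]]; lab[, , 10] <- lbl[["epidermis"]]
  lab[, , 2] <- lbl[["airspace"]]   # guarantee a stomatal patch
  v <- as_labelled_volume(lab, 2)
  ts <- assemble_system(v, transport_params(), lambda = 10)
  keep <- setdiff(seq_len(ts$nc + ts$nb), ts$dir_idx)
  w <- ts$sym_weights
  As <- Matrix::Diagonal(x = w) %*% ts$A %*% Matrix::Diagonal(x = 1 / w)
  As <- As[keep, keep]
  asym <- max(abs(As - Matrix::t(As))) / max(abs(As))
  expect_lt(asym, 1e-10)
  ev <- eigen(as.matrix((As + Matrix::t(As)) / 2), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("zero sink gives uniform fields at the boundary equilibrium", {
  v <- tiny_volume()
  tp <- transport_params(ci_boundary = 350)
  kp0 <- kinetic_params(vcmax = 0, jmax = 1e-9, rd = 0)
  st <- solve_coupled(v, tp, tiny_light(), kp0)
  cbc <- eleaf:::ubar_to_gas_conc(350)
  gas <- st$co2_field[v$label == 0]
  liq <- st$co2_field[v$label %in% c(2, 3, 4, 6, 7)]
  expect_equal(max(abs(gas - cbc)) / cbc, 0, tolerance = 1e-8)
  expect_equal(max(abs(liq - tp$henry_constant * cbc)) / cbc, 0,
               tolerance = 1e-8)
  expect_equal(st$a_net_leaf, 0, tolerance = 1e-10)
  b <- st$hco3_field[!is.na(st$hco3_field)]
  expect_gt(min(b), 0)
})

test_that("1D constant-sink liquid slab reproduces the parabola", {
  n_liq <- 30; h <- 1
  v <- column_volume(n_liq, h)
  ## matched phases: H = 1, no reaction, no membrane/wall resistance
  tp <- transport_params(henry_constant = 1, k_hydration = 0,
                         wall_diffusivity_factor = 1,
                         p_membrane = 1e9, p_envelope = 1e9,
                         cytosol_film = 0, ci_boundary = 300,
                         d_co2_gas = 1.9e-5)
  qs <- 0.1  # mol m-3 s-1; weak enough that concentrations stay positive
  sink <- array(0, v$dims)
  sink[, , 3 + seq_len(n_liq)] <- qs
  ts <- assemble_system(v, tp, sink_field = sink)
  x <- as.numeric(Matrix::solve(ts$A, ts$rhs))
  prof <- x[ts$cidx[1, 1, 3 + seq_len(n_liq)]]
  d_l <- tp$d_co2_liquid
  l_m <- n_liq * h * 1e-6
  c0 <- eleaf:::ubar_to_gas_conc(300)
  zc <- ((seq_len(n_liq) - 0.5) * h) * 1e-6
  analytic <- c0 - qs * zc * (l_m - zc) / (2 * d_l)
  expect_equal(prof, analytic, tolerance = 0.01)
})

test_that("dark leaf respires at exactly Rd", {
  v <- tiny_volume()
  kp <- kinetic_params()
  f0 <- trace_light(v, optical_props(), light_source(0), n_rays = 2000,
                    seed = 3)
  st <- solve_coupled(v, transport_params(), f0, kp)
  expect_equal(st$a_net_leaf, -kp$rd, tolerance = 0.01 * kp$rd)
})

test_that("boundary influx balances the net sink at convergence", {
  st <- tiny_state(280, 2000)
  expect_lt(st$mass_balance_error, 1e-6)
  out <- compute_outputs(st)
  expect_identical(out$a_net, st$a_net_leaf)
})

test_that("outputs refuse an unconverged state", {
  st <- tiny_state(280, 2000)
  st$converged <- FALSE
  expect_error(compute_outputs(st), "unconverged")
})

test_that("A_N is monotone in C_i and in Q; Cc stays below C_i", {
  a_ci <- vapply(c(150, 500, 1200), function(ci) {
    tiny_state(ci, 2000)$a_net_leaf
  }, numeric(1))
  expect_true(all(diff(a_ci) > 0))
  a_q <- vapply(c(200, 800, 2000), function(q) {
    tiny_state(280, q)$a_net_leaf
  }, numeric(1))
  expect_true(all(diff(a_q) > 0))
  st <- tiny_state(280, 2000)
  expect_lt(max(st$cc_field, na.rm = TRUE), 280)
})

test_that("solution is reproducible and mass-consistent across C_i", {
  st1 <- solve_coupled(tiny_volume(), transport_params(ci_boundary = 400),
                       tiny_light(), kinetic_params())
  st2 <- solve_coupled(tiny_volume(), transport_params(ci_boundary = 400),
                       tiny_light(), kinetic_params())
  expect_identical(st1$a_net_leaf, st2$a_net_leaf)
  expect_lt(st1$mass_balance_error, 1e-6)
})

test_that("halving the voxel size on a fixed geometry changes A_N little", {
  ## refine the PDE mesh by voxel subdivision: identical physical geometry,
  ## half the cell size -- isolates discretisation error from the
  ## resolution dependence of the generator itself
  v <- tiny_volume()
  refine <- function(a) {
    d <- dim(a)
    a[rep(seq_len(d[1]), each = 2),
      rep(seq_len(d[2]), each = 2),
      rep(seq_len(d[3]), each = 2)]
  }
  v2 <- structure(list(label = refine(v$label), cell = refine(v$cell),
                       voxel_size = v$voxel_size / 2,
                       dims = 2L * v$dims, params = v$params, seed = v$seed,
                       achieved = v$achieved, provenance = v$provenance),
                  class = "labelled_volume")
  op <- optical_props(); kp <- kinetic_params()
  a <- vapply(list(v, v2), function(vol) {
    f <- trace_light(vol, op, light_source(1500), n_rays = 40000, seed = 7)
    solve_coupled(vol, transport_params(ci_boundary = 400), f,
                  kp)$a_net_leaf
  }, numeric(1))
  ## leading discretisation error is the first-order half-cell film at
  ## membrane interfaces; a few percent at 2 um
  expect_lt(abs(a[2] / a[1] - 1), 0.05)
})
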