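#' Net carbonic-anhydrase hydration rate
#'
#' `rate = k_h (c - b / K_eq)`: positive rates consume dissolved CO2 and
#' produce bicarbonate, negative rates the reverse; at `b = K_eq c` the
#' reaction is at equilibrium.
#'
#' @param c Dissolved CO2 concentration (mol m-3), vectorised.
#' @param b Bicarbonate concentration (mol m-3), vectorised.
#' @param tp A [transport_params] object.
#' @param k_eq Equilibrium ratio to use (defaults to the cytosolic value).
#' @return Net hydration rate (mol m-3 s-1).
#' @export
ca_reaction <- function(c, b, tp, k_eq = tp$equilibrium_ratio) {
  stopifnot(inherits(tp, "transport_params"))
  if (any(c < 0) || any(b < 0)) {
    stop_eleaf("transport", "concentrations must be >= 0")
  }
  tp$k_hydration * (c - b / k_eq)
}

## wrap a raw label array as a labelled_volume (synthetic volumes for
## analytic benchmarks); cell defaults to one cell spanning all liquid
#' Construct a labelled volume from a raw label array
#'
#' Intended for synthetic benchmark geometries (slabs, columns) and tests;
#' [pack_mesophyll()] is the generator for leaf-like volumes.
#'
#' @param label Integer 3D array of [leaf_labels()] codes.
#' @param voxel_size Voxel edge (um).
#' @param cell Optional integer array of cell ids (defaults to id 1 on all
#'   mesophyll compartments, negative ids on bundle-sheath compartments).
#' @param params Anatomy parameters to attach (defaults to
#'   [anatomy_params()] defaults).
#' @return A `labelled_volume`.
#' @export
as_labelled_volume <- function(label, voxel_size, cell = NULL,
                               params = anatomy_params()) {
  stopifnot(length(dim(label)) == 3L)
  if (!all(label %in% .LBL)) stop_eleaf("geometry", "unknown label codes")
  label <- array(as.integer(label), dim(label))
  if (is.null(cell)) {
    cell <- array(0L, dim(label))
    cell[label %in% .MC_LABELS] <- 1L
    cell[label %in% .BS_LABELS] <- -1L
  }
  structure(list(label = label, cell = array(as.integer(cell), dim(label)),
                 voxel_size = voxel_size, dims = dim(label), params = params,
                 seed = NA_integer_,
                 achieved = list(porosity = NA, smes = NA, n_cells = max(cell),
                                 iterations = 0L),
                 provenance = list(seed = NA_integer_,
                                   params_hash = params_hash(params))),
            class = "labelled_volume")
}

## stomatal boundary patches: airspace voxels adjacent (in z) to each
## epidermis, within circular patches (default one per patch_area um^2 of
## surface); returns linear voxel indices
stomatal_patches <- function(volume, patch_area = 2500, patch_radius = 8,
                             surfaces = c("adaxial", "abaxial")) {
  lab <- volume$label; d <- volume$dims; h <- volume$voxel_size
  air <- lab == .LBL[["airspace"]]
  epi <- lab == .LBL[["epidermis"]]
  idx_all <- integer()
  lx <- d[1] * h
  area <- d[1] * d[2] * h^2
  n_patch <- max(1L, as.integer(round(area / patch_area)),
                 as.integer(round(lx / 50)))
  centers <- (seq_len(n_patch) - 0.5) * lx / n_patch
  ## stomata overlie the intercellular-airspace channels, so add the
  ## channel positions of the generator as patch centres
  ivd <- volume$params$interveinal_distance
  n_chan <- max(1L, as.integer(round(ivd / 35)))
  centers <- unique(c(centers, seq_len(n_chan) * ivd / (n_chan + 1)))
  for (surf in surfaces) {
    below <- shift3(array(as.integer(epi), d), "z", fill = 1L) == 1L
    above <- c(array(1L, d[1] * d[2]),
               as.integer(epi)[seq_len(prod(d) - d[1] * d[2])])
    dim(above) <- d
    adj <- if (surf == "adaxial") air & (above == 1L) else air & below
    cand <- which(adj, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    xs <- (cand[, 1] - 0.5) * h
    dmin <- vapply(xs, function(x) {
      min(abs(((x - centers + lx / 2) %% lx) - lx / 2))
    }, numeric(1))
    r <- patch_radius
    sel <- which(dmin <= r)
    while (length(sel) == 0L && r <= 2 * lx) {
      r <- r * 2
      sel <- which(dmin <= r)
    }
    if (length(sel)) {
      idx_all <- c(idx_all,
                   cand[sel, 1] + d[1] * (cand[sel, 2] - 1L) +
                     d[1] * d[2] * (cand[sel, 3] - 1L))
    }
  }
  unique(idx_all)
}

#' Assemble the finite-volume reaction-diffusion operator
#'
#' Cell-centred finite volumes on the voxel grid, one CO2 unknown per
#' participating voxel (gas-phase in airspace, dissolved elsewhere) and
#' one HCO3- unknown per carbonic-anhydrase compartment voxel.  Interface
#' conditions: Henry partition at air/liquid faces, wall
#' (`t_wall / (f_wall D_l)`) plus membrane permeabilities in series at
#' cell surfaces and cell-cell contacts, chloroplast envelope at stromal
#' faces; bicarbonate diffuses only within a compartment (membranes are
#' impermeable to it).  Dirichlet rows fix the CO2 concentration at the
#' stomatal airspace patches; all solid tissue (epidermis, vein,
#' bulliform) is zero-flux.
#'
#' @param volume A `labelled_volume`.
#' @param tp A [transport_params] object.
#' @param sink_field Optional per-voxel volumetric CO2 sink
#'   (mol m-3 s-1, array congruent with the volume) folded into the
#'   right-hand side.
#' @param lambda Linearisation shift (s-1) added to the diagonal of
#'   chloroplast voxels (used by [solve_coupled()]; 0 for a plain linear
#'   system).
#' @param patch_area Leaf surface area per stomatal patch (um^2).
#' @param surfaces Which epidermes carry stomatal patches (rice is
#'   amphistomatous).
#' @return A `transport_system` list: sparse operator `A`, right-hand side
#'   `rhs`, index maps, Dirichlet and flux-face bookkeeping, and the
#'   symmetrising weights of the similarity transform.
#' @export
assemble_system <- function(volume, tp, sink_field = NULL, lambda = 0,
                            patch_area = 2500,
                            surfaces = c("adaxial", "abaxial")) {
  stopifnot(inherits(volume, "labelled_volume"),
            inherits(tp, "transport_params"))
  lab <- volume$label; cell <- volume$cell; d <- volume$dims
  h <- volume$voxel_size
  h_m <- h * 1e-6
  af <- h_m^2                 # face area m2
  vv <- h_m^3                 # voxel volume m3

  part_c <- lab %in% c(.LBL[["airspace"]], .LIQUID_LABELS)
  ca_lab <- .LBL[c("mc_cytosol", "mc_chloroplast", "bs_cytosol",
                   "bs_chloroplast")]
  ## without the (de)hydration reaction the bicarbonate pool is decoupled
  ## (membranes are impermeable to it), so it carries no unknowns
  part_b <- if (tp$k_hydration > 0) lab %in% ca_lab else rep(FALSE, length(lab))
  nvox <- prod(d)
  cidx <- integer(nvox); cidx[part_c] <- seq_len(sum(part_c))
  nc <- sum(part_c)
  bidx <- integer(nvox); bidx[part_b] <- nc + seq_len(sum(part_b))
  nb <- sum(part_b)
  n_unknown <- nc + nb

  ## Dirichlet stomatal patches
  dir_vox <- stomatal_patches(volume, patch_area = patch_area,
                              surfaces = surfaces)
  if (length(dir_vox) == 0L) {
    stop_eleaf("transport",
               "no stomatal patch reachable: no airspace voxel adjacent ",
               "to an epidermis")
  }
  dir_idx <- cidx[dir_vox]
  c_bc <- ubar_to_gas_conc(tp$ci_boundary)

  ## face lists along the three axes (periodic x, y; open z)
  lin <- array(seq_len(nvox), d)
  ii <- jj <- integer(0)
  for (axis in c("x", "y", "z")) {
    nb_lin <- shift3(lin, axis, fill = NA_integer_)
    keep <- !is.na(nb_lin)
    ii <- c(ii, lin[keep]); jj <- c(jj, nb_lin[keep])
  }
  keep <- part_c[ii] & part_c[jj]
  fi <- ii[keep]; fj <- jj[keep]
  li <- lab[fi]; lj <- lab[fj]
  ci_ <- cell[fi]; cj_ <- cell[fj]

  ## orient air-liquid faces with the air side first
  is_air_i <- li == .LBL[["airspace"]]
  is_air_j <- lj == .LBL[["airspace"]]
  swap <- !is_air_i & is_air_j
  tmp <- fi[swap]; fi[swap] <- fj[swap]; fj[swap] <- tmp
  tmp <- li[swap]; li[swap] <- lj[swap]; lj[swap] <- tmp
  tmp <- ci_[swap]; ci_[swap] <- cj_[swap]; cj_[swap] <- tmp
  is_air_i <- li == .LBL[["airspace"]]
  is_air_j <- lj == .LBL[["airspace"]]

  d_of <- function(l) {
    ifelse(l == .LBL[["airspace"]], tp$d_co2_gas,
           ifelse(l %in% .LBL[c("mc_wall", "bs_wall")],
                  tp$wall_diffusivity_factor * tp$d_co2_liquid,
                  tp$d_co2_liquid))
  }
  r_half_i <- (h_m / 2) / d_of(li)
  r_half_j <- (h_m / 2) / d_of(lj)

  t_w <- volume$params$wall_thickness * 1e-6
  t_cyt <- tp$cytosol_film * 1e-6
  r_wall <- t_w / (tp$wall_diffusivity_factor * tp$d_co2_liquid)
  r_pm <- 1 / tp$p_membrane
  r_env <- 1 / tp$p_envelope + t_cyt / tp$d_co2_liquid
  is_chl_i <- li %in% .CHLORO_LABELS
  is_chl_j <- lj %in% .CHLORO_LABELS

  henry <- is_air_i & !is_air_j
  both_liq <- !is_air_i & !is_air_j
  same_cell <- ci_ == cj_
  r_extra <- numeric(length(fi))
  ## airspace -> cell surface: wall + plasma membrane (+ envelope if the
  ## peripheral voxel is chloroplast)
  r_extra[henry] <- r_wall + r_pm + ifelse(is_chl_j[henry], r_env, 0)
  ## cell-cell contact: two walls + two membranes (+ envelopes)
  cc_face <- both_liq & !same_cell
  r_extra[cc_face] <- 2 * (r_wall + r_pm) +
    ifelse(is_chl_i[cc_face], r_env, 0) + ifelse(is_chl_j[cc_face], r_env, 0)
  ## within-cell envelope crossings
  wc_face <- both_liq & same_cell & (is_chl_i != is_chl_j)
  r_extra[wc_face] <- r_env

  g_face <- af / (r_half_i + r_half_j + r_extra)

  H <- tp$henry_constant
  ti <- tj <- tx <- numeric(0)
  add <- function(i, j, x) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, x)
  }
  ui <- cidx[fi]; uj <- cidx[fj]
  ## symmetric faces (gas-gas and liquid-liquid)
  sym <- !henry
  add(ui[sym], ui[sym], g_face[sym])
  add(uj[sym], uj[sym], g_face[sym])
  add(ui[sym], uj[sym], -g_face[sym])
  add(uj[sym], ui[sym], -g_face[sym])
  ## Henry two-film faces: flux = K (H c_gas - c_liq),
  ## K = A / (H r_gas + r_liq)
  if (any(henry)) {
    kf <- af / (H * r_half_i[henry] + r_half_j[henry] + r_extra[henry])
    add(ui[henry], ui[henry], kf * H)
    add(ui[henry], uj[henry], -kf)
    add(uj[henry], uj[henry], kf)
    add(uj[henry], ui[henry], -kf * H)
  }

  ## carbonic anhydrase coupling and bicarbonate diffusion
  keq_vox <- numeric(nvox)
  keq_vox[lab %in% .LBL[c("mc_cytosol", "bs_cytosol")]] <- tp$equilibrium_ratio
  keq_vox[lab %in% .CHLORO_LABELS] <- tp$stroma_equilibrium_ratio
  if (nb > 0L && tp$k_hydration > 0) {
    bv <- which(part_b)
    vb <- bidx[bv]; vc <- cidx[bv]
    kh_v <- vv * tp$k_hydration
    add(vc, vc, rep(kh_v, nb))
    add(vc, vb, -kh_v / keq_vox[bv])
    add(vb, vb, kh_v / keq_vox[bv])
    add(vb, vc, rep(-kh_v, nb))
  }
  if (nb > 0L) {
    bkeep <- part_b[ii] & part_b[jj] & lab[ii] == lab[jj] &
      cell[ii] == cell[jj]
    bi <- bidx[ii[bkeep]]; bj <- bidx[jj[bkeep]]
    gb <- af * tp$d_hco3 / h_m
    add(bi, bi, rep(gb, length(bi)))
    add(bj, bj, rep(gb, length(bi)))
    add(bi, bj, rep(-gb, length(bi)))
    add(bj, bi, rep(-gb, length(bi)))
  }

  ## linearisation shift on chloroplast diagonal
  chl_vox <- which(lab %in% .CHLORO_LABELS & part_c)
  if (lambda > 0 && length(chl_vox)) {
    add(cidx[chl_vox], cidx[chl_vox], rep(vv * lambda, length(chl_vox)))
  }

  ## Dirichlet rows: identity
  drop <- ti %in% dir_idx
  ## record boundary faces before dropping (for influx accounting)
  bnd_keep <- (cidx[fi] %in% dir_idx) != (cidx[fj] %in% dir_idx)
  bnd <- list(i = cidx[fi[bnd_keep]], j = cidx[fj[bnd_keep]],
              g = g_face[bnd_keep],
              henry = henry[bnd_keep],
              k = ifelse(henry[bnd_keep],
                         af / (H * r_half_i[bnd_keep] + r_half_j[bnd_keep] +
                                 r_extra[bnd_keep]),
                         g_face[bnd_keep]))
  ti <- ti[!drop]; tj <- tj[!drop]; tx <- tx[!drop]

  ## reduced operator: Dirichlet columns eliminated to the right-hand side
  ## (their contribution is dir_colsum * c_bc); with rows and columns both
  ## removed the remaining operator is symmetric under the similarity
  ## weights, so the solver can use a sparse Cholesky factorisation
  col_drop <- tj %in% dir_idx
  dir_colsum <- numeric(n_unknown)
  if (any(col_drop)) {
    cs <- rowsum(tx[col_drop], ti[col_drop])
    dir_colsum[as.integer(rownames(cs))] <- cs[, 1]
  }
  ri <- c(ti[!col_drop], dir_idx)
  rj <- c(tj[!col_drop], dir_idx)
  rx <- c(tx[!col_drop], rep(1, length(dir_idx)))
  A_red <- Matrix::sparseMatrix(i = ri, j = rj, x = rx,
                                dims = c(n_unknown, n_unknown))
  zd <- which(Matrix::diag(A_red) == 0)
  if (length(zd)) {
    ## voxels with no connections at all (walled-off): pin them
    A_red <- A_red + Matrix::sparseMatrix(i = zd, j = zd,
                                          x = rep(1, length(zd)),
                                          dims = c(n_unknown, n_unknown))
  }

  ti <- c(ti, dir_idx); tj <- c(tj, dir_idx); tx <- c(tx, rep(1, length(dir_idx)))
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(n_unknown, n_unknown))
  rhs <- numeric(n_unknown)
  rhs[dir_idx] <- c_bc
  if (!is.null(sink_field)) {
    sf <- as.numeric(sink_field)
    if (length(sf) != nvox) {
      stop_eleaf("transport", "sink_field not congruent with volume")
    }
    tgt <- which(part_c & sf != 0)
    tgt <- setdiff(tgt, dir_vox)
    rhs[cidx[tgt]] <- rhs[cidx[tgt]] - vv * sf[tgt]
  }

  ## symmetrising weights: w = 1 (gas), 1/sqrt(H) (liquid CO2),
  ## 1/sqrt(H Keq) (bicarbonate)
  w <- rep(1, n_unknown)
  liq_vox <- which(part_c & lab %in% .LIQUID_LABELS)
  w[cidx[liq_vox]] <- 1 / sqrt(H)
  if (nb > 0L) {
    bv <- which(part_b)
    w[bidx[bv]] <- 1 / sqrt(H * keq_vox[bv])
  }

  structure(list(A = A, A_red = A_red, dir_colsum = dir_colsum,
                 rhs = rhs, nc = nc, nb = nb,
                 cidx = array(cidx, d), bidx = array(bidx, d),
                 part_c = array(part_c, d), part_b = array(part_b, d),
                 dir_vox = dir_vox, dir_idx = dir_idx, c_bc = c_bc,
                 boundary_faces = bnd, keq_vox = keq_vox,
                 sym_weights = w, vox_vol = vv, voxel_size = h, dims = d,
                 henry = H, lambda = lambda),
            class = "transport_system")
}

## boundary influx (mol s-1) into the domain through the Dirichlet patches
boundary_influx <- function(ts, x) {
  bf <- ts$boundary_faces
  if (!length(bf$i)) return(0)
  dir_on_i <- bf$i %in% ts$dir_idx
  xi <- x[bf$i]; xj <- x[bf$j]
  ## flux from i (air side of the stored orientation) towards j
  fl <- ifelse(bf$henry, bf$k * (ts$henry * xi - xj), bf$g * (xi - xj))
  sum(ifelse(dir_on_i, fl, -fl))
}

## maximum slope of the volumetric FvCB sink wrt dissolved CO2 (s-1),
## independent of the light field (J bounded by jmax)
sink_lipschitz <- function(kin, kp, tp) {
  cc <- exp(seq(log(0.5), log(5000), length.out = 400))
  kco <- kp$kc * (1 + kp$o2 / kp$ko)
  jv_max <- kp$jmax * kin$leaf_area /
    (sum(kin$chloro_mask) * kin$vox_vol)
  wc <- kin$vcmax_vol * cc / (cc + kco)
  wj <- jv_max * cc / (4 * cc + 8 * kp$gamma_star)
  g1 <- (1 - kp$gamma_star / cc) * wc
  g2 <- (1 - kp$gamma_star / cc) * wj
  sl <- max(diff(g1) / diff(cc), diff(g2) / diff(cc), 0)
  dcc_dc <- .GAS_R * .T_LEAF / (.UBAR_PA * tp$henry_constant)  # ubar per mol m-3
  sl * 1e-6 * dcc_dc    # (mol m-3 s-1) per (mol m-3)
}

#' Solve the coupled transport-metabolism steady state
#'
#' Damped Picard iteration between the linear reaction-diffusion operator
#' and the nonlinear FvCB chloroplast sink.  The sink is linearised with a
#' fixed diagonal shift (its maximum slope), so the sparse factorisation
#' is computed once and reused across iterations -- and across calls that
#' share a geometry (pass `system` and `factor` via `solver_cfg` or reuse
#' the returned ones).
#'
#' @param volume A `labelled_volume`.
#' @param tp A [transport_params] object (its `ci_boundary` sets C_i).
#' @param light_field An `absorbed_light_field` for this volume.
#' @param kp A [kinetic_params] object.
#' @param solver_cfg Optional list: `tol` (relative update, default 1e-8),
#'   `max_iter` (default 120), `system`/`factor` (precomputed
#'   [assemble_system()] output and its LU factor), `patch_area`,
#'   `surfaces`.
#' @return A `steady_state`: CO2 and HCO3- fields (mol m-3), chloroplast
#'   CO2 field `cc_field` (ubar), leaf `a_net_leaf` and `phi_psii_leaf`,
#'   boundary influx cross-check, residual history, iteration count, and
#'   the reusable `system`/`factor`.
#' @export
solve_coupled <- function(volume, tp, light_field, kp, solver_cfg = list()) {
  stopifnot(inherits(volume, "labelled_volume"),
            inherits(tp, "transport_params"),
            inherits(light_field, "absorbed_light_field"),
            inherits(kp, "kinetic_params"))
  if (!identical(light_field$dims, volume$dims)) {
    stop_eleaf("transport", "light field not congruent with volume")
  }
  tol <- solver_cfg$tol %||% 1e-8
  max_iter <- solver_cfg$max_iter %||% 400L

  kin <- distribute_kinetics(volume, kp)
  d <- volume$dims

  ## per-cell potential electron transport from absorbed light
  pc <- absorbed_per_chloroplast(light_field, volume)
  share <- pc$n_chloroplast_voxels / sum(pc$n_chloroplast_voxels)
  x_exc <- kp$s_factor * kp$y2ll * pc$i_abs
  jm_cell <- kp$jmax * share
  th <- kp$theta
  j_cell <- if (th < 1e-10) {
    x_exc * jm_cell / (x_exc + jm_cell + (x_exc + jm_cell == 0))
  } else {
    bq <- x_exc + jm_cell
    (bq - sqrt(pmax(0, bq^2 - 4 * th * x_exc * jm_cell))) / (2 * th)
  }
  ## volumetric J density per chloroplast voxel (umol e- m-3 s-1)
  jv_cell <- j_cell * kin$leaf_area / (pc$n_chloroplast_voxels * kin$vox_vol)
  jv <- numeric(prod(d))
  chl_lin <- which(kin$chloro_mask)
  cell_of_chl <- volume$cell[chl_lin]
  jv[chl_lin] <- jv_cell[match(cell_of_chl, pc$cell)]

  lam <- sink_lipschitz(kin, kp, tp)
  ts <- solver_cfg$system
  if (is.null(ts)) {
    ts <- assemble_system(volume, tp, lambda = lam,
                          patch_area = solver_cfg$patch_area %||% 2500,
                          surfaces = solver_cfg$surfaces %||%
                            c("adaxial", "abaxial"))
  }
  fac <- solver_cfg$factor
  wts <- ts$sym_weights
  if (is.null(fac)) {
    a_sym <- Matrix::Diagonal(x = wts) %*% ts$A_red %*%
      Matrix::Diagonal(x = 1 / wts)
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(a_sym), LDL = FALSE)
  }
  solve_sym <- function(b) {
    as.numeric(Matrix::solve(fac, wts * b)) / wts
  }

  vv <- ts$vox_vol
  n_unknown <- ts$nc + ts$nb
  cvec_idx <- ts$cidx[chl_lin]

  ## base right-hand side: Dirichlet values (for the *current* ci_boundary,
  ## so a cached system can be reused across C_i grid points) + respiration
  c_bc <- ubar_to_gas_conc(tp$ci_boundary)
  rhs0 <- ts$rhs
  rhs0[ts$dir_idx] <- c_bc
  ## eliminated Dirichlet columns act on the right-hand side
  rhs0 <- rhs0 - ts$dir_colsum * c_bc
  resp_lin <- which(kin$resp_mask)
  resp_lin <- setdiff(resp_lin, ts$dir_vox)
  rhs0[ts$cidx[resp_lin]] <- rhs0[ts$cidx[resp_lin]] + vv * kin$rd_vol * 1e-6

  ## initial state: boundary equilibrium everywhere
  x <- numeric(n_unknown)
  x[seq_len(ts$nc)] <- c_bc
  liq <- ts$cidx[ts$part_c & array(volume$label %in% .LIQUID_LABELS, d)]
  x[liq] <- c_bc * tp$henry_constant
  if (ts$nb > 0) {
    bv <- which(ts$part_b)
    x[ts$bidx[bv]] <- c_bc * tp$henry_constant * ts$keq_vox[bv]
  }

  kco <- kp$kc * (1 + kp$o2 / kp$ko)
  gst <- kp$gamma_star
  sink_of <- function(cc_ubar) {
    wc <- kin$vcmax_vol * cc_ubar / (cc_ubar + kco)
    wj <- jv[chl_lin] * cc_ubar / (4 * cc_ubar + 8 * gst)
    ifelse(cc_ubar > 0, (1 - gst / pmax(cc_ubar, 1e-300)) * pmin(wc, wj), 0)
  }

  res_hist <- numeric(0)
  omega <- 1
  converged <- FALSE
  dx_prev <- NULL
  for (it in seq_len(max_iter)) {
    c_chl <- x[cvec_idx]
    cc_ubar <- pmax(liquid_conc_to_ubar(c_chl, tp$henry_constant), 0)
    sink_umol <- sink_of(cc_ubar)
    sink_mol <- sink_umol * 1e-6
    rhs <- rhs0
    rhs[cvec_idx] <- rhs[cvec_idx] + vv * (ts$lambda * c_chl - sink_mol)
    x_new <- solve_sym(rhs)
    dx <- x_new - x
    rel <- max(abs(dx)) / max(max(abs(x_new)), 1e-300)
    res_hist <- c(res_hist, rel)
    if (it > 2 && rel > res_hist[it - 1] && rel > res_hist[it - 2]) {
      omega <- max(0.25, omega / 2)
    }
    ## geometric-series (Aitken) extrapolation: the lambda-shifted Picard
    ## map contracts with a near-constant ratio, so sum the remaining tail
    if (omega == 1 && !is.null(dx_prev)) {
      denom <- sum(dx_prev * dx_prev)
      r <- if (denom > 0) sum(dx * dx_prev) / denom else 0
      if (r > 0.2 && r < 0.995) {
        x <- x + dx / (1 - r)
      } else {
        x <- x + dx
      }
    } else {
      x <- x + omega * dx
    }
    dx_prev <- dx
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop_eleaf("transport", "no convergence after ", max_iter,
               " iterations; residual history tail: ",
               paste(signif(utils::tail(res_hist, 5), 3), collapse = ", "))
  }

  cvals <- x[seq_len(ts$nc)]
  if (min(cvals) < -1e-6 * max(abs(cvals))) {
    stop_eleaf("transport", "negative CO2 concentration ", min(cvals),
               " at convergence; the mesh is too coarse for these ",
               "parameters")
  }

  ## final fields and outputs
  c_chl <- x[cvec_idx]
  cc_ubar <- pmax(liquid_conc_to_ubar(c_chl, tp$henry_constant), 0)
  sink_umol <- sink_of(cc_ubar)
  a_net <- (sum(sink_umol) * vv - kin$rd_vol * vv * length(resp_lin)) /
    kin$leaf_area
  influx_mol <- boundary_influx(ts, x)
  net_mol <- (sum(sink_umol) - kin$rd_vol * length(resp_lin)) * vv * 1e-6
  mass_err <- abs(influx_mol - net_mol) /
    max(abs(influx_mol), abs(net_mol), (sum(abs(sink_umol)) +
          kin$rd_vol * length(resp_lin)) * vv * 1e-6, 1e-300)

  ## realised electron transport per chloroplast voxel
  wc <- kin$vcmax_vol * cc_ubar / (cc_ubar + kco)
  wj <- jv[chl_lin] * cc_ubar / (4 * cc_ubar + 8 * gst)
  w <- pmin(wc, wj)
  j_real_vol <- ifelse(cc_ubar > 0, w * (4 * cc_ubar + 8 * gst) / cc_ubar, 0)
  j_real_leaf <- sum(j_real_vol) * vv / kin$leaf_area
  q_inc <- light_field$incident_ppfd
  absf <- unname(light_field$totals["absorbed"])
  phi <- if (q_inc > 0 && absf > 0) {
    phi_psii(j_real_leaf, q_inc, kp, leaf_absorptance = absf)
  } else {
    NA_real_
  }

  co2_field <- array(NA_real_, d)
  co2_field[ts$part_c] <- cvals
  hco3_field <- array(NA_real_, d)
  if (ts$nb > 0) hco3_field[ts$part_b] <- x[(ts$nc + 1):(ts$nc + ts$nb)]
  cc_field <- array(NA_real_, d)
  cc_field[chl_lin] <- cc_ubar

  structure(list(co2_field = co2_field, hco3_field = hco3_field,
                 cc_field = cc_field,
                 a_net_leaf = a_net, phi_psii_leaf = phi,
                 j_real_leaf = j_real_leaf,
                 influx_mol = influx_mol, net_uptake_mol = net_mol,
                 mass_balance_error = mass_err,
                 residual_norm = utils::tail(res_hist, 1),
                 residual_history = res_hist,
                 iterations = length(res_hist), converged = TRUE,
                 ci_boundary = tp$ci_boundary,
                 incident_ppfd = q_inc,
                 system = ts, factor = fac),
            class = "steady_state")
}

#' Leaf-level outputs of a converged steady state
#'
#' @param state A `steady_state` from [solve_coupled()].
#' @return List with `a_net` (umol m-2 s-1), `phi_psii`, and the
#'   sink-vs-boundary-flux mass-balance error.
#' @export
compute_outputs <- function(state) {
  stopifnot(inherits(state, "steady_state"))
  if (!isTRUE(state$converged)) {
    stop_eleaf("transport", "refusing to report outputs of an unconverged ",
               "state")
  }
  list(a_net = state$a_net_leaf, phi_psii = state$phi_psii_leaf,
       mass_balance_error = state$mass_balance_error)
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> A_N = ", signif(x$a_net_leaf, 4),
      " umol m-2 s-1, PhiPSII = ", signif(x$phi_psii_leaf, 3),
      " (Ci ", x$ci_boundary, " ubar, Q ", x$incident_ppfd, ")\n", sep = "")
  cat(sprintf("  %d iterations, residual %.2e, mass balance %.2e\n",
              x$iterations, x$residual_norm, x$mass_balance_error))
  invisible(x)
}
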