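#' Potential electron transport rate from absorbed light
#'
#' Non-rectangular hyperbola: `J` is the smaller root of
#' `theta J^2 - (x + Jmax) J + x Jmax = 0` with `x = s * y2ll * i_abs`,
#' the effective excitation flux derived from absorbed PPFD.  For
#' `theta -> 0` the expression degenerates smoothly to the rectangular
#' hyperbola `x Jmax / (x + Jmax)`.
#'
#' @param i_abs Absorbed photon flux (umol m-2 s-1), vectorised.
#' @param params A [kinetic_params] object.
#' @return Potential electron transport `J` (umol e- m-2 s-1), in
#'   `[0, jmax]`.
#' @export
electron_transport <- function(i_abs, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(i_abs < 0)) stop_eleaf("metabolism", "`i_abs` must be >= 0")
  x <- params$s_factor * params$y2ll * i_abs
  jm <- params$jmax
  th <- params$theta
  if (th < 1e-10) {
    return(x * jm / (x + jm + (x + jm == 0)))
  }
  b <- x + jm
  disc <- pmax(0, b^2 - 4 * th * x * jm)
  (b - sqrt(disc)) / (2 * th)
}

#' FvCB net assimilation rate
#'
#' `Wc = Vcmax Cc / (Cc + Kc (1 + O / Ko))`,
#' `Wj = J Cc / (4 Cc + 8 Gamma*)`,
#' `An = (1 - Gamma*/Cc) min(Wc, Wj) - Rd`.  At `Cc = 0` carboxylation
#' vanishes and the function returns `-Rd` without a singularity.
#'
#' @param cc Chloroplast CO2 partial pressure (ubar), vectorised.
#' @param j Electron transport rate (umol e- m-2 s-1), vectorised
#'   (recycled against `cc`).
#' @param params A [kinetic_params] object.
#' @return Net assimilation (umol m-2 s-1; same basis as `vcmax`).
#' @export
net_rate <- function(cc, j, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(cc < 0)) stop_eleaf("metabolism", "`cc` must be >= 0")
  n <- max(length(cc), length(j))
  cc <- rep_len(cc, n); j <- rep_len(j, n)
  kco <- params$kc * (1 + params$o2 / params$ko)
  wc <- params$vcmax * cc / (cc + kco)
  wj <- j * cc / (4 * cc + 8 * params$gamma_star)
  gross <- ifelse(cc > 0,
                  (1 - params$gamma_star / pmax(cc, 1e-300)) * pmin(wc, wj),
                  0)
  gross - params$rd
}

#' Distribute leaf-area kinetics over the voxel grid
#'
#' Leaf-area-based `vcmax` is spread uniformly over the chloroplast
#' volume; `rd` uniformly over the combined cytosol + chloroplast volume
#' (no explicit mitochondria).  Re-integrating density x volume over the
#' leaf area returns the inputs exactly.
#'
#' @param volume A `labelled_volume`.
#' @param params A [kinetic_params] object.
#' @return List with volumetric densities `vcmax_vol` and `rd_vol`
#'   (umol m-3 s-1), the voxel masks `chloro_mask` and `resp_mask`, the
#'   leaf area (m2) and voxel volume (m3).
#' @export
distribute_kinetics <- function(volume, params) {
  stopifnot(inherits(volume, "labelled_volume"),
            inherits(params, "kinetic_params"))
  h <- volume$voxel_size
  d <- volume$dims
  leaf_area <- d[1] * d[2] * h^2 * 1e-12          # m2
  vox_vol <- h^3 * 1e-18                          # m3
  chloro_mask <- volume$label %in% .CHLORO_LABELS
  dim(chloro_mask) <- d
  resp_mask <- volume$label %in%
    .LBL[c("mc_cytosol", "mc_chloroplast", "bs_cytosol", "bs_chloroplast")]
  dim(resp_mask) <- d
  n_chl <- sum(chloro_mask)
  if (n_chl == 0L) stop_eleaf("metabolism", "volume has no chloroplast voxels")
  v_chl <- n_chl * vox_vol
  v_resp <- sum(resp_mask) * vox_vol
  list(vcmax_vol = params$vcmax * leaf_area / v_chl,
       rd_vol = params$rd * leaf_area / v_resp,
       chloro_mask = chloro_mask, resp_mask = resp_mask,
       leaf_area = leaf_area, vox_vol = vox_vol)
}

#' Effective PSII quantum yield
#'
#' `PhiPSII = J_realised / (s * absorptance * i_incident)`, clipped to
#' `[0, 1]`.  `J_realised` is the electron flux consistent with the
#' realised assimilation (Rubisco-limited regions run below the potential
#' `J`).  In the low-light limit this converges to `y2ll`.
#'
#' @param j_realised Realised electron transport (umol e- m-2 s-1).
#' @param i_incident Incident PPFD (umol m-2 s-1), > 0.
#' @param params A [kinetic_params] object.
#' @param leaf_absorptance Fraction of incident light absorbed by the
#'   leaf.
#' @return PhiPSII (dimensionless).
#' @export
phi_psii <- function(j_realised, i_incident, params,
                     leaf_absorptance = params$absorptance) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(i_incident <= 0)) {
    stop_eleaf("metabolism", "`i_incident` must be > 0")
  }
  clamp(j_realised / (params$s_factor * leaf_absorptance * i_incident), 0, 1)
}
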