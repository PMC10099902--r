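#' Unpolarised Fresnel reflectance and refraction angle
#'
#' Mean of the s- and p-polarised Fresnel reflectances with Snell
#' refraction; total internal reflection returns reflectance 1 and an `NA`
#' refraction angle.
#'
#' @param incidence_angle Angle from the surface normal, radians, in
#'   `[0, pi/2)`.
#' @param n1,n2 Refractive indices of the incident and transmitting media
#'   (>= 1).
#' @return List with `reflectance` and `refraction_angle` (radians).
#' @export
#' @examples
#' fresnel_interface(0, 1, 1.5)$reflectance  # ((1-1.5)/(1+1.5))^2 = 0.04
fresnel_interface <- function(incidence_angle, n1, n2) {
  check_number(incidence_angle, "incidence_angle", lo = 0, hi = pi / 2 - 1e-12,
               stage = "optics")
  check_number(n1, "n1", lo = 1, stage = "optics")
  check_number(n2, "n2", lo = 1, stage = "optics")
  cos_i <- cos(incidence_angle)
  sin_t2 <- (n1 / n2)^2 * (1 - cos_i^2)
  if (sin_t2 >= 1) {
    return(list(reflectance = 1, refraction_angle = NA_real_))
  }
  cos_t <- sqrt(1 - sin_t2)
  rs <- ((n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t))^2
  rp <- ((n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i))^2
  list(reflectance = (rs + rp) / 2, refraction_angle = asin(sqrt(sin_t2)))
}

## per-label refractive index and absorption coefficient (um^-1) vectors,
## indexed by label code + 1
optical_tables <- function(volume, optics) {
  lbl <- .LBL
  n_by <- rep(optics$n_liquid, length(lbl))
  names(n_by) <- names(lbl)
  n_by["airspace"] <- optics$n_air
  n_by[c("mc_wall", "bs_wall", "epidermis", "vein")] <- optics$n_wall
  n_by["bulliform"] <- optics$n_liquid

  n_chl_vox <- sum(volume$label %in% .CHLORO_LABELS)
  k_by <- rep(0, length(lbl))
  names(k_by) <- names(lbl)
  if (n_chl_vox > 0 && volume$params$chlorophyll_per_area > 0) {
    d <- volume$dims
    leaf_area_um2 <- d[1] * d[2] * volume$voxel_size^2
    v_chl_per_area_m <- n_chl_vox * volume$voxel_size^3 / leaf_area_um2 * 1e-6
    conc <- volume$params$chlorophyll_per_area / v_chl_per_area_m  # umol m-3
    k_m <- optics$k_chl * conc                                     # m^-1
    k_by[c("mc_chloroplast", "bs_chloroplast")] <- k_m * 1e-6      # um^-1
  }
  ord <- order(lbl)
  list(n = unname(n_by[ord]), k = unname(k_by[ord]))
}

#' Monte-Carlo ray tracing through a labelled leaf volume
#'
#' Traces `n_rays` photon packets entering the adaxial surface, with
#' Fresnel reflection/refraction at every refractive-index step between
#' voxels, Beer-Lambert absorption by chlorophyll inside chloroplast
#' voxels, periodic lateral boundaries and Russian-roulette termination of
#' low-weight packets.  The chlorophyll concentration in chloroplasts is
#' the leaf chlorophyll content divided by the chloroplast volume per leaf
#' area of this geometry.
#'
#' @param volume A `labelled_volume` from [pack_mesophyll()].
#' @param optics An [optical_props] object.
#' @param source A [light_source] object.
#' @param n_rays Number of photon packets (>= 1).
#' @param seed RNG seed for the tracer (independent of R's RNG).
#' @param n_batches Ray batches used for Monte-Carlo standard errors.
#'
#' @return An `absorbed_light_field`: per-voxel absorbed fraction of the
#'   incident flux (`absorbed_frac`), the volumetric absorption field in
#'   umol photons m-3 s-1 (`absorbed`), totals (reflected / transmitted /
#'   absorbed / lost fractions) with batch standard errors, `n_rays` and
#'   `seed`.
#' @export
trace_light <- function(volume, optics, source, n_rays = 20000L, seed = 1L,
                        n_batches = 20L) {
  stopifnot(inherits(volume, "labelled_volume"),
            inherits(optics, "optical_props"),
            inherits(source, "light_source"))
  n_rays <- as.integer(n_rays)
  if (n_rays < 1L) stop_eleaf("optics", "`n_rays` must be >= 1")
  if (!all(volume$label %in% .LBL)) {
    stop_eleaf("optics", "volume contains unlabelled voxels")
  }
  tabs <- optical_tables(volume, optics)
  res <- trace_rays_cpp(as.integer(volume$label), as.integer(volume$dims),
                        volume$voxel_size, tabs$n, tabs$k,
                        n_rays, as.integer(seed), source$direction,
                        source$diffuse_fraction, as.integer(n_batches),
                        1e-4, 1000L)
  frac <- array(res$absorbed, volume$dims)
  d <- volume$dims; h <- volume$voxel_size
  ## volumetric absorption: fraction * Q * leaf area / voxel volume
  vol_factor <- source$incident_ppfd * d[1] * d[2] / h * 1e6  # umol m-3 s-1
  structure(list(absorbed_frac = frac,
                 absorbed = frac * vol_factor,
                 totals = c(reflected = res$reflected,
                            transmitted = res$transmitted,
                            absorbed = res$absorbed_total,
                            lost = res$lost),
                 se = c(reflected = res$se_reflected,
                        transmitted = res$se_transmitted,
                        absorbed = res$se_absorbed),
                 incident_ppfd = source$incident_ppfd,
                 n_rays = n_rays, seed = as.integer(seed),
                 voxel_size = h, dims = d),
            class = "absorbed_light_field")
}

#' Absorbed light per cell
#'
#' Sums the absorbed flux over the chloroplast voxels of each cell
#' (mesophyll cells have positive ids, bundle-sheath cells negative ids)
#' and expresses it on a leaf-area basis, the quantity feeding the
#' potential electron transport of each cell.
#'
#' @param field An `absorbed_light_field`.
#' @param volume The congruent `labelled_volume`.
#' @return Data frame with `cell`, `n_chloroplast_voxels`,
#'   `absorbed_fraction` (of incident flux) and `i_abs` (umol photons m-2
#'   leaf s-1).
#' @export
absorbed_per_chloroplast <- function(field, volume) {
  stopifnot(inherits(field, "absorbed_light_field"),
            inherits(volume, "labelled_volume"))
  if (!identical(field$dims, volume$dims)) {
    stop_eleaf("optics", "field and volume dimensions differ")
  }
  chl <- volume$label %in% .CHLORO_LABELS
  ids <- volume$cell[chl]
  fr <- field$absorbed_frac[chl]
  agg <- rowsum(cbind(frac = fr, n = 1), group = ids)
  cells <- as.integer(rownames(agg))
  data.frame(cell = cells,
             n_chloroplast_voxels = as.integer(agg[, "n"]),
             absorbed_fraction = agg[, "frac"],
             i_abs = agg[, "frac"] * field$incident_ppfd,
             row.names = NULL)
}

#' @export
print.absorbed_light_field <- function(x, ...) {
  cat("<absorbed_light_field> ", paste(x$dims, collapse = " x "),
      " voxels, ", x$n_rays, " rays (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  reflected %.4f  transmitted %.4f  absorbed %.4f  lost %.2g\n",
              x$totals["reflected"], x$totals["transmitted"],
              x$totals["absorbed"], x$totals["lost"]))
  invisible(x)
}
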