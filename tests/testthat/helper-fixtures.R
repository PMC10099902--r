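## Shared fixtures, built once per test session and cached.  All fixtures
## are generated in code; the tiny unit cell is the default rice-like
## parameterisation voxelised at 2 um.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

tiny_volume <- function(seed = 1) {
  cached(paste0("vol_", seed),
         pack_mesophyll(anatomy_preset("aCO2"), seed, voxel_size = 2))
}

tiny_light <- function(q = 2000, n_rays = 20000, seed = 7) {
  cached(paste0("light_", q, "_", n_rays, "_", seed),
         trace_light(tiny_volume(), optical_props(),
                     light_source(incident_ppfd = q), n_rays = n_rays,
                     seed = seed))
}

## steady state at (ci, q) on the tiny volume, reusing one factorisation
tiny_state <- function(ci = 280, q = 2000) {
  key <- paste0("state_", ci, "_", q)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  tp <- transport_params(ci_boundary = ci)
  f <- tiny_light()
  fq <- eleaf:::with_ppfd(f, q)
  cfg <- list()
  if (!is.null(.fixtures$sys)) {
    cfg$system <- .fixtures$sys
    cfg$factor <- .fixtures$fac
  }
  st <- solve_coupled(tiny_volume(), tp, fq, kinetic_params(), cfg)
  if (is.null(.fixtures$sys)) {
    .fixtures$sys <- st$system
    .fixtures$fac <- st$factor
  }
  .fixtures[[key]] <- st
  st
}

## 1D liquid column wrapped between airspace + epidermis at both ends
column_volume <- function(n_liq = 30, h = 1,
                          label_liq = leaf_labels()[["mc_cytosol"]]) {
  lab <- array(leaf_labels()[["airspace"]], c(1, 1, n_liq + 6))
  lab[, , 1:2] <- leaf_labels()[["epidermis"]]
  lab[, , n_liq + 5:6] <- leaf_labels()[["epidermis"]]
  lab[, , 3 + seq_len(n_liq)] <- label_liq
  as_labelled_volume(lab, voxel_size = h,
                     params = anatomy_params(wall_thickness = 1e-6,
                                             epidermis_thickness = 2 * h))
}
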