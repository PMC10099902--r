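#' Anatomical parameters of the leaf unit cell
#'
#' All structural inputs needed to reconstruct one periodic interveinal
#' unit of a rice leaf: leaf-scale dimensions, mesophyll-cell (MC) size and
#' shape, packing targets (porosity and exposed mesophyll surface area),
#' bundle-sheath (BS) dimensions, subcellular plastid fractions, wall
#' thickness and chlorophyll content.  Lengths are in micrometres, areas in
#' square micrometres, fractions dimensionless in `[0, 1]`, chlorophyll in
#' umol per square metre of leaf.
#'
#' @param mesophyll_thickness_vein Mesophyll thickness at the minor vein
#'   (um).
#' @param mesophyll_thickness_bulliform Mesophyll thickness under the
#'   bulliform cells (um); the difference to `mesophyll_thickness_vein`
#'   sets the depth of the bulliform block.
#' @param interveinal_distance Distance between minor vein centres (um);
#'   the lateral (periodic) extent of the unit cell.
#' @param porosity Target mesophyll porosity: airspace volume fraction of
#'   the mesophyll layer.
#' @param mc_length,mc_width,mc_depth MC dimensions (um): length across the
#'   leaf (lateral), width across the leaf thickness, depth along the
#'   proximo-distal axis.
#' @param lobe_number Number of lobes on the MC cross-section (>= 3).
#' @param lobe_amplitude Relative amplitude of the lobes (0 = smooth
#'   ellipse; default 0.35 reproduces the strongly lobed rice MC outline).
#' @param smes_fraction Target exposed mesophyll surface area: fraction of
#'   MC wall in contact with intercellular airspace.
#' @param mc_plastid_fraction Fraction of MC volume occupied by
#'   chloroplasts.
#' @param bs_cell_area Cross-sectional area of one BS cell (um^2).
#' @param bs_thickness Thickness of the BS layer around the vein (um).
#' @param bs_plastid_fraction Fraction of BS cell volume occupied by
#'   chloroplasts.
#' @param wall_thickness MC wall thickness (um).  Walls thinner than the
#'   voxel size are treated as interface resistances by the transport
#'   module rather than as voxels.
#' @param chlorophyll_per_area Leaf chlorophyll content (umol m-2).
#' @param epidermis_thickness Thickness of each epidermis (um).
#' @param bulliform_width Lateral width of the bulliform block (um).
#'
#' @return An object of class `anatomy_params` (validated named list).
#' @seealso [anatomy_preset()] for ready-made parameter sets,
#'   [pack_mesophyll()] for the reconstruction itself.
#' @export
anatomy_params <- function(mesophyll_thickness_vein = 80,
                           mesophyll_thickness_bulliform = 52,
                           interveinal_distance = 140,
                           porosity = 0.30,
                           mc_length = 34,
                           mc_width = 13,
                           mc_depth = 16,
                           lobe_number = 7L,
                           lobe_amplitude = 0.35,
                           smes_fraction = 0.32,
                           mc_plastid_fraction = 0.55,
                           bs_cell_area = 180,
                           bs_thickness = 14,
                           bs_plastid_fraction = 0.10,
                           wall_thickness = 0.15,
                           chlorophyll_per_area = 450,
                           epidermis_thickness = 14,
                           bulliform_width = 42) {
  p <- list(mesophyll_thickness_vein = mesophyll_thickness_vein,
            mesophyll_thickness_bulliform = mesophyll_thickness_bulliform,
            interveinal_distance = interveinal_distance,
            porosity = porosity,
            mc_length = mc_length,
            mc_width = mc_width,
            mc_depth = mc_depth,
            lobe_number = as.integer(lobe_number),
            lobe_amplitude = lobe_amplitude,
            smes_fraction = smes_fraction,
            mc_plastid_fraction = mc_plastid_fraction,
            bs_cell_area = bs_cell_area,
            bs_thickness = bs_thickness,
            bs_plastid_fraction = bs_plastid_fraction,
            wall_thickness = wall_thickness,
            chlorophyll_per_area = chlorophyll_per_area,
            epidermis_thickness = epidermis_thickness,
            bulliform_width = bulliform_width)
  class(p) <- "anatomy_params"
  validate_anatomy_params(p)
}

validate_anatomy_params <- function(p) {
  lengths <- c("mesophyll_thickness_vein", "mesophyll_thickness_bulliform",
               "interveinal_distance", "mc_length", "mc_width", "mc_depth",
               "bs_thickness", "wall_thickness", "epidermis_thickness",
               "bulliform_width")
  for (f in lengths) check_number(p[[f]], f, lo = 1e-9, stage = "anatomy")
  fractions <- c("porosity", "smes_fraction", "mc_plastid_fraction",
                 "bs_plastid_fraction")
  for (f in fractions) check_number(p[[f]], f, lo = 0, hi = 1, stage = "anatomy")
  check_number(p$lobe_amplitude, "lobe_amplitude", lo = 0, hi = 1 - 1e-9,
               stage = "anatomy")
  check_number(p$bs_cell_area, "bs_cell_area", lo = 1e-9, stage = "anatomy")
  check_number(p$chlorophyll_per_area, "chlorophyll_per_area", lo = 0,
               stage = "anatomy")
  if (p$lobe_number < 3L) {
    stop_eleaf("anatomy", "`lobe_number` must be >= 3, got ", p$lobe_number)
  }
  for (f in c("mesophyll_thickness_vein", "mesophyll_thickness_bulliform")) {
    tot <- p[[f]] + 2 * p$epidermis_thickness
    if (p[[f]] >= tot) stop_eleaf("anatomy", "`", f, "` exceeds leaf thickness")
  }
  p
}

#' Metabolic (FvCB) parameters
#'
#' Kinetic constants of the Farquhar-von-Caemmerer-Berry model plus the
#' fluorescence coupling constants linking absorbed light to potential
#' electron transport.  Rates are on a leaf-area basis; the model runs at a
#' fixed leaf temperature of 28 degC, so no temperature-response functions
#' are applied and the Rubisco constants default to tobacco-derived values
#' adjusted to 28 degC.
#'
#' @param vcmax Maximum Rubisco carboxylation rate (umol m-2 s-1).
#' @param jmax Maximum electron transport rate (umol e- m-2 s-1).
#' @param rd Day respiration (umol m-2 s-1).
#' @param gamma_star CO2 compensation point without day respiration (ubar).
#' @param kc Michaelis constant of carboxylation (ubar).
#' @param ko Michaelis constant of oxygenation (mbar).
#' @param o2 Oxygen partial pressure (mbar).
#' @param theta Curvature of the non-rectangular hyperbola for J (0, 1].
#' @param y2ll PSII quantum yield at low light (dimensionless).
#' @param s_factor Lumped scaling between absorbed PPFD x PSII yield and
#'   electron flux (dimensionless); fitted jointly with `y2ll` from
#'   combined gas-exchange/fluorescence data.
#' @param absorptance Leaf absorptance assumed by the big-leaf surrogate
#'   used in curve fitting (the 3D model computes absorptance itself).
#'
#' @return An object of class `kinetic_params`.
#' @seealso [kinetics_preset()], [net_rate()], [electron_transport()]
#' @export
kinetic_params <- function(vcmax = 160,
                           jmax = 215,
                           rd = 1.5,
                           gamma_star = 49.8,
                           kc = 557,
                           ko = 322,
                           o2 = 210,
                           theta = 0.90,
                           y2ll = 0.78,
                           s_factor = 1.0,
                           absorptance = 0.90) {
  p <- list(vcmax = vcmax, jmax = jmax, rd = rd, gamma_star = gamma_star,
            kc = kc, ko = ko, o2 = o2, theta = theta, y2ll = y2ll,
            s_factor = s_factor, absorptance = absorptance)
  class(p) <- "kinetic_params"
  validate_kinetic_params(p)
}

validate_kinetic_params <- function(p) {
  for (f in c("vcmax", "jmax", "rd", "gamma_star", "kc", "ko", "o2",
              "s_factor")) {
    check_number(p[[f]], f, lo = 0, stage = "kinetics")
  }
  check_number(p$theta, "theta", lo = 0, hi = 1, stage = "kinetics")
  check_number(p$y2ll, "y2ll", lo = 1e-12, hi = 1, stage = "kinetics")
  check_number(p$absorptance, "absorptance", lo = 1e-6, hi = 1,
               stage = "kinetics")
  p
}

#' Physical transport parameters
#'
#' Diffusivities, interface permeabilities and carbonic-anhydrase (CA)
#' reaction constants of the CO2/HCO3- reaction-diffusion system, all at
#' 28 degC.  Defaults are literature-typical values for leaf tissue.
#'
#' @param d_co2_gas Gas-phase CO2 diffusivity (m2 s-1).
#' @param d_co2_liquid Dissolved CO2 diffusivity in cytosol/stroma
#'   (m2 s-1).
#' @param d_hco3 HCO3- diffusivity (m2 s-1).  Bicarbonate does not cross
#'   membranes, so its diffusion is confined within each compartment.
#' @param henry_constant Dimensionless Henry ratio, liquid/gas CO2
#'   concentration at equilibrium (approx. 0.74 at 28 degC).
#' @param k_hydration Effective CA-accelerated (de)hydration rate constant
#'   (s-1), applied in cytosol and stroma.
#' @param equilibrium_ratio Equilibrium ratio `[HCO3-]/[CO2]` in the
#'   cytosol (set by cytosolic pH 7.2).
#' @param stroma_equilibrium_ratio Same ratio in the chloroplast stroma
#'   (pH 7.8).
#' @param wall_diffusivity_factor Effective diffusivity reduction inside
#'   the cell wall (fraction of `d_co2_liquid`).
#' @param p_membrane Plasma-membrane CO2 permeability (m s-1);
#'   default at the aquaporin-facilitated end of the literature range.
#' @param p_envelope Chloroplast-envelope CO2 permeability (m s-1).
#' @param ci_boundary Intercellular CO2 partial pressure imposed at the
#'   stomatal boundary patches (ubar).
#' @param cytosol_film Thickness of the cytosolic film between plasma
#'   membrane and chloroplast envelope where the peripheral chloroplast
#'   directly abuts the wall (um).
#'
#' @return An object of class `transport_params`.
#' @seealso [assemble_system()], [solve_coupled()]
#' @export
transport_params <- function(d_co2_gas = 1.6e-5,
                             d_co2_liquid = 1.9e-9,
                             d_hco3 = 1.2e-9,
                             henry_constant = 0.74,
                             k_hydration = 1000,
                             equilibrium_ratio = 7.4,
                             stroma_equilibrium_ratio = 29.5,
                             wall_diffusivity_factor = 0.3,
                             p_membrane = 7e-3,
                             p_envelope = 7e-3,
                             ci_boundary = 280,
                             cytosol_film = 0.5) {
  p <- list(d_co2_gas = d_co2_gas, d_co2_liquid = d_co2_liquid,
            d_hco3 = d_hco3, henry_constant = henry_constant,
            k_hydration = k_hydration, equilibrium_ratio = equilibrium_ratio,
            stroma_equilibrium_ratio = stroma_equilibrium_ratio,
            wall_diffusivity_factor = wall_diffusivity_factor,
            p_membrane = p_membrane, p_envelope = p_envelope,
            ci_boundary = ci_boundary, cytosol_film = cytosol_film)
  class(p) <- "transport_params"
  validate_transport_params(p)
}

validate_transport_params <- function(p) {
  for (f in c("d_co2_gas", "d_co2_liquid", "d_hco3", "henry_constant",
              "k_hydration", "equilibrium_ratio", "stroma_equilibrium_ratio",
              "p_membrane", "p_envelope", "ci_boundary")) {
    check_number(p[[f]], f, lo = 0, stage = "transport")
  }
  check_number(p$wall_diffusivity_factor, "wall_diffusivity_factor",
               lo = 1e-12, hi = 1, stage = "transport")
  check_number(p$cytosol_film, "cytosol_film", lo = 0, stage = "transport")
  p
}

#' Optical properties for ray tracing
#'
#' Refractive indices per compartment and the chlorophyll-specific
#' absorption coefficient.  Absorption occurs only in chloroplast voxels;
#' the chlorophyll concentration there is derived at trace time from the
#' leaf chlorophyll content divided by the chloroplast volume per leaf area
#' of the generated geometry, i.e. the measured chlorophyll is spread
#' uniformly over all chloroplasts.
#'
#' @param n_air Refractive index of the intercellular airspace.
#' @param n_liquid Refractive index of cytosol, vacuole and stroma.
#' @param n_wall Refractive index of cell wall material; epidermis, vein
#'   and bulliform tissue use this value.
#' @param k_chl Chlorophyll-specific absorption coefficient, PPFD-weighted
#'   over the photosynthetically active waveband (m2 umol-1 Chl).
#'
#' @return An object of class `optical_props`.
#' @seealso [trace_light()]
#' @export
optical_props <- function(n_air = 1.0,
                          n_liquid = 1.353,
                          n_wall = 1.415,
                          k_chl = 0.005) {
  for (nm in c("n_air", "n_liquid", "n_wall")) {
    check_number(get(nm), nm, lo = 1, stage = "optics")
  }
  check_number(k_chl, "k_chl", lo = 0, stage = "optics")
  p <- list(n_air = n_air, n_liquid = n_liquid, n_wall = n_wall,
            k_chl = k_chl)
  class(p) <- "optical_props"
  p
}

#' Incident light source
#'
#' @param incident_ppfd Incident photosynthetic photon flux density at the
#'   adaxial surface (umol photons m-2 s-1).
#' @param direction Unit propagation vector of the collimated component;
#'   default normal to the adaxial surface.
#' @param diffuse_fraction Fraction of rays launched with a cosine-weighted
#'   diffuse direction instead of `direction`.
#'
#' @return An object of class `light_source`.
#' @export
light_source <- function(incident_ppfd = 2000,
                         direction = c(0, 0, 1),
                         diffuse_fraction = 0) {
  check_number(incident_ppfd, "incident_ppfd", lo = 0, stage = "optics")
  check_number(diffuse_fraction, "diffuse_fraction", lo = 0, hi = 1,
               stage = "optics")
  if (length(direction) != 3L || !is.numeric(direction)) {
    stop_eleaf("optics", "`direction` must be a numeric vector of length 3")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop_eleaf("optics", "`direction` must be non-zero")
  direction <- direction / nrm
  if (direction[3] <= 0) {
    stop_eleaf("optics", "`direction` must point into the leaf (positive z)")
  }
  p <- list(incident_ppfd = incident_ppfd, direction = direction,
            diffuse_fraction = diffuse_fraction)
  class(p) <- "light_source"
  p
}

#' Ready-made parameter presets for the two growth conditions
#'
#' Synthetic parameter sets emulating rice leaves grown under ambient
#' (`"aCO2"`, 480 ppm) or elevated (`"eCO2"`, 1000 ppm) CO2.  These values
#' are literature-typical for rice (IR64-like) and encode the qualitative
#' acclimation pattern observed when rice develops under elevated CO2:
#' reduced mesophyll porosity and exposed mesophyll surface, slightly
#' thicker walls and slightly reduced mesophyll plastid fraction, with leaf
#' thickness, interveinal distance and cell size unchanged; metabolic
#' acclimation shifts capacity from carboxylation towards electron
#' transport with increased respiration.  They are documented fixtures for
#' simulation studies, not measurements.
#'
#' @param condition `"aCO2"` or `"eCO2"`.
#' @return For `anatomy_preset` an [anatomy_params] object, for
#'   `kinetics_preset` a [kinetic_params] object.
#' @export
anatomy_preset <- function(condition = c("aCO2", "eCO2")) {
  condition <- match.arg(condition)
  switch(condition,
    aCO2 = anatomy_params(),
    eCO2 = anatomy_params(porosity = 0.285,
                          smes_fraction = 0.305,
                          mc_length = 35,
                          mc_width = 13.4,
                          mc_depth = 16.5,
                          mc_plastid_fraction = 0.54,
                          wall_thickness = 0.165,
                          bs_cell_area = 190,
                          bs_thickness = 14.5,
                          bs_plastid_fraction = 0.12,
                          chlorophyll_per_area = 480))
}

#' @rdname anatomy_preset
#' @export
kinetics_preset <- function(condition = c("aCO2", "eCO2")) {
  condition <- match.arg(condition)
  switch(condition,
    aCO2 = kinetic_params(),
    eCO2 = kinetic_params(vcmax = 140, jmax = 242, rd = 2.2, y2ll = 0.74))
}

#' @export
print.anatomy_params <- function(x, ...) {
  cat("<anatomy_params>\n")
  for (f in names(x)) cat(sprintf("  %-30s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  for (f in names(x)) cat(sprintf("  %-14s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' @export
print.transport_params <- function(x, ...) {
  cat("<transport_params>\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}
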