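#' Chamber geometry
#'
#' Describes a rectangular parallel-plate perfusion chamber. The reference
#' design is 250 um high, 1250 um wide and 13000 um long, so that the
#' cross-section is wide and shallow and the flow is well approximated by
#' plane Poiseuille flow between parallel plates.
#'
#' @param height_um chamber height h (um); the characteristic transport length.
#' @param width_um chamber width w (um).
#' @param length_um chamber length L (um), along the flow direction.
#' @return an object of class `chamber_geometry` with fields in um.
#' @export
chamber_geometry <- function(height_um = 250, width_um = 1250, length_um = 13000) {
  if (any(c(height_um, width_um, length_um) <= 0)) {
    stop_invalid("chamber dimensions must be strictly positive (h=%g, w=%g, L=%g um)",
                 height_um, width_um, length_um)
  }
  if (height_um > width_um) {
    warning("chamber height exceeds width; parallel-plate (w >> h) assumption is doubtful",
            call. = FALSE)
  }
  structure(list(height_um = height_um, width_um = width_um, length_um = length_um),
            class = "chamber_geometry")
}

#' Perfusion setting
#'
#' @param q_ul_per_hr volumetric flow rate Q (uL/hr). The reference design
#'   perfuses each chamber at 33 uL/hr.
#' @param viscosity_pa_s dynamic viscosity (Pa s); default 1e-3 for aqueous
#'   culture medium at 37 C.
#' @return an object of class `perfusion_setting`.
#' @export
perfusion_setting <- function(q_ul_per_hr = 33, viscosity_pa_s = 1e-3) {
  if (q_ul_per_hr < 0) stop_invalid("flow rate must be >= 0 (got %g uL/hr)", q_ul_per_hr)
  if (viscosity_pa_s <= 0) stop_invalid("viscosity must be > 0 (got %g Pa s)", viscosity_pa_s)
  structure(list(q_ul_per_hr = q_ul_per_hr, viscosity_pa_s = viscosity_pa_s),
            class = "perfusion_setting")
}

#' Ligand specification
#'
#' A diffusible secreted factor characterised by molecular weight and
#' diffusivity. For a ~20 kDa growth factor the diffusivity in medium is of
#' order 1e-6 to 1e-7 cm^2/s; the conservative (convection-underestimating)
#' choice is the upper end, 1e-6 cm^2/s.
#'
#' @param mw_kda molecular weight (kDa).
#' @param d_cm2_s diffusivity D_L (cm^2/s).
#' @return an object of class `ligand_spec`.
#' @export
ligand_spec <- function(mw_kda = 20, d_cm2_s = 1e-6) {
  if (mw_kda <= 0 || d_cm2_s <= 0) {
    stop_invalid("ligand MW and diffusivity must be positive (MW=%g kDa, D=%g cm2/s)",
                 mw_kda, d_cm2_s)
  }
  if (d_cm2_s <= 1e-9 || d_cm2_s >= 1e-4) {
    stop_invalid("diffusivity %g cm2/s outside the plausible (1e-9, 1e-4) window", d_cm2_s)
  }
  structure(list(mw_kda = mw_kda, d_cm2_s = d_cm2_s), class = "ligand_spec")
}

#' Receptor specification
#'
#' Surface receptor kinetics of the adherent cells. Defaults describe a cell
#' with 1e4 receptors, an attached radius of 10 um, and a deliberately high
#' association rate k_on = 1e6 M^-1 s^-1 so that ligand binding, if anything,
#' is overestimated relative to convection.
#'
#' @param kon_per_M_s association rate k_on (M^-1 s^-1).
#' @param receptors_per_cell receptor count N_R per cell.
#' @param cell_radius_um radius of the attached (spread) cell footprint (um).
#' @return an object of class `receptor_spec`.
#' @export
receptor_spec <- function(kon_per_M_s = 1e6, receptors_per_cell = 1e4,
                          cell_radius_um = 10) {
  if (kon_per_M_s < 0 || receptors_per_cell < 0 || cell_radius_um <= 0) {
    stop_invalid("receptor parameters must be non-negative with radius > 0")
  }
  structure(list(kon_per_M_s = kon_per_M_s,
                 receptors_per_cell = receptors_per_cell,
                 cell_radius_um = cell_radius_um),
            class = "receptor_spec")
}

#' Mean fluid velocity in the chamber
#'
#' v_mean = Q / (w h). At 33 uL/hr through a 1250 x 250 um cross-section this
#' is 0.0293 mm/s, conventionally rounded to ~0.03 mm/s.
#'
#' @param setting a [perfusion_setting()].
#' @param geom a [chamber_geometry()].
#' @return mean velocity (mm/s).
#' @export
mean_velocity <- function(setting, geom) {
  area_m2 <- um_to_m(geom$width_um) * um_to_m(geom$height_um)
  if (area_m2 <= 0) stop_invalid("chamber cross-section must be positive")
  m_to_mm(ul_per_hr_to_m3_per_s(setting$q_ul_per_hr) / area_m2)
}

#' Diffusivity from molecular-weight scaling
#'
#' Stokes-Einstein scaling for globular macromolecules: the hydrodynamic
#' radius grows as MW^(1/3), so D scales as MW^(-1/3) relative to an anchor
#' molecule of known diffusivity.
#'
#' @param mw_kda molecular weight of the molecule of interest (kDa).
#' @param anchor_mw_kda molecular weight of the anchor (kDa).
#' @param anchor_d_cm2_s diffusivity of the anchor (cm^2/s).
#' @return estimated diffusivity (cm^2/s).
#' @export
estimate_diffusivity <- function(mw_kda, anchor_mw_kda = 20, anchor_d_cm2_s = 1e-6) {
  if (any(c(mw_kda, anchor_mw_kda, anchor_d_cm2_s) <= 0)) {
    stop_invalid("molecular weights and anchor diffusivity must be positive")
  }
  anchor_d_cm2_s * (anchor_mw_kda / mw_kda)^(1 / 3)
}

#' Peclet number
#'
#' Pe = v_mean h / D_L: convective over diffusive transport across the
#' chamber height. Pe >> 1 marks convection-dominated transport; the
#' reference design point (v ~ 0.03 mm/s, h = 250 um, D = 1e-6 cm^2/s) gives
#' Pe ~ 75.
#'
#' @param v_mean_mm_s mean velocity (mm/s).
#' @param geom a [chamber_geometry()].
#' @param ligand a [ligand_spec()].
#' @return dimensionless Peclet number.
#' @export
peclet <- function(v_mean_mm_s, geom, ligand) {
  d_m2_s <- cm2_per_s_to_m2_per_s(ligand$d_cm2_s)
  if (d_m2_s <= 0) stop_invalid("diffusivity must be positive to form Pe")
  (v_mean_mm_s * 1e-3) * um_to_m(geom$height_um) / d_m2_s
}

#' Receptor areal density on the chamber floor
#'
#' Receptors of one cell spread over its projected disc: rho_R =
#' N_R / (pi r^2 N_A), in mol/m^2. This confluent-monolayer convention treats
#' the floor as uniformly reactive. `convention = "sphere"` instead spreads
#' the receptors over the membrane of a sphere of the same radius (4 pi r^2),
#' a quarter of the disc density.
#'
#' @param rec a [receptor_spec()].
#' @param convention `"disc"` (default) or `"sphere"`.
#' @return molar surface density (mol/m^2).
#' @export
receptor_areal_density <- function(rec, convention = c("disc", "sphere")) {
  convention <- match.arg(convention)
  r_m <- um_to_m(rec$cell_radius_um)
  area <- switch(convention, disc = pi * r_m^2, sphere = 4 * pi * r_m^2)
  rec$receptors_per_cell / (area * N_AVOGADRO)
}

#' Damkohler number
#'
#' Da = k_on rho_R h / D_L: receptor binding at the floor over diffusion
#' across the chamber height, with rho_R from [receptor_areal_density()] and
#' k_on converted to m^3 mol^-1 s^-1. The reference parameters (k_on = 1e6
#' M^-1 s^-1, 1e4 receptors over a 10 um disc, h = 250 um, D = 1e-6 cm^2/s)
#' give Da ~ 0.132: diffusion outpaces binding.
#'
#' @inheritParams receptor_areal_density
#' @param geom a [chamber_geometry()].
#' @param ligand a [ligand_spec()].
#' @return dimensionless Damkohler number.
#' @export
damkohler <- function(rec, geom, ligand, convention = "disc") {
  kon_si <- per_M_s_to_m3_per_mol_s(rec$kon_per_M_s)
  rho <- receptor_areal_density(rec, convention)
  kon_si * rho * um_to_m(geom$height_um) / cm2_per_s_to_m2_per_s(ligand$d_cm2_s)
}

#' Ratio of Peclet to Damkohler number
#'
#' Pe/Da compares convection with reaction (binding). Pe/Da >> 1 means flow
#' removes ligand much faster than receptors can capture it; the reference
#' design point gives ~568 (of order 500).
#'
#' @param pe Peclet number.
#' @param da Damkohler number (> 0).
#' @return dimensionless ratio.
#' @export
pe_over_da <- function(pe, da) {
  if (da == 0) {
    stop_invalid("Pe/Da undefined at Da = 0: reaction-free regime, binding is absent")
  }
  pe / da
}

#' Wall shear stress under plane Poiseuille flow
#'
#' tau = 6 mu Q / (w h^2), reported in dyn/cm^2 (1 Pa = 10 dyn/cm^2).
#' `cell_factor` is a multiplicative correction for flow perturbation by
#' attached cells; the uncorrected wall value at the reference design point
#' is 7.0e-3 dyn/cm^2, and any realistic correction leaves the shear far
#' below the ~1 dyn/cm^2 scale at which phenotypic effects are reported.
#'
#' @param setting a [perfusion_setting()].
#' @param geom a [chamber_geometry()].
#' @param cell_factor dimensionless correction factor (> 0), default 1.
#' @return shear stress (dyn/cm^2).
#' @export
wall_shear <- function(setting, geom, cell_factor = 1.0) {
  if (cell_factor <= 0) stop_invalid("cell_factor must be > 0")
  q <- ul_per_hr_to_m3_per_s(setting$q_ul_per_hr)
  tau_pa <- 6 * setting$viscosity_pa_s * q /
    (um_to_m(geom$width_um) * um_to_m(geom$height_um)^2)
  cell_factor * pa_to_dyn_per_cm2(tau_pa)
}

#' Surface-area-to-volume ratio
#'
#' For a perfusion chamber whose floor is the sole culture surface, SA/V =
#' (w L)/(w L h) = 1/h: 4/mm at h = 250 um. For a conventional dish, SA/V =
#' growth area / media volume: a 10-cm dish (78.5 cm^2) under 10 mL gives
#' ~0.79/mm. The contrast drives the higher volumetric cell density in
#' microchambers at equal areal seeding density.
#'
#' @param geom a [chamber_geometry()], for chamber mode.
#' @param dish_area_cm2,dish_volume_ml growth area and media volume, for dish
#'   mode (both must be given together, and `geom` omitted).
#' @return ratio (1/mm).
#' @export
surface_to_volume <- function(geom = NULL, dish_area_cm2 = NULL, dish_volume_ml = NULL) {
  if (!is.null(geom)) {
    return(1 / (geom$height_um / 1000))
  }
  if (is.null(dish_area_cm2) || is.null(dish_volume_ml)) {
    stop_invalid("provide either a chamber geometry or both dish area and volume")
  }
  if (dish_volume_ml <= 0) stop_invalid("dish media volume must be positive")
  (dish_area_cm2 * 100) / (dish_volume_ml * 1000)  # mm^2 / mm^3
}

#' Classify the transport regime
#'
#' A design point is convection-dominated when Pe and Pe/Da both clear their
#' thresholds (defaults 10; the design aim is >> 1, so 10 is a conservative
#' reading of "much greater"). Otherwise, Da against 1 separates the
#' diffusion-dominated from the reaction-limited regime; a reactive floor
#' under weak flow with Da near 1 is labelled mixed.
#'
#' @param pe Peclet number (>= 0).
#' @param da Damkohler number (>= 0).
#' @param pe_threshold,ratio_threshold regime thresholds, default 10.
#' @return one of `"convection_dominated"`, `"diffusion_dominated"`,
#'   `"reaction_limited"`, `"mixed"`.
#' @export
classify_regime <- function(pe, da, pe_threshold = 10, ratio_threshold = 10) {
  if (pe < 0 || da < 0) stop_invalid("Pe and Da must be non-negative")
  ratio <- if (da > 0) pe / da else Inf
  if (pe > pe_threshold && ratio > ratio_threshold) return("convection_dominated")
  if (da > 1) {
    if (pe > pe_threshold) return("mixed") else return("reaction_limited")
  }
  "diffusion_dominated"
}

#' Dimensionless design summary for a perfusion chamber
#'
#' Chains the transport calculations for one design point and returns the
#' summary used to judge whether perfusion can wash out secreted ligand.
#'
#' @param geom a [chamber_geometry()].
#' @param setting a [perfusion_setting()].
#' @param ligand a [ligand_spec()].
#' @param rec a [receptor_spec()].
#' @param cell_factor shear correction factor, see [wall_shear()].
#' @param v_mean_mm_s optionally override the Q-derived mean velocity (mm/s),
#'   e.g. to use a conventionally rounded value.
#' @return an object of class `dimensionless_summary`: list with `v_mean_mm_s`,
#'   `pe`, `da`, `pe_over_da`, `tau_dyn_cm2`, `sa_v_per_mm`, `regime`.
#' @export
design_summary <- function(geom = chamber_geometry(),
                           setting = perfusion_setting(),
                           ligand = ligand_spec(),
                           rec = receptor_spec(),
                           cell_factor = 1.0,
                           v_mean_mm_s = NULL) {
  v <- if (is.null(v_mean_mm_s)) mean_velocity(setting, geom) else v_mean_mm_s
  pe <- peclet(v, geom, ligand)
  da <- damkohler(rec, geom, ligand)
  structure(list(
    v_mean_mm_s = v,
    pe = pe,
    da = da,
    pe_over_da = pe_over_da(pe, da),
    tau_dyn_cm2 = wall_shear(setting, geom, cell_factor),
    sa_v_per_mm = surface_to_volume(geom),
    regime = classify_regime(pe, da)
  ), class = "dimensionless_summary")
}

#' @export
print.dimensionless_summary <- function(x, ...) {
  cat("Perfusion chamber transport summary\n")
  cat(sprintf("  mean velocity : %.4f mm/s\n", x$v_mean_mm_s))
  cat(sprintf("  Pe            : %.3g\n", x$pe))
  cat(sprintf("  Da            : %.3g\n", x$da))
  cat(sprintf("  Pe/Da         : %.3g\n", x$pe_over_da))
  cat(sprintf("  wall shear    : %.2e dyn/cm^2\n", x$tau_dyn_cm2))
  cat(sprintf("  SA/V          : %.3g /mm\n", x$sa_v_per_mm))
  cat(sprintf("  regime        : %s\n", x$regime))
  invisible(x)
}
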