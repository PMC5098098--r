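# Concentric-cylinder limb geometry and tetrapolar electrode placement.
# SI units (metres) throughout; helper sweeps accept millimetres explicitly.

#' Build the concentric-cylinder limb model
#'
#' The upper arm is modelled as concentric cylinders of fixed length:
#' bone marrow, cortical bone (optional), muscle and a merged
#' skin/subcutaneous-fat layer, from the axis outward.
#'
#' Two conventions for "muscle thickness" are supported, since the quantity
#' is anatomically ambiguous: `"outer_diameter"` (default) reads the value
#' as the outer diameter of the muscle layer (so a 51 mm muscle in a limb
#' with 5 mm fat gives a 61 mm arm diameter, anatomically plausible);
#' `"annular"` reads it as the per-side radial thickness of the muscle
#' annulus.
#'
#' @param muscle_thickness Muscle thickness in m (interpretation set by
#'   `thickness_convention`).
#' @param fat_thickness Radial thickness of the merged skin-fat layer, m.
#' @param length Cylinder length in m (default 0.146).
#' @param marrow_radius Outer radius of the marrow core, m.
#' @param bone_radius Outer radius of the cortical bone layer, m. Ignored
#'   when `include_cortical_bone = FALSE`.
#' @param thickness_convention `"outer_diameter"` or `"annular"`.
#' @param include_cortical_bone Include the cortical bone layer (default
#'   TRUE); when FALSE the model has three layers (marrow, muscle, skin-fat).
#' @return An object of class `limb_model` with fields `length`,
#'   `layer_radii` (named, strictly increasing outer radii), `layer_materials`
#'   and the build parameters.
#' @export
#' @examples
#' m <- build_limb(muscle_thickness = 0.051, fat_thickness = 0.005)
#' m$layer_radii
build_limb <- function(muscle_thickness = 0.051, fat_thickness = 0.005,
                       length = 0.146,
                       marrow_radius = 0.007, bone_radius = 0.012,
                       thickness_convention = c("outer_diameter", "annular"),
                       include_cortical_bone = TRUE) {
  thickness_convention <- match.arg(thickness_convention)
  stopifnot(muscle_thickness > 0, fat_thickness > 0, length > 0,
            marrow_radius > 0)
  bone_outer <- if (include_cortical_bone) bone_radius else marrow_radius
  if (include_cortical_bone && bone_radius <= marrow_radius)
    stop("bone_radius must exceed marrow_radius")
  muscle_outer <- switch(thickness_convention,
    outer_diameter = muscle_thickness / 2,
    annular = bone_outer + muscle_thickness)
  if (muscle_outer <= bone_outer)
    stop("muscle layer collapses: outer radius ", muscle_outer,
         " m does not exceed bone outer radius ", bone_outer, " m")
  radii <- c(marrow = marrow_radius)
  materials <- c(marrow = "marrow")
  if (include_cortical_bone) {
    radii <- c(radii, cortical_bone = bone_radius)
    materials <- c(materials, cortical_bone = "cortical_bone")
  }
  radii <- c(radii, muscle = muscle_outer,
             skin_fat = muscle_outer + fat_thickness)
  materials <- c(materials, muscle = "muscle", skin_fat = "skin_fat")
  if (any(diff(radii) <= 0)) stop("layer radii must be strictly increasing")
  if (radii[[length(radii)]] >= length / 2)
    stop("outer radius must be smaller than length/2 (slender limb)")
  structure(list(length = length, layer_radii = radii,
                 layer_materials = materials,
                 muscle_thickness = muscle_thickness,
                 fat_thickness = fat_thickness,
                 thickness_convention = thickness_convention,
                 include_cortical_bone = include_cortical_bone),
            class = "limb_model")
}

#' Homogeneous cylinder (verification-oracle geometry)
#'
#' @param radius Outer radius, m.
#' @param length Cylinder length, m.
#' @param material Material name to assign (default `"uniform"`).
#' @return A single-layer `limb_model`.
#' @export
homogeneous_limb <- function(radius, length, material = "uniform") {
  stopifnot(radius > 0, length > 0, radius < length / 2)
  structure(list(length = length,
                 layer_radii = stats::setNames(radius, material),
                 layer_materials = stats::setNames(material, material),
                 muscle_thickness = NA_real_, fat_thickness = NA_real_,
                 thickness_convention = "none",
                 include_cortical_bone = FALSE),
            class = "limb_model")
}

#' Rebuild a limb model with a new muscle thickness
#'
#' The fat-layer thickness, the bone radii and the length are preserved;
#' only the muscle outer radius (and hence the limb outer radius) changes.
#'
#' @param model A `limb_model` built by [build_limb()].
#' @param new_thickness Muscle thickness in m, interpreted under the model's
#'   thickness convention.
#' @return A new `limb_model`.
#' @export
with_muscle_thickness <- function(model, new_thickness) {
  stopifnot(inherits(model, "limb_model"), new_thickness > 0)
  build_limb(muscle_thickness = new_thickness,
             fat_thickness = model$fat_thickness,
             length = model$length,
             marrow_radius = model$layer_radii[["marrow"]],
             bone_radius = if (model$include_cortical_bone)
               model$layer_radii[["cortical_bone"]] else 0.012,
             thickness_convention = model$thickness_convention,
             include_cortical_bone = model$include_cortical_bone)
}

#' Rebuild a limb model with a new skin-fat thickness
#'
#' @param model A `limb_model`.
#' @param new_thickness Fat-layer radial thickness in m.
#' @return A new `limb_model`.
#' @export
with_fat_thickness <- function(model, new_thickness) {
  stopifnot(inherits(model, "limb_model"), new_thickness > 0)
  build_limb(muscle_thickness = model$muscle_thickness,
             fat_thickness = new_thickness,
             length = model$length,
             marrow_radius = model$layer_radii[["marrow"]],
             bone_radius = if (model$include_cortical_bone)
               model$layer_radii[["cortical_bone"]] else 0.012,
             thickness_convention = model$thickness_convention,
             include_cortical_bone = model$include_cortical_bone)
}

#' @export
print.limb_model <- function(x, ...) {
  cat("<limb_model> length", x$length * 1e3, "mm; outer radii (mm):\n")
  print(round(x$layer_radii * 1e3, 3))
  invisible(x)
}

# -- electrode configuration --------------------------------------------------

#' Tetrapolar electrode configuration
#'
#' Four curved rectangular patches on the outer surface, symmetric about
#' mid-length and all centred on the same angular position: drive_A,
#' sense_1, sense_2, drive_B in axial order. Axial spacings follow the
#' edge-to-edge convention, so a "15-30-15" arrangement means 15 mm between
#' each drive and its neighbouring sense electrode and 30 mm between the
#' sense electrodes.
#'
#' @param drive_width Axial width of each drive electrode, m.
#' @param sense_width Axial width of each sense electrode, m.
#' @param angular_halfwidth_drive Angular coverage of the drive electrodes,
#'   degrees per side of the symmetry plane, in (0, 180].
#' @param angular_halfwidth_sense Same for the sense electrodes.
#' @param gap_sense_sense Edge-to-edge axial gap between the two sense
#'   electrodes, m (> 0).
#' @param gap_sense_drive Edge-to-edge axial gap between each sense
#'   electrode and its neighbouring drive electrode, m (> 0).
#' @param label Optional configuration label carried into outputs.
#' @return An object of class `electrode_config`.
#' @export
electrode_config <- function(drive_width, sense_width,
                             angular_halfwidth_drive,
                             angular_halfwidth_sense,
                             gap_sense_sense, gap_sense_drive,
                             label = "custom") {
  stopifnot(drive_width > 0, sense_width > 0,
            gap_sense_sense > 0, gap_sense_drive > 0)
  if (angular_halfwidth_drive <= 0 || angular_halfwidth_drive > 180 ||
      angular_halfwidth_sense <= 0 || angular_halfwidth_sense > 180)
    stop("angular halfwidths must lie in (0, 180] degrees")
  structure(list(drive_width = drive_width, sense_width = sense_width,
                 angular_halfwidth_drive = angular_halfwidth_drive,
                 angular_halfwidth_sense = angular_halfwidth_sense,
                 gap_sense_sense = gap_sense_sense,
                 gap_sense_drive = gap_sense_drive,
                 label = label),
            class = "electrode_config")
}

#' Total axial footprint of a configuration, m
#' @param config An `electrode_config`.
#' @return Footprint in m: `2 w_drive + 2 w_sense + 2 gap_sd + gap_ss`.
#' @export
config_footprint <- function(config) {
  2 * config$drive_width + 2 * config$sense_width +
    2 * config$gap_sense_drive + config$gap_sense_sense
}

#' Inner-edge axial separation of the drive electrodes, m
#' @param config An `electrode_config`.
#' @return `2 gap_sense_drive + 2 w_sense + gap_ss` in m.
#' @export
drive_separation <- function(config) {
  2 * config$gap_sense_drive + 2 * config$sense_width +
    config$gap_sense_sense
}

#' Named electrode-configuration presets
#'
#' Three arrangements studied with the cylindrical arm model:
#' \describe{
#'   \item{conventional}{15-30-15 mm gaps, 65 mm (circumferential) x 7 mm
#'     (axial) electrodes.}
#'   \item{optimized}{33-7-33 mm gaps, 7 mm x 7 mm electrodes.}
#'   \item{wide}{44-2-44 mm gaps, 1 mm x 1 mm electrodes.}
#'   \item{point}{conventional 15-30-15 mm gaps with 1 mm x 1 mm
#'     electrodes.}
#' }
#' The circumferential extent (mm of arc) is converted to an angular
#' halfwidth at the outer radius of `model`.
#'
#' @param name Preset name.
#' @param model `limb_model` supplying the outer radius for the arc-to-angle
#'   conversion (default: reference arm, 51 mm muscle / 5 mm fat).
#' @return An `electrode_config`.
#' @export
electrode_preset <- function(name = c("conventional", "optimized", "wide",
                                      "point"),
                             model = build_limb()) {
  name <- match.arg(name)
  a <- model$layer_radii[[length(model$layer_radii)]]
  hw <- function(arc_m) {
    deg <- (arc_m / 2) / a * 180 / pi
    min(deg, 180)
  }
  p <- switch(name,
    conventional = list(arc = 0.065, w = 0.007, ss = 0.030, sd = 0.015),
    optimized    = list(arc = 0.007, w = 0.007, ss = 0.007, sd = 0.033),
    wide         = list(arc = 0.001, w = 0.001, ss = 0.002, sd = 0.044),
    point        = list(arc = 0.001, w = 0.001, ss = 0.030, sd = 0.015))
  electrode_config(drive_width = p$w, sense_width = p$w,
                   angular_halfwidth_drive = hw(p$arc),
                   angular_halfwidth_sense = hw(p$arc),
                   gap_sense_sense = p$ss, gap_sense_drive = p$sd,
                   label = name)
}

#' Place the four electrode patches on a limb model
#'
#' @param model A `limb_model`.
#' @param config An `electrode_config` whose footprint fits the model
#'   length.
#' @return A list of four `electrode_patch` objects (fields `role`, `z0`,
#'   `z1` in m, `theta_halfwidth` in degrees) in axial order drive_A,
#'   sense_1, sense_2, drive_B.
#' @export
place_electrodes <- function(model, config) {
  stopifnot(inherits(model, "limb_model"),
            inherits(config, "electrode_config"))
  L <- model$length
  if (config_footprint(config) > L)
    stop("electrode footprint ", config_footprint(config) * 1e3,
         " mm exceeds model length ", L * 1e3, " mm")
  mid <- L / 2
  s1 <- c(mid - config$gap_sense_sense / 2 - config$sense_width,
          mid - config$gap_sense_sense / 2)
  s2 <- c(mid + config$gap_sense_sense / 2,
          mid + config$gap_sense_sense / 2 + config$sense_width)
  dA <- c(s1[1] - config$gap_sense_drive - config$drive_width,
          s1[1] - config$gap_sense_drive)
  dB <- c(s2[2] + config$gap_sense_drive,
          s2[2] + config$gap_sense_drive + config$drive_width)
  patch <- function(role, zz, hw) {
    structure(list(role = role, z0 = zz[1], z1 = zz[2],
                   theta_halfwidth = hw), class = "electrode_patch")
  }
  patches <- list(
    patch("drive_A", dA, config$angular_halfwidth_drive),
    patch("sense_1", s1, config$angular_halfwidth_sense),
    patch("sense_2", s2, config$angular_halfwidth_sense),
    patch("drive_B", dB, config$angular_halfwidth_drive))
  z0s <- vapply(patches, `[[`, 0, "z0")
  z1s <- vapply(patches, `[[`, 0, "z1")
  if (any(z0s < 0) || any(z1s > L))
    stop("electrode patches extend beyond the cylinder ends")
  if (any(z0s[-1] <= z1s[-4]))
    stop("electrode patches overlap axially")
  patches
}
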