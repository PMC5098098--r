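# Independent verification oracles that gate every study-level experiment:
# a closed-form uniform-field reference, a Richardson mesh-refinement
# study, and exact discrete identities (reciprocity, conservation).

#' Closed-form resistance of a homogeneous cylinder between ring senses
#'
#' For full-ring drive electrodes far (more than one radius) from the sense
#' rings on a homogeneous cylinder with insulated lateral surface, the
#' axial field at the sense rings is uniform and the four-point resistance
#' is `R = d / (sigma * pi * a^2)` with `d` the sense-ring centre
#' separation.
#'
#' @param sigma Conductivity, S/m.
#' @param outer_radius Cylinder radius `a`, m.
#' @param sense_separation Sense-ring centre separation `d`, m.
#' @return Resistance in ohm.
#' @export
ring_electrode_closed_form <- function(sigma, outer_radius,
                                       sense_separation) {
  stopifnot(sigma > 0, outer_radius > 0, sense_separation > 0)
  sense_separation / (sigma * pi * outer_radius^2)
}

#' Reference homogeneous-cylinder oracle case
#'
#' Geometry chosen so the closed form is valid: drive-to-sense distance
#' (100 mm) twice the radius, narrow sense rings (2 mm) so their shunting
#' perturbation is negligible against the 50 mm centre separation.
#'
#' @param sigma Conductivity of the uniform medium, S/m.
#' @param eps_r Relative permittivity (default 0: purely resistive).
#' @return List with `model`, `config`, `patches`, `lib`,
#'   `sense_separation` (centre-to-centre, m) and `R_ref` (ohm).
#' @export
oracle_case_homogeneous <- function(sigma = 1, eps_r = 0) {
  model <- homogeneous_limb(radius = 0.05, length = 0.5)
  cfg <- electrode_config(drive_width = 0.02, sense_width = 0.002,
                          angular_halfwidth_drive = 180,
                          angular_halfwidth_sense = 180,
                          gap_sense_sense = 0.048,
                          gap_sense_drive = 0.100,
                          label = "oracle_homogeneous")
  d <- cfg$gap_sense_sense + cfg$sense_width
  list(model = model, config = cfg,
       patches = place_electrodes(model, cfg),
       lib = uniform_library(sigma, eps_r),
       sense_separation = d,
       R_ref = ring_electrode_closed_form(sigma, 0.05, d))
}

#' Layered isotropic oracle case (self-consistency reference)
#'
#' A three-layer isotropic cylinder with an order-of-magnitude conductivity
#' contrast, full-ring electrodes; no closed form, used with
#' [brute_force_fine_grid()] as its own extrapolated reference.
#'
#' @return List with `model`, `config`, `patches`, `lib`.
#' @export
oracle_case_layered <- function() {
  model <- structure(list(
    length = 0.5,
    layer_radii = c(core = 0.012, mid = 0.045, shell = 0.05),
    layer_materials = c(core = "core", mid = "mid", shell = "shell"),
    muscle_thickness = NA_real_, fat_thickness = NA_real_,
    thickness_convention = "none", include_cortical_bone = FALSE),
    class = "limb_model")
  cfg <- electrode_config(drive_width = 0.02, sense_width = 0.002,
                          angular_halfwidth_drive = 180,
                          angular_halfwidth_sense = 180,
                          gap_sense_sense = 0.048,
                          gap_sense_drive = 0.100,
                          label = "oracle_layered")
  lib <- structure(list(condition = "oracle", version = "1",
                        specs = list(core = constant_material(0.02, 0),
                                     mid = constant_material(0.5, 0),
                                     shell = constant_material(0.05, 0))),
                   class = "tissue_library")
  list(model = model, config = cfg,
       patches = place_electrodes(model, cfg), lib = lib)
}

# Explicit refinement ladder used by the convergence study (axisymmetric
# cases: angular resolution held coarse, r and z refined by 2 per level).
.oracle_levels <- function(model, nlev = 3) {
  a <- model$layer_radii[[length(model$layer_radii)]]
  lapply(seq_len(nlev), function(l)
    list(dr = a / (5 * 2^(l - 1)), dtheta = 90, dz = 0.012 / 2^(l - 1)))
}

#' Mesh-refinement (Richardson) convergence study
#'
#' Solves a case on a ladder of uniformly refined grids, estimates the
#' empirical convergence order from consecutive differences and
#' extrapolates a reference impedance.
#'
#' @param case A list with `model`, `patches`, `lib` (see
#'   [oracle_case_homogeneous()]).
#' @param nlev Number of refinement levels (>= 3).
#' @param frequency Hz.
#' @return List of class `oracle_report`: per-level data frame (`nodes`,
#'   `Z_real`, `Z_imag`, `rel_error` vs the extrapolated reference),
#'   `order` (empirical), `Z_ref` (Richardson-extrapolated), `monotone`
#'   (whether the error sequence decreases).
#' @export
brute_force_fine_grid <- function(case, nlev = 3, frequency = 5e4) {
  stopifnot(nlev >= 3)
  levels <- .oracle_levels(case$model, nlev)
  Z <- complex(nlev)
  nodes <- integer(nlev)
  recip <- numeric(nlev)
  for (l in seq_len(nlev)) {
    mesh <- generate_mesh(case$model, case$patches, levels[[l]])
    s <- assemble_and_solve(mesh, case$lib, frequency)
    s2 <- assemble_and_solve(mesh, case$lib, frequency, swap_roles = TRUE)
    Z[l] <- s$Z
    recip[l] <- Mod(s$Z - s2$Z) / Mod(s$Z)
    nodes[l] <- mesh$N
  }
  d <- Mod(diff(Z))
  order <- log2(d[-length(d)] / d[-1])
  p <- order[length(order)]
  Z_ref <- Z[nlev] + (Z[nlev] - Z[nlev - 1]) / (2^p - 1)
  err <- Mod(Z - Z_ref) / Mod(Z_ref)
  structure(list(
    levels = data.frame(level = seq_len(nlev), nodes = nodes,
                        Z_real = Re(Z), Z_imag = Im(Z),
                        rel_error = err, reciprocity = recip),
    order = order, Z_ref = Z_ref,
    monotone = all(diff(err) < 0)), class = "oracle_report")
}

# cache of oracle-suite results per resolution, per session
.oracle_cache <- new.env(parent = emptyenv())

#' Run the verification oracle suite
#'
#' Three gates: (1) homogeneous-cylinder resistance within 2% of the
#' closed form and exactly real when the medium has zero permittivity;
#' (2) reciprocity under drive/sense exchange below 1e-8 relative on a
#' layered anisotropic limb mesh; (3) electrode current conservation below
#' 1e-10 of the drive current.
#'
#' @param resolution Mesh resolution the gates are checked at.
#' @return List of class `oracle_suite` with per-check results and a
#'   `passed` flag.
#' @export
oracle_suite <- function(resolution = "coarse") {
  hc <- oracle_case_homogeneous()
  mesh <- generate_mesh(hc$model, hc$patches, resolution)
  s <- assemble_and_solve(mesh, hc$lib, 5e4)
  closed_form <- list(R = Re(s$Z), R_ref = hc$R_ref,
                      rel_error = abs(Re(s$Z) - hc$R_ref) / hc$R_ref,
                      X_abs = abs(Im(s$Z)),
                      pass = abs(Re(s$Z) - hc$R_ref) / hc$R_ref < 0.02 &&
                        Im(s$Z) == 0)

  model <- build_limb()
  cfg <- electrode_preset("conventional", model)
  lib <- make_tissue_library("normal")
  mesh2 <- generate_mesh(model, place_electrodes(model, cfg), "coarse")
  a1 <- assemble_and_solve(mesh2, lib, 5e4)
  a2 <- assemble_and_solve(mesh2, lib, 5e4, swap_roles = TRUE)
  recip <- list(rel_dev = Mod(a1$Z - a2$Z) / Mod(a1$Z),
                pass = Mod(a1$Z - a2$Z) / Mod(a1$Z) < 1e-8)
  conserv <- list(value = max(a1$conservation, s$conservation),
                  pass = max(a1$conservation, s$conservation) < 1e-10)

  out <- structure(list(resolution = resolution,
                        closed_form = closed_form, reciprocity = recip,
                        conservation = conserv,
                        passed = closed_form$pass && recip$pass &&
                          conserv$pass),
                   class = "oracle_suite")
  out
}

#' Require a passing oracle suite before an experiment runs
#'
#' Runs (and caches per session) the oracle suite at the given resolution;
#' stops with an informative error if any gate fails.
#'
#' @param resolution Mesh resolution to gate at.
#' @return The cached `oracle_suite`, invisibly.
#' @export
require_oracles <- function(resolution = "coarse") {
  key <- if (is.list(resolution)) "explicit" else resolution
  if (is.null(.oracle_cache[[key]])) {
    .oracle_cache[[key]] <- oracle_suite(if (is.list(resolution))
      "coarse" else resolution)
  }
  os <- .oracle_cache[[key]]
  if (!os$passed)
    stop("verification oracle suite failed at resolution '", key,
         "': closed-form rel error ", signif(os$closed_form$rel_error, 3),
         ", reciprocity ", signif(os$reciprocity$rel_dev, 3),
         ", conservation ", signif(os$conservation$value, 3))
  invisible(os)
}

#' @export
print.oracle_suite <- function(x, ...) {
  cat("<oracle_suite> resolution:", x$resolution,
      if (x$passed) "PASSED" else "FAILED", "\n")
  cat(sprintf("  closed form rel error: %.3g (gate 0.02), |X| = %g\n",
              x$closed_form$rel_error, x$closed_form$X_abs))
  cat(sprintf("  reciprocity: %.3g (gate 1e-8)\n", x$reciprocity$rel_dev))
  cat(sprintf("  conservation: %.3g (gate 1e-10)\n",
              x$conservation$value))
  invisible(x)
}
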