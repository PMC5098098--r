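# Tissue dielectric models: Cole-Cole dispersions and the tissue library.

EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Cole-Cole dispersion specification for one tissue material
#'
#' Parameterizes the complex relative permittivity of a tissue as
#' \deqn{\epsilon^*(\omega) = \epsilon_\infty +
#'   \sum_k \frac{\Delta\epsilon_k}{1 + (j\omega\tau_k)^{1-\alpha_k}} +
#'   \frac{\sigma_s}{j\omega\epsilon_0},}
#' the standard representation of measured tissue dielectric spectra.
#' The effective conductivity and relative permittivity at any frequency
#' follow from the real and imaginary parts (see [evaluate_dispersion()]).
#'
#' @param eps_inf High-frequency relative permittivity (dimensionless, >= 1).
#' @param sigma_static Ionic (static) conductivity in S/m (>= 0).
#' @param delta_eps Numeric vector of dispersion magnitudes (>= 0), one per
#'   relaxation term. May be empty for a dispersion-free material.
#' @param tau Relaxation times in seconds (> 0), same length as `delta_eps`.
#' @param alpha Cole-Cole broadening exponents in `[0, 1)`, same length as
#'   `delta_eps`. `alpha = 0` gives a pure Debye term.
#' @return An object of class `dispersion_spec`.
#' @export
#' @examples
#' muscle <- dispersion_spec(60, 0.30, delta_eps = 2.5e4, tau = 1.59e-6,
#'                           alpha = 0.25)
#' evaluate_dispersion(muscle, 5e4)
dispersion_spec <- function(eps_inf, sigma_static,
                            delta_eps = numeric(), tau = numeric(),
                            alpha = numeric()) {
  stopifnot(length(eps_inf) == 1L, length(sigma_static) == 1L,
            is.finite(eps_inf), is.finite(sigma_static))
  if (eps_inf < 1) stop("eps_inf must be >= 1")
  if (sigma_static < 0) stop("sigma_static must be >= 0")
  n <- length(delta_eps)
  if (length(tau) != n || length(alpha) != n)
    stop("delta_eps, tau and alpha must have equal length")
  if (n > 0) {
    if (any(delta_eps < 0)) stop("delta_eps must be >= 0")
    if (any(tau <= 0)) stop("tau must be > 0")
    if (any(alpha < 0 | alpha >= 1)) stop("alpha must lie in [0, 1)")
  }
  structure(list(eps_inf = as.numeric(eps_inf),
                 sigma_static = as.numeric(sigma_static),
                 delta_eps = as.numeric(delta_eps),
                 tau = as.numeric(tau),
                 alpha = as.numeric(alpha)),
            class = "dispersion_spec")
}

#' Frequency-independent material (solver-level convenience)
#'
#' A degenerate material with constant conductivity and relative
#' permittivity, used mainly by the verification oracles (e.g. a purely
#' resistive cylinder with `eps_r = 0`). Unlike [dispersion_spec()], it
#' allows `eps_r` down to 0.
#'
#' @param sigma Conductivity, S/m (> 0).
#' @param eps_r Relative permittivity (>= 0).
#' @return An object of class `constant_material`.
#' @export
constant_material <- function(sigma, eps_r = 0) {
  stopifnot(is.finite(sigma), is.finite(eps_r), sigma > 0, eps_r >= 0)
  structure(list(sigma = as.numeric(sigma), eps_r = as.numeric(eps_r)),
            class = "constant_material")
}

#' Evaluate a dispersion at given frequencies
#'
#' Computes the complex relative permittivity of the Cole-Cole model and
#' returns the equivalent conductivity/permittivity pair
#' `sigma = -omega * eps0 * Im(eps*)`, `eps_r = Re(eps*)` (the ionic term
#' contributes `sigma_static` to `sigma` and nothing to `eps_r`).
#'
#' @param spec A [dispersion_spec()] or [constant_material()].
#' @param frequency Frequencies in Hz (> 0); vectorized.
#' @return A list with numeric vectors `sigma` (S/m) and `eps_r`.
#' @export
evaluate_dispersion <- function(spec, frequency) {
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be positive and finite")
  if (inherits(spec, "constant_material")) {
    n <- length(frequency)
    return(list(sigma = rep(spec$sigma, n), eps_r = rep(spec$eps_r, n)))
  }
  stopifnot(inherits(spec, "dispersion_spec"))
  w <- 2 * pi * frequency
  eps <- complex(real = rep(spec$eps_inf, length(w)), imaginary = 0)
  for (k in seq_along(spec$delta_eps)) {
    jwt <- (1i * w * spec$tau[k])^(1 - spec$alpha[k])
    eps <- eps + spec$delta_eps[k] / (1 + jwt)
  }
  sigma <- spec$sigma_static - w * EPS0 * Im(eps)
  list(sigma = sigma, eps_r = Re(eps))
}

# -- tissue library -----------------------------------------------------------

# Default dispersion constants. Values are synthetic: they are chosen to sit
# in the physiological ranges reported for limb tissues in the 1-500 kHz band
# (muscle conductivity a few tenths of S/m and strongly dispersive; fat, bone
# and marrow one to two orders of magnitude less conductive), with muscle
# anisotropy applied as a multiplicative factor on the transverse entry.
.default_tissue_specs <- function() {
  list(
    marrow = dispersion_spec(12, 0.0035,
                             delta_eps = 2e3, tau = 7.96e-6, alpha = 0.10),
    cortical_bone = dispersion_spec(15, 0.020,
                                    delta_eps = 1e3, tau = 7.96e-6,
                                    alpha = 0.20),
    skin_fat = dispersion_spec(25, 0.035,
                               delta_eps = 5e3, tau = 7.96e-6, alpha = 0.20),
    muscle_transverse = dispersion_spec(60, 0.30,
                                        delta_eps = 2.5e4, tau = 1.59e-6,
                                        alpha = 0.25)
  )
}

.scale_spec <- function(spec, sigma_factor = 1, eps_factor = 1) {
  dispersion_spec(max(1, spec$eps_inf * eps_factor),
                  spec$sigma_static * sigma_factor,
                  delta_eps = spec$delta_eps * eps_factor,
                  tau = spec$tau, alpha = spec$alpha)
}

#' Build the tissue dielectric library
#'
#' Assembles the full set of dispersions used by the forward solver: bone
#' marrow, cortical bone, merged skin/subcutaneous fat (all isotropic) and
#' muscle (anisotropic: longitudinal along the limb axis, transverse across
#' it). The longitudinal muscle entry is the transverse one with both
#' `sigma_static` and `delta_eps` scaled by `anisotropy_ratio`, so the
#' effective conductivity ratio equals `anisotropy_ratio` at every frequency.
#' The atrophied condition differs from normal only in the muscle entries,
#' whose conductivity and permittivity are reduced by fixed multipliers.
#'
#' @param condition `"normal"` or `"atrophied"`.
#' @param anisotropy_ratio Longitudinal/transverse muscle conductivity ratio
#'   (>= 1). Default 3, a mid-range value for skeletal muscle.
#' @param atrophy_sigma_factor Multiplier on muscle conductivity in the
#'   atrophied condition (default 0.5).
#' @param atrophy_eps_factor Multiplier on muscle permittivity in the
#'   atrophied condition (default 0.6).
#' @param seed Optional integer; when given, applies a small reproducible
#'   lognormal jitter (5% coefficient of variation) to the library via
#'   [perturb_library()]. `NULL` (default) returns the deterministic
#'   reference library.
#' @return An object of class `tissue_library`: a list with `condition`,
#'   `version` and `specs` (named list; `muscle` holds `longitudinal` and
#'   `transverse` [dispersion_spec()]s, other entries are single specs).
#' @export
make_tissue_library <- function(condition = c("normal", "atrophied"),
                                anisotropy_ratio = 3,
                                atrophy_sigma_factor = 0.5,
                                atrophy_eps_factor = 0.6,
                                seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(is.finite(anisotropy_ratio))
  if (anisotropy_ratio < 1) stop("anisotropy_ratio must be >= 1")
  base <- .default_tissue_specs()
  trans <- base$muscle_transverse
  if (condition == "atrophied") {
    trans <- .scale_spec(trans, atrophy_sigma_factor, atrophy_eps_factor)
  }
  long <- .scale_spec(trans, anisotropy_ratio, anisotropy_ratio)
  lib <- structure(list(
    condition = condition,
    version = "1",
    specs = list(
      marrow = base$marrow,
      cortical_bone = base$cortical_bone,
      muscle = list(longitudinal = long, transverse = trans),
      skin_fat = base$skin_fat
    )
  ), class = "tissue_library")
  if (!is.null(seed)) lib <- perturb_library(lib, cv = 0.05, seed = seed)
  lib
}

#' Uniform single-material library (oracle cases)
#'
#' @param sigma Conductivity in S/m.
#' @param eps_r Relative permittivity (>= 0; default 0 gives a purely
#'   resistive medium).
#' @return A `tissue_library` with one isotropic entry named `"uniform"`.
#' @export
uniform_library <- function(sigma, eps_r = 0) {
  structure(list(condition = "uniform", version = "1",
                 specs = list(uniform = constant_material(sigma, eps_r))),
            class = "tissue_library")
}

.map_specs <- function(lib, f) {
  specs <- lapply(lib$specs, function(entry) {
    if (inherits(entry, "dispersion_spec") ||
        inherits(entry, "constant_material")) f(entry)
    else lapply(entry, f)
  })
  lib$specs <- specs
  lib
}

#' Randomly perturb a tissue library
#'
#' Multiplies every `sigma_static` and every `delta_eps` entry by
#' independent lognormal factors with unit mean and coefficient of variation
#' `cv`. Used to probe the robustness of qualitative conclusions to the
#' uncertain literature dielectric constants.
#'
#' @param lib A `tissue_library`.
#' @param cv Coefficient of variation, in `[0, 0.5)`.
#' @param seed Integer seed; the perturbation is reproducible.
#' @return A perturbed `tissue_library`.
#' @export
perturb_library <- function(lib, cv, seed) {
  stopifnot(inherits(lib, "tissue_library"), is.finite(cv))
  if (cv < 0 || cv >= 0.5) stop("cv must lie in [0, 0.5)")
  if (cv == 0) return(lib)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2  # unit-mean lognormal
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  .map_specs(lib, function(sp) {
    if (inherits(sp, "constant_material")) return(sp)
    sp$sigma_static <- sp$sigma_static * stats::rlnorm(1, meanlog, sdlog)
    if (length(sp$delta_eps))
      sp$delta_eps <- sp$delta_eps *
        stats::rlnorm(length(sp$delta_eps), meanlog, sdlog)
    dispersion_spec(sp$eps_inf, sp$sigma_static, sp$delta_eps, sp$tau,
                    sp$alpha)
  })
}

#' Tissue properties of one layer at given frequencies
#'
#' @param lib A `tissue_library`.
#' @param layer Material name (e.g. `"muscle"`, `"skin_fat"`).
#' @param frequency Frequencies in Hz.
#' @return For isotropic layers, `list(sigma, eps_r)`; for muscle,
#'   `list(sigma = list(longitudinal, transverse), eps_r = list(...))`.
#' @export
tissue_properties <- function(lib, layer, frequency) {
  entry <- lib$specs[[layer]]
  if (is.null(entry)) stop("unknown layer: ", layer)
  if (inherits(entry, "dispersion_spec") ||
      inherits(entry, "constant_material"))
    return(evaluate_dispersion(entry, frequency))
  lon <- evaluate_dispersion(entry$longitudinal, frequency)
  tra <- evaluate_dispersion(entry$transverse, frequency)
  list(sigma = list(longitudinal = lon$sigma, transverse = tra$sigma),
       eps_r = list(longitudinal = lon$eps_r, transverse = tra$eps_r))
}

# Per-material complex admittivity gamma = sigma + j*w*eps0*eps_r at one
# frequency, split into the perpendicular (r, theta) and parallel (z)
# directions. Muscle is the only anisotropic entry: longitudinal along z.
.gamma_table <- function(lib, frequency) {
  stopifnot(length(frequency) == 1L)
  w <- 2 * pi * frequency
  nm <- names(lib$specs)
  perp <- par <- complex(length(nm))
  for (i in seq_along(nm)) {
    entry <- lib$specs[[nm[i]]]
    if (inherits(entry, "dispersion_spec") ||
        inherits(entry, "constant_material")) {
      p <- evaluate_dispersion(entry, frequency)
      g <- complex(real = p$sigma, imaginary = w * EPS0 * p$eps_r)
      perp[i] <- g; par[i] <- g
    } else {
      pl <- evaluate_dispersion(entry$longitudinal, frequency)
      pt <- evaluate_dispersion(entry$transverse, frequency)
      par[i]  <- complex(real = pl$sigma, imaginary = w * EPS0 * pl$eps_r)
      perp[i] <- complex(real = pt$sigma, imaginary = w * EPS0 * pt$eps_r)
    }
  }
  names(perp) <- names(par) <- nm
  list(perp = perp, par = par)
}

#' @export
print.tissue_library <- function(x, ...) {
  cat("<tissue_library> condition:", x$condition,
      " version:", x$version, "\n")
  p <- tissue_properties(x, names(x$specs)[1], 5e4)
  cat("materials:", paste(names(x$specs), collapse = ", "), "\n")
  invisible(x)
}

# -- serialization ------------------------------------------------------------

#' Serialize a tissue library to JSON
#'
#' Plain-text schema (SI units): top-level `condition`, `version`, `specs`;
#' each spec lists `eps_inf`, `sigma_static` (S/m), `delta_eps`, `tau` (s),
#' `alpha`; the muscle entry nests `longitudinal`/`transverse`.
#'
#' @param lib A `tissue_library`.
#' @param path Optional file path; when `NULL`, returns the JSON string.
#' @return The JSON string, invisibly when written to file.
#' @export
library_to_json <- function(lib, path = NULL) {
  ser <- function(sp) {
    if (inherits(sp, "constant_material"))
      list(type = "constant", sigma = sp$sigma, eps_r = sp$eps_r)
    else list(type = "cole_cole", eps_inf = sp$eps_inf,
              sigma_static = sp$sigma_static, delta_eps = sp$delta_eps,
              tau = sp$tau, alpha = sp$alpha)
  }
  obj <- list(condition = lib$condition, version = lib$version,
              specs = lapply(lib$specs, function(e) {
                if (inherits(e, "dispersion_spec") ||
                    inherits(e, "constant_material")) ser(e)
                else lapply(e, ser)
              }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a tissue library from JSON
#'
#' @param path File path or a JSON string produced by [library_to_json()].
#' @return A `tissue_library`.
#' @export
library_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  de <- function(s) {
    if (identical(s$type, "constant")) constant_material(s$sigma, s$eps_r)
    else dispersion_spec(s$eps_inf, s$sigma_static,
                         delta_eps = as.numeric(unlist(s$delta_eps)),
                         tau = as.numeric(unlist(s$tau)),
                         alpha = as.numeric(unlist(s$alpha)))
  }
  specs <- lapply(obj$specs, function(e) {
    if (!is.null(e$type)) de(e) else lapply(e, de)
  })
  structure(list(condition = obj$condition, version = obj$version,
                 specs = specs), class = "tissue_library")
}
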