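# Structured cylindrical tensor-grid mesh with precomputed finite-volume
# edge geometry. Layer boundaries and electrode patch edges are grid
# surfaces by construction, so material coefficients are single-valued on
# every control-volume face that crosses a radial edge, and patch node sets
# are exact.

.MIN_FEATURE <- 2e-4  # m; smallest resolvable electrode extent

.resolution_targets <- function(resolution) {
  if (is.list(resolution)) {
    stopifnot(all(c("dr", "dtheta", "dz") %in% names(resolution)))
    return(resolution)
  }
  switch(match.arg(resolution, c("coarse", "medium", "fine")),
    coarse = list(dr = 3.0e-3, dtheta = 30, dz = 10.0e-3),
    medium = list(dr = 1.8e-3, dtheta = 15, dz = 5.0e-3),
    fine   = list(dr = 1.0e-3, dtheta = 9,  dz = 2.8e-3))
}

# subdivide [a, b] into n equal cells, returning interior+right nodes
.fill <- function(a, b, n) a + (b - a) * seq_len(n) / n

# graded subdivision: cells cluster toward ends flagged TRUE (used next to
# electrode patch edges, where the current density is singular)
.graded_fill <- function(a, b, n, gl = FALSE, gr = FALSE, p = 3) {
  t <- seq_len(n) / n
  x <- if (gl && gr) t^p / (t^p + (1 - t)^p)
       else if (gl) t^p
       else if (gr) 1 - (1 - t)^p
       else t
  a + (b - a) * x
}

#' Generate a conforming mesh for a limb model with placed electrodes
#'
#' Builds a tensor grid in cylindrical coordinates (r, theta, z). All layer
#' radii and all electrode patch boundaries coincide with grid surfaces;
#' every patch is covered by at least two cells in each surface direction.
#' The r = 0 axis is represented by a single shared node per z plane with
#' area-weighted closure fluxes, so no singular node equation arises.
#'
#' @param model A `limb_model`.
#' @param patches Patch list from [place_electrodes()].
#' @param resolution `"coarse"`, `"medium"`, `"fine"`, or a list with
#'   explicit targets `dr` (m), `dtheta` (degrees), `dz` (m).
#' @return An object of class `eim_mesh` carrying node coordinates, the
#'   per-interval material map, the finite-volume edge table and the node
#'   classification (free / drive_A / drive_B / sense_1 / sense_2).
#' @export
generate_mesh <- function(model, patches, resolution = "coarse") {
  stopifnot(inherits(model, "limb_model"))
  tg <- .resolution_targets(resolution)
  a_out <- model$layer_radii[[length(model$layer_radii)]]
  tol <- 1e-9

  # refuse unresolvable electrodes
  for (p in patches) {
    if ((p$z1 - p$z0) < .MIN_FEATURE)
      stop("electrode patch '", p$role, "' axial width ",
           (p$z1 - p$z0) * 1e3, " mm is below the minimum resolvable ",
           "feature (", .MIN_FEATURE * 1e3, " mm); enlarge the electrode")
    arc <- 2 * p$theta_halfwidth * pi / 180 * a_out
    if (arc < .MIN_FEATURE)
      stop("electrode patch '", p$role, "' angular arc ", arc * 1e3,
           " mm is below the minimum resolvable feature; enlarge it")
  }

  # radial grid: >=2 cells per layer, conforming to layer boundaries
  bounds <- c(0, unname(model$layer_radii))
  rn <- numeric(0)
  mat_of_interval <- character(0)
  nlay <- length(model$layer_radii)
  for (li in seq_len(nlay)) {
    thick <- bounds[li + 1] - bounds[li]
    n <- max(2L, ceiling(thick / tg$dr))
    # outermost layer: cluster cells toward the electrode-bearing surface
    rn <- c(rn, .graded_fill(bounds[li], bounds[li + 1], n,
                             gl = FALSE, gr = (li == nlay)))
    mat_of_interval <- c(mat_of_interval,
                         rep(unname(model$layer_materials[li]), n))
  }
  nr <- length(rn)

  # angular grid (radians): breakpoints at the symmetry plane, the
  # anti-plane and every patch edge; each patch spans >=2 cells because the
  # symmetry plane theta = 0 bisects it
  hws <- unique(vapply(patches, `[[`, 0, "theta_halfwidth"))
  bp <- c(0, pi)
  for (h in hws) {
    if (h < 180 - 1e-9) {
      hr <- h * pi / 180
      bp <- c(bp, hr, 2 * pi - hr)
    }
  }
  patch_bp <- sort(unique(round(
    unlist(lapply(hws[hws < 180 - 1e-9],
                  function(h) c(h, 360 - h) * pi / 180)) / tol) * tol))
  bp <- sort(unique(round(bp / tol) * tol))
  bp <- bp[bp < 2 * pi - tol]
  is_edge <- function(x) length(patch_bp) > 0 &&
    any(abs(patch_bp - x) < 10 * tol)
  th <- numeric(0)
  dth_t <- tg$dtheta * pi / 180
  spans <- c(diff(bp), 2 * pi - bp[length(bp)] + bp[1])
  for (s in seq_along(bp)) {
    n <- max(1L, ceiling(spans[s] / dth_t))
    right <- if (s < length(bp)) bp[s + 1] else bp[1] + 2 * pi
    fill <- .graded_fill(bp[s], right, n, is_edge(bp[s]),
                         is_edge(right %% (2 * pi)))
    th <- c(th, bp[s], fill[-n])
  }
  th <- sort(th)
  nt <- length(th)
  if (nt < 4) {  # degenerate all-ring case at very coarse targets
    th <- 2 * pi * (0:3) / 4
    nt <- 4L
  }

  # axial grid: conforms to patch edges; >=2 cells inside each patch
  zedges <- sort(unique(round(c(0, model$length, model$length / 2,
                                unlist(lapply(patches, function(p)
                                  c(p$z0, p$z1)))) / tol) * tol))
  in_patch <- function(z0, z1) {
    any(vapply(patches, function(p)
      z0 >= p$z0 - tol && z1 <= p$z1 + tol, TRUE))
  }
  pedges <- sort(unique(round(unlist(lapply(patches, function(p)
    c(p$z0, p$z1))) / tol) * tol))
  zedge_flag <- function(x) any(abs(pedges - x) < 10 * tol)
  z <- 0
  for (s in seq_len(length(zedges) - 1)) {
    z0 <- zedges[s]; z1 <- zedges[s + 1]
    n <- if (in_patch(z0, z1)) max(2L, ceiling((z1 - z0) / tg$dz))
         else max(1L, ceiling((z1 - z0) / tg$dz))
    z <- c(z, .graded_fill(z0, z1, n, zedge_flag(z0), zedge_flag(z1)))
  }
  nz <- length(z)

  mesh <- .finish_mesh(model, patches, rn, mat_of_interval, th, z,
                       if (is.list(resolution)) "explicit" else resolution)
  mesh
}

# Assemble node bookkeeping + finite-volume edge table from grid vectors.
.finish_mesh <- function(model, patches, rn, mat_of_interval, th, z,
                         resolution_label) {
  nr <- length(rn); nt <- length(th); nz <- length(z)
  n_ring <- nr * nt * nz
  N <- n_ring + nz
  mat_names <- unique(mat_of_interval)
  nmat <- length(mat_names)
  mat <- match(mat_of_interval, mat_names)   # interval -> material index
  perp <- function(m) mat[m]                 # gamma slot helpers
  par_ <- function(m) mat[m] + nmat

  rn0 <- c(0, rn[-nr])
  rh <- (rn0 + rn) / 2                       # inner CV face radius of node i
  rh_out <- c(rh[-1], rn[nr])                # outer CV limit of node i

  dth <- c(diff(th), 2 * pi - th[nt] + th[1])
  wth <- (c(dth[nt], dth[-nt]) + dth) / 2    # periodic node widths
  dzg <- diff(z)
  wz <- c(dzg[1] / 2, (dzg[-1] + dzg[-(nz - 1)]) / 2, dzg[nz - 1] / 2)

  id <- function(i, j, k) i + nr * ((j - 1) + nt * (k - 1))

  ea <- eb <- integer(0); es1 <- es2 <- integer(0)
  eg1 <- eg2 <- numeric(0)
  add <- function(a, b, s1, g1, s2, g2) {
    n <- length(a)
    ea <<- c(ea, a); eb <<- c(eb, b)
    es1 <<- c(es1, rep_len(s1, n)); eg1 <<- c(eg1, rep_len(g1, n))
    es2 <<- c(es2, rep_len(s2, n)); eg2 <<- c(eg2, rep_len(g2, n))
  }

  JK_J <- rep(1:nt, times = nz)
  JK_K <- rep(1:nz, each = nt)
  wthJ <- wth[JK_J]; wzK <- wz[JK_K]

  # radial edges ring i -> i+1 (face in interval i+1)
  if (nr > 1) {
    I <- rep(1:(nr - 1), times = nt * nz)
    J <- rep(JK_J, each = nr - 1)
    K <- rep(JK_K, each = nr - 1)
    g <- rh[I + 1] * wth[J] * wz[K] / (rn[I + 1] - rn[I])
    add(id(I, J, K), id(I + 1, J, K), perp(I + 1), g, perp(I + 1), 0)
  }

  # axis -> ring 1 edges (face at rh[1], interval 1)
  add(n_ring + JK_K, id(1L, JK_J, JK_K), rep(perp(1), nt * nz),
      rh[1] * wthJ * wzK / rn[1], rep(perp(1), nt * nz), 0)

  # theta edges (i, j) -> (i, j+1); strip split at rn[i] into intervals
  # i (inner log weight) and i+1 (outer log weight)
  lg_in <- log(rn / rh)
  lg_out <- c(log(rh[-1] / rn[-nr]), 0)
  I <- rep(1:nr, times = nt * nz)
  J <- rep(JK_J, each = nr)
  K <- rep(JK_K, each = nr)
  Jn <- J %% nt + 1L
  base <- wz[K] / dth[J]
  add(id(I, J, K), id(I, Jn, K),
      perp(I), lg_in[I] * base,
      perp(pmin(I + 1, nr)), lg_out[I] * base)

  # z edges (i, j, k) -> (i, j, k+1); annular strip split at rn[i]
  q_in <- (rn^2 - rh^2) / 2
  q_out <- c((rh[-1]^2 - rn[-nr]^2) / 2, 0)
  if (nz > 1) {
    JKz_J <- rep(1:nt, times = nz - 1)
    JKz_K <- rep(1:(nz - 1), each = nt)
    I <- rep(1:nr, times = nt * (nz - 1))
    J <- rep(JKz_J, each = nr)
    K <- rep(JKz_K, each = nr)
    base <- wth[J] / dzg[K]
    add(id(I, J, K), id(I, J, K + 1),
        par_(I), q_in[I] * base,
        par_(pmin(I + 1, nr)), q_out[I] * base)
    # axis z edges: disc of radius rh[1]
    Kz <- 1:(nz - 1)
    add(n_ring + Kz, n_ring + Kz + 1L,
        rep(par_(1), nz - 1), pi * rh[1]^2 / dzg[Kz],
        rep(par_(1), nz - 1), 0)
  }

  # node classification from patches (surface ring i = nr)
  cls <- integer(N)
  roles <- c(drive_A = 1L, drive_B = 2L, sense_1 = 3L, sense_2 = 4L)
  th_dist <- pmin(th, 2 * pi - th)  # angular distance to symmetry plane
  tolm <- 1e-8
  for (p in patches) {
    jset <- if (p$theta_halfwidth >= 180 - 1e-9) 1:nt
            else which(th_dist <= p$theta_halfwidth * pi / 180 + 1e-7)
    kset <- which(z >= p$z0 - tolm & z <= p$z1 + tolm)
    if (length(jset) < 3 && p$theta_halfwidth < 180 - 1e-9)
      stop("patch '", p$role, "' covers fewer than 2 angular cells")
    if (length(kset) < 3)
      stop("patch '", p$role, "' covers fewer than 2 axial cells")
    idx <- id(nr, rep(jset, times = length(kset)),
              rep(kset, each = length(jset)))
    cls[idx] <- roles[[p$role]]
  }

  structure(list(rn = rn, theta = th, z = z, nr = nr, nt = nt, nz = nz,
                 N = N, n_ring = n_ring,
                 mat_names = mat_names, mat_of_interval = mat_of_interval,
                 edges = list(a = ea, b = eb, s1 = es1, g1 = eg1,
                              s2 = es2, g2 = eg2),
                 cls = cls, model = model, patches = patches,
                 resolution = resolution_label),
            class = "eim_mesh")
}

#' @export
print.eim_mesh <- function(x, ...) {
  cat("<eim_mesh>", x$nr, "x", x$nt, "x", x$nz, "(r x theta x z),",
      x$N, "nodes,", length(x$edges$a), "edges, resolution:",
      x$resolution, "\n")
  invisible(x)
}
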