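# Quasi-static complex-admittivity forward solver.
#
# Discrete problem: node-centred finite volumes on the cylindrical tensor
# grid give a complex-symmetric system K = A + iB (A the conduction part,
# B the displacement part). Drive electrodes are Dirichlet potential
# surfaces (1 V / 0 V); sense electrodes are floating equipotentials
# obtained by collapsing their surface nodes onto one master unknown, which
# enforces zero net current through them; all other outer boundaries are
# insulating (natural condition of the finite-volume scheme).
#
# The complex solve uses a sparse Cholesky factorization of A as a
# preconditioner for a COCG (conjugate orthogonal CG) iteration on K, which
# converges in a handful of iterations because the preconditioned spectrum
# {1 + i * loss-tangent} is well clustered. A block-real sparse LU is the
# fallback if the iteration ever fails to converge.

#' Assemble and solve the forward problem at one frequency
#'
#' @param mesh An `eim_mesh` from [generate_mesh()].
#' @param lib A `tissue_library` providing every material named in the
#'   mesh.
#' @param frequency Frequency in Hz (scalar, > 0).
#' @param drive_voltage Drive amplitude in volts (default 1); the transfer
#'   impedance is independent of it (linearity).
#' @param drive_current Optional prescribed drive current in amperes
#'   (complex allowed). The potential-driven solution is rescaled by
#'   linearity so the drive electrode carries exactly this current; `Z`
#'   is unchanged.
#' @param swap_roles If `TRUE`, drive the sense pair and sense the drive
#'   pair (reciprocity check).
#' @param solver `"auto"` (COCG with Cholesky preconditioner, direct
#'   Cholesky when the system is purely real), `"cocg"`, or `"lu"` (block
#'   real sparse LU).
#' @param tol Relative residual tolerance for the iterative solve.
#' @return A list of class `solve_result`: `Z` (complex transfer impedance,
#'   ohm), `I` (complex drive current, A), `I_electrodes` (named per-patch
#'   currents), `conservation` (|sum of electrode currents| / |I|),
#'   `frequency`, `V` (complex node potentials), `iterations`, `residual`.
#' @export
assemble_and_solve <- function(mesh, lib, frequency, drive_voltage = 1,
                               drive_current = NULL, swap_roles = FALSE,
                               solver = c("auto", "cocg", "lu"),
                               tol = 1e-12) {
  solver <- match.arg(solver)
  stopifnot(inherits(mesh, "eim_mesh"), inherits(lib, "tissue_library"),
            length(frequency) == 1L, frequency > 0)
  gt <- .gamma_table(lib, frequency)
  missing <- setdiff(mesh$mat_names, names(gt$perp))
  if (length(missing))
    stop("tissue library lacks material(s): ",
         paste(missing, collapse = ", "))
  gam <- c(gt$perp[mesh$mat_names], gt$par[mesh$mat_names])
  ed <- mesh$edges
  G <- gam[ed$s1] * ed$g1 + gam[ed$s2] * ed$g2
  if (any(!is.finite(G)) || any(Re(G) <= 0))
    stop("non-positive or non-finite edge conductance; ",
         "check tissue library values")

  # electrical roles: 1 = +drive (Dirichlet Vd), 2 = -drive (Dirichlet 0),
  # 3 = +sense (floating), 4 = -sense (floating)
  cls <- mesh$cls
  role <- cls
  if (swap_roles) {
    role <- integer(length(cls))
    role[cls == 3L] <- 1L; role[cls == 4L] <- 2L
    role[cls == 1L] <- 3L; role[cls == 2L] <- 4L
  }
  for (r in 1:4) if (!any(role == r)) stop("electrode role ", r,
                                           " has no mesh nodes")
  free <- role == 0L
  nf <- sum(free)
  map <- integer(mesh$N)
  map[free] <- seq_len(nf)
  map[role == 3L] <- nf + 1L
  map[role == 4L] <- nf + 2L
  nu <- nf + 2L
  vd <- numeric(mesh$N)
  vd[role == 1L] <- drive_voltage

  ma <- map[ed$a]; mb <- map[ed$b]
  ra <- role[ed$a]; rb <- role[ed$b]
  both <- ma > 0L & mb > 0L & ma != mb
  adir <- ma == 0L & mb > 0L   # a Dirichlet, b unknown
  bdir <- mb == 0L & ma > 0L

  ti <- c(ma[both], mb[both], ma[both], mb[both], mb[adir], ma[bdir])
  tj <- c(mb[both], ma[both], ma[both], mb[both], mb[adir], ma[bdir])
  tx <- c(-G[both], -G[both], G[both], G[both], G[adir], G[bdir])
  rhs <- complex(nu)
  add_rhs <- function(idx, val) {
    if (!length(idx)) return(invisible())
    re <- rowsum(Re(val), idx)
    im <- rowsum(Im(val), idx)
    ii <- as.integer(rownames(re))
    rhs[ii] <<- rhs[ii] + complex(real = re[, 1], imaginary = im[, 1])
    invisible()
  }
  add_rhs(mb[adir], G[adir] * vd[ed$a[adir]])
  add_rhs(ma[bdir], G[bdir] * vd[ed$b[bdir]])

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = Re(tx), dims = c(nu, nu))
  has_imag <- any(Im(tx) != 0) || any(Im(rhs) != 0)
  B <- if (has_imag)
    Matrix::sparseMatrix(i = ti, j = tj, x = Im(tx), dims = c(nu, nu))
  else NULL

  sol <- .solve_complex(A, B, rhs, solver, tol)

  V <- complex(mesh$N)
  V[map > 0L] <- sol$x[map[map > 0L]]
  V[role == 1L] <- drive_voltage
  V[role == 2L] <- 0

  # per-electrode currents: sum of edge fluxes leaving each patch
  dV <- V[ed$a] - V[ed$b]
  Ie <- complex(4)
  for (r in 1:4) {
    out_a <- ra == r & rb != r
    out_b <- rb == r & ra != r
    Ie[r] <- sum(G[out_a] * dV[out_a]) - sum(G[out_b] * dV[out_b])
  }
  names(Ie) <- c("drive_pos", "drive_neg", "sense_pos", "sense_neg")
  I <- Ie[["drive_pos"]]
  if (Mod(I) == 0) stop("zero drive current; singular configuration")
  Vs <- sol$x[nf + 1L] - sol$x[nf + 2L]
  if (!is.null(drive_current)) {
    # current-driven mode: rescale the linear solution
    sc <- drive_current / I
    V <- V * sc; Ie <- Ie * sc; Vs <- Vs * sc; I <- I * sc
  }
  structure(list(Z = Vs / I, I = I, I_electrodes = Ie,
                 conservation = Mod(sum(Ie)) / Mod(I),
                 frequency = frequency, V = V,
                 iterations = sol$iterations, residual = sol$residual,
                 solver = sol$solver),
            class = "solve_result")
}

# Solve (A + iB) x = b.
.solve_complex <- function(A, B, b, solver, tol) {
  As <- Matrix::forceSymmetric(A)
  if (is.null(B) && solver != "lu") {
    ch <- Matrix::Cholesky(As, LDL = FALSE)
    x <- as.numeric(Matrix::solve(ch, Re(b)))
    return(list(x = complex(real = x, imaginary = 0), iterations = 0L,
                residual = 0, solver = "cholesky"))
  }
  if (is.null(B)) B <- A * 0
  if (solver == "lu") return(.solve_block_lu(A, B, b))
  ch <- Matrix::Cholesky(As, LDL = FALSE)
  res <- .cocg(A, B, ch, b, tol = tol)
  if (!res$converged) {
    warning("COCG did not converge (residual ", signif(res$residual, 3),
            "); falling back to block-real sparse LU")
    return(.solve_block_lu(A, B, b))
  }
  res
}

.cocg <- function(A, B, ch, b, tol = 1e-12, maxit = 500L) {
  n <- length(b)
  Kmul <- function(v) {
    vr <- Re(v); vi <- Im(v)
    complex(real = as.numeric(A %*% vr) - as.numeric(B %*% vi),
            imaginary = as.numeric(A %*% vi) + as.numeric(B %*% vr))
  }
  Minv <- function(v) {
    complex(real = as.numeric(Matrix::solve(ch, Re(v))),
            imaginary = as.numeric(Matrix::solve(ch, Im(v))))
  }
  x <- complex(n)
  r <- b
  bn <- sqrt(sum(Mod(b)^2))
  if (bn == 0) return(list(x = x, iterations = 0L, residual = 0,
                           converged = TRUE, solver = "cocg"))
  z <- Minv(r)
  p <- z
  rz <- sum(r * z)
  res <- 1
  for (it in seq_len(maxit)) {
    Kp <- Kmul(p)
    pkp <- sum(p * Kp)
    if (Mod(pkp) == 0) break
    alpha <- rz / pkp
    x <- x + alpha * p
    r <- r - alpha * Kp
    res <- sqrt(sum(Mod(r)^2)) / bn
    if (res < tol)
      return(list(x = x, iterations = it, residual = res,
                  converged = TRUE, solver = "cocg"))
    z <- Minv(r)
    rz_new <- sum(r * z)
    if (Mod(rz) == 0) break
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x, iterations = maxit, residual = res, converged = FALSE,
       solver = "cocg")
}

.solve_block_lu <- function(A, B, b) {
  n <- nrow(A)
  M <- rbind(cbind(A, -B), cbind(B, A))
  xy <- as.numeric(Matrix::solve(M, c(Re(b), Im(b))))
  list(x = complex(real = xy[1:n], imaginary = xy[n + (1:n)]),
       iterations = 0L, residual = 0, converged = TRUE,
       solver = "block_lu")
}

#' Derived tetrapolar quantities from a complex transfer impedance
#'
#' Uses the positive-reactance reporting convention standard in impedance
#' myography: `R = Re(Z)`, `X = -Im(Z)` (a capacitive tissue then has
#' X > 0), phase `theta = atan2(X, R)` in degrees, and the admittance
#' decomposition `G = R/(R^2+X^2)`, `C = X/((R^2+X^2) omega)`.
#'
#' @param Z Complex impedance in ohm (nonzero).
#' @param frequency Frequency in Hz.
#' @param K Optional geometric (cell) factor in 1/m; when supplied, the
#'   apparent conductivity `sigma = K * G` and relative permittivity
#'   `eps_r = K * C / eps0` are included.
#' @return A one-row `data.frame` with columns `frequency_Hz`, `R_ohm`,
#'   `X_ohm`, `phase_deg`, `G_S`, `C_F` (plus `sigma_S_per_m`,
#'   `eps_r` when `K` is given).
#' @export
derived_quantities <- function(Z, frequency, K = NULL) {
  if (Mod(Z) == 0) stop("Z must be nonzero")
  stopifnot(frequency > 0)
  R <- Re(Z)
  X <- -Im(Z)
  m2 <- R^2 + X^2
  w <- 2 * pi * frequency
  out <- data.frame(frequency_Hz = frequency, R_ohm = R, X_ohm = X,
                    phase_deg = atan2(X, R) * 180 / pi,
                    G_S = R / m2, C_F = X / (m2 * w))
  if (!is.null(K)) {
    out$sigma_S_per_m <- K * out$G_S
    out$eps_r <- K * out$C_F / EPS0
  }
  out
}

#' Impedance spectrum of a limb model under one electrode configuration
#'
#' Builds the mesh once and solves per frequency.
#'
#' @param model A `limb_model`.
#' @param config An `electrode_config`.
#' @param lib A `tissue_library`.
#' @param frequencies Ascending positive frequencies, Hz.
#' @param resolution Mesh resolution (see [generate_mesh()]).
#' @param ... Passed to [assemble_and_solve()].
#' @return An object of class `impedance_spectrum`: a `data.frame` with
#'   one row per frequency (columns of [derived_quantities()] plus
#'   `Z_real`, `Z_imag`), with the mesh and configuration attached as
#'   attributes.
#' @export
spectrum <- function(model, config, lib, frequencies,
                     resolution = "coarse", ...) {
  stopifnot(length(frequencies) >= 1, all(frequencies > 0),
            !is.unsorted(frequencies))
  patches <- place_electrodes(model, config)
  mesh <- generate_mesh(model, patches, resolution)
  rows <- lapply(frequencies, function(f) {
    s <- assemble_and_solve(mesh, lib, f, ...)
    cbind(derived_quantities(s$Z, f),
          data.frame(Z_real = Re(s$Z), Z_imag = Im(s$Z)))
  })
  out <- do.call(rbind, rows)
  attr(out, "mesh") <- mesh
  attr(out, "config") <- config
  attr(out, "library_version") <- lib$version
  class(out) <- c("impedance_spectrum", "data.frame")
  out
}
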