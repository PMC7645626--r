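# Finite-volume assembly of the steady axisymmetric convection-diffusion
# problem.  Unknowns are cell-centred concentrations; equations are per-cell
# flux balances (sum of outward fluxes = 0), so the scheme is locally and
# globally conservative by construction.  All fluxes are per radian of
# azimuth: a radial face at radius r_f spanning dz has area r_f*dz, and an
# axial face over the annulus [ra, rb] has area (rb^2 - ra^2)/2.

# Global index of cell (ir, iz) in zone k.
cell_index <- function(offsets, nr, k, ir, iz) {
  offsets[k] + (iz - 1L) * nr[k] + ir
}

#' Assemble the sparse linear system for a transport problem on a mesh
#'
#' Diffusion uses two-point fluxes with cell-centre distances (harmonic
#' averaging arises naturally at the graded interface faces); convection is
#' first-order upwind, with an optional second-order central operator used
#' by the deferred-correction solver mode.  The partition jump at an
#' interface is enforced by eliminating the interface unknowns: with
#' one-sided transmissibilities `a = D_L/d_L`, `b = D_R/d_R` and jump factor
#' `lambda` (outer-side concentration = `lambda` x inner-side), the coupling
#' flux from the inner to the outer cell is
#' `A_f * a*b/(a + lambda*b) * (lambda*C_L - C_R)`,
#' which reproduces both flux continuity and the concentration jump.
#'
#' @param problem A `transport_problem`.
#' @param mesh A `contactor_mesh` built for the same problem.
#' @param scheme `"upwind"` (default) or `"central"` (also builds the central
#'   convection operator used by [solve_steady()]).
#' @return A list of class `fv_system` with the sparse matrix `A`, right
#'   side `b`, the interior upwind convection operator `conv` (and `conv_central`
#'   for the central scheme), zone index `offsets`, and per-zone exact
#'   cell-average velocities `vbar`.
#' @export
assemble_system <- function(problem, mesh, scheme = c("upwind", "central")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(problem, "transport_problem"),
            inherits(mesh, "contactor_mesh"))
  nzone <- length(problem$zones)
  if (length(mesh$zones) != nzone) stop("mesh and problem zone counts differ")
  nr <- vapply(mesh$zones, `[[`, 0L, "nr")
  nz <- mesh$nz
  dz <- mesh$dz
  offsets <- c(0L, cumsum(nr * nz))[seq_len(nzone)]
  N <- sum(nr) * nz

  # well-posedness pre-check: at least one Dirichlet datum somewhere
  has_dirichlet <- any(vapply(problem$zones, function(z) {
    z$v_sign != 0L || z$inner_bc$type == "dirichlet" ||
      z$outer_bc$type == "dirichlet"
  }, FALSE))
  if (!has_dirichlet)
    stop("singular system: no inlet or Dirichlet boundary anywhere")

  ti <- tj <- tx <- list()  # A triplets (diffusion + boundary terms)
  ci <- cj <- cx <- list()  # interior upwind convection triplets
  di <- dj <- dx <- list()  # interior central convection triplets
  b <- numeric(N)
  vbar <- vector("list", nzone)
  push <- function(lst, v) c(lst, list(v))

  for (k in seq_len(nzone)) {
    z <- problem$zones[[k]]
    mz <- mesh$zones[[k]]
    nrk <- nr[k]
    vb <- cell_average_velocity(mz$r_edges, z$profile, z$v_mean, z$geom_pars)
    vbar[[k]] <- vb

    # --- radial internal faces -------------------------------------------
    if (nrk > 1L) {
      ir <- seq_len(nrk - 1L)
      Tr <- z$D * mz$r_edges[ir + 1L] * dz / (mz$r_cent[ir + 1L] - mz$r_cent[ir])
      irv <- rep(ir, nz)
      izv <- rep(seq_len(nz), each = nrk - 1L)
      p <- cell_index(offsets, nr, k, irv, izv)
      q <- p + 1L
      Tv <- rep(Tr, nz)
      ti <- push(ti, c(p, p, q, q)); tj <- push(tj, c(p, q, q, p))
      tx <- push(tx, c(Tv, -Tv, Tv, -Tv))
    }

    # --- axial internal faces: diffusion + convection --------------------
    irv <- rep(seq_len(nrk), nz - 1L)
    izv <- rep(seq_len(nz - 1L), each = nrk)
    p <- cell_index(offsets, nr, k, irv, izv)
    q <- p + nrk
    Tz <- rep(z$D * mz$area2 / dz, nz - 1L)
    ti <- push(ti, c(p, p, q, q)); tj <- push(tj, c(p, q, q, p))
    tx <- push(tx, c(Tz, -Tz, Tz, -Tz))

    if (z$v_sign != 0L) {
      phi <- rep(z$v_sign * vb * mz$area2, nz - 1L)  # signed mass flow p -> q
      up <- ifelse(phi >= 0, p, q)                   # upwind donor cell
      ci <- push(ci, c(p, q)); cj <- push(cj, c(up, up))
      cx <- push(cx, c(phi, -phi))
      if (scheme == "central") {
        di <- push(di, c(p, p, q, q)); dj <- push(dj, c(p, q, p, q))
        dx <- push(dx, c(phi / 2, phi / 2, -phi / 2, -phi / 2))
      }
      # --- axial boundary faces: inlet Dirichlet + convective outflow ----
      iz_in <- if (z$v_sign > 0L) 1L else nz
      iz_out <- if (z$v_sign > 0L) nz else 1L
      pin <- cell_index(offsets, nr, k, seq_len(nrk), rep(iz_in, nrk))
      pout <- cell_index(offsets, nr, k, seq_len(nrk), rep(iz_out, nrk))
      a_d <- z$D * mz$area2 / (dz / 2)
      phi_b <- abs(vb) * mz$area2
      ti <- push(ti, c(pin, pout)); tj <- push(tj, c(pin, pout))
      tx <- push(tx, c(a_d, phi_b))
      b[pin] <- b[pin] + (a_d + phi_b) * z$C_in
    }

    # --- radial Dirichlet walls ------------------------------------------
    for (side in c("inner", "outer")) {
      bc <- if (side == "inner") z$inner_bc else z$outer_bc
      if (bc$type == "dirichlet") {
        if (side == "inner") {
          r_f <- mz$r_edges[1L]
          d <- mz$r_cent[1L] - r_f
          irw <- 1L
        } else {
          r_f <- mz$r_edges[nrk + 1L]
          d <- r_f - mz$r_cent[nrk]
          irw <- nrk
        }
        if (r_f <= 0) stop("Dirichlet condition on a zero-area axis face")
        a_w <- z$D * r_f * dz / d
        pw <- cell_index(offsets, nr, k, rep(irw, nz), seq_len(nz))
        ti <- push(ti, pw); tj <- push(tj, pw)
        tx <- push(tx, rep(a_w, nz))
        b[pw] <- b[pw] + a_w * bc$value
      }
    }
  }

  # --- interface coupling between consecutive zones ----------------------
  for (k in seq_len(nzone - 1L)) {
    zl <- problem$zones[[k]]; zr <- problem$zones[[k + 1L]]
    ml <- mesh$zones[[k]]; mr <- mesh$zones[[k + 1L]]
    lam <- problem$interfaces[[k]]$lambda
    r_f <- ml$r_edges[ml$nr + 1L]
    a <- zl$D / (r_f - ml$r_cent[ml$nr])
    bb <- zr$D / (mr$r_cent[1L] - r_f)
    t <- if (a + lam * bb > 0) r_f * dz * a * bb / (a + lam * bb) else 0
    p <- cell_index(offsets, nr, k, rep(nr[k], nz), seq_len(nz))
    q <- cell_index(offsets, nr, k + 1L, rep(1L, nz), seq_len(nz))
    tv <- rep(t, nz)
    ti <- push(ti, c(p, p, q, q)); tj <- push(tj, c(p, q, q, p))
    tx <- push(tx, c(lam * tv, -tv, tv, -lam * tv))
  }

  spm <- function(i, j, x)
    Matrix::sparseMatrix(i = as.integer(unlist(i) %||% integer(0)),
                         j = as.integer(unlist(j) %||% integer(0)),
                         x = as.numeric(unlist(x) %||% numeric(0)),
                         dims = c(N, N))
  conv <- spm(ci, cj, cx)
  A <- spm(ti, tj, tx) + conv
  conv_central <- if (scheme == "central") spm(di, dj, dx) else NULL

  # cells with no equation at all (possible only in the exact D = 0 limit of
  # a stagnant zone): pin them to zero concentration
  rs <- Matrix::rowSums(abs(A))
  zero_rows <- which(rs == 0 & b == 0)
  if (length(zero_rows)) {
    A <- A + Matrix::sparseMatrix(i = zero_rows, j = zero_rows,
                                  x = rep(1, length(zero_rows)), dims = c(N, N))
  } else if (any(rs == 0)) {
    stop("singular system: empty equation with nonzero right side")
  }

  structure(list(A = A, b = b, conv = conv, conv_central = conv_central,
                 offsets = offsets, nr = nr, nz = nz, vbar = vbar,
                 scheme = scheme, mesh = mesh, problem = problem),
            class = "fv_system")
}
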