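# Independent verification oracles: classical closed-form / spectral
# solutions the finite-volume solver is checked against.  These never call
# the assembly or solver code paths they validate.

#' Single-tube Graetz benchmark problem
#'
#' Laminar Poiseuille flow in a tube of radius `r1` with the wall
#' concentration pinned to zero at `r1` (a perfect sink): the classical
#' Graetz configuration.  Used purely for solver verification; the
#' membrane and shell are bypassed.
#'
#' @param r1 Tube radius, m. @param L Tube length, m.
#' @param D Diffusivity, m^2/s. @param v_mean Mean speed, m/s.
#' @param C0 Inlet concentration (default 1).
#' @return A `transport_problem` with a single tube zone.
#' @export
graetz_problem <- function(r1, L, D, v_mean, C0 = 1) {
  zone <- list(name = "tube", r_in = 0, r_out = r1, D = D,
               profile = "poiseuille", geom_pars = list(r1 = r1),
               v_mean = v_mean, v_sign = +1L, C_in = C0,
               inner_bc = list(type = "natural"),
               outer_bc = list(type = "dirichlet", value = 0),
               refine_at = "end")
  new_transport_problem(list(zone), list(), L,
                        meta = list(feed_zone = "tube", solvent_zone = NULL))
}

#' Stagnant annulus conduction benchmark problem
#'
#' Pure radial diffusion between fixed concentrations at the inner and
#' outer radii; the exact solution is `C(r) = A + B log(r)` (see
#' [annular_profile()]).
#'
#' @param r1,r2 Inner/outer radii, m. @param D Diffusivity, m^2/s.
#' @param C_inner,C_outer Fixed boundary concentrations.
#' @param L Axial length, m (immaterial; the problem is radially 1-D).
#' @return A `transport_problem` with a single stagnant zone.
#' @export
annulus_problem <- function(r1, r2, D, C_inner, C_outer, L = 0.01) {
  zone <- list(name = "annulus", r_in = r1, r_out = r2, D = D,
               profile = "none", geom_pars = list(),
               v_mean = 0, v_sign = 0L, C_in = NA_real_,
               inner_bc = list(type = "dirichlet", value = C_inner),
               outer_bc = list(type = "dirichlet", value = C_outer),
               refine_at = "both")
  new_transport_problem(list(zone), list(), L,
                        meta = list(feed_zone = NULL, solvent_zone = NULL))
}

#' Exact steady conduction profile in an annulus
#'
#' @param r Radii to evaluate at, m.
#' @param r1,r2 Inner/outer radii. @param C_inner,C_outer Boundary values.
#' @return `C(r) = C_inner + (C_outer - C_inner) * log(r/r1) / log(r2/r1)`.
#' @export
annular_profile <- function(r, r1, r2, C_inner, C_outer) {
  C_inner + (C_outer - C_inner) * log(r / r1) / log(r2 / r1)
}

#' Spectral Graetz-series oracle
#'
#' Computes the eigenfunction expansion of the Graetz problem
#' `2 (1 - rho^2) d(theta)/dZ = (1/rho) d/d rho (rho d(theta)/d rho)`,
#' `theta(1, Z) = 0`, `theta(rho, 0) = 1`, where `rho = r/r1` and
#' `Z = z D / (v_mean r1^2)`, by solving the self-adjoint Sturm-Liouville
#' eigenproblem on a fine 1-D radial grid (dense symmetric eigensolve -
#' a completely different numerical route from the finite-volume solver).
#' The mixing-cup profile is
#' `theta_b(Z) = sum_n w_n exp(-lambda_n^2 Z)`.
#'
#' @param n_r Radial grid resolution of the eigensolve (default 800).
#' @param n_modes Number of retained modes (default 120).
#' @return An object of class `graetz_oracle` with eigenvalues `lambda2`,
#'   bulk weights `w` (`= c_n B_n`), wall-gradient weights `g`, and the
#'   asymptotic Sherwood number `Sh_inf` (expected 3.657 on the diameter).
#' @export
graetz_oracle <- function(n_r = 800L, n_modes = 120L) {
  h <- 1 / n_r
  rho <- (seq_len(n_r) - 0.5) * h
  rho_f <- seq_len(n_r - 1L) * h           # interior face positions
  off <- rho_f / h^2
  dia <- c(off, 0) + c(0, off)
  dia[n_r] <- dia[n_r] + 2 * 1 / h^2        # wall Dirichlet, face at rho = 1
  W <- 2 * rho * (1 - rho^2)
  sW <- sqrt(W)
  # symmetrized operator S = W^{-1/2} T W^{-1/2}
  S <- matrix(0, n_r, n_r)
  S[cbind(seq_len(n_r), seq_len(n_r))] <- dia / W
  idx <- cbind(seq_len(n_r - 1L), seq_len(n_r - 1L) + 1L)
  S[idx] <- -off / (sW[-n_r] * sW[-1L])
  S[idx[, 2:1]] <- S[idx]
  es <- eigen(S, symmetric = TRUE)
  ord <- order(es$values)                   # ascending lambda^2
  keep <- ord[seq_len(min(n_modes, n_r))]
  lambda2 <- es$values[keep]
  phi <- es$vectors[, keep, drop = FALSE] / sW
  num <- colSums(W * phi) * h               # <1, phi>_W
  cn <- num / (colSums(W * phi^2) * h)
  Bn <- 2 * num / (sum(2 * W) * h)          # flow-weighted bulk projection
  w <- cn * Bn
  g <- cn * phi[n_r, ] / (h / 2)            # c_n * (-phi_n'(1))
  structure(list(lambda2 = lambda2, w = w, g = g,
                 Sh_inf = 2 * (phi[n_r, 1] / (h / 2)) / Bn[1],
                 n_r = n_r),
            class = "graetz_oracle")
}

#' @rdname graetz_oracle
#' @param zeta Dimensionless axial position `z D / (v_mean r1^2)`.
#' @param oracle A `graetz_oracle`.
#' @export
graetz_bulk_theta <- function(zeta, oracle = graetz_oracle()) {
  vapply(zeta, function(z) sum(oracle$w * exp(-oracle$lambda2 * z)), 0)
}

#' @rdname graetz_oracle
#' @export
graetz_sherwood <- function(zeta, oracle = graetz_oracle()) {
  vapply(zeta, function(z) {
    e <- exp(-oracle$lambda2 * z)
    2 * sum(oracle$g * e) / sum(oracle$w * e)
  }, 0)
}

# Local Sherwood number of a solved Graetz field at axial index iz,
# from the discrete wall gradient and the local mixing-cup concentration.
graetz_fv_sherwood <- function(field, iz) {
  problem <- field$problem
  mz <- field$mesh$zones[[1L]]
  z <- problem$zones[[1L]]
  r1 <- z$r_out
  d <- r1 - mz$r_cent[mz$nr]
  vb <- zone_cell_velocities(problem, field$mesh, 1L)
  Cv <- field$C[[1L]][, iz]
  C_b <- sum(Cv * vb * mz$area2) / sum(vb * mz$area2)
  q_w <- z$D * (Cv[mz$nr] - 0) / d
  2 * r1 * q_w / (z$D * C_b)
}

#' Run the solver verification oracle suite
#'
#' Four independent checks: (1) the Happel free-surface radius closed form
#' against brute-force root finding; (2) the membrane-only annular
#' conduction solution against `A + B log(r)`; (3) the Graetz wall-sink
#' mixing-cup outlet against the spectral eigenfunction series; (4) solute
#' mass-balance closure on the canonical ibuprofen case.
#'
#' @param quiet Suppress per-check messages.
#' @return Named logical vector of check results, invisibly; all `TRUE`
#'   means the suite passed.
#' @export
verify_oracles <- function(quiet = FALSE) {
  say <- function(...) if (!quiet) cat(sprintf(...), "\n")
  results <- c(happel = FALSE, annulus = FALSE, graetz = FALSE,
               conservation = FALSE)

  r2 <- 1.5e-4; n <- 9950; R <- 0.0315
  r3 <- happel_shell_radius(r2, n, R)
  root <- uniroot(function(x) x^2 * (n * r2^2 / R^2) - r2^2,
                  c(r2, R), tol = 1e-14)$root
  results["happel"] <- abs(r3 - root) / root < 1e-8 &&
    abs(r3 - 3.158e-4) / 3.158e-4 < 5e-4
  say("happel radius: r3 = %.4g m vs root-found %.4g m [%s]", r3, root,
      if (results["happel"]) "ok" else "FAIL")

  ann <- annulus_problem(1.1e-4, 1.5e-4, 1e-10, 2, 5)
  f <- solve_steady(ann, build_mesh(ann, nr = 48, nz = 3))
  exact <- annular_profile(f$mesh$zones[[1]]$r_cent, 1.1e-4, 1.5e-4, 2, 5)
  err_ann <- max(abs(f$C[[1]][, 2] - exact) / abs(exact))
  results["annulus"] <- err_ann < 1e-3
  say("annular conduction: max rel err %.2e [%s]", err_ann,
      if (results["annulus"]) "ok" else "FAIL")

  gz <- graetz_problem(r1 = 1.1e-4, L = 0.15, D = 7.17e-10, v_mean = 2.2)
  fg <- solve_steady(gz, build_mesh(gz, nr = 32, nz = 120))
  orc <- graetz_oracle(n_r = 500L)
  zeta <- 0.15 * 7.17e-10 / (2.2 * 1.1e-4^2)
  theta_fv <- mixing_cup(fg, "feed")
  theta_series <- graetz_bulk_theta(zeta, orc)
  err_gz <- abs(theta_fv - theta_series) / theta_series
  results["graetz"] <- err_gz < 0.02
  say("graetz outlet: FV %.5f vs series %.5f (rel err %.2e) [%s]",
      theta_fv, theta_series, err_gz,
      if (results["graetz"]) "ok" else "FAIL")

  case <- table1_case("IP")
  fld <- solve_steady(case$problem,
                      build_mesh(case$problem, c(24, 12, 24), 100))
  res <- mass_balance_residual(fld)
  results["conservation"] <- res <= 0.005
  say("conservation: residual %.2e [%s]", res,
      if (results["conservation"]) "ok" else "FAIL")

  invisible(results)
}
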