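#' Solute transport properties
#'
#' @param name Identifier, e.g. `"IP"` or `"4-IBAP"`.
#' @param D_aq Diffusivity in the aqueous phase, m^2/s.
#' @param D_org Diffusivity in the organic phase, m^2/s.
#' @param m Partition coefficient, `C_org / C_aq` at equilibrium
#'   (dimensionless; `m > 1` means the solute prefers the organic phase).
#' @param C0 Feed inlet concentration, g/mL.
#' @return An object of class `solute_spec`.
#' @export
solute_spec <- function(name, D_aq, D_org, m, C0) {
  if (D_aq <= 0 || D_org <= 0) stop("diffusivities must be > 0")
  if (m <= 0) stop("partition coefficient must be > 0")
  if (C0 <= 0) stop("inlet concentration must be > 0")
  structure(list(name = as.character(name), D_aq = D_aq, D_org = D_org,
                 m = m, C0 = C0),
            class = "solute_spec")
}

#' Porous membrane properties
#'
#' The pores are assumed wetted by the organic phase only, so the membrane
#' transports solute by diffusion through organic-filled pores, slowed by
#' porosity and tortuosity.
#'
#' @param porosity Void fraction of the fiber wall, in `(0, 1]`.
#' @param tortuosity Pore tortuosity factor, `>= 1`.
#' @return An object of class `membrane_spec`.
#' @export
membrane_spec <- function(porosity, tortuosity) {
  if (porosity <= 0 || porosity > 1) stop("porosity must be in (0, 1]")
  if (tortuosity < 1) stop("tortuosity must be >= 1")
  structure(list(porosity = porosity, tortuosity = tortuosity),
            class = "membrane_spec")
}

#' Effective diffusivity inside the porous membrane
#'
#' Standard porous-medium correction `D_org * porosity / tortuosity`.
#'
#' @param D_org Organic-phase diffusivity, m^2/s.
#' @param membrane A [membrane_spec()].
#' @return Effective diffusivity, m^2/s.
#' @export
effective_membrane_diffusivity <- function(D_org, membrane) {
  stopifnot(inherits(membrane, "membrane_spec"), D_org >= 0)
  D_org * membrane$porosity / membrane$tortuosity
}

# Low-level problem constructor shared by build_problem() and the
# verification oracles.  `zones` is an ordered (inner to outer) list; each
# zone is a list with fields:
#   name, r_in, r_out          radial extent, m
#   D                          diffusivity in the zone, m^2/s
#   profile                    "poiseuille" | "annular_happel" | "none"
#   geom_pars                  parameters the profile needs (r1 / r2, r3)
#   v_mean                     mean speed magnitude, m/s (0 for "none")
#   v_sign                     +1 flow toward +z, -1 toward -z, 0 stagnant
#   C_in                       inlet concentration (Dirichlet) if v_sign != 0
#   inner_bc, outer_bc         list(type = "natural") or
#                              list(type = "dirichlet", value = ...)
#   refine_at                  "start" | "end" | "both" | "none" (mesh grading)
# `interfaces` couples consecutive zones: list(lambda = ...) where the
# interface concentrations satisfy C_outer_side = lambda * C_inner_side,
# together with diffusive flux continuity.
new_transport_problem <- function(zones, interfaces, L, meta = list()) {
  stopifnot(length(interfaces) == length(zones) - 1L, L > 0)
  r_prev <- -Inf
  for (z in zones) {
    if (z$r_in >= z$r_out) stop("zone with non-positive radial thickness")
    if (z$r_in < r_prev) stop("zones must be ordered and non-overlapping")
    r_prev <- z$r_out
  }
  for (k in seq_along(interfaces)) {
    if (abs(zones[[k]]$r_out - zones[[k + 1L]]$r_in) > 1e-15)
      stop("adjacent zones must share their interface radius")
    if (interfaces[[k]]$lambda <= 0) stop("interface jump factor must be > 0")
  }
  structure(c(list(zones = zones, interfaces = interfaces, L = L), meta),
            class = "transport_problem")
}

#' Assemble the full three-domain transport problem
#'
#' Builds the steady axisymmetric convection-diffusion problem
#' `div(C V) = div(D grad C)` on the coupled tube / membrane / shell
#' domains of one Happel cell:
#' \itemize{
#'   \item the feed stream enters at `z = 0` with `C = C0` and leaves at
#'     `z = L` through a convective-outflow plane; the solvent stream runs
#'     counter-currently (`C = 0` at `z = L`);
#'   \item the membrane wall is stagnant, organic-filled, with effective
#'     diffusivity `D_org * porosity / tortuosity` and insulated ends;
#'   \item at the aqueous/organic interface the concentration jumps by the
#'     partition coefficient (organic side `= m *` aqueous side) with
#'     continuous diffusive flux; the organic/organic interface carries
#'     plain continuity;
#'   \item axial symmetry at `r = 0`, insulation at the free surface `r3`.
#' }
#' With `configuration = "feed_in_tube"` the partition jump sits at `r1`
#' and continuity at `r2`; with `"feed_in_shell"` they swap.
#'
#' @param geom A [contactor_geometry()].
#' @param solute A [solute_spec()].
#' @param membrane A [membrane_spec()].
#' @param flows A [flow_spec()].
#' @return An object of class `transport_problem`.
#' @examples
#' case <- table1_case("IP")
#' case$problem
#' @export
build_problem <- function(geom, solute, membrane, flows) {
  stopifnot(inherits(geom, "contactor_geometry"),
            inherits(solute, "solute_spec"),
            inherits(membrane, "membrane_spec"),
            inherits(flows, "flow_spec"))
  if (flows$arrangement != "counter_current")
    stop("only counter-current arrangement is modeled")
  v <- mean_velocities(flows, geom)
  feed_in_tube <- flows$configuration == "feed_in_tube"
  D_mem <- effective_membrane_diffusivity(solute$D_org, membrane)

  tube <- list(
    name = "tube", r_in = 0, r_out = geom$r1,
    D = if (feed_in_tube) solute$D_aq else solute$D_org,
    profile = "poiseuille", geom_pars = list(r1 = geom$r1),
    v_mean = v[["tube"]],
    v_sign = if (feed_in_tube) +1L else -1L,
    C_in = if (feed_in_tube) solute$C0 else 0,
    inner_bc = list(type = "natural"),   # axial symmetry (zero-area face)
    outer_bc = list(type = "natural"),
    refine_at = "end")
  memb <- list(
    name = "membrane", r_in = geom$r1, r_out = geom$r2,
    D = D_mem, profile = "none", geom_pars = list(),
    v_mean = 0, v_sign = 0L, C_in = NA_real_,
    inner_bc = list(type = "natural"), outer_bc = list(type = "natural"),
    refine_at = "both")
  shell <- list(
    name = "shell", r_in = geom$r2, r_out = geom$r3,
    D = if (feed_in_tube) solute$D_org else solute$D_aq,
    profile = "annular_happel",
    geom_pars = list(r2 = geom$r2, r3 = geom$r3),
    v_mean = v[["shell"]],
    v_sign = if (feed_in_tube) -1L else +1L,
    C_in = if (feed_in_tube) 0 else solute$C0,
    inner_bc = list(type = "natural"),
    outer_bc = list(type = "natural"),   # insulation at the free surface
    refine_at = "start")

  interfaces <- if (feed_in_tube) {
    list(list(at = geom$r1, lambda = solute$m),   # C_m = m * C_i
         list(at = geom$r2, lambda = 1))          # C_s = C_m
  } else {
    list(list(at = geom$r1, lambda = 1),          # C_m = C_t (both organic)
         list(at = geom$r2, lambda = 1 / solute$m))  # C_s = C_m / m
  }

  new_transport_problem(
    zones = list(tube, memb, shell), interfaces = interfaces, L = geom$L,
    meta = list(geometry = geom, solute = solute, membrane = membrane,
                flows = flows, feed_zone = if (feed_in_tube) "tube" else "shell",
                solvent_zone = if (feed_in_tube) "shell" else "tube"))
}

#' @export
print.transport_problem <- function(x, ...) {
  cat("Steady transport problem:", length(x$zones), "radial zone(s), L =",
      format(x$L), "m\n")
  for (z in x$zones) {
    dir <- c("-1" = "-z", "0" = "stagnant", "1" = "+z")[as.character(z$v_sign)]
    cat(sprintf("  %-9s r in [%.4g, %.4g] m  D = %.3g m2/s  flow %s",
                z$name, z$r_in, z$r_out, z$D, dir))
    if (z$v_sign != 0L)
      cat(sprintf("  vbar = %.4g m/s  C_in = %.3g g/mL", z$v_mean, z$C_in))
    cat("\n")
  }
  for (i in x$interfaces)
    cat(sprintf("  interface at r = %.4g m: outer side = %.4g x inner side\n",
                i$at, i$lambda))
  invisible(x)
}

# Which zone index carries the feed / solvent stream.
zone_index <- function(problem, name) {
  idx <- which(vapply(problem$zones, `[[`, "", "name") == name)
  if (length(idx) != 1L) stop("no unique zone named '", name, "'")
  idx
}
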