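#' Fiber packing fraction of a contactor module
#'
#' Fraction of the module cross-section occupied by fibers,
#' `n * r2^2 / R_module^2`.  In the Happel free-surface construction this
#' equals `1 - phi`, where `phi` is the void fraction of the bundle.
#'
#' @param n Number of fibers (non-negative integer).
#' @param r2 Fiber outer radius, m.
#' @param R_module Module (housing) inner radius, m.
#' @return Dimensionless fraction in `[0, 1]`.
#' @examples
#' packing_fraction(9950, 1.5e-4, 0.0315)
#' @seealso [happel_shell_radius()]
#' @export
packing_fraction <- function(n, r2, R_module) {
  stopifnot(length(n) == 1L, length(r2) == 1L, length(R_module) == 1L)
  if (n < 0) stop("fiber count 'n' must be >= 0")
  if (!is.finite(r2) || r2 <= 0) stop("fiber outer radius 'r2' must be > 0")
  if (!is.finite(R_module) || R_module <= r2)
    stop("module radius must exceed the fiber outer radius")
  f <- n * r2^2 / R_module^2
  if (f > 1) stop(sprintf("fibers do not fit in the module (packing fraction %.3f > 1)", f))
  f
}

#' Happel free-surface radius of the shell envelope around one fiber
#'
#' Each fiber in the bundle is assigned a concentric fluid envelope with a
#' shear-free outer surface at radius `r3 = r2 * (1 / (n r2^2 / R^2))^0.5`,
#' so that the envelopes jointly tile the module cross-section.  A single
#' fiber plus its envelope then represents the whole module.
#'
#' @inheritParams packing_fraction
#' @return Free-surface radius `r3`, m (always `> r2`).
#' @examples
#' happel_shell_radius(1.5e-4, 9950, 0.0315)  # 3.158e-4 m
#' @export
happel_shell_radius <- function(r2, n, R_module) {
  f <- packing_fraction(n, r2, R_module)
  if (f == 0) stop("packing fraction is zero: free-surface radius is unbounded")
  if (f >= 1) stop("packing fraction >= 1: no room for a fluid envelope")
  r2 * sqrt(1 / f)
}

#' Contactor geometry of a single Happel cell
#'
#' Collects the fiber and module dimensions and derives the Happel
#' free-surface radius `r3`.  All lengths in metres.
#'
#' @param r1 Fiber inner radius, m.
#' @param r2 Fiber outer radius, m.
#' @param R_module Module inner radius, m.
#' @param L Fiber length, m.
#' @param n Number of fibers.
#' @return An object of class `contactor_geometry` with fields
#'   `r1, r2, r3, L, n, R_module`.
#' @examples
#' contactor_geometry(1.1e-4, 1.5e-4, 0.0315, 0.15, 9950)
#' @export
contactor_geometry <- function(r1, r2, R_module, L, n) {
  stopifnot(is.finite(r1), is.finite(r2), is.finite(R_module),
            is.finite(L), is.finite(n))
  if (r1 <= 0 || r2 <= r1) stop("need 0 < r1 < r2")
  if (L <= 0) stop("fiber length must be > 0")
  if (n < 1 || n != round(n)) stop("fiber count must be a positive integer")
  r3 <- happel_shell_radius(r2, n, R_module)
  if (r3 <= r2) stop("derived r3 must exceed r2")  # unreachable, kept as guard
  structure(list(r1 = r1, r2 = r2, r3 = r3, L = L,
                 n = as.integer(n), R_module = R_module),
            class = "contactor_geometry")
}

#' @export
print.contactor_geometry <- function(x, ...) {
  cat("Hollow-fiber contactor geometry (Happel cell)\n")
  cat(sprintf("  r1 = %.4g m, r2 = %.4g m, r3 = %.4g m (derived)\n",
              x$r1, x$r2, x$r3))
  cat(sprintf("  L  = %.4g m, n = %d fibers, R_module = %.4g m\n",
              x$L, x$n, x$R_module))
  cat(sprintf("  packing fraction = %.4f\n",
              packing_fraction(x$n, x$r2, x$R_module)))
  invisible(x)
}

#' Convert litres per minute to cubic metres per second
#' @param x Flow rate, L/min.
#' @return Flow rate, m^3/s.
#' @export
lpm <- function(x) x / 6e4

#' Module flow specification
#'
#' Total volumetric flow rates of the aqueous feed and the organic solvent
#' for the whole module, and the flow configuration.  Only counter-current
#' operation is modeled: the feed always enters at `z = 0` and the solvent
#' at `z = L`.  Per-fiber (per-Happel-cell) flows are the totals divided by
#' the fiber count.
#'
#' @param Q_aq Total aqueous flow, m^3/s (see [lpm()] to convert).
#' @param Q_org Total organic flow, m^3/s.
#' @param configuration `"feed_in_tube"` (aqueous in the fiber lumen,
#'   octanol in the shell) or `"feed_in_shell"` (the mirrored arrangement).
#' @param arrangement Only `"counter_current"` is supported.
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(Q_aq, Q_org,
                      configuration = c("feed_in_tube", "feed_in_shell"),
                      arrangement = "counter_current") {
  configuration <- match.arg(configuration)
  arrangement <- match.arg(arrangement, "counter_current")
  if (!is.finite(Q_aq) || Q_aq <= 0) stop("Q_aq must be > 0")
  if (!is.finite(Q_org) || Q_org <= 0) stop("Q_org must be > 0")
  structure(list(Q_aq = Q_aq, Q_org = Q_org,
                 configuration = configuration,
                 arrangement = arrangement),
            class = "flow_spec")
}

#' Bulk fluid properties (Reynolds-number diagnostics only)
#'
#' Density and viscosity play no role in the mass-transfer solution because
#' the laminar velocity profiles are analytic; they are used solely to check
#' that the assumed laminar regime is plausible.
#'
#' @param density kg/m^3. @param viscosity Pa s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density, viscosity) {
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' @rdname fluid_properties
#' @export
water_properties <- function() fluid_properties(997, 8.9e-4)

#' @rdname fluid_properties
#' @export
octanol_properties <- function() fluid_properties(824, 7.29e-3)

#' Per-fiber mean axial velocities
#'
#' Divides the module flows equally among the `n` identical Happel cells and
#' converts to mean speeds over the tube cross-section `pi r1^2` and the
#' shell annulus `pi (r3^2 - r2^2)`.  Which stream occupies which side
#' follows the flow configuration.
#'
#' @param flows A [flow_spec()].
#' @param geom A [contactor_geometry()].
#' @return Named numeric vector `c(tube = ..., shell = ...)`, m/s.
#' @export
mean_velocities <- function(flows, geom) {
  stopifnot(inherits(flows, "flow_spec"), inherits(geom, "contactor_geometry"))
  if (geom$n < 1) stop("zero fiber count")
  A_tube <- pi * geom$r1^2
  A_shell <- pi * (geom$r3^2 - geom$r2^2)
  if (A_tube <= 0 || A_shell <= 0) stop("non-positive flow area")
  Q_tube <- if (flows$configuration == "feed_in_tube") flows$Q_aq else flows$Q_org
  Q_shell <- if (flows$configuration == "feed_in_tube") flows$Q_org else flows$Q_aq
  c(tube = (Q_tube / geom$n) / A_tube,
    shell = (Q_shell / geom$n) / A_shell)
}

#' Fully developed laminar velocity profiles
#'
#' `tube_velocity()` is the Poiseuille profile in the fiber lumen;
#' `shell_velocity()` is the fully developed annular profile with no slip at
#' the fiber outer wall (`r2`) and zero shear at the Happel free surface
#' (`r3`), `V(r) = K * ((r2^2 - r^2) + 2 r3^2 log(r / r2))`, normalized so
#' that its flow-area average equals `v_mean`.
#'
#' @param r Radial position(s), m, inside the respective domain.
#' @param v_mean Area-averaged axial speed, m/s.
#' @param r1,r2,r3 Domain radii, m.
#' @return Axial speed(s), m/s (magnitude; direction is carried separately).
#' @export
tube_velocity <- function(r, v_mean, r1) {
  if (any(r < -1e-15 | r > r1 * (1 + 1e-12))) stop("r outside [0, r1]")
  2 * v_mean * (1 - (r / r1)^2)
}

#' @rdname tube_velocity
#' @export
shell_velocity <- function(r, v_mean, r2, r3) {
  if (r3 <= r2) stop("need r3 > r2")
  if (any(r < r2 * (1 - 1e-12) | r > r3 * (1 + 1e-12))) stop("r outside [r2, r3]")
  K <- shell_profile_constant(v_mean, r2, r3)
  K * ((r2^2 - r^2) + 2 * r3^2 * log(r / r2))
}

# Normalization constant K of the shell profile so that
# (2 / (r3^2 - r2^2)) * int_{r2}^{r3} r V(r) dr = v_mean.
shell_profile_constant <- function(v_mean, r2, r3) {
  I <- shell_flux_antideriv(r3, r2, r3) - shell_flux_antideriv(r2, r2, r3)
  v_mean * (r3^2 - r2^2) / 2 / I
}

# Antiderivative of r * V(r) / K for the shell profile.
shell_flux_antideriv <- function(r, r2, r3) {
  r2^2 * r^2 / 2 - r^4 / 4 + 2 * r3^2 * (r^2 / 2 * log(r / r2) - r^2 / 4)
}

# Antiderivative of r * v(r) for the tube (Poiseuille) profile.
tube_flux_antideriv <- function(r, v_mean, r1) {
  2 * v_mean * (r^2 / 2 - r^4 / (4 * r1^2))
}

# Exact flow-area-averaged velocity on each annular cell [edges[i], edges[i+1]].
# Using exact cell averages makes the discrete flow equal the prescribed
# per-fiber flow to round-off, which the mixing-cup average relies on.
cell_average_velocity <- function(edges, profile, v_mean, geom_pars) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  area2 <- (hi^2 - lo^2) / 2  # per-radian annular area
  switch(profile,
    poiseuille = {
      r1 <- geom_pars$r1
      (tube_flux_antideriv(hi, v_mean, r1) - tube_flux_antideriv(lo, v_mean, r1)) / area2
    },
    annular_happel = {
      K <- shell_profile_constant(v_mean, geom_pars$r2, geom_pars$r3)
      K * (shell_flux_antideriv(hi, geom_pars$r2, geom_pars$r3) -
             shell_flux_antideriv(lo, geom_pars$r2, geom_pars$r3)) / area2
    },
    none = rep(0, length(lo)),
    stop("unknown velocity profile: ", profile)
  )
}

# Pointwise velocity for a zone (used by the independent flux audit).
pointwise_velocity <- function(r, profile, v_mean, geom_pars) {
  switch(profile,
    poiseuille = tube_velocity(r, v_mean, geom_pars$r1),
    annular_happel = shell_velocity(r, v_mean, geom_pars$r2, geom_pars$r3),
    none = rep(0, length(r)),
    stop("unknown velocity profile: ", profile)
  )
}

#' Reynolds numbers of both streams (laminar-regime diagnostic)
#'
#' Tube Reynolds number uses the lumen diameter `2 r1`; the shell uses the
#' hydraulic diameter of the Happel annulus, `2 (r3 - r2)`.
#'
#' @inheritParams mean_velocities
#' @param aqueous,organic [fluid_properties()] of the two streams.
#' @return Named vector `c(tube = ..., shell = ...)`.
#' @export
reynolds_numbers <- function(flows, geom,
                             aqueous = water_properties(),
                             organic = octanol_properties()) {
  v <- mean_velocities(flows, geom)
  tube_fluid <- if (flows$configuration == "feed_in_tube") aqueous else organic
  shell_fluid <- if (flows$configuration == "feed_in_tube") organic else aqueous
  c(tube = tube_fluid$density * v[["tube"]] * 2 * geom$r1 / tube_fluid$viscosity,
    shell = shell_fluid$density * v[["shell"]] * 2 * (geom$r3 - geom$r2) /
      shell_fluid$viscosity)
}
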