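# Cell-average velocities of a mesh zone (recomputed from the analytic
# profiles; identical to what the assembly used).
zone_cell_velocities <- function(problem, mesh, k) {
  z <- problem$zones[[k]]
  cell_average_velocity(mesh$zones[[k]]$r_edges, z$profile, z$v_mean,
                        z$geom_pars)
}

# Resolve which zone carries a named stream and its outlet axial index.
stream_zone <- function(problem, outlet = c("feed", "solvent")) {
  outlet <- match.arg(outlet)
  nm <- if (outlet == "feed") problem$feed_zone else problem$solvent_zone
  if (is.null(nm)) stop("problem has no ", outlet, " stream")
  zone_index(problem, nm)
}

#' Mixing-cup (bulk) concentration at a stream outlet
#'
#' Velocity-weighted average over the outlet cross-section,
#' `int C V r dr / int V r dr`, evaluated with the mesh's own annular areas
#' and exact cell-average velocities.  This is the thermodynamically
#' meaningful "outlet concentration".  Set `weighted = FALSE` for a plain
#' area average (sensitivity check).
#'
#' @param field A `concentration_field`.
#' @param outlet `"feed"` or `"solvent"`.
#' @param weighted Velocity-weight the average (default `TRUE`).
#' @return Concentration, g/mL.
#' @export
mixing_cup <- function(field, outlet = c("feed", "solvent"), weighted = TRUE) {
  problem <- field$problem
  k <- stream_zone(problem, outlet)
  z <- problem$zones[[k]]
  mz <- field$mesh$zones[[k]]
  if (z$v_sign == 0L) stop("outlet plane has zero net flow")
  iz_out <- if (z$v_sign > 0L) field$mesh$nz else 1L
  Cv <- field$C[[k]][, iz_out]
  w <- if (weighted) {
    zone_cell_velocities(problem, field$mesh, k) * mz$area2
  } else {
    mz$area2
  }
  if (sum(w) == 0) stop("outlet plane has zero net flow")
  sum(Cv * w) / sum(w)
}

#' Percentage of solute separated from the feed
#'
#' `100 * (1 - C_outlet / C_inlet)`.  Outlet concentrations outside
#' `[0, C_inlet]` by more than `tol` (relative) signal a broken solve and
#' raise an error; smaller excursions are clamped as round-off.
#'
#' @param C_inlet Feed inlet concentration, g/mL (> 0).
#' @param C_outlet Feed outlet (mixing-cup) concentration, g/mL.
#' @param tol Relative round-off tolerance (default 1e-8).
#' @return Separation, percent, in `[0, 100]`.
#' @export
separation_percent <- function(C_inlet, C_outlet, tol = 1e-8) {
  if (!is.finite(C_inlet) || C_inlet <= 0) stop("C_inlet must be > 0")
  if (C_outlet < -tol * C_inlet || C_outlet > C_inlet * (1 + tol))
    stop(sprintf(
      "C_outlet = %.6g outside [0, C_inlet = %.6g]: solve looks broken",
      C_outlet, C_inlet))
  C_outlet <- min(max(C_outlet, 0), C_inlet)
  100 * (1 - C_outlet / C_inlet)
}

#' One-row summary of a solved extraction case
#'
#' @param field A `concentration_field` from a full contactor problem.
#' @return A `separation_summary` data frame with the solute,
#'   configuration, inlet and mixing-cup outlet concentrations, separation
#'   percent and the mass-balance residual fraction.
#' @export
separation_summary <- function(field) {
  problem <- field$problem
  if (is.null(problem$solute)) stop("not a full contactor problem")
  C0 <- problem$solute$C0
  C_out <- mixing_cup(field, "feed")
  out <- data.frame(
    solute = problem$solute$name,
    configuration = problem$flows$configuration,
    C_inlet = C0,
    C_outlet = C_out,
    separation_percent = separation_percent(C0, C_out),
    mass_balance_residual = mass_balance_residual(field),
    stringsAsFactors = FALSE)
  class(out) <- c("separation_summary", "data.frame")
  out
}

#' Axial concentration profile along a membrane interface
#'
#' Reconstructs the one-sided interface concentrations from the two
#' adjacent cell rows using the same interface-elimination formula as the
#' assembly, and returns them against the dimensionless axial coordinate
#' `z/L` measured from the feed inlet (which is `z = 0` in every
#' configuration), normalized by the feed concentration `C0`.
#'
#' @param field A `concentration_field`.
#' @param interface `"r1"` (tube/membrane) or `"r2"` (membrane/shell);
#'   for generic problems, the 1-based interface number.
#' @param side Name of the zone whose side of the interface to report
#'   (default: the inner zone).
#' @return Data frame with `z_hat`, `C`, `C_hat`.
#' @export
interface_profile <- function(field, interface = c("r1", "r2"), side = NULL) {
  problem <- field$problem
  if (is.character(interface)) {
    interface <- match.arg(interface)
    j <- if (interface == "r1") 1L else 2L
  } else j <- as.integer(interface)
  if (j < 1L || j > length(problem$interfaces)) stop("no such interface")
  k <- j
  zl <- problem$zones[[k]]; zr <- problem$zones[[k + 1L]]
  ml <- field$mesh$zones[[k]]; mr <- field$mesh$zones[[k + 1L]]
  lam <- problem$interfaces[[j]]$lambda
  r_f <- ml$r_edges[ml$nr + 1L]
  a <- zl$D / (r_f - ml$r_cent[ml$nr])
  bb <- zr$D / (mr$r_cent[1L] - r_f)
  C_L <- field$C[[k]][ml$nr, ]
  C_R <- field$C[[k + 1L]][1L, ]
  C_inner <- (a * C_L + bb * C_R) / (a + lam * bb)
  C_outer <- lam * C_inner
  if (is.null(side)) side <- zl$name
  value <- if (side == zl$name) C_inner else if (side == zr$name) C_outer
           else stop("side must be '", zl$name, "' or '", zr$name, "'")
  C0 <- if (!is.null(problem$solute)) problem$solute$C0 else
    max(vapply(problem$zones, function(z) if (is.na(z$C_in)) 0 else z$C_in, 0))
  data.frame(z_hat = field$mesh$z_cent / problem$L,
             C = value, C_hat = value / C0)
}

#' Solute mass-balance audit
#'
#' Recomputes the solute flow through the three open planes (feed inlet,
#' feed outlet, solvent inlet/outlet) by independent quadrature - pointwise
#' analytic velocities at the cell centres rather than the assembly's exact
#' cell averages - and returns
#' `|feed_in - feed_out - solvent_out| / feed_in`.
#' Because the quadrature is independent of the discretization, the
#' residual measures genuine discretization error and shrinks under mesh
#' refinement.
#'
#' @param field A `concentration_field` from a full contactor problem.
#' @return Residual fraction (>= 0).
#' @export
mass_balance_residual <- function(field) {
  problem <- field$problem
  mesh <- field$mesh
  dz <- mesh$dz
  plane_fluxes <- function(outlet) {
    k <- stream_zone(problem, outlet)
    z <- problem$zones[[k]]
    mz <- mesh$zones[[k]]
    v_pt <- pointwise_velocity(mz$r_cent, z$profile, z$v_mean, z$geom_pars)
    phi <- v_pt * mz$area2
    iz_in <- if (z$v_sign > 0L) 1L else mesh$nz
    iz_out <- if (z$v_sign > 0L) mesh$nz else 1L
    list(conv_in = sum(phi) * z$C_in,
         diff_in = sum(z$D * mz$area2 * (z$C_in - field$C[[k]][, iz_in]) /
                         (dz / 2)),
         conv_out = sum(phi * field$C[[k]][, iz_out]))
  }
  f <- plane_fluxes("feed")
  s <- plane_fluxes("solvent")
  inflow <- f$conv_in + f$diff_in
  outflow <- f$conv_out + s$conv_out - s$diff_in  # -s$diff_in: diffusion out
  abs(inflow - outflow) / inflow                  # through the solvent inlet
}

#' Export a concentration field to CSV or legacy VTK
#'
#' CSV is long-format (`domain, r, z, C`), one row per cell.  VTK writes one
#' legacy ASCII `STRUCTURED_GRID` file per domain (suffix `_<domain>.vtk`)
#' with cell-centre points and a `concentration` scalar.
#'
#' @param field A `concentration_field`.
#' @param path Output file path (for VTK, the stem of the per-domain files).
#' @param format `"csv"` or `"vtk"`.
#' @return The written path(s), invisibly.
#' @export
export_field <- function(field, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  mesh <- field$mesh
  if (format == "csv") {
    rows <- lapply(seq_along(field$C), function(k) {
      mz <- mesh$zones[[k]]
      data.frame(domain = mz$name,
                 r = rep(mz$r_cent, mesh$nz),
                 z = rep(mesh$z_cent, each = mz$nr),
                 C = as.vector(field$C[[k]]))
    })
    df <- do.call(rbind, rows)
    ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                   error = function(e)
                     stop("failed to write CSV to '", path, "': ",
                          conditionMessage(e)))
    return(invisible(path))
  }
  stem <- sub("\\.vtk$", "", path)
  paths <- character(0)
  for (k in seq_along(field$C)) {
    mz <- mesh$zones[[k]]
    fp <- sprintf("%s_%s.vtk", stem, mz$name)
    pts <- cbind(rep(mz$r_cent, mesh$nz), rep(mesh$z_cent, each = mz$nr), 0)
    lines <- c("# vtk DataFile Version 3.0",
               paste("membrex concentration field -", mz$name),
               "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", mz$nr, mesh$nz),
               sprintf("POINTS %d double", nrow(pts)),
               apply(pts, 1L, function(p) paste(format(p, digits = 12),
                                                collapse = " ")),
               sprintf("POINT_DATA %d", nrow(pts)),
               "SCALARS concentration double 1",
               "LOOKUP_TABLE default",
               format(as.vector(field$C[[k]]), digits = 12))
    tryCatch(writeLines(lines, fp),
             error = function(e)
               stop("failed to write VTK to '", fp, "': ",
                    conditionMessage(e)))
    paths <- c(paths, fp)
  }
  invisible(paths)
}
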