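#' Solve the steady transport problem
#'
#' Assembles and solves the finite-volume system by sparse direct
#' factorization.  With `scheme = "central"` the convective fluxes use
#' second-order central differencing instead of first-order upwinding (the
#' solved system equals the fixed point of the classical deferred-correction
#' iteration); the upwind default is positivity-preserving and is what the
#' acceptance properties assume.
#'
#' @param problem A `transport_problem`.
#' @param mesh A `contactor_mesh` (default: [build_mesh()] at the package's
#'   default resolution).
#' @param scheme `"upwind"` or `"central"`.
#' @param tol Relative residual tolerance on the discrete system (1e-10).
#' @return An object of class `concentration_field`: per-zone concentration
#'   matrices (`nr x nz`, g/mL), the mesh, the problem and solver
#'   diagnostics (`residual`, `residual_history`, `scheme`, `n_unknowns`).
#' @examples
#' case <- table1_case("IP")
#' field <- solve_steady(case$problem, build_mesh(case$problem, c(12, 6, 12), 40))
#' separation_summary(field)
#' @export
solve_steady <- function(problem, mesh = build_mesh(problem),
                         scheme = c("upwind", "central"),
                         tol = 1e-10) {
  scheme <- match.arg(scheme)
  sys <- assemble_system(problem, mesh, scheme)
  bnorm <- max(sqrt(sum(sys$b^2)), .Machine$double.xmin)
  history <- numeric(0)

  A <- if (scheme == "central")
    sys$A + (sys$conv_central - sys$conv) else sys$A
  x <- as.numeric(Matrix::solve(A, sys$b))
  resid <- sqrt(sum((as.numeric(A %*% x) - sys$b)^2)) / bnorm
  history <- c(history, resid)
  if (!is.finite(resid) || resid > tol) {
    cond <- structure(
      class = c("membrex_solver_error", "error", "condition"),
      list(message = sprintf(
             "linear solve did not reach tolerance (residual %.3g > %.3g)",
             resid, tol),
           call = sys.call(), residual_history = history))
    stop(cond)
  }

  C <- vector("list", length(problem$zones))
  names(C) <- vapply(problem$zones, `[[`, "", "name")
  for (k in seq_along(problem$zones)) {
    nrk <- sys$nr[k]
    C[[k]] <- matrix(x[sys$offsets[k] + seq_len(nrk * sys$nz)],
                     nrow = nrk, ncol = sys$nz)
  }
  field <- structure(list(C = C, mesh = mesh, problem = problem,
                          diagnostics = list(residual = resid,
                                             residual_history = history,
                                             scheme = scheme,
                                             n_unknowns = length(x))),
                     class = "concentration_field")
  check_field_bounds(field)
  field
}

# Soft validation of the discrete maximum principle: aqueous-side
# concentrations must stay in [0, C0], organic-side in [0, m*C0], up to
# round-off.  Violations signal an assembly defect, so warn loudly.
check_field_bounds <- function(field, rel_tol = 1e-8) {
  problem <- field$problem
  if (is.null(problem$solute)) return(invisible(field))
  C0 <- problem$solute$C0
  m <- problem$solute$m
  for (k in seq_along(problem$zones)) {
    z <- problem$zones[[k]]
    cap <- if (z$name == problem$feed_zone) C0 else m * C0
    v <- field$C[[k]]
    if (any(!is.finite(v)))
      warning("non-finite concentrations in zone ", z$name)
    else if (min(v) < -rel_tol * C0 || max(v) > cap * (1 + rel_tol))
      warning(sprintf("zone %s violates concentration bounds [0, %.3g]",
                      z$name, cap))
  }
  invisible(field)
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("Steady concentration field on", total_cells(x$mesh), "cells",
      sprintf("(residual %.2e, %s scheme)\n",
              x$diagnostics$residual, x$diagnostics$scheme))
  for (k in seq_along(x$C))
    cat(sprintf("  %-9s C in [%.4g, %.4g] g/mL\n", names(x$C)[k],
                min(x$C[[k]]), max(x$C[[k]])))
  invisible(x)
}

#' Mesh-independence study by uniform refinement
#'
#' Solves the problem on successively bisected meshes until the feed-outlet
#' mixing-cup concentration changes by less than `tol` (relative) between
#' consecutive levels, mirroring the usual CFD mesh-independence test.
#'
#' @param problem A `transport_problem`.
#' @param tol Relative change tolerance between levels (default 1e-3).
#' @param max_levels Maximum number of mesh levels to try.
#' @param nr,nz,grading Base-mesh resolution (level 0).
#' @param scheme Convection scheme, see [solve_steady()].
#' @return A list with the finest `concentration_field` and a
#'   `mesh_study_report` data frame (`level`, `cells`, `outlet_concentration`,
#'   `rel_change`) whose `converged` attribute records success.  If the
#'   budget is exhausted an error of class `membrex_no_convergence` is
#'   raised carrying the partial report.
#' @export
refine_until_converged <- function(problem, tol = 1e-3, max_levels = 5L,
                                   nr = c(12, 6, 12), nz = 50, grading = 1.15,
                                   scheme = "upwind") {
  stopifnot(tol > 0, max_levels >= 2L)
  mesh <- build_mesh(problem, nr, nz, grading)
  report <- data.frame(level = integer(), cells = integer(),
                       outlet_concentration = numeric(),
                       rel_change = numeric())
  field <- NULL
  prev <- NA_real_
  for (lev in seq_len(max_levels) - 1L) {
    field <- solve_steady(problem, mesh, scheme = scheme)
    c_out <- mixing_cup(field, "feed")
    rel <- if (is.na(prev)) NA_real_ else abs(c_out - prev) / abs(prev)
    report <- rbind(report, data.frame(level = lev, cells = total_cells(mesh),
                                       outlet_concentration = c_out,
                                       rel_change = rel))
    if (!is.na(rel) && rel < tol) {
      attr(report, "converged") <- TRUE
      class(report) <- c("mesh_study_report", "data.frame")
      return(list(field = field, report = report))
    }
    prev <- c_out
    mesh <- refine_mesh(mesh)
  }
  attr(report, "converged") <- FALSE
  class(report) <- c("mesh_study_report", "data.frame")
  cond <- structure(
    class = c("membrex_no_convergence", "error", "condition"),
    list(message = sprintf(
           "outlet concentration not mesh-independent after %d levels (last change %.3g > %.3g)",
           max_levels, report$rel_change[nrow(report)], tol),
         call = sys.call(), report = report))
  stop(cond)
}

#' @export
print.mesh_study_report <- function(x, ...) {
  cat("Mesh-independence study",
      if (isTRUE(attr(x, "converged"))) "(converged)" else "(NOT converged)",
      "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
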