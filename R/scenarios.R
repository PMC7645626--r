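# Canonical physicochemical parameter sets for the two solutes (ibuprofen
# and its metabolite 4-isobutylacetophenone, both extracted into octanol).
solute_catalog <- function() {
  list(
    "IP" = list(name = "IP", D_aq = 7.17e-10, D_org = 1.47e-10,
                m = 31.62, C0 = 1e-4),
    "4-IBAP" = list(name = "4-IBAP", D_aq = 7.53e-10, D_org = 1.56e-10,
                    m = 37.15, C0 = 1e-4))
}

default_params <- function() {
  list(r1 = 1.1e-4, r2 = 1.5e-4, R_module = 0.0315, L = 0.15, n = 9950,
       porosity = 0.40, tortuosity = 2.2,
       Q_aq = lpm(50), Q_org = lpm(50))
}

# Build a scenario from a flat parameter list (geometry + membrane + flows
# + solute fields).  Central rebuild point for sweeps.
case_from_params <- function(params, solute_pars, configuration, label = NULL) {
  geom <- contactor_geometry(params$r1, params$r2, params$R_module,
                             params$L, params$n)
  memb <- membrane_spec(params$porosity, params$tortuosity)
  sol <- solute_spec(solute_pars$name, solute_pars$D_aq, solute_pars$D_org,
                     solute_pars$m, solute_pars$C0)
  flows <- flow_spec(params$Q_aq, params$Q_org, configuration)
  structure(list(label = label %||% sprintf("%s/%s", sol$name, configuration),
                 solute = sol, configuration = configuration,
                 params = params, solute_params = solute_pars,
                 problem = build_problem(geom, sol, memb, flows)),
            class = "scenario_case")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical extraction scenario for the shipped parameter set
#'
#' Builds the fully specified transport problem for either solute and flow
#' configuration at the canonical operating point: `r1 = 1.1e-4` m,
#' `r2 = 1.5e-4` m, module radius 0.0315 m, porosity 0.40, tortuosity 2.2,
#' `L = 0.15` m, 9950 fibers, and 50 L/min on both streams.
#'
#' @param solute `"IP"` (ibuprofen) or `"4-IBAP"`.
#' @param configuration `"feed_in_tube"` or `"feed_in_shell"`.
#' @param overrides Named list of parameter overrides; allowed names are
#'   the geometric/membrane/flow parameters (`r1, r2, R_module, L, n,
#'   porosity, tortuosity, Q_aq, Q_org`, SI units) and the solute
#'   properties (`D_aq, D_org, m, C0`).
#' @return A `scenario_case` containing the `transport_problem`.
#' @examples
#' case <- table1_case("4-IBAP", "feed_in_shell")
#' case$problem$geometry$r3   # 3.158e-4 m
#' @export
table1_case <- function(solute = c("IP", "4-IBAP"),
                        configuration = c("feed_in_tube", "feed_in_shell"),
                        overrides = list()) {
  solute <- match.arg(solute)
  configuration <- match.arg(configuration)
  params <- default_params()
  sol <- solute_catalog()[[solute]]
  if (length(overrides)) {
    bad <- setdiff(names(overrides), c(names(params), "D_aq", "D_org", "m", "C0"))
    if (length(bad))
      stop("unknown override parameter(s): ", paste(bad, collapse = ", "))
    for (nm in intersect(names(overrides), names(params)))
      params[[nm]] <- overrides[[nm]]
    for (nm in intersect(names(overrides), c("D_aq", "D_org", "m", "C0")))
      sol[[nm]] <- overrides[[nm]]
  }
  case_from_params(params, sol, configuration)
}

#' @export
print.scenario_case <- function(x, ...) {
  cat("Scenario:", x$label, "\n")
  print(x$problem)
  invisible(x)
}

# Solve a scenario at a given resolution.
solve_case <- function(case, nr = c(48, 24, 48), nz = 200, grading = 1.15,
                       scheme = "upwind") {
  solve_steady(case$problem, build_mesh(case$problem, nr, nz, grading),
               scheme = scheme)
}

#' Parameter sweep reproducing the flow-rate / porosity / fiber-count studies
#'
#' Re-solves the scenario once per swept value, rebuilding the geometry when
#' the fiber count changes (the Happel radius `r3` depends on `n`; the
#' module radius is held fixed).
#'
#' @param base A `scenario_case` (see [table1_case()]).
#' @param parameter One of `"Q_aq"` (m^3/s), `"porosity"`, `"n_fibers"`.
#' @param values Strictly monotone vector of parameter values.  Defaults:
#'   10-50 L/min for `Q_aq`, 0.2-0.6 for `porosity`, 4000-12000 for
#'   `n_fibers` - five values bracketing the canonical operating point.
#' @param nr,nz,grading,scheme Solver resolution (defaults trimmed for
#'   sweep throughput; trends are mesh-robust).
#' @return A `sweep_result` data frame: one row per value with the outlet
#'   mixing-cup concentration (g/mL) and separation percent.  If a member
#'   solve fails, an error of class `membrex_sweep_error` carries the
#'   partial table in its `partial` field.
#' @export
sweep <- function(base, parameter = c("Q_aq", "porosity", "n_fibers"),
                  values = NULL, nr = c(24, 12, 24), nz = 100,
                  grading = 1.15, scheme = "upwind") {
  stopifnot(inherits(base, "scenario_case"))
  parameter <- match.arg(parameter)
  if (is.null(values))
    values <- switch(parameter,
                     Q_aq = lpm(c(10, 20, 30, 40, 50)),
                     porosity = c(0.2, 0.3, 0.4, 0.5, 0.6),
                     n_fibers = c(4000, 6000, 8000, 9950, 12000))
  if (length(values) < 2L || any(diff(values) <= 0))
    stop("'values' must be strictly increasing with at least two entries")
  unit <- switch(parameter, Q_aq = "m3/s", porosity = "-", n_fibers = "count")
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    p <- base$params
    p[[switch(parameter, Q_aq = "Q_aq", porosity = "porosity",
              n_fibers = "n")]] <- values[i]
    res <- tryCatch({
      case_i <- case_from_params(p, base$solute_params, base$configuration)
      fld <- solve_case(case_i, nr, nz, grading, scheme)
      C_out <- mixing_cup(fld, "feed")
      data.frame(parameter = parameter, value = values[i],
                 C_outlet = C_out,
                 separation_percent = separation_percent(base$solute$C0, C_out))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      partial <- do.call(rbind, rows[seq_len(i - 1L)])
      cond <- structure(
        class = c("membrex_sweep_error", "error", "condition"),
        list(message = sprintf("sweep aborted at %s = %.4g: %s", parameter,
                               values[i], conditionMessage(res)),
             call = sys.call(), partial = partial))
      stop(cond)
    }
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "unit") <- unit
  attr(out, "solute") <- base$solute$name
  attr(out, "configuration") <- base$configuration
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep of %s [%s] - %s, %s\n", x$parameter[1],
              attr(x, "unit"), attr(x, "solute"), attr(x, "configuration")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Compare the two flow configurations at identical conditions
#'
#' Solves the same solute and operating point with the feed in the tube and
#' in the shell, and reports both separations and their difference
#' (shell-feed minus tube-feed).
#'
#' @param solute `"IP"` or `"4-IBAP"`.
#' @param overrides Parameter overrides, as in [table1_case()].
#' @param nr,nz,grading,scheme Solver resolution.
#' @return A `configuration_comparison` data frame (one row per
#'   configuration) with attribute `shell_minus_tube`.
#' @export
compare_configurations <- function(solute = c("IP", "4-IBAP"),
                                   overrides = list(),
                                   nr = c(24, 12, 24), nz = 100,
                                   grading = 1.15, scheme = "upwind") {
  solute <- match.arg(solute)
  rows <- lapply(c("feed_in_tube", "feed_in_shell"), function(cfg) {
    case <- table1_case(solute, cfg, overrides)
    fld <- solve_case(case, nr, nz, grading, scheme)
    summ <- separation_summary(fld)
    summ[, c("solute", "configuration", "C_outlet", "separation_percent")]
  })
  out <- do.call(rbind, rows)
  attr(out, "shell_minus_tube") <-
    out$separation_percent[2] - out$separation_percent[1]
  class(out) <- c("configuration_comparison", "data.frame")
  out
}

#' @export
print.configuration_comparison <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  d <- attr(x, "shell_minus_tube")
  cat(sprintf("shell-feed minus tube-feed separation: %+.3f points (%s)\n", d,
              if (d > 0) "shell-side feed removes more" else
                "tube-side feed removes more"))
  invisible(x)
}
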