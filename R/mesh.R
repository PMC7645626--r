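# Geometrically graded cell edges on [a, b].  refine_at says where the fine
# cells sit; ratio is the growth factor between neighbouring cell widths.
graded_edges <- function(a, b, n, ratio = 1.15,
                         refine_at = c("none", "start", "end", "both")) {
  refine_at <- match.arg(refine_at)
  stopifnot(b > a, n >= 1, ratio >= 1)
  if (ratio == 1 || refine_at == "none")
    return(seq(a, b, length.out = n + 1L))
  widths <- switch(refine_at,
    start = ratio^(seq_len(n) - 1L),          # smallest first
    end   = ratio^(n - seq_len(n)),           # smallest last
    both  = {
      n1 <- n %/% 2L
      n2 <- n - n1
      c(ratio^(seq_len(n1) - 1L), ratio^(n2 - seq_len(n2)))
    })
  widths <- widths / sum(widths) * (b - a)
  edges <- a + c(0, cumsum(widths))
  edges[length(edges)] <- b  # kill round-off drift
  edges
}

#' Build a structured, mapped, graded mesh for a transport problem
#'
#' Each radial zone gets its own cell-centred grid, geometrically graded so
#' that the finest cells sit against the membrane interfaces (`r1`, `r2`)
#' where concentration boundary layers form; the axial grid is uniform and
#' shared by all zones.  Interface faces coincide exactly across zones.
#'
#' @param problem A `transport_problem`.
#' @param nr Radial cell counts, one per zone (recycled if length 1).
#'   Default `c(48, 24, 48)` for tube/membrane/shell.
#' @param nz Axial cell count (default 200).
#' @param grading Geometric stretching ratio between neighbouring radial
#'   cells (default 1.15; 1 gives uniform spacing).
#' @return An object of class `contactor_mesh`.
#' @export
build_mesh <- function(problem, nr = c(48, 24, 48), nz = 200, grading = 1.15) {
  stopifnot(inherits(problem, "transport_problem"))
  nzone <- length(problem$zones)
  nr <- as.integer(rep_len(nr, nzone))
  nz <- as.integer(nz)
  if (any(nr < 3) || nz < 3) stop("need at least 3 cells per direction per domain")
  zones <- vector("list", nzone)
  for (k in seq_len(nzone)) {
    z <- problem$zones[[k]]
    edges <- graded_edges(z$r_in, z$r_out, nr[k], grading, z$refine_at)
    zones[[k]] <- list(
      name = z$name,
      r_edges = edges,
      r_cent = (edges[-1] + edges[-length(edges)]) / 2,
      area2 = (edges[-1]^2 - edges[-length(edges)]^2) / 2,  # per-radian area
      nr = nr[k])
  }
  z_edges <- seq(0, problem$L, length.out = nz + 1L)
  structure(list(zones = zones,
                 z_edges = z_edges,
                 z_cent = (z_edges[-1] + z_edges[-length(z_edges)]) / 2,
                 dz = problem$L / nz,
                 nz = nz, nr = nr, grading = grading, L = problem$L),
            class = "contactor_mesh")
}

#' Uniformly refine a mesh by bisecting every cell
#'
#' Keeps the mesh family nested (each parent cell splits into 4 children in
#' 2-D), which is what the mesh-independence study and Richardson order
#' estimates assume.
#'
#' @param mesh A `contactor_mesh`.
#' @return The refined `contactor_mesh`.
#' @export
refine_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "contactor_mesh"))
  bisect <- function(edges) {
    mid <- (edges[-1] + edges[-length(edges)]) / 2
    sort(c(edges, mid))
  }
  zones <- lapply(mesh$zones, function(z) {
    edges <- bisect(z$r_edges)
    list(name = z$name, r_edges = edges,
         r_cent = (edges[-1] + edges[-length(edges)]) / 2,
         area2 = (edges[-1]^2 - edges[-length(edges)]^2) / 2,
         nr = length(edges) - 1L)
  })
  z_edges <- bisect(mesh$z_edges)
  structure(list(zones = zones, z_edges = z_edges,
                 z_cent = (z_edges[-1] + z_edges[-length(z_edges)]) / 2,
                 dz = mesh$L / (2L * mesh$nz),
                 nz = 2L * mesh$nz, nr = 2L * mesh$nr,
                 grading = mesh$grading, L = mesh$L),
            class = "contactor_mesh")
}

#' @export
print.contactor_mesh <- function(x, ...) {
  cat("Structured mesh:", paste(x$nr, collapse = " / "), "radial cells x",
      x$nz, "axial cells =", total_cells(x), "cells\n")
  invisible(x)
}

total_cells <- function(mesh) sum(mesh$nr) * mesh$nz
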