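test_that("mixing cup reduces to the plain value for uniform fields", {
  zone <- list(name = "tube", r_in = 0, r_out = 1e-4, D = 1e-9,
               profile = "poiseuille", geom_pars = list(r1 = 1e-4),
               v_mean = 0.5, v_sign = 1L, C_in = 4,
               inner_bc = list(type = "natural"),
               outer_bc = list(type = "natural"), refine_at = "end")
  pr <- membrex:::new_transport_problem(list(zone), list(), 0.05,
                                        meta = list(feed_zone = "tube",
                                                    solvent_zone = NULL))
  f <- solve_steady(pr, build_mesh(pr, 8, 10))
  expect_equal(mixing_cup(f, "feed"), 4, tolerance = 1e-12)
  expect_equal(mixing_cup(f, "feed", weighted = FALSE), 4, tolerance = 1e-12)
  # C = 0 everywhere
  zone$C_in <- 0
  pr0 <- membrex:::new_transport_problem(list(zone), list(), 0.05,
                                         meta = list(feed_zone = "tube",
                                                     solvent_zone = NULL))
  f0 <- solve_steady(pr0, build_mesh(pr0, 8, 10))
  expect_equal(mixing_cup(f0, "feed"), 0)
})

test_that("mixing cup of a linear radial profile matches fine quadrature", {
  gz <- graetz_problem(r1 = 1e-4, L = 0.1, D = 1e-9, v_mean = 0.5)
  mesh <- build_mesh(gz, 48, 10)
  f <- solve_steady(gz, mesh)
  # overwrite the outlet column with a synthetic linear C(r) = 1 + r/r1
  rc <- mesh$zones[[1]]$r_cent
  f$C[[1]][, mesh$nz] <- 1 + rc / 1e-4
  num <- integrate(function(r) (1 + r / 1e-4) *
                     tube_velocity(r, 0.5, 1e-4) * r, 0, 1e-4,
                   rel.tol = 1e-12)$value
  den <- integrate(function(r) tube_velocity(r, 0.5, 1e-4) * r, 0, 1e-4,
                   rel.tol = 1e-12)$value
  expect_equal(mixing_cup(f, "feed"), num / den, tolerance = 1e-3)
})

test_that("separation percent implements the outlet/inlet definition", {
  expect_equal(separation_percent(1e-4, 1e-4), 0)
  expect_equal(separation_percent(1e-4, 0), 100)
  expect_equal(separation_percent(5, 1), 80)
  expect_equal(separation_percent(1, -1e-12), 100)  # round-off clamp
  expect_error(separation_percent(1, 1.1), "broken")
  expect_error(separation_percent(0, 0), "C_inlet")
})

test_that("interface profile starts near C0 at the feed inlet and decays", {
  f <- solve_table1("IP", "feed_in_tube")
  prof <- interface_profile(f, "r1", side = "tube")
  expect_equal(nrow(prof), f$mesh$nz)
  # the first axial cell averages over the entrance singularity, so the
  # inlet-end sample sits below the C0 limit and climbs toward 1 as nz grows
  expect_gt(prof$C_hat[1], 0.85)
  expect_lte(max(prof$C_hat), 1 + 1e-10)
  expect_true(all(diff(prof$C_hat) < 0))  # monotone along the feed direction
  f2 <- solve_table1("IP", "feed_in_tube", nr = c(16, 8, 16), nz = 240)
  f3 <- solve_table1("IP", "feed_in_tube", nr = c(16, 8, 16), nz = 960)
  c1 <- interface_profile(f2, "r1", side = "tube")$C_hat[1]
  c2 <- interface_profile(f3, "r1", side = "tube")$C_hat[1]
  expect_true(prof$C_hat[1] < c1 && c1 < c2 && c2 < 1)
})

test_that("metabolite interface profile sits below the parent drug's", {
  p_ip <- interface_profile(solve_table1("IP", "feed_in_tube"), "r1", "tube")
  p_ib <- interface_profile(solve_table1("4-IBAP", "feed_in_tube"), "r1", "tube")
  expect_true(all(p_ib$C_hat <= p_ip$C_hat + 1e-12))
})

test_that("mass balance closes and tightens under refinement", {
  f <- solve_table1("IP", "feed_in_tube")
  res <- mass_balance_residual(f)
  expect_gte(res, 0)
  expect_lt(res, 5e-3)
  f2 <- solve_table1("IP", "feed_in_tube", nr = c(32, 16, 32), nz = 120)
  expect_lt(mass_balance_residual(f2), res)
})

test_that("CSV export round-trips decimal-representable values bit-exactly", {
  f <- solve_table1("IP", "feed_in_tube", nr = c(4, 3, 4), nz = 5)
  for (k in 1:3) f$C[[k]][] <- seq(0.5, by = 0.25,
                                   length.out = length(f$C[[k]]))
  path <- file.path(tempdir(), "field.csv")
  export_field(f, path, "csv")
  df <- read.csv(path)
  expect_equal(nrow(df), membrex:::total_cells(f$mesh))
  expect_identical(df$C[df$domain == "tube"], as.vector(f$C[[1]]))
  expect_identical(sort(unique(df$domain)), c("membrane", "shell", "tube"))
})

test_that("VTK export writes well-formed structured grids per domain", {
  f <- solve_table1("IP", "feed_in_tube", nr = c(4, 3, 4), nz = 5)
  paths <- export_field(f, file.path(tempdir(), "field.vtk"), "vtk")
  expect_length(paths, 3)
  for (k in seq_along(paths)) {
    expect_true(file.exists(paths[k]))
    lines <- readLines(paths[k])
    expect_identical(lines[1], "# vtk DataFile Version 3.0")
    expect_identical(lines[4], "DATASET STRUCTURED_GRID")
    n_pts <- f$mesh$zones[[k]]$nr * f$mesh$nz
    expect_identical(lines[5], sprintf("DIMENSIONS %d %d 1",
                                       f$mesh$zones[[k]]$nr, f$mesh$nz))
    vals <- as.numeric(utils::tail(lines, n_pts))
    expect_false(any(is.na(vals)))
    expect_equal(vals, as.vector(f$C[[k]]), tolerance = 1e-9)
  }
})

test_that("separation summary collects the reported quantities consistently", {
  f <- solve_table1("IP", "feed_in_tube")
  s <- separation_summary(f)
  expect_identical(s$solute, "IP")
  expect_identical(s$configuration, "feed_in_tube")
  expect_equal(s$separation_percent,
               100 * (1 - s$C_outlet / s$C_inlet))
  expect_true(s$separation_percent >= 0 && s$separation_percent <= 100)
  expect_gte(s$mass_balance_residual, 0)
})
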