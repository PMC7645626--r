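test_that("packing fraction matches direct arithmetic and rejects misfits", {
  expect_equal(packing_fraction(0, 1.5e-4, 0.0315), 0)
  expect_equal(packing_fraction(4, 1, 2), 1)  # n r2^2 == R^2: full packing
  # independent one-line evaluation of the bundle fraction
  expect_equal(packing_fraction(9950, 1.5e-4, 0.0315),
               9950 * (1.5e-4)^2 / 0.0315^2)
  expect_error(packing_fraction(5, 1, 2), "do not fit")
  expect_error(packing_fraction(10, -1e-4, 0.03), "r2")
  expect_error(packing_fraction(-1, 1e-4, 0.03), "n")
})

test_that("Happel free-surface radius: printed value, closed form, root-finding", {
  r3 <- happel_shell_radius(1.5e-4, 9950, 0.0315)
  expect_equal(signif(r3, 4), 3.158e-4)
  expect_gt(r3, 1.5e-4)
  # quarter packing gives exactly twice the fiber radius
  expect_equal(happel_shell_radius(1, 1, 2), 2)
  # brute-force root of r3^2 * (n r2^2 / R^2) = r2^2 as an independent oracle
  f <- function(x) x^2 * (9950 * (1.5e-4)^2 / 0.0315^2) - (1.5e-4)^2
  root <- uniroot(f, c(1.5e-4, 0.0315), tol = 1e-15)$root
  expect_equal(r3, root, tolerance = 1e-9)
  expect_error(happel_shell_radius(1.5e-4, 0, 0.0315), "zero")
})

test_that("Happel radius is monotone in fiber count and module radius", {
  ns <- c(100, 1000, 5000, 9950, 20000)
  r3n <- vapply(ns, function(n) happel_shell_radius(1.5e-4, n, 0.0315), 0)
  expect_true(all(diff(r3n) < 0))
  Rs <- c(0.02, 0.0315, 0.05, 0.08)
  r3R <- vapply(Rs, function(R) happel_shell_radius(1.5e-4, 9950, R), 0)
  expect_true(all(diff(r3R) > 0))
})

test_that("mean velocities invert the per-fiber flow definition", {
  geom <- table1_geom()
  Q1 <- geom$n * pi * geom$r1^2 * 1.0  # makes the tube mean exactly 1 m/s
  v <- mean_velocities(flow_spec(Q1, lpm(50)), geom)
  expect_equal(v[["tube"]], 1.0)
  v2 <- mean_velocities(flow_spec(2 * Q1, lpm(50)), geom)
  expect_equal(v2[["tube"]], 2 * v[["tube"]])
  # canonical operating point, cross-checked by independent arithmetic
  v50 <- mean_velocities(flow_spec(lpm(50), lpm(50)), geom)
  expect_equal(v50[["tube"]], (50 / 6e4 / 9950) / (pi * 1.1e-4^2))
  expect_equal(v50[["shell"]],
               (50 / 6e4 / 9950) / (pi * (geom$r3^2 - 1.5e-4^2)))
  # configuration swaps which stream is in the tube
  va <- mean_velocities(flow_spec(lpm(10), lpm(50), "feed_in_shell"), geom)
  expect_equal(va[["shell"]],
               (10 / 6e4 / 9950) / (pi * (geom$r3^2 - 1.5e-4^2)))
})

test_that("tube profile: centerline max, no slip, exact mean by quadrature", {
  r1 <- 1.1e-4
  expect_equal(tube_velocity(0, 0.7, r1), 1.4)
  expect_equal(tube_velocity(r1, 0.7, r1), 0)
  Q <- integrate(function(r) 2 * pi * r * tube_velocity(r, 0.7, r1),
                 0, r1, rel.tol = 1e-13)$value
  expect_equal(Q, pi * r1^2 * 0.7, tolerance = 1e-10)
  expect_error(tube_velocity(1.2 * r1, 0.7, r1), "outside")
})

test_that("shell profile: no slip at r2, free surface at r3, exact mean", {
  r2 <- 1.5e-4; r3 <- 3.158e-4; vm <- 0.35
  expect_equal(shell_velocity(r2, vm, r2, r3), 0)
  h <- 1e-10
  dVdr <- (shell_velocity(r3, vm, r2, r3) -
             shell_velocity(r3 - h, vm, r2, r3)) / h
  # zero-shear free surface: slope tiny relative to the interior scale
  expect_lt(abs(dVdr), abs(vm / (r3 - r2)) * 1e-4)
  Q <- integrate(function(r) 2 * pi * r * shell_velocity(r, vm, r2, r3),
                 r2, r3, rel.tol = 1e-13)$value
  expect_equal(Q, pi * (r3^2 - r2^2) * vm, tolerance = 1e-10)
  expect_error(shell_velocity(r2 / 2, vm, r2, r3), "outside")
})

test_that("velocity profiles are non-negative, vanishing only at no-slip walls", {
  for (pars in list(c(1e-4, 2e-4), c(1.5e-4, 3.158e-4), c(2e-4, 8e-4))) {
    r2 <- pars[1]; r3 <- pars[2]
    r <- seq(r2 + 1e-9, r3, length.out = 200)
    expect_true(all(shell_velocity(r, 1, r2, r3) > 0))
  }
  r <- seq(0, 1.1e-4 - 1e-9, length.out = 200)
  expect_true(all(tube_velocity(r, 1, 1.1e-4) > 0))
})

test_that("Reynolds diagnostics confirm the laminar assumption at 50 L/min", {
  geom <- table1_geom()
  Re <- reynolds_numbers(flow_spec(lpm(50), lpm(50)), geom)
  expect_true(all(Re > 0))
  expect_true(all(Re < 2100))
})

test_that("geometry and flow constructors enforce their invariants", {
  expect_error(contactor_geometry(1.5e-4, 1.1e-4, 0.0315, 0.15, 9950), "r1")
  expect_error(contactor_geometry(1.1e-4, 1.5e-4, 0.0315, -1, 9950), "length")
  expect_error(flow_spec(-1, 1), "Q_aq")
  expect_error(flow_spec(lpm(50), lpm(50), arrangement = "co_current"))
  expect_error(fluid_properties(0, 1e-3), "> 0")
})
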