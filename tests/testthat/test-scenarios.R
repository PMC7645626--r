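test_that("canonical cases carry the shipped physicochemical constants", {
  ip <- table1_case("IP")
  expect_equal(ip$solute$m, 31.62)
  expect_equal(ip$solute$D_aq, 7.17e-10)
  expect_equal(ip$solute$C0, 1e-4)
  ib <- table1_case("4-IBAP", "feed_in_shell")
  expect_equal(ib$solute$m, 37.15)
  expect_equal(ib$solute$D_org, 1.56e-10)
  g <- ip$problem$geometry
  expect_equal(c(g$r1, g$r2, g$R_module, g$L, g$n),
               c(1.1e-4, 1.5e-4, 0.0315, 0.15, 9950))
  expect_equal(signif(g$r3, 4), 3.158e-4)
  expect_error(table1_case("aspirin"), "arg")
  expect_error(table1_case("IP", overrides = list(bogus = 1)), "unknown")
})

test_that("sweeps tabulate one converged solve per value and stay ordered", {
  base <- table1_case("IP")
  res <- sweep(base, "Q_aq", lpm(c(20, 35, 50)), nr = c(10, 5, 10), nz = 30)
  expect_s3_class(res, "sweep_result")
  expect_equal(nrow(res), 3)
  expect_true(all(diff(res$value) > 0))
  expect_true(all(diff(res$C_outlet) > 0))  # residence-time effect
  expect_error(sweep(base, "Q_aq", lpm(c(50, 20))), "strictly increasing")
  expect_error(sweep(base, "viscosity", 1:3), "arg")
})

test_that("a failing sweep member aborts with partial results attached", {
  base <- table1_case("IP")
  # the last fiber count cannot fit in the module: packing fraction > 1
  err <- tryCatch(
    sweep(base, "n_fibers", c(5000, 9950, 9e5), nr = c(8, 4, 8), nz = 20),
    membrex_sweep_error = function(e) e)
  expect_s3_class(err, "membrex_sweep_error")
  expect_equal(nrow(err$partial), 2)
})

test_that("metabolite-over-parent ordering holds at every swept flow rate", {
  for (sol in c("IP", "4-IBAP")) assign(paste0("s_", sol),
    sweep(table1_case(sol), "Q_aq", lpm(c(15, 30, 50)),
          nr = c(10, 5, 10), nz = 30))
  expect_true(all(s_IP$C_outlet > `s_4-IBAP`$C_outlet))
})

test_that("separation approaches complete removal as the feed slows down", {
  base <- table1_case("IP")
  res <- sweep(base, "Q_aq", lpm(c(0.5, 2, 10, 50)), nr = c(10, 5, 10), nz = 30)
  expect_true(all(diff(res$separation_percent) < 0))
  expect_gt(res$separation_percent[1], res$separation_percent[4])
})

test_that("configuration comparison runs both arrangements at identical conditions", {
  cmpr <- compare_configurations("IP", nr = c(10, 5, 10), nz = 30)
  expect_equal(nrow(cmpr), 2)
  expect_identical(cmpr$configuration, c("feed_in_tube", "feed_in_shell"))
  expect_equal(attr(cmpr, "shell_minus_tube"),
               cmpr$separation_percent[2] - cmpr$separation_percent[1])
  expect_true(all(cmpr$separation_percent > 0))
})

test_that("a well-mixed symmetric surrogate separates equally in both arrangements", {
  # fast diffusion + m = 1 + open membrane: film resistances vanish, so the
  # arrangement cannot matter beyond discretization error
  ov <- list(m = 1, D_aq = 1e-7, D_org = 1e-7, porosity = 1, tortuosity = 1)
  seps <- vapply(c("feed_in_tube", "feed_in_shell"), function(cfg) {
    f <- solve_table1("IP", cfg, ov)
    separation_percent(1e-4, mixing_cup(f, "feed"))
  }, 0)
  expect_equal(seps[[1]], seps[[2]], tolerance = 1e-3)
})

test_that("reruns are byte-identical: the model has no stochastic component", {
  r1 <- sweep(table1_case("IP"), "porosity", c(0.3, 0.5),
              nr = c(8, 4, 8), nz = 20)
  r2 <- sweep(table1_case("IP"), "porosity", c(0.3, 0.5),
              nr = c(8, 4, 8), nz = 20)
  expect_identical(r1, r2)
})

test_that("CLI run writes a summary and fails cleanly on bad input", {
  out <- file.path(tempdir(), "cli_run")
  cfgf <- file.path(tempdir(), "case.json")
  jsonlite::write_json(list(
    flows = list(Q_aq_lpm = 50, Q_org_lpm = 50, configuration = "feed_in_tube"),
    numerics = list(nr = c(8, 4, 8), nz = 20)), cfgf, auto_unbox = TRUE)
  status <- run_cli(c("run", "--config", cfgf, "--solute", "IP",
                      "--out", out))
  expect_identical(status, 0L)
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_identical(summ$solute, "IP")
  expect_true(summ$separation_percent > 0)
  # determinism: a second run reproduces the summary byte-for-byte
  file.copy(file.path(out, "summary.json"), file.path(out, "first.json"))
  run_cli(c("run", "--config", cfgf, "--solute", "IP", "--out", out))
  expect_identical(readLines(file.path(out, "summary.json")),
                   readLines(file.path(out, "first.json")))
  # malformed config and unknown subcommand exit non-zero
  bad <- file.path(tempdir(), "bad.json")
  writeLines("{not json", bad)
  expect_identical(suppressMessages(
    run_cli(c("run", "--config", bad))), 1L)
  expect_identical(suppressMessages(run_cli("frobnicate")), 1L)
  expect_identical(suppressMessages(run_cli(c("run", "--config"))), 1L)
})

test_that("CLI sweep writes one CSV row per value per solute", {
  out <- file.path(tempdir(), "cli_sweep")
  status <- run_cli(c("sweep", "--param", "Q_aq", "--values", "20,35,50",
                      "--nr", "8,4,8", "--nz", "20", "--out", out))
  expect_identical(status, 0L)
  for (sol in c("IP", "4IBAP")) {
    df <- read.csv(file.path(out, sprintf("sweep_Q_aq_%s.csv", sol)))
    expect_equal(nrow(df), 3)
    expect_true(all(c("value", "C_outlet", "separation_percent") %in%
                      names(df)))
  }
})

test_that("shipped YAML and JSON configs parse to the same case", {
  yml <- system.file("extdata", "table1.yaml", package = "membrex")
  jsn <- system.file("extdata", "table1.json", package = "membrex")
  skip_if(yml == "" || !requireNamespace("yaml", quietly = TRUE),
          "yaml fixture or package unavailable")
  c1 <- membrex:::case_from_config(membrex:::read_config(yml))
  c2 <- membrex:::case_from_config(membrex:::read_config(jsn))
  expect_equal(c1$params, c2$params)
  expect_equal(c1$solute, c2$solute)
})
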