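# Shared solve cache: several test files interrogate the same solved cases;
# the model is deterministic, so memoizing is safe and keeps the suite fast.
.membrex_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .membrex_test_cache))
    assign(key, force(expr), envir = .membrex_test_cache)
  get(key, envir = .membrex_test_cache)
}

solve_table1 <- function(solute = "IP", configuration = "feed_in_tube",
                         overrides = list(), nr = c(16, 8, 16), nz = 60) {
  key <- paste(solute, configuration,
               paste(names(overrides), unlist(overrides), collapse = "_"),
               paste(nr, collapse = "-"), nz, sep = "|")
  cached(key, {
    case <- table1_case(solute, configuration, overrides)
    solve_steady(case$problem, build_mesh(case$problem, nr, nz))
  })
}

test_oracle <- function(n_r = 500L) cached(paste0("graetz_oracle_", n_r),
                                           graetz_oracle(n_r))

table1_geom <- function() contactor_geometry(1.1e-4, 1.5e-4, 0.0315, 0.15, 9950)
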