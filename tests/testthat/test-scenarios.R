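small_cfg <- function(seed = 101, ...) {
  scenario_config(LET = 0.3, n_histories = 3, n_spurs = 10, seed = seed, ...)
}

test_that("scenario configuration picks geometry and defaults from LET", {
  a <- scenario_config(LET = 0.3)
  expect_equal(a$geometry, "spur-line")
  b <- scenario_config(LET = 25)
  expect_equal(b$geometry, "cylinder")
  expect_equal(b$length_um, 1)
  d <- scenario_config(LET = 72)
  expect_equal(d$length_um, 0.5)
  e <- scenario_config(proton_energy_MeV = 1)
  expect_equal(e$LET, 25)
  expect_error(scenario_config(LET = -1))
})

test_that("scenario runs are bit-identical under a fixed seed", {
  cfg <- small_cfg()
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$per_history, r2$per_history)
  ## a different seed gives a different realisation
  r3 <- run_scenario(small_cfg(seed = 102))
  expect_false(identical(r1$per_history$G_Fe3_100s, r3$per_history$G_Fe3_100s))
})

test_that("merged series is continuous at hand-off and spans 1 ps to t_end", {
  r <- run_scenario(small_cfg())
  s <- r$series
  expect_equal(s$time[1], 1e-12)
  expect_equal(s$time[nrow(s)], 200, tolerance = 1e-9)
  expect_true(all(diff(s$time) > 0))
  ## H2 is frozen across the bulk stage: constant after hand-off
  i <- which(s$time >= 1e-6)
  expect_equal(max(s$H2[i]) - min(s$H2[i]), 0, tolerance = 1e-12)
  ## ferric yield is non-decreasing through both stages
  expect_true(all(diff(s$Fe3p) >= -1e-9))
  ## channel tags stay additive after the merge
  expect_equal(s$Fe3p_OH + s$Fe3p_HO2 + s$Fe3p_H2O2, s$Fe3p,
               tolerance = 1e-9)
})

test_that("summary row and reference matching", {
  r <- run_scenario(small_cfg())
  tab <- summarize_scenarios(r)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$reference, 15.35)
  expect_true(is.finite(tab$rel_dev))
  ## non-standard acid has no tabulated reference
  r2 <- run_scenario(small_cfg(acid_molarity = 0.05))
  expect_true(is.na(summarize_scenarios(r2)$reference))
})

test_that("per-history standard error is propagated", {
  r <- run_scenario(small_cfg())
  expect_equal(r$summary$stderr,
               sd(r$per_history$G_Fe3_100s) / sqrt(3), tolerance = 1e-12)
})

test_that("series CSV is written in long format", {
  r <- run_scenario(small_cfg())
  tf <- tempfile(fileext = ".csv")
  write_series_csv(r, tf)
  d <- read.csv(tf)
  expect_named(d, c("scenario_id", "time_s", "species", "G"))
  expect_true("Fe3p" %in% d$species)
  expect_equal(nrow(d), (ncol(r$series) - 1) * nrow(r$series))
})

test_that("preset grids cover the documented conditions", {
  ## escape_profiles: deaerated, no solutes, truncated shortly after hand-off
  rep <- reproduce_figure("escape_profiles", seed = 3, n_histories = 2)
  expect_length(rep$results, 2)
  expect_setequal(vapply(rep$results, function(r) r$config$acid_molarity,
                         numeric(1)), c(0.4, 0.05))
  for (r in rep$results) {
    expect_equal(r$config$o2_molarity, 0)
    expect_equal(r$config$fe2_molarity, 0)
    expect_equal(max(r$series$time), 2e-6, tolerance = 1e-9)
    expect_equal(max(r$series$Fe3p), 0)
  }
  ## no reference rows for the deaerated condition
  expect_true(all(is.na(rep$summary$reference)))
})
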