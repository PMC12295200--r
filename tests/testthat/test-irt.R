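## a system with the real kinetics but no background solutes, so pair
## statistics are not confounded by scavenging
no_scavenging_system <- function() {
  sys <- build_fricke_system(0.4, 0, 0)
  sys$background[] <- 0
  frickesim:::.refresh_kinetics(sys)
}

test_that("ultimate reaction probability is geometric times alpha", {
  expect_equal(ultimate_reaction_probability(1e-9, 0.5e-9), 0.5)
  expect_equal(ultimate_reaction_probability(0.4e-9, 0.5e-9), 1)
  p <- ultimate_reaction_probability(1e-9, 0.5e-9, "partial",
                                     k_act = 5e9, D_rel = 5e-9)
  v <- 5e9 / (4 * pi * (0.5e-9)^2 * 6.02214076e23 * 1000)
  alpha <- v * 0.5e-9 / (5e-9 + v * 0.5e-9)
  expect_equal(p, 0.5 * alpha, tolerance = 1e-12)
})

test_that("fully controlled pair times follow the analytic kernel", {
  set.seed(21)
  R <- 0.5e-9; r0 <- 1.5e-9; D <- 5e-9
  ts <- sample_pair_time(40000, r0, R, D)
  winf <- R / r0
  expect_lt(abs(mean(is.finite(ts)) - winf),
            4 * sqrt(winf * (1 - winf) / 40000))
  for (t in c(1e-11, 1e-10, 1e-9)) {
    ## W(t) = winf * erfc((r0 - R) / sqrt(4 D t))
    w <- winf * frickesim:::.pair_cdf(t, r0 - R, 0, D)
    emp <- mean(ts <= t)
    expect_lt(abs(emp - w), 4 * sqrt(w * (1 - w) / 40000) + 1e-4)
  }
})

test_that("radiation-boundary pair times follow the analytic kernel", {
  set.seed(22)
  R <- 0.45e-9; r0 <- 0.9e-9; D <- 8e-9; k_act <- 9e9
  ts <- sample_pair_time(40000, r0, R, D, control = "partial", k_act = k_act)
  winf <- ultimate_reaction_probability(r0, R, "partial", k_act, D)
  v <- k_act / (4 * pi * R^2 * 6.02214076e23 * 1000)
  gam <- 1 / R + v / D
  for (t in c(5e-11, 2e-10, 1e-9)) {
    w <- winf * frickesim:::.pair_cdf(t, r0 - R, gam, D)
    emp <- mean(ts <= t)
    expect_lt(abs(emp - w), 3 * sqrt(w * (1 - w) / 40000) + 1e-4)
  }
})

test_that("engine reproduces single-pair reaction probabilities", {
  sys <- no_scavenging_system()
  tb <- frickesim:::build_irt_tables(sys)
  npair <- function(d, n) {
    mean(replicate(n, {
      ev <- run_irt(d, sys, t_handoff = 1e-7, tables = tb)$events
      sum(ev$kind == 0) > 0
    }))
  }
  ## fully controlled cross pair: e_aq + OH at r0 = 2 R
  r <- sys$reactions["e_OH", ]
  set.seed(23)
  p1 <- npair(pair_distribution(c("e_aq", "OH"), c(0, 2 * r$R_eff * 1e9)),
              3000)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 3000))
  ## partially controlled self pair: OH + OH uses the doubled partition
  r2 <- sys$reactions["OH_OH", ]
  a2 <- r2$k_act_pair / (r2$k_act_pair + r2$k_diff)
  set.seed(24)
  p2 <- npair(pair_distribution(c("OH", "OH"), c(0, 2 * r2$R_eff * 1e9)),
              3000)
  expect_lt(abs(p2 - 0.5 * a2), 3 * sqrt(0.25 / 3000))
})

test_that("IRT matches a Brownian-dynamics oracle on a two-particle system", {
  sys <- no_scavenging_system()
  r <- sys$reactions["H_OH", ]
  r0 <- 2 * r$R_eff; t_obs <- 2e-10
  set.seed(25)
  bd <- bd_pair_probability(r0, r$R_eff, r$D_rel, t_obs, n = 20000,
                            dt = 4e-14, control = "partial",
                            k_act = r$k_act_pair)
  pos <- cbind(c(0, r0 * 1e9), 0, 0)
  irt <- irt_multi_first_reaction(sys, c("H", "OH"), pos, t_obs, n = 6000)
  se <- sqrt(bd$se^2 + irt * (1 - irt) / 6000)
  ## 3 SE plus a 2% allowance for the O(sqrt(dt)) boundary bias of the oracle
  expect_lt(abs(bd$p - irt), 3 * se + 0.02 * bd$p)
})

test_that("IRT matches the Brownian oracle on a three-particle system", {
  sys <- no_scavenging_system()
  ## H + OH + OH triangle at moderate separations
  pos <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0.6, 1.1, 0))
  t_obs <- 1.5e-10
  set.seed(26)
  bd <- bd_multi_first_reaction(sys, c("H", "OH", "OH"), pos, t_obs,
                                dt = 5e-14, n = 6000)
  irt <- irt_multi_first_reaction(sys, c("H", "OH", "OH"), pos, t_obs,
                                  n = 6000)
  se <- sqrt(bd * (1 - bd) / 6000 + irt * (1 - irt) / 6000)
  expect_lt(abs(bd - irt), 3 * se + 0.02 * max(bd, irt))
})

test_that("time dilation is exact for diffusion-only chemistry", {
  sys1 <- fully_controlled_system()
  sys2 <- apply_viscosity(sys1, 10)
  p <- spur_parameters()
  set.seed(27)
  d <- sample_spur_ensemble(p, 8, spacing = p$mean_spur_energy / 0.3)
  set.seed(28)
  r1 <- run_irt(d, sys1, t_handoff = 1e-6)
  set.seed(28)
  r2 <- run_irt(d, sys2, t_handoff = 1e-5)
  expect_identical(r1$events$rid, r2$events$rid)
  expect_identical(r1$events$kind, r2$events$kind)
  expect_identical(r1$events$survivors, r2$events$survivors)
  expect_equal(r2$events$t, r1$events$t * 10, tolerance = 1e-12)
})

test_that("track series conserve elements and charge at every time", {
  set.seed(29)
  sys <- build_fricke_system(0.4, 1e-3, 2.5e-4)
  p <- spur_parameters()
  d <- sample_spur_ensemble(p, 20, spacing = p$mean_spur_energy / 0.3)
  r <- run_irt(d, sys, t_handoff = 1e-6)
  comp <- series_composition(r$series, sys$species)
  for (col in colnames(comp)) {
    drift <- max(abs(comp[, col] - comp[1, col]))
    expect_lt(drift, 1e-9 * max(1, abs(comp[1, col])))
  }
  ## ferric production is cumulative and channel-additive
  fe <- r$series$Fe3p
  expect_true(all(diff(fe) >= -1e-12))
  chan_sum <- r$series$Fe3p_OH + r$series$Fe3p_HO2 + r$series$Fe3p_H2O2
  expect_equal(chan_sum, fe, tolerance = 1e-9)
})

test_that("IRT histories are reproducible under a fixed seed", {
  sys <- build_fricke_system(0.4, 1e-3, 2.5e-4)
  p <- spur_parameters()
  run_once <- function() {
    set.seed(30)
    d <- sample_spur_ensemble(p, 10, spacing = p$mean_spur_energy / 0.3)
    run_irt(d, sys, t_handoff = 1e-6)
  }
  r1 <- run_once(); r2 <- run_once()
  expect_identical(r1$series, r2$series)
  expect_identical(r1$events, r2$events)
})

test_that("escape and hand-off inventories are consistent with the series", {
  set.seed(31)
  sys <- build_fricke_system(0.4, 1e-3, 2.5e-4)
  p <- spur_parameters()
  d <- sample_spur_ensemble(p, 10, spacing = p$mean_spur_energy / 0.3)
  r <- run_irt(d, sys, t_handoff = 1e-6, escape_time = 2e-7)
  i <- max(which(r$series$time <= 2e-7))
  expect_equal(unclass(r$escape)[["OH"]], r$series$OH[i], tolerance = 1e-12)
  expect_equal(r$handoff[["H2"]], r$series$H2[nrow(r$series)],
               tolerance = 1e-12)
  expect_error(run_irt(d, sys, t_handoff = 1e-8), "coalescence")
})

test_that("scavenging times are exponential with the observed rate", {
  set.seed(32)
  ts <- sample_scavenging_time(3.4e8, 1e-3, 20000)
  expect_equal(mean(ts), 1 / (3.4e8 * 1e-3), tolerance = 0.03)
  expect_identical(sample_scavenging_time(3.4e8, 0, 3), rep(Inf, 3))
})
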