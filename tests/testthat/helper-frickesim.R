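## Shared test helpers.

## two- or three-particle initial distribution at explicit positions (nm)
pair_distribution <- function(species, x, y = 0, z = 0, energy_eV = 100) {
  structure(list(
    particles = data.frame(species = species, x = x,
                           y = rep_len(y, length(species)),
                           z = rep_len(z, length(species)),
                           stringsAsFactors = FALSE),
    deposited_energy = energy_eV, geometry = "custom",
    length_um = NA_real_, periodic = FALSE, LET = NA_real_
  ), class = "initial_distribution")
}

## a chem_system stripped to pure diffusion-controlled pair chemistry:
## every reaction fully controlled, no background solutes (no scavenging).
## Used for exact-symmetry tests of the IRT engine.
fully_controlled_system <- function() {
  sys <- build_fricke_system(0.4, 0, 0)
  rx <- sys$reactions
  rx$control <- "fully"
  rx$k_act <- Inf
  rx$k_act_pair <- Inf
  sys$reactions <- rx
  sys$background[] <- 0
  frickesim:::.refresh_kinetics(sys)
}

## composition-weighted totals (H, O, S, Fe, charge) of one series row,
## counting simulated species, counters, implicit water and the bulk
## bookkeeping columns
series_composition <- function(series, species_table) {
  comp <- function(name) frickesim:::.composition(species_table, name)
  cols <- setdiff(names(series),
                  c("time", "Fe3p_OH", "Fe3p_HO2", "Fe3p_H2O2"))
  out <- matrix(0, nrow(series), 5,
                dimnames = list(NULL, c("H", "O", "S", "Fe", "charge")))
  for (cn in cols) {
    sp <- sub("^bulk_", "", cn)
    out <- out + outer(series[[cn]], comp(sp))
  }
  out
}

## brute-force Brownian dynamics for 2-3 particles with the full pairwise
## reaction table of `sys`; returns fraction of replicas with >= 1 reaction
## by t_max (first reaction only, matching a single IRT event)
bd_multi_first_reaction <- function(sys, species, pos_nm, t_max, dt,
                                    n = 8000) {
  tb <- frickesim:::build_irt_tables(sys)
  np <- length(species)
  spi <- match(species, tb$sim)
  D <- tb$D[spi]
  pos <- lapply(seq_len(np), function(i) {
    list(x = rep(pos_nm[i, 1] * 1e-9, n),
         y = rep(pos_nm[i, 2] * 1e-9, n),
         z = rep(pos_nm[i, 3] * 1e-9, n))
  })
  pairs <- list()
  for (i in 1:(np - 1)) for (j in (i + 1):np) {
    rid <- tb$pair_rid[spi[i], spi[j]]
    if (rid > 0) {
      r <- rid
      v <- if (tb$ctrl[r] == 0) Inf else
        (tb$alpha[r] / (1 - tb$alpha[r])) * tb$Drel[r] / tb$Reff[r]
      pairs[[length(pairs) + 1]] <-
        list(i = i, j = j, R = tb$Reff[r],
             p_abs = if (is.infinite(v)) 1 else
               min(1, v * sqrt(pi * dt / tb$Drel[r])))
    }
  }
  done <- logical(n)
  nstep <- ceiling(t_max / dt)
  for (k in seq_len(nstep)) {
    live <- which(!done)
    if (!length(live)) break
    m <- length(live)
    for (i in seq_len(np)) {
      s <- sqrt(2 * D[i] * dt)
      pos[[i]]$x[live] <- pos[[i]]$x[live] + rnorm(m, 0, s)
      pos[[i]]$y[live] <- pos[[i]]$y[live] + rnorm(m, 0, s)
      pos[[i]]$z[live] <- pos[[i]]$z[live] + rnorm(m, 0, s)
    }
    for (p in pairs) {
      live <- which(!done)
      if (!length(live)) break
      dx <- pos[[p$i]]$x[live] - pos[[p$j]]$x[live]
      dy <- pos[[p$i]]$y[live] - pos[[p$j]]$y[live]
      dz <- pos[[p$i]]$z[live] - pos[[p$j]]$z[live]
      rr <- sqrt(dx^2 + dy^2 + dz^2)
      inside <- rr < p$R
      if (any(inside)) {
        idx <- live[inside]
        hit <- if (p$p_abs >= 1) rep(TRUE, length(idx)) else
          runif(length(idx)) < p$p_abs
        done[idx[hit]] <- TRUE
        ## survivors: mirror the relative coordinate at the contact sphere
        ## (r -> 2R - r), the scheme the absorption constant is derived for
        refl <- idx[!hit]
        if (length(refl)) {
          sel <- match(refl, live)
          corr <- 2 * (p$R - rr[sel]) / rr[sel]
          for (ax in c("x", "y", "z")) {
            d <- pos[[p$i]][[ax]][refl] - pos[[p$j]][[ax]][refl]
            pos[[p$i]][[ax]][refl] <- pos[[p$i]][[ax]][refl] + d * corr / 2
            pos[[p$j]][[ax]][refl] <- pos[[p$j]][[ax]][refl] - d * corr / 2
          }
        }
      }
    }
  }
  mean(done)
}

## IRT estimate of the same observable (>= 1 pair event by t_max)
irt_multi_first_reaction <- function(sys, species, pos_nm, t_max, n = 4000) {
  tb <- frickesim:::build_irt_tables(sys)
  d <- pair_distribution(species, pos_nm[, 1])
  d$particles$y <- pos_nm[, 2]
  d$particles$z <- pos_nm[, 3]
  hits <- replicate(n, {
    ev <- run_irt(d, sys, t_handoff = max(t_max, 1e-7), tables = tb)$events
    any(ev$kind == 0 & ev$t <= t_max)
  })
  mean(hits)
}
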