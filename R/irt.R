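## IRT module: stochastic engine for the nonhomogeneous stage (1 ps ->
## hand-off). The per-history event loop runs in compiled code
## (src/irt_engine.cpp); this file builds the engine tables from a
## `chem_system`, exposes the sampling kernels at the R level, and turns
## event logs into yield time series.

## species that can exist as discrete particles in the track stage
.SIM_SPECIES <- c("e_aq", "H3Op", "H", "H2", "OH", "H2O2", "HO2", "O2", "SO4rm")
## counted products that do not diffuse/react further in the track stage
.COUNTER_SPECIES <- c("Fe3p", "SO4m2", "S2O8m2")
## background solutes that scavenge pseudo-first-order
.BULK_SPECIES <- c("H3Op", "HSO4m", "Fe2p", "O2")
## reactions whose commitment oxidises one Fe2+ (ferric bookkeeping)
.FE3_RIDS <- c("OH_Fe2p", "HO2_Fe2p", "H2O2_Fe2p", "SO4_Fe2p")

#' Default logarithmic output time grid
#'
#' Ten points per decade from 1 ps to 200 s.
#' @param t_min,t_max Grid limits (s).
#' @return Numeric vector of times (s), strictly increasing.
#' @export
yield_time_grid <- function(t_min = 1e-12, t_max = 200) {
  g <- 10^seq(log10(t_min), log10(t_max), by = 0.1)
  if (g[length(g)] < t_max) g <- c(g, t_max)
  g
}

## resolve a product list to (<=1) surviving diffusing species + counters +
## implicit-water/bulk bookkeeping, applying the instant acid-side transforms
.resolve_products <- function(products, transforms) {
  surv <- character(0); counters <- character(0)
  h2o <- 0L; h3op_bulk <- 0L
  for (p in products) {
    i <- match(p, transforms$from)
    if (!is.na(i)) {
      h3op_bulk <- h3op_bulk + 1L
      h2o <- h2o + transforms$water[i]
      p <- transforms$to[i]
      if (is.na(p)) next
    }
    if (p %in% .SIM_SPECIES) surv <- c(surv, p)
    else if (p %in% .COUNTER_SPECIES) counters <- c(counters, p)
    else if (p == "H2O") h2o <- h2o + 1L
    else stop("unresolvable product species: ", p)
  }
  if (length(surv) > 1) stop("more than one diffusing product")
  list(survivor = if (length(surv)) surv else NA_character_,
       counters = counters, h2o = h2o, h3op_bulk = h3op_bulk)
}

## Build the flat tables consumed by the compiled engine, plus the
## per-event stoichiometric delta matrices used for bookkeeping.
## Cached on the system object by run_irt().
build_irt_tables <- function(system) {
  rx <- system$reactions
  sp <- system$species
  sim <- .SIM_SPECIES
  ns <- length(sim)
  D <- sp[sim, "D"]

  nr <- nrow(rx)
  ## the pair kernel uses the pairwise partition (doubled for self-pairs)
  ctrl <- ifelse(rx$control == "fully", 0L, 1L)
  v <- ifelse(is.infinite(rx$k_act_pair), Inf,
              rx$k_act_pair / (4 * pi * rx$R_eff_pair^2 * .N_A * 1000))
  alpha <- ifelse(is.infinite(rx$k_act_pair), 1,
                  v * rx$R_eff_pair / (rx$D_rel + v * rx$R_eff_pair))
  gamma <- ifelse(is.infinite(rx$k_act_pair), 0,
                  1 / rx$R_eff_pair + v / rx$D_rel)

  pair_rid <- matrix(0L, ns, ns, dimnames = list(sim, sim))
  for (i in seq_len(nr)) {
    if (rx$r1[i] %in% sim && rx$r2[i] %in% sim) {
      pair_rid[rx$r1[i], rx$r2[i]] <- i
      pair_rid[rx$r2[i], rx$r1[i]] <- i
    }
  }

  resolved <- lapply(rx$products, .resolve_products,
                     transforms = system$instant_transforms)
  prod_sp <- vapply(resolved, function(r) {
    if (is.na(r$survivor)) 0L else match(r$survivor, sim)
  }, integer(1))

  ## scavenging channels: reactions pairing a simulated species with a
  ## background solute at positive concentration
  scav_sp <- integer(0); scav_rate <- numeric(0); scav_rid <- integer(0)
  for (i in seq_len(nr)) {
    for (ord in list(c(rx$r1[i], rx$r2[i]), c(rx$r2[i], rx$r1[i]))) {
      if (ord[1] %in% sim && ord[2] %in% .BULK_SPECIES && ord[1] != ord[2]) {
        conc <- system$background[[ord[2]]]
        if (!is.null(conc) && conc > 0) {
          scav_sp <- c(scav_sp, match(ord[1], sim))
          scav_rate <- c(scav_rate, rx$k_obs[i] * conc)
          scav_rid <- c(scav_rid, i)
        }
      }
    }
  }

  ## stoichiometric deltas per committed event
  entities <- c(sim, .COUNTER_SPECIES, "H2O",
                paste0("bulk_", .BULK_SPECIES))
  delta_pair <- matrix(0, nr, length(entities),
                       dimnames = list(rx$id, entities))
  delta_scav <- delta_pair
  for (i in seq_len(nr)) {
    r <- resolved[[i]]
    add <- function(m, col, val) { m[i, col] <- m[i, col] + val; m }
    for (m in c("pair", "scav")) {
      d <- if (m == "pair") delta_pair else delta_scav
      ## reactants
      if (m == "pair") {
        for (rr in c(rx$r1[i], rx$r2[i])) {
          if (rr %in% sim) d[i, rr] <- d[i, rr] - 1
        }
      } else {
        ## bulk partner: the reactant that is a background solute; reactions
        ## without one can never fire as scavenging events
        bulk <- intersect(c(rx$r1[i], rx$r2[i]), .BULK_SPECIES)
        if (length(bulk) == 0) next
        bulk <- bulk[1]
        other <- setdiff(c(rx$r1[i], rx$r2[i]), bulk)
        if (length(other) == 0) other <- bulk  # identical pair, degenerate
        d[i, paste0("bulk_", bulk)] <- d[i, paste0("bulk_", bulk)] - 1
        if (other[1] %in% sim) d[i, other[1]] <- d[i, other[1]] - 1
      }
      ## products
      if (!is.na(r$survivor)) d[i, r$survivor] <- d[i, r$survivor] + 1
      for (cc in r$counters) d[i, cc] <- d[i, cc] + 1
      d[i, "H2O"] <- d[i, "H2O"] + r$h2o + rx$water[i]
      d[i, "bulk_H3Op"] <- d[i, "bulk_H3Op"] - r$h3op_bulk
      if (m == "pair") delta_pair <- d else delta_scav <- d
    }
  }

  list(sim = sim, D = D, pair_rid = pair_rid, ctrl = ctrl,
       Reff = rx$R_eff_pair, alpha = alpha, gamma = gamma, Drel = rx$D_rel,
       prod_sp = prod_sp, scav_sp = scav_sp, scav_rate = scav_rate,
       scav_rid = scav_rid, entities = entities,
       delta_pair = delta_pair, delta_scav = delta_scav,
       fe3_rids = match(.FE3_RIDS, rx$id), rx_id = rx$id)
}

#' Ultimate (infinite-time) pair reaction probability
#'
#' For a pair at initial separation `r0`: under full diffusion control the
#' probability of ever reacting is `R_eff / r0`; under the radiation
#' (partially diffusion controlled) boundary condition it is reduced by
#' `k_act / (k_act + k_diff)` evaluated at contact. Separations at or inside
#' the reaction distance react with the contact probability (1 or alpha).
#'
#' @param r0 Initial separation (m).
#' @param R_eff Effective reaction distance (m).
#' @param control `"fully"` or `"partial"`/`"activation"`.
#' @param k_act Activation-limited rate constant (1/M/s; `Inf` for full
#'   diffusion control).
#' @param D_rel Relative diffusion coefficient (m^2/s; required unless
#'   `control == "fully"`).
#' @return Reaction probability in `[0, 1]`.
#' @examples
#' ultimate_reaction_probability(1e-9, 0.5e-9)   # = 0.5
#' @export
ultimate_reaction_probability <- function(r0, R_eff, control = "fully",
                                          k_act = Inf, D_rel = NULL) {
  stopifnot(all(r0 >= 0), all(R_eff > 0))
  geo <- pmin(R_eff / r0, 1)
  if (control == "fully" || all(is.infinite(k_act))) return(geo)
  if (is.null(D_rel)) stop("D_rel required for partially controlled pairs")
  v <- k_act / (4 * pi * R_eff^2 * .N_A * 1000)
  alpha <- v * R_eff / (D_rel + v * R_eff)
  geo * alpha
}

.erfcx <- function(x) {
  ifelse(x > 6,
         (1 / (x * sqrt(pi))) * (1 - 0.5 / x^2 + 0.75 / x^4 - 1.875 / x^6),
         exp(x^2) * 2 * pnorm(-x * sqrt(2)))
}

## conditional reaction-time CDF W(t)/Winf
.pair_cdf <- function(t, b, gamma, D_rel) {
  sDt <- sqrt(D_rel * t)
  y <- b / (2 * sDt)
  erfc_y <- 2 * pnorm(-y * sqrt(2))
  if (gamma == 0) return(erfc_y)
  erfc_y - exp(-y^2) * .erfcx(y + gamma * sDt)
}

#' Sample pair reaction times
#'
#' Draws `n` independent reaction times for a pair at separation `r0`; each
#' draw is infinite with probability `1 - Winf` and otherwise solves
#' `W(t) = u Winf` for the first-passage kernel (closed-form erfc inversion
#' under full diffusion control, numerical inversion of the
#' radiation-boundary kernel otherwise).
#'
#' @inheritParams ultimate_reaction_probability
#' @param n Number of draws.
#' @param u Optional uniform variates (for reproducibility checks).
#' @return Times in seconds (may be `Inf`).
#' @export
sample_pair_time <- function(n, r0, R_eff, D_rel, control = "fully",
                             k_act = Inf, u = NULL) {
  stopifnot(r0 >= R_eff)
  if (is.null(u)) u <- runif(n)
  winf <- ultimate_reaction_probability(r0, R_eff, control, k_act, D_rel)
  out <- rep(Inf, length(u))
  hit <- u < winf
  u2 <- u[hit] / winf
  b <- r0 - R_eff
  if (control == "fully" || is.infinite(k_act)) {
    xq <- qnorm(1 - u2 / 2) / sqrt(2)
    out[hit] <- b^2 / (4 * D_rel * xq^2)
  } else {
    v <- k_act / (4 * pi * R_eff^2 * .N_A * 1000)
    gamma <- 1 / R_eff + v / D_rel
    out[hit] <- vapply(u2, function(ui) {
      lo <- -20; hi <- 20
      for (i in 1:80) {
        mid <- (lo + hi) / 2
        if (.pair_cdf(10^mid, b, gamma, D_rel) < ui) lo <- mid else hi <- mid
      }
      10^((lo + hi) / 2)
    }, numeric(1))
  }
  out
}

#' Sample pseudo-first-order scavenging times
#'
#' Exponential waiting times with rate `k_obs * conc`; infinite when the
#' scavenger is absent.
#'
#' @param k_obs Observed (ionic-strength corrected) rate constant (1/M/s).
#' @param conc Scavenger concentration (M, >= 0).
#' @param n Number of draws.
#' @return Times in seconds.
#' @export
sample_scavenging_time <- function(k_obs, conc, n = 1) {
  stopifnot(conc >= 0, k_obs >= 0)
  if (conc == 0 || k_obs == 0) return(rep(Inf, n))
  rexp(n, rate = k_obs * conc)
}

#' Run the IRT stage for one track history
#'
#' Samples all pair and scavenging channels of the 1-ps distribution,
#' executes the event sequence up to the hand-off time, and returns the
#' yield time series (molecules/100 eV on the log grid), the escape yields
#' at spur coalescence, and the hand-off inventory for the bulk stage.
#'
#' @param dist An `initial_distribution` (positions in nm).
#' @param system A `chem_system`.
#' @param t_handoff Hand-off to homogeneous kinetics (s, >= 1e-7). Scale
#'   proportionally to the viscosity factor so the same dimensionless spur
#'   relaxation is covered.
#' @param escape_time Time at which escape yields are reported (s; ~0.2 us
#'   at standard diffusion, scaled with viscosity like `t_handoff`).
#' @param tables Precomputed engine tables (optional, for repeated calls).
#' @param w_min Pair channels with ultimate probability below this are
#'   ignored (bounds the channel set; negligible bias).
#' @return A list with `series` (data frame: time + per-entity G columns),
#'   `escape` (an `escape_yields`), `handoff` (named G inventory of
#'   survivors plus cumulative Fe3+ and channel tags), `energy_eV`, and the
#'   raw `events`.
#' @export
run_irt <- function(dist, system, t_handoff = 1e-6,
                    escape_time = 2e-7, tables = NULL, w_min = 1e-4) {
  stopifnot(inherits(dist, "initial_distribution"),
            inherits(system, "chem_system"))
  if (t_handoff < 1e-7) stop("hand-off must be at or after spur coalescence")
  if (is.null(tables)) tables <- build_irt_tables(system)

  p <- dist$particles
  spi <- match(p$species, tables$sim)
  if (anyNA(spi)) stop("distribution contains non-simulated species")
  pos <- cbind(p$x, p$y, p$z) * 1e-9          # nm -> m
  if (nrow(p) == 0) pos <- matrix(0, 0, 3)
  box_L <- if (isTRUE(dist$periodic)) dist$length_um * 1e-6 else 0

  log_ <- irt_history_cpp(as.integer(spi), pos, tables$D, tables$pair_rid,
                          tables$ctrl, tables$Reff, tables$alpha,
                          tables$gamma, tables$Drel, tables$prod_sp,
                          tables$scav_sp, tables$scav_rate, tables$scav_rid,
                          t_handoff, box_L, w_min)

  grid <- yield_time_grid()
  grid <- c(grid[grid < t_handoff], t_handoff)
  nent <- length(tables$entities)
  init <- numeric(nent)
  names(init) <- tables$entities
  tab <- table(factor(p$species, levels = tables$sim))
  init[tables$sim] <- as.numeric(tab)

  nev <- length(log_$t)
  if (nev > 0) {
    dmat <- matrix(0, nev, nent)
    is_pair <- log_$kind == 0
    dmat[is_pair, ] <- tables$delta_pair[log_$rid[is_pair], , drop = FALSE]
    dmat[!is_pair, ] <- tables$delta_scav[log_$rid[!is_pair], , drop = FALSE]
    cum <- apply(dmat, 2, cumsum)
    if (nev == 1) cum <- matrix(cum, 1)
    idx <- findInterval(grid, log_$t)
    counts <- matrix(rep(init, each = length(grid)), length(grid), nent)
    nz <- idx > 0
    counts[nz, ] <- counts[nz, ] + cum[idx[nz], , drop = FALSE]
    ## internal consistency: survivors from the engine match bookkeeping
    fin <- init[tables$sim] + cum[nev, seq_along(tables$sim)]
    surv <- table(factor(tables$sim[log_$survivors], levels = tables$sim))
    if (any(abs(fin - as.numeric(surv)) > 1e-9)) {
      stop("event-queue inconsistency: bookkeeping does not match survivors")
    }
    ## ferric channel decomposition (cumulative oxidations by oxidant class)
    fe3_tag <- .fe3_channel_tags(log_, tables)
    chan <- vapply(c("OH", "HO2", "H2O2"), function(ch) {
      tt <- log_$t[fe3_tag == ch]
      findInterval(grid, sort(tt))
    }, numeric(length(grid)))
  } else {
    counts <- matrix(rep(init, each = length(grid)), length(grid), nent)
    chan <- matrix(0, length(grid), 3,
                   dimnames = list(NULL, c("OH", "HO2", "H2O2")))
  }
  colnames(chan) <- paste0("Fe3p_", c("OH", "HO2", "H2O2"))
  colnames(counts) <- tables$entities

  E <- dist$deposited_energy
  G <- counts * 100 / E
  Gchan <- chan * 100 / E
  series <- data.frame(time = grid, G, Gchan, check.names = FALSE)

  esc_i <- max(which(grid <= escape_time))
  esc <- G[esc_i, c("e_aq", "H", "H2", "OH", "H2O2", "HO2", "SO4rm")]
  handoff <- c(G[length(grid), c(tables$sim, "Fe3p")],
               Gchan[length(grid), ])

  list(series = series, escape = escape_yields(esc), handoff = handoff,
       energy_eV = E, events = log_, entities = tables$entities)
}

## classify each ferric-producing event by its oxidant channel
.fe3_channel_tags <- function(log_, tables) {
  id <- tables$rx_id[log_$rid]
  out <- rep(NA_character_, length(id))
  out[id %in% c("OH_Fe2p", "SO4_Fe2p")] <- "OH"
  out[id == "HO2_Fe2p"] <- "HO2"
  out[id == "H2O2_Fe2p"] <- "H2O2"
  out
}
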