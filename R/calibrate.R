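## Calibration harness: fits the synthetic-track parameters (two Gaussian
## width classes and bounded 1-ps yield scales) so that the simulated escape
## yields at spur coalescence reproduce the accepted primary yields of
## air-free 0.4 M H2SO4 radiolysis at low LET.

#' Accepted escape yields of deaerated 0.4 M H2SO4 at low LET
#'
#' g(H) = 3.70, g(H2) = 0.40, g(OH) = 2.90, g(H2O2) = 0.80 (and
#' g(HO2) = 0.02, g(e_aq) = 0) molecules/100 eV at 25 C; the calibration
#' anchor of the synthetic track stage.
#' @return An `escape_yields` object.
#' @export
reference_escape_yields <- function() {
  escape_yields(H = 3.70, H2 = 0.40, OH = 2.90, H2O2 = 0.80,
                HO2 = 0.02, e_aq = 0)
}

## simulate pooled escape yields for one parameter set
.escape_sim <- function(params, system, tables, n_segments, spurs_per_segment,
                        LET, escape_time) {
  spacing <- params$mean_spur_energy / LET   # nm
  tot <- NULL; E <- 0
  for (s in seq_len(n_segments)) {
    d <- sample_spur_ensemble(params, spurs_per_segment, spacing = spacing)
    r <- run_irt(d, system, t_handoff = escape_time * 1.25,
                 escape_time = escape_time, tables = tables)
    g <- unclass(r$escape) * r$energy_eV
    tot <- if (is.null(tot)) g else tot + g
    E <- E + r$energy_eV
  }
  escape_yields(tot / E)
}

#' Calibrate the synthetic spur parameters
#'
#' Optimises the two position-width classes and (within bounds) the 1-ps
#' yields so the simulated 0.2-us escape yields in deaerated 0.4 M sulfuric
#' acid at low LET match the target to within `tol` per species for H, OH,
#' H2 and H2O2. Uses common random numbers across objective evaluations
#' (Nelder-Mead on a smooth box transform) followed by a larger verification
#' run with an independent stream.
#'
#' @param system Calibration medium; a deaerated, iron-free acid system at
#'   standard diffusion (viscosity factor 1).
#' @param target Target escape yields; defaults to
#'   [reference_escape_yields()].
#' @param start Anchor `spur_params`; the bounded yield scales are relative
#'   to its `initial_yields`. Defaults to the packaged values.
#' @param start_sigma,start_scales Optimizer starting point (widths in nm
#'   and yield scales relative to `start`).
#' @param LET Low-LET reference value (keV/um) setting the spur spacing.
#' @param tol Per-species relative tolerance on the verification run.
#' @param n_segments,spurs_per_segment Monte Carlo size of each objective
#'   evaluation.
#' @param verify_segments Size of the verification run.
#' @param maxit Nelder-Mead iteration cap.
#' @param escape_time Coalescence time at which yields are matched (s).
#' @return Calibrated `spur_params` with attributes `residuals` (per-species
#'   relative errors on the verification run), `escape` (verified yields)
#'   and `objective` (final value).
#' @export
calibrate_spur_parameters <- function(system = build_fricke_system(0.4, 0, 0),
                                      target = reference_escape_yields(),
                                      start = spur_parameters(),
                                      start_sigma = c(electron = 3.0,
                                                      radical = 0.55),
                                      start_scales = c(e_aq = 0.72, OH = 0.92,
                                                       H = 1.2, H2 = 1.35),
                                      LET = 0.3, tol = 0.05,
                                      n_segments = 24, spurs_per_segment = 30,
                                      verify_segments = 120,
                                      maxit = 300, escape_time = 2e-7) {
  if (system$viscosity_factor != 1) {
    stop("calibrate at standard diffusion (viscosity factor 1)")
  }
  if (system$background[["Fe2p"]] > 0 || system$background[["O2"]] > 0) {
    stop("calibration medium must be deaerated acid water without iron")
  }
  defs <- .spur_defaults()
  tables <- build_irt_tables(system)
  fit_species <- c("H", "OH", "H2", "H2O2")
  tgt <- unclass(target)[fit_species]

  ## box transform: theta (unconstrained) -> parameter in [lo, hi]
  box <- function(theta, lo, hi) lo + (hi - lo) * stats::plogis(theta)
  unbox <- function(p, lo, hi) stats::qlogis(pmin(pmax((p - lo) / (hi - lo),
                                                       1e-6), 1 - 1e-6))
  sb <- defs$sigma_bounds
  yb <- defs$yield_bounds
  scale_species <- c("e_aq", "OH", "H", "H2")

  theta0 <- c(unbox(start_sigma[["electron"]], sb$electron[1], sb$electron[2]),
              unbox(start_sigma[["radical"]], sb$radical[1], sb$radical[2]),
              unbox(start_scales[scale_species], yb[1], yb[2]))

  make_params <- function(theta) {
    sig <- c(electron = box(theta[1], sb$electron[1], sb$electron[2]),
             radical = box(theta[2], sb$radical[1], sb$radical[2]))
    sc <- box(theta[2 + seq_along(scale_species)], yb[1], yb[2])
    y <- start$initial_yields
    y[scale_species] <- y[scale_species] * sc
    y["H3Op"] <- y[["e_aq"]]     # ionisation charge balance
    spur_parameters(initial_yields = y, sigma = sig,
                    mean_spur_energy = start$mean_spur_energy)
  }

  crn_seed <- sample.int(2^31 - 1, 2)
  objective <- function(theta) {
    p <- make_params(theta)
    g <- withr_seed(crn_seed[1], .escape_sim(p, system, tables, n_segments,
                                             spurs_per_segment, LET,
                                             escape_time))
    sum(((unclass(g)[fit_species] - tgt) / tgt)^2)
  }

  ## optimise in theta/2 so the default Nelder-Mead simplex explores O(0.1)
  ## logit steps even for coordinates starting near zero; restart once from
  ## the incumbent to escape premature simplex collapse
  opt <- optim(theta0 / 2, function(phi) objective(2 * phi),
               method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-6))
  opt2 <- optim(opt$par, function(phi) objective(2 * phi),
                method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-6))
  if (opt2$value < opt$value) opt <- opt2
  fit <- make_params(2 * opt$par)

  verified <- withr_seed(crn_seed[2],
                         .escape_sim(fit, system, tables, verify_segments,
                                     spurs_per_segment, LET, escape_time))
  res <- (unclass(verified)[fit_species] - tgt) / tgt
  attr(fit, "residuals") <- res
  attr(fit, "escape") <- verified
  attr(fit, "objective") <- opt$value
  if (any(abs(res) > tol)) {
    cnd <- simpleError(paste0(
      "calibration failed tolerance; residuals: ",
      paste(sprintf("%s=%+.1f%%", fit_species, 100 * res), collapse = ", ")))
    cnd$fit <- fit   # best parameters remain available to the caller
    class(cnd) <- c("calibration_error", class(cnd))
    stop(cnd)
  }
  if (verified[["e_aq"]] >= 0.05) {
    stop("hydrated electrons not fully converted at coalescence (g = ",
         signif(verified[["e_aq"]], 3), ")")
  }
  fit
}

## evaluate expr under a temporary seed, restoring the caller's RNG stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}
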