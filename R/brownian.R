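## Brute-force Brownian dynamics oracle for the pair first-passage kernels.
## Deliberately simple and slow: used to validate the IRT sampling kernels
## against an independent discretisation, not for production runs.

#' Brownian-dynamics estimate of the pair reaction probability
#'
#' Simulates the relative coordinate of an isolated pair (3D random walk
#' with diffusion coefficient `D_rel`, time step `dt`) from separation `r0`
#' and returns the fraction of replicas that react by `t_max`. Under full
#' diffusion control the boundary at `R_eff` is absorbing; under the
#' radiation boundary condition a crossing is absorbed with the
#' Erban-Chapman probability `v * sqrt(pi * dt / D_rel)` (with
#' `v = k_act / (4 pi R_eff^2 N_A * 1000)`) and reflected otherwise. The
#' estimate converges to the analytic kernel as `dt -> 0`.
#'
#' @param r0 Initial separation (m, > `R_eff`).
#' @param R_eff Reaction distance (m).
#' @param D_rel Relative diffusion coefficient (m^2/s).
#' @param t_max Observation time (s).
#' @param n Number of replicas.
#' @param dt Time step (s); should be small enough that the rms step is a
#'   small fraction of `r0 - R_eff`.
#' @param control `"fully"` or `"partial"`.
#' @param k_act Activation-limited rate constant (1/M/s) for
#'   `control = "partial"`.
#' @return List with `p` (reacted fraction), `se` (binomial standard
#'   error), `n`, `dt`.
#' @export
bd_pair_probability <- function(r0, R_eff, D_rel, t_max, n = 20000,
                                dt = NULL, control = "fully", k_act = Inf) {
  stopifnot(r0 > R_eff, R_eff > 0, D_rel > 0, t_max > 0)
  if (is.null(dt)) dt <- ((r0 - R_eff) / 10)^2 / (2 * D_rel)
  nstep <- ceiling(t_max / dt)
  if (nstep > 2e5) stop("too many steps; increase dt or reduce t_max")
  p_abs <- if (control == "fully" || is.infinite(k_act)) {
    1
  } else {
    v <- k_act / (4 * pi * R_eff^2 * .N_A * 1000)
    p <- v * sqrt(pi * dt / D_rel)
    if (p > 0.5) stop("dt too large for the radiation boundary (p = ",
                      signif(p, 3), "); reduce dt")
    p
  }
  s <- sqrt(2 * D_rel * dt)
  x <- rep(r0, n); y <- z <- numeric(n)
  done <- logical(n)
  for (k in seq_len(nstep)) {
    live <- which(!done)
    if (length(live) == 0) break
    m <- length(live)
    x[live] <- x[live] + rnorm(m, 0, s)
    y[live] <- y[live] + rnorm(m, 0, s)
    z[live] <- z[live] + rnorm(m, 0, s)
    r <- sqrt(x[live]^2 + y[live]^2 + z[live]^2)
    inside <- r < R_eff
    if (any(inside)) {
      idx <- live[inside]
      hit <- if (p_abs >= 1) rep(TRUE, length(idx)) else
        runif(length(idx)) < p_abs
      done[idx[hit]] <- TRUE
      ## reflect survivors back outside the contact sphere radially
      refl <- idx[!hit]
      if (length(refl)) {
        rr <- sqrt(x[refl]^2 + y[refl]^2 + z[refl]^2)
        scale <- (2 * R_eff - rr) / rr
        x[refl] <- x[refl] * scale
        y[refl] <- y[refl] * scale
        z[refl] <- z[refl] * scale
      }
    }
  }
  p <- mean(done)
  list(p = p, se = sqrt(p * (1 - p) / n), n = n, dt = dt)
}
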