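## Chemistry module: species registry, Fricke/acid-water reaction network,
## sulfuric-acid speciation, ionic-strength corrections, viscosity scaling.

.chem_cache <- new.env(parent = emptyenv())

#' Load the chemistry configuration
#'
#' Reads the species registry and reaction network (rate constants at 25 C
#' and infinite dilution, diffusion coefficients, control regimes) from the
#' packaged YAML configuration, or from a user-supplied file with the same
#' layout.
#'
#' @param path Path to a YAML configuration; defaults to the packaged table.
#' @return A list with elements `species` (data frame), `reactions`
#'   (data frame), `instant_transforms` (data frame) and `R_contact` (m).
#' @export
fricke_chemistry_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fricke_chemistry.yaml", package = "frickesim")
  }
  key <- normalizePath(path)
  if (!is.null(.chem_cache[[key]])) return(.chem_cache[[key]])
  raw <- yaml::read_yaml(path)

  elements <- c("H", "O", "S", "Fe")
  sp <- data.frame(
    name   = names(raw$species),
    charge = vapply(raw$species, function(s) as.integer(s$charge), integer(1)),
    D      = vapply(raw$species, function(s) as.numeric(s$D), numeric(1)),
    sigma_class = vapply(raw$species, function(s) s$sigma_class, character(1)),
    stringsAsFactors = FALSE
  )
  for (el in elements) {
    sp[[el]] <- vapply(raw$species, function(s) {
      n <- s$elements[[el]]
      if (is.null(n)) 0L else as.integer(n)
    }, integer(1))
  }
  rownames(sp) <- sp$name
  if (any(sp$D <= 0)) stop("diffusion coefficients must be positive")

  rx <- data.frame(
    id = vapply(raw$reactions, `[[`, character(1), "id"),
    r1 = vapply(raw$reactions, function(r) r$reactants[[1]], character(1)),
    r2 = vapply(raw$reactions, function(r) r$reactants[[2]], character(1)),
    k0 = vapply(raw$reactions, function(r) as.numeric(r$k), numeric(1)),
    control = vapply(raw$reactions, `[[`, character(1), "control"),
    water = vapply(raw$reactions, function(r) as.integer(r$water), integer(1)),
    salt_exempt = vapply(raw$reactions, function(r) isTRUE(r$salt_exempt), logical(1)),
    stringsAsFactors = FALSE
  )
  rx$products <- lapply(raw$reactions, function(r) as.character(unlist(r$products)))
  rownames(rx) <- rx$id

  tr <- data.frame(
    id = vapply(raw$instant_transforms, `[[`, character(1), "id"),
    from = vapply(raw$instant_transforms, `[[`, character(1), "from"),
    to = vapply(raw$instant_transforms, function(x) {
      if (is.null(x$to)) NA_character_ else x$to
    }, character(1)),
    water = vapply(raw$instant_transforms, function(x) as.integer(x$water), integer(1)),
    stringsAsFactors = FALSE
  )

  cfg <- list(species = sp, reactions = rx, instant_transforms = tr,
              R_contact = as.numeric(raw$R_contact))
  .validate_balance(cfg)
  .chem_cache[[key]] <- cfg
  cfg
}

## species composition vector c(H, O, S, Fe, charge)
.composition <- function(sp, name) {
  if (is.na(name)) return(c(H = 0, O = 0, S = 0, Fe = 0, charge = 0))
  row <- sp[name, ]
  if (is.null(row) || is.na(row$charge)) stop("unknown species in reaction table: ", name)
  c(H = row$H, O = row$O, S = row$S, Fe = row$Fe, charge = row$charge)
}

## charge and element conservation for every reaction, water included
.validate_balance <- function(cfg) {
  sp <- cfg$species
  water <- c(H = 2, O = 1, S = 0, Fe = 0, charge = 0)
  for (i in seq_len(nrow(cfg$reactions))) {
    r <- cfg$reactions[i, ]
    lhs <- .composition(sp, r$r1) + .composition(sp, r$r2) +
      pmax(-r$water, 0) * water
    rhs <- Reduce(`+`, lapply(r$products[[1]], .composition, sp = sp),
                  accumulate = FALSE, init = c(H = 0, O = 0, S = 0, Fe = 0, charge = 0)) +
      pmax(r$water, 0) * water
    if (any(lhs != rhs)) {
      stop("unbalanced reaction: ", r$id, " (",
           paste(names(lhs), lhs - rhs, collapse = ", "), ")")
    }
  }
  for (i in seq_len(nrow(cfg$instant_transforms))) {
    t <- cfg$instant_transforms[i, ]
    ## base form + bulk H3O+ -> acid form + water
    lhs <- .composition(sp, t$from) + .composition(sp, "H3Op")
    rhs <- .composition(sp, t$to) + t$water * water
    if (any(lhs != rhs)) stop("unbalanced instant transform: ", t$id)
  }
  invisible(TRUE)
}

#' Sulfuric acid speciation and ionic strength
#'
#' The first dissociation of H2SO4 is complete; the second
#' (HSO4- <-> H+ + SO4^2-, pKa2 = 1.99 at 25 C) is solved from its
#' concentration-based equilibrium constant. The ionic strength
#' I = 1/2 sum(c_i z_i^2) runs over all background ions, including FeSO4
#' when present.
#'
#' @param acid_molarity H2SO4 concentration (M, >= 0).
#' @param fe2_molarity FeSO4 concentration (M, >= 0); contributes Fe2+ and
#'   SO4^2- to the ionic strength.
#' @return A list with `concentrations` (named: H3Op, HSO4m, SO4m2, Fe2p),
#'   `ionic_strength` (M) and `pH` (concentration-based, reported only).
#' @examples
#' acid_speciation(0.4)$concentrations
#' @export
acid_speciation <- function(acid_molarity, fe2_molarity = 0) {
  if (!is.numeric(acid_molarity) || acid_molarity < 0) {
    stop("acid molarity must be non-negative")
  }
  if (fe2_molarity < 0) stop("FeSO4 molarity must be non-negative")
  C <- acid_molarity
  if (C > 0) {
    ## x (C + x) / (C - x) = Ka2
    x <- uniroot(function(x) x * (C + x) - .KA2 * (C - x),
                 c(0, C), tol = 1e-14)$root
  } else {
    x <- 0
  }
  conc <- c(H3Op = C + x, HSO4m = C - x, SO4m2 = x + fe2_molarity,
            Fe2p = fe2_molarity)
  ## z = +1, -1, -2, +2
  I <- 0.5 * (conc[["H3Op"]] * 1 + conc[["HSO4m"]] * 1 +
                conc[["SO4m2"]] * 4 + conc[["Fe2p"]] * 4)
  list(concentrations = conc, ionic_strength = unname(I),
       pH = if (C > 0) -log10(conc[["H3Op"]]) else NA_real_)
}

#' Kinetic ionic-strength (salt-effect) multiplier
#'
#' Debye-Brønsted correction for rate constants between ions at finite ionic
#' strength: log10(k/k0) = 1.02 z1 z2 sqrt(I) / (1 + sqrt(I)) at 25 C.
#' Reactions with a neutral partner are unaffected, as is the
#' hydrated-electron self-recombination (exempt on empirical grounds).
#'
#' @param z1,z2 Integer charges of the reactants.
#' @param I Ionic strength (M, >= 0).
#' @param exempt If `TRUE` the multiplier is 1 regardless of charges.
#' @return Multiplier on the infinite-dilution rate constant.
#' @examples
#' ionic_strength_factor(1, -1, 0.42)
#' @export
ionic_strength_factor <- function(z1, z2, I, exempt = FALSE) {
  if (any(I < 0)) stop("ionic strength must be non-negative")
  if (exempt) return(rep(1, length.out = max(length(z1), length(I))))
  zz <- z1 * z2
  ifelse(zz == 0, 1, 10^(.SALT_A * zz * sqrt(I) / (1 + sqrt(I))))
}

#' Build the Fricke dosimeter chemistry system
#'
#' Assembles the full reaction system for an (optionally aerated) ferrous
#' sulfate solution in sulfuric acid: acid speciation, background solute
#' concentrations, ionic-strength-corrected rate constants, and the
#' activation/diffusion partition of every rate constant that makes
#' Stokes-Einstein viscosity scaling self-consistent.
#'
#' @param acid_molarity H2SO4 concentration in (0, 1] M (0.4 M standard,
#'   0.05 M gel formulation).
#' @param fe2_molarity Ferrous sulfate concentration (M; 1e-3 standard, 0 for
#'   the deaerated acid-water calibration medium).
#' @param o2_molarity Dissolved oxygen (M; 2.5e-4 air-saturated, 0 deaerated).
#' @param config Chemistry configuration, see [fricke_chemistry_config()].
#' @return An object of class `chem_system`.
#' @examples
#' sys <- build_fricke_system(0.4, 1e-3, 2.5e-4)
#' sys$reactions[c("e_H3Op", "H2O2_Fe2p"), c("k0", "k_eff")]
#' @export
build_fricke_system <- function(acid_molarity = 0.4, fe2_molarity = 1e-3,
                                o2_molarity = 2.5e-4,
                                config = fricke_chemistry_config()) {
  if (acid_molarity <= 0 || acid_molarity > 1) {
    stop("acid molarity must lie in (0, 1] M")
  }
  if (fe2_molarity < 0 || o2_molarity < 0) {
    stop("solute molarities must be non-negative")
  }
  spec <- acid_speciation(acid_molarity, fe2_molarity)
  background <- c(spec$concentrations, O2 = o2_molarity)
  I <- spec$ionic_strength

  sp <- config$species
  sp$D0 <- sp$D            # unscaled 25 C values; D holds the working copy

  rx <- config$reactions
  z1 <- sp[rx$r1, "charge"]
  z2 <- sp[rx$r2, "charge"]
  rx$salt_factor <- ionic_strength_factor(z1, z2, I)
  rx$salt_factor[rx$salt_exempt] <- 1
  rx$k_eff <- rx$k0 * rx$salt_factor   # corrected observed k at f = 1

  rx$D_rel0 <- sp[rx$r1, "D0"] + sp[rx$r2, "D0"]
  rx$R_eff <- NA_real_
  rx$k_act <- NA_real_
  fully <- rx$control == "fully"
  rx$R_eff[fully] <- rx$k_eff[fully] / (4 * pi * rx$D_rel0[fully] * .N_A * 1000)
  rx$k_act[fully] <- Inf
  rx$R_eff[!fully] <- config$R_contact
  k_diff0 <- .k_smoluchowski(rx$D_rel0[!fully], config$R_contact)
  if (any(k_diff0 <= rx$k_eff[!fully])) {
    bad <- rx$id[!fully][k_diff0 <= rx$k_eff[!fully]]
    stop("observed k exceeds diffusion limit at the assumed contact radius: ",
         paste(bad, collapse = ", "))
  }
  rx$k_act[!fully] <- 1 / (1 / rx$k_eff[!fully] - 1 / k_diff0)

  ## identical-reactant pairs: the tabulated k is defined through the rate
  ## law -d[A]/dt = 2k[A]^2, so the per-pair encounter kernel corresponds to
  ## 2k. The pair stage therefore uses a separate partition of 2 k_eff; the
  ## homogeneous k_obs keeps the conventional definition.
  self <- rx$r1 == rx$r2
  rx$R_eff_pair <- rx$R_eff
  rx$k_act_pair <- rx$k_act
  fs <- fully & self
  rx$R_eff_pair[fs] <- 2 * rx$R_eff[fs]
  ps <- !fully & self
  if (any(ps)) {
    kd <- .k_smoluchowski(rx$D_rel0[ps], config$R_contact)
    if (any(kd <= 2 * rx$k_eff[ps])) {
      stop("doubled self-reaction k exceeds the diffusion limit: ",
           paste(rx$id[ps][kd <= 2 * rx$k_eff[ps]], collapse = ", "))
    }
    rx$k_act_pair[ps] <- 1 / (1 / (2 * rx$k_eff[ps]) - 1 / kd)
  }

  sys <- structure(list(
    species = sp,
    reactions = rx,
    instant_transforms = config$instant_transforms,
    background = background,
    ionic_strength = I,
    pH = spec$pH,
    acid_molarity = acid_molarity,
    viscosity_factor = 1,
    temperature_C = 25
  ), class = "chem_system")
  .refresh_kinetics(sys)
}

## recompute D, k_diff, k_obs from the current viscosity factor
.refresh_kinetics <- function(sys) {
  f <- sys$viscosity_factor
  sys$species$D <- sys$species$D0 / f
  rx <- sys$reactions
  D_rel <- rx$D_rel0 / f
  k_diff <- .k_smoluchowski(D_rel, rx$R_eff)
  k_obs <- ifelse(is.infinite(rx$k_act), k_diff,
                  1 / (1 / rx$k_act + 1 / k_diff))
  rx$D_rel <- D_rel
  rx$k_diff <- k_diff
  rx$k_obs <- k_obs
  sys$reactions <- rx
  sys
}

#' Scale the system to a higher viscosity
#'
#' Uniform Stokes-Einstein scaling: every species' diffusion coefficient is
#' divided by `f` (including Fe2+ and Fe3+). Diffusion-limited rate components
#' are recomputed from the scaled diffusion coefficients with the effective
#' reaction radii held fixed; activation components are viscosity-invariant;
#' observed rate constants are recombined through the Noyes partition
#' 1/k = 1/k_act + 1/k_diff. Factors compose multiplicatively.
#'
#' @param system A `chem_system`.
#' @param f Viscosity factor (>= 1) relative to the current state.
#' @return The rescaled `chem_system`.
#' @examples
#' gel <- apply_viscosity(build_fricke_system(), 10)
#' gel$species["Fe3p", "D"]   # 2e-10 m^2/s, the gelatin band
#' @export
apply_viscosity <- function(system, f) {
  stopifnot(inherits(system, "chem_system"))
  if (!is.numeric(f) || length(f) != 1 || f < 1) {
    stop("viscosity factor must be a scalar >= 1")
  }
  system$viscosity_factor <- system$viscosity_factor * f
  .refresh_kinetics(system)
}

#' @export
print.chem_system <- function(x, ...) {
  cat("<chem_system>", nrow(x$species), "species,", nrow(x$reactions),
      "reactions\n")
  cat(sprintf("  H2SO4 %.3g M (pH %.2f), Fe2+ %.3g M, O2 %.3g M\n",
              x$acid_molarity, x$pH, x$background[["Fe2p"]],
              x$background[["O2"]]))
  cat(sprintf("  ionic strength %.3f M, viscosity factor %g\n",
              x$ionic_strength, x$viscosity_factor))
  invisible(x)
}

#' Escape-yield container
#'
#' Named vector of g-values (molecules/100 eV) at spur/track coalescence
#' (~0.2 us), the hand-off inventory between the stochastic and deterministic
#' stages.
#'
#' @param ... Named g-values, or a single named numeric vector.
#' @return An `escape_yields` object.
#' @examples
#' escape_yields(H = 3.70, H2 = 0.40, OH = 2.90, H2O2 = 0.80, HO2 = 0.02)
#' @export
escape_yields <- function(...) {
  args <- list(...)
  g <- if (length(args) == 1 && is.null(names(args))) unlist(args) else unlist(args)
  if (is.null(names(g)) || any(names(g) == "")) stop("escape yields must be named")
  if (any(g < 0)) stop("escape yields must be non-negative")
  structure(g, class = "escape_yields")
}

#' Stoichiometric ferric-ion yield of the aerated Fricke dosimeter
#'
#' Closed-form asymptotic yield
#' G(Fe3+) = g(OH) + 3 g(H) + 2 g(H2O2) + 3 g(HO2): each escaped OH oxidises
#' one Fe2+; each H atom is converted by O2 to HO2, whose oxidation of Fe2+
#' yields H2O2 and hence two further oxidations through the Fenton chain;
#' each escaped H2O2 oxidises two.
#'
#' @param e Escape yields (named, molecules/100 eV); missing species count as
#'   zero with a warning.
#' @return G(Fe3+) in molecules/100 eV.
#' @examples
#' stoichiometric_yield(escape_yields(H = 3.70, OH = 2.90, H2O2 = 0.80,
#'                                    HO2 = 0.02))
#' @export
stoichiometric_yield <- function(e) {
  w <- c(OH = 1, H = 3, H2O2 = 2, HO2 = 3)
  g <- unclass(e)
  if (any(g < 0)) stop("escape yields must be non-negative")
  missing <- setdiff(names(w), names(g))
  if (length(missing)) {
    warning("missing escape yields treated as zero: ",
            paste(missing, collapse = ", "))
  }
  present <- intersect(names(w), names(g))
  sum(w[present] * g[present])
}
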