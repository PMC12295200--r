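#' @useDynLib frickesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pnorm qnorm plogis qlogis rexp rpois runif rnorm
#' @importFrom stats setNames uniroot sd
#' @importFrom utils modifyList write.csv
NULL

## Avogadro constant (1/mol)
.N_A <- 6.02214076e23

## 1 molecule/100 eV expressed in mol/J
.G_SI <- 1.0364e-7

## Debye-Brønsted prefactor at 25 C in water (log10 units)
.SALT_A <- 1.02

## Second dissociation constant of sulfuric acid at 25 C (pKa2 = 1.99)
.KA2 <- 10^(-1.99)

#' Convert a radiation-chemical yield to SI units
#'
#' G-values in radiation chemistry are conventionally expressed in molecules
#' formed (or consumed) per 100 eV of absorbed energy. One molecule/100 eV
#' corresponds to 1.0364e-7 mol/J.
#'
#' @param g Yield in molecules per 100 eV (non-negative).
#' @return The same yield in mol/J.
#' @examples
#' to_mol_per_joule(15.5)
#' @export
to_mol_per_joule <- function(g) {
  stopifnot(is.numeric(g), all(g >= 0))
  g * .G_SI
}

## Smoluchowski diffusion-limited rate constant, 1/M/s
## D_rel in m^2/s, R in m
.k_smoluchowski <- function(D_rel, R) {
  4 * pi * D_rel * R * .N_A * 1000
}
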