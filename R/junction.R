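#' Built-in relative ionic mobility table
#'
#' Relative mobilities (K+ = 1) of the ionic species commonly found in
#' patch-clamp solutions, from the classical liquid-junction-potential tables
#' of the patch-clamp literature. Note on gluconate: the table ships the
#' acetate-analogue value (0.556) used by the classical calculators of the
#' pClamp era; the directly measured value is lower (0.33) and can be supplied
#' via the `mobility` argument of [solution_spec()] or by editing the table.
#' The two entries move a K-gluconate/aCSF junction potential by several mV.
#'
#' @return named numeric vector of relative mobilities with a `valence`
#'   attribute (named integer vector).
#' @export
ion_mobility_table <- function() {
  u <- c(K = 1.00, Na = 0.682, Li = 0.525, Cs = 1.05,
         Mg = 0.361, Ca = 0.4048,
         Cl = 1.0388, Br = 1.063, F = 0.753,
         HCO3 = 0.605, H2PO4 = 0.449, SO4 = 0.544,
         gluconate = 0.556, HEPES = 0.30, MES = 0.37,
         ATP = 0.24, GTP = 0.24)
  z <- c(K = 1L, Na = 1L, Li = 1L, Cs = 1L,
         Mg = 2L, Ca = 2L,
         Cl = -1L, Br = -1L, F = -1L,
         HCO3 = -1L, H2PO4 = -1L, SO4 = -2L,
         gluconate = -1L, HEPES = -1L, MES = -1L,
         ATP = -2L, GTP = -2L)
  attr(u, "valence") <- z
  u
}

#' Describe an electrolyte solution for junction-potential calculation
#'
#' @param species character vector of ion names.
#' @param conc_mM numeric vector of concentrations in mM (same length).
#' @param valence optional integer vector; defaults to the built-in table.
#' @param mobility optional numeric vector of relative mobilities (K+ = 1);
#'   defaults to the built-in table.
#' @param temperature_c temperature in degrees Celsius (default 33, the
#'   midpoint of a 32-34 degree recording bath).
#' @return object of class `solution_spec`.
#' @export
solution_spec <- function(species, conc_mM, valence = NULL, mobility = NULL,
                          temperature_c = 33) {
  stopifnot(length(species) == length(conc_mM))
  if (any(conc_mM < 0)) stop("concentrations must be >= 0")
  tab <- ion_mobility_table()
  ztab <- attr(tab, "valence")
  if (is.null(mobility)) {
    unknown <- setdiff(species, names(tab))
    if (length(unknown) > 0)
      stop("no built-in mobility for species: ", paste(unknown, collapse = ", "),
           "; supply `mobility` and `valence`")
    mobility <- unname(tab[species])
  }
  if (is.null(valence)) valence <- unname(ztab[species])
  if (any(valence == 0 & mobility != 0))
    warning("neutral species with nonzero listed mobility carry no current; ",
            "they are ignored in the junction potential")
  if (any(valence != 0 & mobility == 0))
    stop("every charged species needs a nonzero mobility")
  structure(list(species = species, conc_mM = as.numeric(conc_mM),
                 valence = as.integer(valence), mobility = as.numeric(mobility),
                 temperature_c = temperature_c),
            class = "solution_spec")
}

#' Standard K-gluconate pipette solution
#'
#' Ionic breakdown (mM) of an internal solution of K-gluconate 135, NaCl 10,
#' HEPES 10, MgCl2 1, Na2ATP 2, GTP 0.3 at pH 7.4: HEPES is treated as fully
#' anionic and ATP/GTP as divalent anions.
#' @param temperature_c bath temperature (degrees C).
#' @return a `solution_spec`.
#' @export
solution_kgluconate_internal <- function(temperature_c = 33) {
  solution_spec(
    species = c("K", "gluconate", "Na", "Cl", "HEPES", "Mg", "ATP", "GTP"),
    conc_mM = c(135, 135, 10 + 4, 10 + 2, 10, 1, 2, 0.3),
    temperature_c = temperature_c)
}

#' Standard artificial cerebrospinal fluid
#'
#' Ionic breakdown (mM) of aCSF with NaCl 123, KCl 4, CaCl2 1, MgSO4 1,
#' NaHCO3 26, NaH2PO4 1.25.
#' @param temperature_c bath temperature (degrees C).
#' @return a `solution_spec`.
#' @export
solution_acsf <- function(temperature_c = 33) {
  solution_spec(
    species = c("Na", "Cl", "K", "Ca", "Mg", "SO4", "HCO3", "H2PO4"),
    conc_mM = c(123 + 26 + 1.25, 123 + 4 + 2, 4, 1, 1, 1, 26, 1.25),
    temperature_c = temperature_c)
}

#' Liquid junction potential by the Henderson equation
#'
#' Computes the potential of the pipette solution relative to the bath at the
#' pipette temperature, using the Henderson continuous-mixture approximation
#' with relative ionic mobilities. A K-gluconate internal against aCSF is
#' negative (the pipette sits below the bath) because gluconate is much less
#' mobile than chloride.
#'
#' @param pipette,bath `solution_spec` objects.
#' @return junction potential in mV (pipette minus bath).
#' @export
henderson_junction_potential <- function(pipette, bath) {
  stopifnot(inherits(pipette, "solution_spec"), inherits(bath, "solution_spec"))
  ions <- union(pipette$species, bath$species)
  pick <- function(sol, what) {
    x <- setNames(sol[[what]], sol$species)[ions]
    x[is.na(x)] <- 0
    unname(x)
  }
  cp <- pick(pipette, "conc_mM"); cb <- pick(bath, "conc_mM")
  # mobilities/valences: prefer the side that defines the species
  u <- z <- numeric(length(ions))
  for (k in seq_along(ions)) {
    src <- if (ions[k] %in% pipette$species) pipette else bath
    idx <- match(ions[k], src$species)
    u[k] <- src$mobility[idx]; z[k] <- src$valence[idx]
  }
  keep <- z != 0
  if (!any(keep)) stop("all-neutral solutions carry no junction potential")
  u <- u[keep]; z <- z[keep]; cp <- cp[keep]; cb <- cb[keep]
  RT_F <- 8.31446 * (273.15 + pipette$temperature_c) / 96485.33 * 1000  # mV
  num <- sum(z * u * (cp - cb))
  den <- sum(z^2 * u * (cp - cb))
  sp <- sum(z^2 * u * cp)
  sb <- sum(z^2 * u * cb)
  if (sp <= 0 || sb <= 0) stop("degenerate solution: no ionic conductivity")
  if (abs(den) < 1e-12) return(0)
  RT_F * (num / den) * log(sb / sp)
}
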