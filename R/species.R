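#' Chemical species set for the radiolysis / lipid-peroxidation network
#'
#' Builds the table of species tracked by the kinetic model together with
#' their roles and initial concentrations. The dynamic core comprises the
#' twelve radiolysis/peroxidation species (hydrated electrons, hydrogen and
#' hydroxyl radicals, molecular hydrogen, hydrogen peroxide, the
#' superoxide/hydroperoxyl pool, the hydroperoxide anion, glutathione and its
#' thiyl radical, alkyl and alkyl-peroxyl radicals, and alkyl hydroperoxide)
#' plus molecular oxygen, which is integrated as a consumable species by
#' default. Auxiliary intermediates that appear only inside single reactions
#' (O^-., O3^-, RH^-, RH2., the R-R dimer, the ROH/RO termination products
#' and the lipid radical L.) are carried as tracked sinks. Water, the generic
#' organic substrate RH, the lipid substrate LH, H+, OH- (pH 7 buffered) and
#' Fe2+ are constant pools whose concentrations never change during
#' integration.
#'
#' @param o2_uM Initial dissolved oxygen, micromolar.
#' @param gsh_uM Initial glutathione, micromolar.
#' @param o2_dynamic If `TRUE` (default) oxygen is consumed/produced by the
#'   chemistry; if `FALSE` it is pinned at its initial value (treated as a
#'   constant pool).
#' @param rh_M Concentration of the generic organic substrate RH (mol/L).
#' @param lh_M Concentration of the oxidisable lipid substrate LH (mol/L).
#' @param h2o_M Water concentration (mol/L).
#' @param h_plus_M,oh_minus_M Proton and hydroxide pool concentrations
#'   (mol/L); defaults are pH 7 buffered.
#' @param fe2_M Ferrous iron pool for the Fenton channel (mol/L); default 0.
#'
#' @return A data frame of class `ros_species` with columns `name`, `role`
#'   (`"dynamic"`, `"sink"` or `"pool"`) and `conc` (mol/L initial value).
#' @seealso [skin_conditions()], [aerated_conditions()], [build_network()]
#' @export
ros_species <- function(o2_uM = 10, gsh_uM = 410, o2_dynamic = TRUE,
                        rh_M = 1, lh_M = 2.04e-3, h2o_M = 55.3,
                        h_plus_M = 1e-7, oh_minus_M = 1e-7, fe2_M = 0) {
  stopifnot(o2_uM >= 0, gsh_uM >= 0, rh_M >= 0, lh_M >= 0)
  core <- data.frame(
    name = c("e", "H", "OH", "H2", "H2O2", "O2m", "HO2m",
             "GSH", "GS", "R", "ROO", "ROOH"),
    role = "dynamic",
    conc = 0,
    stringsAsFactors = FALSE
  )
  core$conc[core$name == "GSH"] <- gsh_uM * 1e-6
  o2 <- data.frame(name = "O2",
                   role = if (o2_dynamic) "dynamic" else "pool",
                   conc = o2_uM * 1e-6)
  sinks <- data.frame(
    name = c("Om", "O3m", "RHm", "RH2", "RR", "ROX", "L"),
    role = c("dynamic", "sink", "sink", "sink", "sink", "sink", "sink"),
    conc = 0
  )
  pools <- data.frame(
    name = c("H2O", "RH", "LH", "Hp", "OHm", "Fe2"),
    role = "pool",
    conc = c(h2o_M, rh_M, lh_M, h_plus_M, oh_minus_M, fe2_M)
  )
  out <- rbind(core, o2, sinks, pools)
  rownames(out) <- NULL
  if (anyDuplicated(out$name)) stop("duplicate species names")
  if (any(out$conc < 0)) stop("negative initial concentration")
  class(out) <- c("ros_species", class(out))
  out
}

#' Representative tissue and in-vitro chemical conditions
#'
#' `skin_conditions()` returns the slightly hypoxic skin environment used for
#' the proton PBS studies: 10 uM dissolved oxygen and 410 uM glutathione.
#' `aerated_conditions()` returns the aerated, scavenger-free environment of
#' the lipid-micelle electron irradiations: oxygen in equilibrium with 21%
#' atm at 25 C converted through Henry's law (0.21 atm x 1.3 mM/atm ~ 273 uM)
#' and zero glutathione.
#'
#' @return A list with elements `o2_uM` and `gsh_uM`.
#' @export
skin_conditions <- function() list(o2_uM = 10, gsh_uM = 410)

#' @rdname skin_conditions
#' @export
aerated_conditions <- function() list(o2_uM = 0.21 * 1300, gsh_uM = 0)

#' Primary radiolytic yields (G-values)
#'
#' Escape yields of the primary water-radiolysis products per unit absorbed
#' energy, for the two beam qualities supported by the model. Only the five
#' primary species carry non-zero yields.
#'
#' @param beam `"proton"` for the entrance plateau of a 227 MeV proton beam,
#'   or `"electron"` for a 6 MeV electron beam.
#' @return Named numeric vector of G-values in umol/J for `e`, `OH`, `H`,
#'   `H2` and `H2O2`.
#' @export
primary_yields <- function(beam = c("proton", "electron")) {
  beam <- match.arg(beam)
  if (beam == "electron") {
    c(e = 0.280, OH = 0.280, H = 0.0580, H2 = 0.0456, H2O2 = 0.0746)
  } else {
    c(e = 0.260, OH = 0.270, H = 0.0586, H2 = 0.0504, H2O2 = 0.0698)
  }
}
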