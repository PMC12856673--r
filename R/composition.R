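#' Species stoichiometry for proton bookkeeping
#'
#' Describes one molecular species by its molar mass and its hydrogen
#' inventory: carbon-bound (nonexchangeable) protons and labile
#' (exchangeable) hydrogen sites such as hydroxyls.
#'
#' @param name Species label.
#' @param molar_mass Molar mass in g/mol (> 0).
#' @param n_nonexchangeable_H Nonexchangeable protons per molecule (>= 0).
#' @param n_exchangeable_sites Labile hydrogen sites per molecule (>= 0).
#'
#' @return An object of class `species_stoichiometry`.
#' @seealso [sucrose()], [water()] for built-in records.
#' @export
species_stoichiometry <- function(name, molar_mass, n_nonexchangeable_H,
                                  n_exchangeable_sites) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0)
    stop("molar_mass must be a single positive number", call. = FALSE)
  if (n_nonexchangeable_H < 0 || n_exchangeable_sites < 0)
    stop("hydrogen counts must be >= 0", call. = FALSE)
  structure(
    list(name = name,
         molar_mass = molar_mass,
         n_nonexchangeable_H = as.integer(n_nonexchangeable_H),
         n_exchangeable_sites = as.integer(n_exchangeable_sites)),
    class = "species_stoichiometry"
  )
}

#' Built-in sucrose record
#'
#' Sucrose (C12H22O11, 342.30 g/mol) carries 14 carbon-bound protons and
#' 8 hydroxyl sites that exchange with the solvent.
#'
#' @return A [species_stoichiometry()] object.
#' @export
sucrose <- function() {
  species_stoichiometry("sucrose", 342.30, 14L, 8L)
}

#' Built-in solvent records
#'
#' Light water (18.015 g/mol) and heavy water (20.027 g/mol), each with two
#' exchangeable hydrogen sites and no nonexchangeable protons.
#'
#' @param kind `"H2O"` or `"D2O"`.
#' @return A [species_stoichiometry()] object.
#' @export
water <- function(kind = c("H2O", "D2O")) {
  kind <- match.arg(kind)
  if (kind == "H2O") species_stoichiometry("H2O", 18.015, 0L, 2L)
  else species_stoichiometry("D2O", 20.027, 0L, 2L)
}

#' Residual protiation assumed for D2O solvent
#'
#' Commercial heavy water is typically 99.7 atom % D; the matching residual
#' H atom fraction at solvent exchangeable sites is used whenever a mixture
#' in D2O does not state its own value.
#' @export
D2O_RESIDUAL_PROTIATION <- 0.003

#' Sample preparation description
#'
#' A solution of one solute in one solvent, described by the solute mass
#' fraction and the isotopic protiation of the two classes of exchangeable
#' sites. `solvent_protiation` is the atom fraction H at solvent sites
#' (1 for H2O; a small residual for D2O). `solute_site_protiation` is the
#' atom fraction H at solute hydroxyl sites (1 for as-purchased sucrose;
#' < 1 after a freeze-dry deuteration protocol, see
#' [freeze_dry_exchange()]).
#'
#' @param solute_wt_fraction Solute mass fraction in \[0, 1\].
#' @param solvent_kind `"H2O"` or `"D2O"`.
#' @param solvent_protiation Atom fraction H at solvent exchangeable sites;
#'   defaults to 1 for H2O and [D2O_RESIDUAL_PROTIATION] for D2O.
#' @param solute_site_protiation Atom fraction H at solute exchangeable
#'   sites (default 1).
#' @param density Optional mixture density in kg/m^3 (> 0); required only
#'   for molar concentrations, never for proton fractions.
#' @param temperature Temperature in degrees C (metadata only).
#'
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(solute_wt_fraction,
                         solvent_kind = c("H2O", "D2O"),
                         solvent_protiation = NULL,
                         solute_site_protiation = 1,
                         density = NULL,
                         temperature = 25) {
  solvent_kind <- match.arg(solvent_kind)
  if (is.null(solvent_protiation))
    solvent_protiation <- if (solvent_kind == "H2O") 1 else D2O_RESIDUAL_PROTIATION
  fr <- c(solute_wt_fraction = solute_wt_fraction,
          solvent_protiation = solvent_protiation,
          solute_site_protiation = solute_site_protiation)
  bad <- fr < 0 | fr > 1 | !is.finite(fr)
  if (any(bad))
    stop("fractions out of [0, 1]: ", paste(names(fr)[bad], collapse = ", "),
         call. = FALSE)
  if (!is.null(density) && (!is.finite(density) || density <= 0))
    stop("density must be positive (kg/m^3)", call. = FALSE)
  structure(
    list(solute_wt_fraction = solute_wt_fraction,
         solvent_kind = solvent_kind,
         solvent_protiation = solvent_protiation,
         solute_site_protiation = solute_site_protiation,
         density = density,
         temperature = temperature),
    class = "mixture_spec"
  )
}

# moles of solute/solvent per kg of mixture
.moles_per_kg <- function(mix, solute, solvent) {
  list(solute = 1000 * mix$solute_wt_fraction / solute$molar_mass,
       solvent = 1000 * (1 - mix$solute_wt_fraction) / solvent$molar_mass)
}

# labile-H occupancy after full scrambling over all exchangeable sites
.scrambled_occupancy <- function(mix, solute, solvent) {
  n <- .moles_per_kg(mix, solute, solvent)
  sites_solvent <- solvent$n_exchangeable_sites * n$solvent
  sites_solute  <- solute$n_exchangeable_sites * n$solute
  sites <- sites_solvent + sites_solute
  labile <- mix$solvent_protiation * sites_solvent +
    mix$solute_site_protiation * sites_solute
  list(occupancy = if (sites > 0) labile / sites else 0,
       sites_solvent = sites_solvent, sites_solute = sites_solute,
       labile = labile, n = n)
}

#' Proton inventory of a prepared sample
#'
#' Converts a sample preparation into concentrations and fractions of
#' exchangeable and nonexchangeable protons. Labile hydrogen is assumed to
#' scramble uniformly over all exchangeable sites (solvent plus solute
#' hydroxyls), consistent with rapid cyclic proton exchange; no equilibrium
#' isotope fractionation is applied. Fractions are always available;
#' concentrations are in mol/m^3 when a density is known and per kg of
#' mixture otherwise (see the `basis` field).
#'
#' @param mix A [mixture_spec()].
#' @param solute,solvent [species_stoichiometry()] records; default sucrose
#'   and the solvent matching `mix$solvent_kind`.
#'
#' @return An object of class `proton_inventory` with fields `A_tot`
#'   (protons at solvent exchangeable sites), `B_tot` (protons at solute
#'   exchangeable sites), `C_nonexch` (carbon-bound solute protons), pool
#'   fractions `x_A`, `x_B` among exchangeable protons, global fractions
#'   `xp_exch`, `xp_non`, the scrambled site `occupancy`, and `basis`
#'   (`"mol_per_m3"` or `"mol_per_kg"`).
#' @export
#'
#' @examples
#' proton_inventory(mixture_spec(0.5, "H2O"))
proton_inventory <- function(mix, solute = sucrose(),
                             solvent = water(mix$solvent_kind)) {
  stopifnot(inherits(mix, "mixture_spec"),
            inherits(solute, "species_stoichiometry"),
            inherits(solvent, "species_stoichiometry"))
  sc <- .scrambled_occupancy(mix, solute, solvent)
  A <- sc$occupancy * sc$sites_solvent     # mol H per kg at solvent sites
  B <- sc$occupancy * sc$sites_solute      # mol H per kg at solute sites
  C <- solute$n_nonexchangeable_H * sc$n$solute
  total <- A + B + C
  if (total <= 0)
    stop("no proton signal: sample contains no protons", call. = FALSE)
  scale <- if (!is.null(mix$density)) mix$density else 1
  structure(
    list(A_tot = A * scale, B_tot = B * scale, C_nonexch = C * scale,
         x_A = if (A + B > 0) A / (A + B) else NA_real_,
         x_B = if (A + B > 0) B / (A + B) else NA_real_,
         xp_exch = (A + B) / total,
         xp_non = C / total,
         occupancy = sc$occupancy,
         basis = if (!is.null(mix$density)) "mol_per_m3" else "mol_per_kg",
         mix = mix),
    class = "proton_inventory"
  )
}

#' @export
print.proton_inventory <- function(x, ...) {
  cat(sprintf("Proton inventory (%s, %.1f wt%%, basis %s)\n",
              x$mix$solvent_kind, 100 * x$mix$solute_wt_fraction, x$basis))
  cat(sprintf("  A_tot = %.4g  B_tot = %.4g  C_nonexch = %.4g\n",
              x$A_tot, x$B_tot, x$C_nonexch))
  cat(sprintf("  x_A = %.4f  x_B = %.4f  xp_exch = %.4f  xp_non = %.4f\n",
              x$x_A, x$x_B, x$xp_exch, x$xp_non))
  invisible(x)
}

#' Equilibrium hydroxyl protiation after dissolution (freeze-dry protocol)
#'
#' For a solute pre-equilibrated in a (partially) deuterated solvent and
#' then freeze-dried, returns the equilibrium H occupancy of exchangeable
#' sites in the stage-1 solution: total labile H divided by total
#' exchangeable sites. Freeze-drying removes the solvent without altering
#' the solute site occupancy, so the returned value becomes the
#' `solute_site_protiation` of the reconstituted sample.
#'
#' @param stage1 A [mixture_spec()] describing the pre-lyophilization
#'   solution (e.g. 20 wt% sucrose in D2O).
#' @inheritParams proton_inventory
#' @return Equilibrium H atom fraction at exchangeable sites, in \[0, 1\].
#' @export
#'
#' @examples
#' # 20 wt% sucrose in ideal D2O
#' freeze_dry_exchange(mixture_spec(0.20, "D2O", solvent_protiation = 0))
freeze_dry_exchange <- function(stage1, solute = sucrose(),
                                solvent = water(stage1$solvent_kind)) {
  sc <- .scrambled_occupancy(stage1, solute, solvent)
  if (sc$sites_solvent + sc$sites_solute <= 0)
    stop("stage-1 mixture has no exchangeable sites", call. = FALSE)
  sc$occupancy
}

#' Empirical density of aqueous sucrose solutions at 25 degrees C
#'
#' Quadratic correlation fitted to standard density tables,
#' rho = 997.0 + 3.7819 P + 0.017443 P^2 with P the sucrose wt%.
#' Intended as a convenience fallback when a measured density is not
#' available; proton fractions never require it.
#'
#' @param wt_fraction Sucrose mass fraction in \[0, 1\] (vectorized).
#' @return Density in kg/m^3.
#' @export
sucrose_solution_density <- function(wt_fraction) {
  stopifnot(all(wt_fraction >= 0 & wt_fraction <= 1))
  P <- 100 * wt_fraction
  997.0 + 3.7819 * P + 0.017443 * P^2
}

#' Molar proton concentrations from a mass-based preparation
#'
#' Multiplies the per-kilogram proton inventory by the mixture density to
#' give mol/m^3 concentrations, the units in which the pseudo-first-order
#' exchange coefficients kA = kex * B_tot and kB = kex * A_tot are formed.
#'
#' @inheritParams proton_inventory
#' @param density Mixture density in kg/m^3; taken from `mix` when omitted
#'   there. When neither is given an error points to
#'   [sucrose_solution_density()].
#' @return A list with `A_tot`, `B_tot`, `C_nonexch` in mol/m^3.
#' @export
wt_to_concentrations <- function(mix, solute = sucrose(),
                                 solvent = water(mix$solvent_kind),
                                 density = mix$density) {
  if (is.null(density))
    stop("density (kg/m^3) is required for molar concentrations; ",
         "supply one or use sucrose_solution_density() for aqueous sucrose",
         call. = FALSE)
  if (!is.finite(density) || density <= 0)
    stop("density must be positive (kg/m^3)", call. = FALSE)
  mix$density <- density
  inv <- proton_inventory(mix, solute, solvent)
  list(A_tot = inv$A_tot, B_tot = inv$B_tot, C_nonexch = inv$C_nonexch)
}

#' Read mixture specifications from a config file
#'
#' Reads a YAML or JSON file holding a list of mixture records with fields
#' `wt_percent`, `solvent`, and optionally `solvent_protiation`,
#' `solute_site_protiation`, `density`, `temperature`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of [mixture_spec()] objects.
#' @export
read_mixtures <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unsupported config format: .", ext, call. = FALSE))
  if (!is.null(raw$mixtures)) raw <- raw$mixtures
  lapply(raw, function(r) {
    mixture_spec(
      solute_wt_fraction = r$wt_percent / 100,
      solvent_kind = r$solvent,
      solvent_protiation = r$solvent_protiation,
      solute_site_protiation = if (is.null(r$solute_site_protiation)) 1
                               else r$solute_site_protiation,
      density = r$density,
      temperature = if (is.null(r$temperature)) 25 else r$temperature)
  })
}

#' Tabulate proton inventories
#'
#' @param inventories A list of [proton_inventory()] objects.
#' @param path Optional CSV path; when given the table is also written.
#' @return A data.frame with columns `wt_percent`, `solvent`, `A_tot`,
#'   `B_tot`, `C_nonexch`, `x_A`, `x_B`, `xp_exch`, `xp_non`.
#' @export
inventory_table <- function(inventories, path = NULL) {
  stopifnot(length(inventories) > 0)
  df <- do.call(rbind, lapply(inventories, function(iv) {
    data.frame(wt_percent = 100 * iv$mix$solute_wt_fraction,
               solvent = iv$mix$solvent_kind,
               A_tot = iv$A_tot, B_tot = iv$B_tot, C_nonexch = iv$C_nonexch,
               x_A = iv$x_A, x_B = iv$x_B,
               xp_exch = iv$xp_exch, xp_non = iv$xp_non)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
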