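#' Ideal-gas molar volume
#'
#' \eqn{V_m = R T / P} with \eqn{R = 0.082057} L atm / (mol K). At 298.15 K
#' and 1 atm this gives 24.46 L/mol (two decimals), the value used to
#' convert reactor gas flows to molar rates.
#'
#' @param temperature_K Temperature in kelvin (default 298.15).
#' @param pressure_atm Pressure in atmospheres (default 1).
#' @return Molar volume in L/mol.
#' @export
molar_volume <- function(temperature_K = 298.15, pressure_atm = 1) {
  if (temperature_K <= 0 || pressure_atm <= 0) {
    stop("temperature and pressure must be positive", call. = FALSE)
  }
  0.082057 * temperature_K / pressure_atm
}

#' Bundle reactor gas measurements
#'
#' @param q_in Gas input rate in litres of gas per litre of reactor per day.
#' @param fractions Named vector of molar gas fractions over `h2`, `ch4`,
#'   `co2`, summing to one.
#' @param molar_volume Molar volume in L/mol (default 24.46, ideal gas at
#'   298 K).
#' @param biomass_density Community dry mass per reactor volume in gDW/L
#'   (default 1.17).
#' @return A `gas_measurements` list.
#' @export
gas_measurements <- function(q_in,
                             fractions = c(h2 = 0.62, ch4 = 0.23, co2 = 0.15),
                             molar_volume = 24.46, biomass_density = 1.17) {
  if (q_in < 0) stop("q_in must be non-negative", call. = FALSE)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("gas fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (molar_volume <= 0 || biomass_density <= 0) {
    stop("molar_volume and biomass_density must be positive", call. = FALSE)
  }
  structure(list(q_in = q_in, fractions = fractions,
                 molar_volume = molar_volume,
                 biomass_density = biomass_density),
            class = "gas_measurements")
}

#' Convert a gas measurement to a specific flux
#'
#' \deqn{flux = \frac{q_{in} \cdot x_{gas} \cdot 1000}
#'                   {V_m \cdot \rho_X \cdot 24}}
#' where \eqn{q_{in}} is in L gas / L reactor / day, \eqn{x_{gas}} the molar
#' fraction, \eqn{V_m} the molar volume (L/mol) and \eqn{\rho_X} the
#' biomass density (gDW/L); the result is in mmol/gDW/h. The map is linear
#' in both `q_in` and the fraction.
#'
#' @param measurements A [gas_measurements()] object.
#' @param gas One of the fraction names (`"h2"`, `"ch4"`, `"co2"`).
#' @return Specific flux in mmol/gDW/h.
#' @export
gas_to_flux <- function(measurements, gas) {
  stopifnot(inherits(measurements, "gas_measurements"))
  if (!gas %in% names(measurements$fractions)) {
    stop("unknown gas '", gas, "'; have: ",
         paste(names(measurements$fractions), collapse = ", "),
         call. = FALSE)
  }
  measurements$q_in * measurements$fractions[[gas]] * 1000 /
    (measurements$molar_volume * measurements$biomass_density * 24)
}

#' Reactor operating point
#'
#' The experimental boundary conditions of the upgrading reactor expressed
#' as community-level flux constraints: forced CO2 and H2 uptake rates, a
#' minimum CH4 export rate, and the set of volatile fatty acids whose net
#' community accumulation is pinned to zero (interspecies transfer through
#' the shared pool stays free). Rates are stored as positive magnitudes and
#' signed on application (uptake-negative convention). The defaults are the
#' measured operating point of the thermophilic biofilm reactors: CO2 and
#' H2 uptake 1.20 and 5.11 mmol/gDW/h, CH4 export at least 1.15 mmol/gDW/h.
#'
#' @param co2_uptake,h2_uptake Fixed community uptake rates (mmol/gDW/h);
#'   `NULL` leaves the corresponding exchange untouched.
#' @param ch4_min_export Minimum CH4 export rate (mmol/gDW/h) or `NULL`.
#' @param vfa_ids Environment metabolite ids pinned to zero net exchange.
#' @param gas_ids Mapping from the three roles to environment metabolite
#'   ids.
#' @return An `operating_point` list.
#' @export
operating_point <- function(co2_uptake = 1.20, h2_uptake = 5.11,
                            ch4_min_export = 1.15,
                            vfa_ids = c("ac", "ppa", "but"),
                            gas_ids = c(co2 = "co2", h2 = "h2",
                                        ch4 = "ch4")) {
  rates <- c(co2_uptake, h2_uptake, ch4_min_export)
  if (any(rates[!vapply(list(co2_uptake, h2_uptake, ch4_min_export),
                        is.null, logical(1))] < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  structure(list(co2_uptake = co2_uptake, h2_uptake = h2_uptake,
                 ch4_min_export = ch4_min_export, vfa_ids = vfa_ids,
                 gas_ids = gas_ids),
            class = "operating_point")
}

#' Pin a community model to a reactor operating point
#'
#' Sets the community CO2 and H2 exchange bounds to `lb = ub = -uptake`
#' (forced uptake), the CH4 exchange lower bound to `+ch4_min_export`, and
#' each listed volatile fatty acid's community exchange to `(0, 0)` so the
#' medium accumulates none of it while species-level exchanges -- and hence
#' cross-feeding through the shared pool -- stay unconstrained.
#'
#' @param community A `community_model` with exchanges for the named gases.
#' @param op An [operating_point()].
#' @return A new `community_model`.
#' @export
apply_operating_point <- function(community, op) {
  stopifnot(inherits(community, "community_model"),
            inherits(op, "operating_point"))
  g <- op$gas_ids
  if (!is.null(op$co2_uptake)) {
    community <- set_community_exchange_bounds(
      community, g[["co2"]], lb = -op$co2_uptake, ub = -op$co2_uptake)
  }
  if (!is.null(op$h2_uptake)) {
    community <- set_community_exchange_bounds(
      community, g[["h2"]], lb = -op$h2_uptake, ub = -op$h2_uptake)
  }
  if (!is.null(op$ch4_min_export)) {
    community <- set_community_exchange_bounds(
      community, g[["ch4"]], lb = op$ch4_min_export)
  }
  for (vfa in intersect(op$vfa_ids,
                        community_exchanges(community)$metabolite)) {
    community <- set_community_exchange_bounds(community, vfa, lb = 0, ub = 0)
  }
  community
}
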