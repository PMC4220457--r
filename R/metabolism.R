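#' Metabolic parameter table
#'
#' Loads (or returns the packaged default) per-phylogenetic-group parameters
#' of the metabolic regression `ln I = ln_i0 + a * ln M - E / (k * T)`, with
#' I in J/h, M in mg fresh mass, T in Kelvin and k the Boltzmann constant
#' (8.617e-5 eV/K). `ln_i0` is the normalization intercept, `a` the allometric
#' mass exponent and `E` the activation energy in eV.
#'
#' The packaged values are editable defaults in the range reported for soil
#' invertebrate groups by the phylogenetically resolved metabolic literature;
#' analyses of real material should substitute the fitted table for their
#' fauna.
#'
#' @param path CSV with columns group, ln_i0, a, E. NULL loads the default.
#' @return Data frame of class `metabolic_params`.
#' @export
read_metabolic_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "metabolic_params.csv",
                        package = "trophicflux", mustWork = TRUE)
  p <- read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("group", "ln_i0", "a", "E"), names(p))
  if (length(need))
    stop("metabolic params missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(p$a <= 0)) stop("mass exponents a must be > 0", call. = FALSE)
  if (any(p$E < 0)) stop("activation energies E must be >= 0", call. = FALSE)
  if (anyDuplicated(p$group)) stop("duplicated group labels", call. = FALSE)
  class(p) <- c("metabolic_params", "data.frame")
  p
}

#' Taxon-to-group mapping for metabolic parameters
#'
#' @param path CSV with columns taxon_key, group; NULL loads the packaged
#'   mapping matching the default allometric registry.
#' @return Data frame mapping each taxon_key to exactly one group.
#' @export
read_taxon_groups <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "taxon_groups.csv",
                        package = "trophicflux", mustWork = TRUE)
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(m$taxon_key))
    stop("each taxon_key must map to exactly one group", call. = FALSE)
  m
}

#' Individual metabolic rate
#'
#' Evaluates `I = exp(ln_i0 + a * ln M - E / (k * T))` for each individual:
#' strictly increasing in body mass, and in temperature whenever E > 0.
#'
#' @param mass_mg Body mass vector, mg fresh mass (> 0).
#' @param temperature_K Temperature in Kelvin (scalar or vector, > 0).
#' @param group Phylogenetic group label(s) present in `params`.
#' @param params A [read_metabolic_params()] table.
#' @return Metabolic rates in J/h.
#' @export
#' @examples
#' p <- read_metabolic_params()
#' individual_metabolic_rate(10, 298.15, "Insecta", p)
individual_metabolic_rate <- function(mass_mg, temperature_K, group, params) {
  n <- max(length(mass_mg), length(temperature_K), length(group))
  mass_mg <- rep_len(mass_mg, n)
  temperature_K <- rep_len(temperature_K, n)
  group <- rep_len(group, n)
  if (any(mass_mg <= 0) || anyNA(mass_mg))
    stop("body masses must be positive and non-missing", call. = FALSE)
  if (any(temperature_K <= 0))
    stop("temperature must be positive Kelvin", call. = FALSE)
  row <- match(group, params$group)
  if (anyNA(row))
    stop("unknown metabolic group(s): ",
         paste(unique(group[is.na(row)]), collapse = ", "), call. = FALSE)
  exp(params$ln_i0[row] + params$a[row] * log(mass_mg) -
        params$E[row] / (BOLTZMANN_EV * temperature_K))
}

#' Community metabolism of a site
#'
#' Sums individual metabolic rates per guild and across the community at the
#' site's mean soil temperature, normalized by sampled area. This is the
#' guild-level metabolic demand X that the energy-flux balance must cover.
#'
#' @param site A `site_community` with fresh masses present.
#' @param params A [read_metabolic_params()] table.
#' @param groups A [read_taxon_groups()] mapping.
#' @return Data frame with one row per guild plus "total": `X_J_h_site`
#'   (J/h per site) and `X_J_h_m2` (J/h/m^2).
#' @export
community_metabolism <- function(site, params = read_metabolic_params(),
                                 groups = read_taxon_groups()) {
  if (is.null(site$temperature_C) || is.na(site$temperature_C))
    stop("site temperature is missing", call. = FALSE)
  ind <- site$individuals
  area <- sampled_area(site)
  if (nrow(ind) == 0) {
    per_guild <- setNames(numeric(length(GUILDS)), GUILDS)
  } else {
    if (anyNA(ind$fresh_mass_mg))
      stop("all individuals must carry a fresh mass; run impute_missing_mass()",
           call. = FALSE)
    grp <- groups$group[match(ind$taxon_key, groups$taxon_key)]
    if (anyNA(grp))
      stop("taxon key(s) missing from group mapping: ",
           paste(unique(ind$taxon_key[is.na(grp)]), collapse = ", "),
           call. = FALSE)
    rate <- individual_metabolic_rate(ind$fresh_mass_mg,
                                      site$temperature_C + 273.15, grp, params)
    per_guild <- vapply(GUILDS, function(g) sum(rate[ind$guild == g]), numeric(1))
  }
  site_total <- c(per_guild, total = sum(per_guild))
  data.frame(guild = names(site_total),
             X_J_h_site = unname(site_total),
             X_J_h_m2 = unname(site_total) / area,
             stringsAsFactors = FALSE)
}
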