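#' Length--mass regression registry
#'
#' Loads (or returns the packaged default) taxon-keyed allometric registry
#' mapping body length (mm) to body mass via the power law `M = a * L^b`.
#' Entries on a dry-mass basis carry a dry-to-fresh conversion factor.
#' Each entry may name a coarser `fallback_key` used when a measured length
#' falls outside the entry's validated length range; the chain must be
#' acyclic and end at a single universal default entry (empty fallback).
#'
#' The packaged defaults are literature-typical values for common litter
#' macroinvertebrate groups. They are deliberately editable stand-ins: any
#' analysis of real material should substitute the regression table assembled
#' for that fauna.
#'
#' @param path CSV with columns taxon_key, a, b, mass_basis
#'   (dry|fresh), dry_to_fresh_factor, len_min_mm, len_max_mm, fallback_key.
#' @return Data frame of class `allometry_registry`.
#' @export
read_allometry_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "length_mass_registry.csv",
                        package = "trophicflux", mustWork = TRUE)
  reg <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_key", "a", "b", "mass_basis", "dry_to_fresh_factor",
            "len_min_mm", "len_max_mm", "fallback_key")
  missing_cols <- setdiff(need, names(reg))
  if (length(missing_cols))
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  reg$fallback_key[is.na(reg$fallback_key) | reg$fallback_key == ""] <- NA_character_
  validate_registry(reg)
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$taxon_key))
    stop("registry has duplicated taxon keys", call. = FALSE)
  if (any(reg$a <= 0)) stop("registry coefficients a must be > 0", call. = FALSE)
  if (any(reg$len_min_mm >= reg$len_max_mm))
    stop("registry has an empty valid length range", call. = FALSE)
  if (!all(reg$mass_basis %in% c("dry", "fresh")))
    stop("mass_basis must be 'dry' or 'fresh'", call. = FALSE)
  dry <- reg$mass_basis == "dry"
  if (any(dry & (is.na(reg$dry_to_fresh_factor) | reg$dry_to_fresh_factor <= 0)))
    stop("dry-basis entries need dry_to_fresh_factor > 0", call. = FALSE)
  roots <- is.na(reg$fallback_key)
  if (sum(roots) != 1)
    stop("registry must contain exactly one universal default entry (empty fallback_key)",
         call. = FALSE)
  # acyclicity: walking up from any entry must reach the default
  for (k in reg$taxon_key) {
    seen <- character()
    cur <- k
    while (!is.na(cur)) {
      if (cur %in% seen)
        stop(sprintf("fallback chain contains a cycle at '%s'", cur), call. = FALSE)
      seen <- c(seen, cur)
      row <- match(cur, reg$taxon_key)
      if (is.na(row))
        stop(sprintf("fallback key '%s' not present in registry", cur), call. = FALSE)
      cur <- reg$fallback_key[[row]]
    }
  }
  class(reg) <- c("allometry_registry", "data.frame")
  reg
}

#' Estimate fresh body mass from body length
#'
#' Applies the taxon's power-law regression `M = a * L^b`, multiplying by the
#' dry-to-fresh factor for dry-basis entries. If the length falls outside the
#' entry's validated range, the fallback chain (family -> order -> class ->
#' universal default) is climbed until an entry accepts the length; the
#' universal default applies unconditionally. Taxa absent from the registry
#' resolve directly to the universal default. Any use of an entry other than
#' the directly keyed one is flagged `fallback_regression`.
#'
#' @param length_mm Numeric vector of body lengths (> 0), in mm.
#' @param taxon_key Character vector (recycled) of registry keys.
#' @param registry An [read_allometry_registry()] table.
#' @return Data frame with columns `fresh_mass_mg`, `mass_source`
#'   ("measured_regression" or "fallback_regression") and `taxon_used`.
#' @export
#' @examples
#' reg <- read_allometry_registry()
#' estimate_fresh_mass(c(2, 5), "Araneae", reg)
estimate_fresh_mass <- function(length_mm, taxon_key, registry) {
  n <- max(length(length_mm), length(taxon_key))
  length_mm <- rep_len(length_mm, n)
  taxon_key <- rep_len(taxon_key, n)
  if (any(!is.na(length_mm) & length_mm <= 0))
    stop("body lengths must be positive", call. = FALSE)
  out <- data.frame(fresh_mass_mg = rep(NA_real_, n),
                    mass_source = rep(NA_character_, n),
                    taxon_used = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  default_key <- registry$taxon_key[is.na(registry$fallback_key)]
  for (i in seq_len(n)) {
    L <- length_mm[[i]]
    if (is.na(L)) next
    key <- taxon_key[[i]]
    used <- if (key %in% registry$taxon_key) key else default_key
    fell_back <- !identical(used, key)
    repeat {
      row <- registry[match(used, registry$taxon_key), ]
      in_range <- L >= row$len_min_mm && L <= row$len_max_mm
      if (in_range || is.na(row$fallback_key)) break
      used <- row$fallback_key
      fell_back <- TRUE
    }
    mass <- row$a * L^row$b
    if (row$mass_basis == "dry") mass <- mass * row$dry_to_fresh_factor
    out$fresh_mass_mg[[i]] <- mass
    out$mass_source[[i]] <- if (fell_back) "fallback_regression" else "measured_regression"
    out$taxon_used[[i]] <- used
  }
  out
}

#' Attach estimated fresh masses to an individuals table
#'
#' Convenience wrapper: runs [estimate_fresh_mass()] on every measurable
#' record and leaves damaged records (missing length) with missing mass for
#' [impute_missing_mass()].
#'
#' @param individuals Data frame with columns body_length_mm and taxon_key.
#' @inheritParams estimate_fresh_mass
#' @return The table with fresh_mass_mg and mass_source columns added.
#' @export
add_fresh_mass <- function(individuals, registry) {
  est <- estimate_fresh_mass(individuals$body_length_mm,
                             individuals$taxon_key, registry)
  individuals$fresh_mass_mg <- est$fresh_mass_mg
  individuals$mass_source <- est$mass_source
  individuals
}

#' Impute fresh mass for damaged specimens
#'
#' Records with missing fresh mass receive the median estimated fresh mass of
#' measured conspecifics; when fewer than two conspecifics were measured, the
#' median of measured individuals sharing the record's taxon key (the
#' order-level registry grouping) is used instead. Measured records are never
#' altered and the record count is conserved.
#'
#' @param records Data frame with columns species_id, taxon_key,
#'   fresh_mass_mg (NA where missing) and mass_source.
#' @return The table with all masses present; imputed rows carry mass_source
#'   "imputed_species_median" or "imputed_order_median".
#' @export
impute_missing_mass <- function(records) {
  miss <- which(is.na(records$fresh_mass_mg))
  if (!length(miss)) return(records)
  measured <- !is.na(records$fresh_mass_mg)
  stranded <- character()
  for (i in miss) {
    sp <- records$species_id[[i]]
    conspecific <- measured & records$species_id == sp
    if (sum(conspecific) >= 2) {
      records$fresh_mass_mg[[i]] <- median(records$fresh_mass_mg[conspecific])
      records$mass_source[[i]] <- "imputed_species_median"
    } else {
      ordinal <- measured & records$taxon_key == records$taxon_key[[i]]
      if (!any(ordinal)) {
        stranded <- c(stranded, sprintf("%s (%s)", sp, records$taxon_key[[i]]))
        next
      }
      records$fresh_mass_mg[[i]] <- median(records$fresh_mass_mg[ordinal])
      records$mass_source[[i]] <- "imputed_order_median"
    }
  }
  if (length(stranded))
    stop("no measured conspecifics or ordinal relatives to impute from: ",
         paste(unique(stranded), collapse = "; "), call. = FALSE)
  records
}

#' Community biomass per unit area
#'
#' Sums individual fresh masses per guild and for the whole community and
#' normalizes by the sampled area (subplots x subplot area). Reported both in
#' mg fresh mass per m^2 and kg per ha (`kg/ha = mg/m2 * 1e-6 * 1e4`).
#'
#' @param site A `site_community` whose individuals all carry fresh_mass_mg.
#' @return Data frame with one row per guild plus a "total" row and columns
#'   `biomass_mg_m2`, `biomass_kg_ha`.
#' @export
community_biomass <- function(site) {
  area <- sampled_area(site)
  if (area <= 0) stop("sampled area must be positive", call. = FALSE)
  ind <- site$individuals
  if (nrow(ind) && anyNA(ind$fresh_mass_mg))
    stop("all individuals must carry a fresh mass; run impute_missing_mass()",
         call. = FALSE)
  per_guild <- vapply(GUILDS, function(g)
    sum(ind$fresh_mass_mg[ind$guild == g]) / area, numeric(1))
  mg_m2 <- c(per_guild, total = sum(per_guild))
  data.frame(guild = names(mg_m2), biomass_mg_m2 = unname(mg_m2),
             biomass_kg_ha = unname(mg_m2) * 1e-6 * 1e4,
             stringsAsFactors = FALSE)
}
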