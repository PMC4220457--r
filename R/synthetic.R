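#' Configuration for a synthetic land-use-gradient study
#'
#' Builds the full parameter set for the synthetic study generator. Defaults
#' emulate a replicated tropical land-use gradient: four transformation
#' systems (secondary forest, jungle rubber, rubber, oil palm) crossed with
#' two landscapes and four replicates (32 sites), each site sampled with
#' three 1-m^2 litter subplots. Per-system multipliers impose multiplicative
#' declines in expected animal density, species-pool retention and mean body
#' mass relative to forest (the reference system, all multipliers 1).
#'
#' Default effect sizes follow the gradient the generator is meant to
#' emulate: oil palm holds roughly half the animal density of forest, loses
#' close to half the species pool and carries slightly lighter animals;
#' jungle rubber and rubber sit in between. Baseline density and species-pool
#' sizes are calibrated so a default study yields on the order of 7,500
#' individuals and 850--900 morphospecies overall.
#'
#' @param systems Ordered system labels; the first is the reference.
#' @param n_landscapes Number of landscapes (random-effect grouping).
#' @param replicates_per_system_per_landscape Sites per system per landscape.
#' @param subplots_per_site Subsamples per site (default 3).
#' @param subplot_area_m2 Area of one subsample in m^2 (default 1).
#' @param base_density_m2 Expected individuals per m^2 in the reference
#'   system, summed over guilds.
#' @param guild_fractions Named proportions of individuals per feeding guild;
#'   must sum to 1.
#' @param species_pool_size Named integer vector: regional species-pool size
#'   per guild.
#' @param abundance_model List with `type` ("lognormal" or "logseries") and
#'   its parameter (`sdlog` for lognormal relative-abundance weights;
#'   `p` in (0,1) for the logarithmic-series distribution), plus
#'   `turnover_sdlog` (>= 0): the sd of a lognormal site-level perturbation
#'   of every species' weight, generating between-site compositional
#'   turnover (beta diversity). 0 means identical relative abundances at
#'   every site.
#' @param body_length List per guild of `c(meanlog, sdlog)` for lognormal
#'   body lengths in mm.
#' @param density_multiplier,richness_retention,body_mass_multiplier Named
#'   per-system factors (> 0) on expected density, species-pool retention
#'   probability and mean fresh body mass; the reference system must be 1.
#' @param temperature_C Matrix (systems x landscapes) of mean soil
#'   temperatures in degrees Celsius.
#' @param prop_damaged Probability that an individual's body length is
#'   unmeasurable (missing), to exercise mass imputation.
#' @param seed Root integer seed; per-site substreams are derived from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(seed = 42)
#' length(generate_study(cfg)$sites)  # 32
synth_config <- function(systems = c("forest", "jungle_rubber", "rubber", "oil_palm"),
                         n_landscapes = 2,
                         replicates_per_system_per_landscape = 4,
                         subplots_per_site = 3,
                         subplot_area_m2 = 1,
                         base_density_m2 = 95,
                         guild_fractions = c(predator = 0.25, omnivore = 0.15,
                                             detritivore = 0.45, herbivore = 0.15),
                         species_pool_size = c(predator = 459, omnivore = 272,
                                               detritivore = 612, herbivore = 357),
                         abundance_model = list(type = "lognormal", sdlog = 2.0,
                                                turnover_sdlog = 2.2),
                         body_length = list(
                           predator    = c(meanlog = log(4.0), sdlog = 0.55),
                           omnivore    = c(meanlog = log(3.5), sdlog = 0.50),
                           detritivore = c(meanlog = log(4.5), sdlog = 0.50),
                           herbivore   = c(meanlog = log(3.0), sdlog = 0.45)),
                         density_multiplier = c(forest = 1, jungle_rubber = 0.85,
                                                rubber = 0.92, oil_palm = 0.52),
                         richness_retention = c(forest = 1, jungle_rubber = 0.88,
                                                rubber = 0.86, oil_palm = 0.60),
                         body_mass_multiplier = c(forest = 1, jungle_rubber = 0.98,
                                                  rubber = 0.97, oil_palm = 0.92),
                         temperature_C = NULL,
                         prop_damaged = 0.02,
                         seed = 1L) {
  if (is.null(temperature_C)) {
    temperature_C <- matrix(
      c(24.8, 25.2,   # forest
        25.6, 26.0,   # jungle rubber
        26.4, 26.8,   # rubber
        27.6, 28.0),  # oil palm
      nrow = length(systems), ncol = n_landscapes, byrow = TRUE,
      dimnames = list(systems, paste0("L", seq_len(n_landscapes))))
    if (nrow(temperature_C) != length(systems)) {
      temperature_C <- matrix(26, length(systems), n_landscapes,
                              dimnames = list(systems, paste0("L", seq_len(n_landscapes))))
    }
  }
  cfg <- structure(list(
    systems = systems,
    n_landscapes = as.integer(n_landscapes),
    replicates_per_system_per_landscape = as.integer(replicates_per_system_per_landscape),
    subplots_per_site = as.integer(subplots_per_site),
    subplot_area_m2 = subplot_area_m2,
    base_density_m2 = base_density_m2,
    guild_fractions = guild_fractions,
    species_pool_size = species_pool_size,
    abundance_model = abundance_model,
    body_length = body_length,
    density_multiplier = density_multiplier,
    richness_retention = richness_retention,
    body_mass_multiplier = body_mass_multiplier,
    temperature_C = temperature_C,
    prop_damaged = prop_damaged,
    seed = as.integer(seed)
  ), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid synthetic configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (length(cfg$systems) < 1 || anyDuplicated(cfg$systems))
    fail("systems", "must be a non-empty set of unique labels")
  ref <- cfg$systems[[1]]
  if (cfg$subplots_per_site < 1) fail("subplots_per_site", "must be >= 1")
  if (cfg$subplot_area_m2 <= 0) fail("subplot_area_m2", "must be > 0")
  if (cfg$base_density_m2 < 0) fail("base_density_m2", "must be >= 0")
  if (cfg$n_landscapes < 1) fail("n_landscapes", "must be >= 1")
  if (cfg$replicates_per_system_per_landscape < 1)
    fail("replicates_per_system_per_landscape", "must be >= 1")
  if (!setequal(names(cfg$guild_fractions), GUILDS))
    fail("guild_fractions", "must be named by the four feeding guilds")
  if (any(cfg$guild_fractions < 0) || abs(sum(cfg$guild_fractions) - 1) > 1e-8)
    fail("guild_fractions", "must be nonnegative and sum to 1")
  if (!setequal(names(cfg$species_pool_size), GUILDS) ||
      any(cfg$species_pool_size < 1))
    fail("species_pool_size", "must give a pool size >= 1 per guild")
  am <- cfg$abundance_model
  if (!am$type %in% c("lognormal", "logseries"))
    fail("abundance_model", "type must be 'lognormal' or 'logseries'")
  if (am$type == "lognormal" && (is.null(am$sdlog) || am$sdlog <= 0))
    fail("abundance_model", "lognormal model needs sdlog > 0")
  if (am$type == "logseries" &&
      (is.null(am$p) || am$p <= 0 || am$p >= 1))
    fail("abundance_model", "logseries model needs p in (0, 1)")
  if (!is.null(am$turnover_sdlog) && am$turnover_sdlog < 0)
    fail("abundance_model", "turnover_sdlog must be >= 0")
  for (g in GUILDS) {
    bl <- cfg$body_length[[g]]
    if (is.null(bl) || bl[["sdlog"]] <= 0)
      fail("body_length", sprintf("guild '%s' needs a lognormal with sdlog > 0", g))
  }
  for (nm in c("density_multiplier", "richness_retention", "body_mass_multiplier")) {
    m <- cfg[[nm]]
    if (!all(cfg$systems %in% names(m)))
      fail(nm, "must be named by every system")
    if (any(m < 0)) fail(nm, "must be nonnegative")
    if (abs(m[[ref]] - 1) > 1e-12)
      fail(nm, sprintf("must equal 1 for the reference system '%s'", ref))
  }
  if (any(cfg$richness_retention > 1))
    fail("richness_retention", "is a probability and must be <= 1")
  if (!all(dim(cfg$temperature_C) == c(length(cfg$systems), cfg$n_landscapes)))
    fail("temperature_C", "must be a systems x landscapes matrix")
  if (cfg$prop_damaged < 0 || cfg$prop_damaged >= 1)
    fail("prop_damaged", "must be in [0, 1)")
  cfg
}

# Taxon keys (family/order/class level) available to each guild; each pool
# species is pinned to one so allometric and metabolic lookups resolve.
GUILD_TAXA <- list(
  predator    = c("Araneae", "Chilopoda", "Formicidae", "Coleoptera"),
  omnivore    = c("Formicidae", "Blattodea", "Coleoptera", "Orthoptera"),
  detritivore = c("Isopoda", "Diplopoda", "Oligochaeta", "Blattodea", "Coleoptera"),
  herbivore   = c("Hemiptera", "Orthoptera", "Gastropoda", "Larvae")
)

# Relative-abundance weight per species under the configured rank-abundance
# model. Lognormal: iid lognormal weights. Logseries: abundances drawn from
# the logarithmic-series distribution P(n) = -p^n / (n log(1 - p)).
draw_abundance_weights <- function(n, model) {
  if (model$type == "lognormal") {
    rlnorm(n, meanlog = 0, sdlog = model$sdlog)
  } else {
    rlogseries(n, model$p)
  }
}

# Inverse-CDF sampler for the logarithmic-series distribution.
rlogseries <- function(n, p) {
  u <- runif(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    k <- 1
    cum <- -p / log(1 - p)
    while (u[i] > cum && k < 1e6) {
      k <- k + 1
      cum <- cum + (-p^k / (k * log(1 - p)))
    }
    out[i] <- k
  }
  out
}

# Build the regional species pools (one row per species) deterministically
# from the config's root seed.
build_species_pools <- function(cfg) {
  with_rng_seed(substream_seed(cfg$seed, 0L), {
    pools <- lapply(GUILDS, function(g) {
      n <- cfg$species_pool_size[[g]]
      data.frame(
        species_id = sprintf("%s_%04d", substr(g, 1, 4), seq_len(n)),
        guild = g,
        taxon_key = sample(GUILD_TAXA[[g]], n, replace = TRUE),
        weight = draw_abundance_weights(n, cfg$abundance_model),
        stringsAsFactors = FALSE
      )
    })
    names(pools) <- GUILDS
    pools
  })
}

#' Draw one synthetic site community
#'
#' Draws the individuals of a single site: per guild, the regional species
#' pool is thinned by the system's retention probability, subplot counts are
#' Poisson with mean `subplot_area * base_density * guild_fraction *
#' density_multiplier`, species are sampled proportional to their
#' rank-abundance weights, and body lengths are lognormal with the system's
#' body-mass multiplier applied on the length scale as `multiplier^(1/3)`
#' (a cube-law approximation of a mass-scale shift).
#'
#' @param config A [synth_config()].
#' @param system,landscape System label and landscape index (1-based).
#' @param seed Integer seed for this site's substream.
#' @param pools Species pools from the study (built from the config if NULL).
#' @param site_id Site identifier string.
#' @param coords Numeric `c(x, y)` site coordinates in metres.
#' @return A `site_community`: metadata plus an `individuals` data frame with
#'   columns subplot, species_id, taxon_key, guild, body_length_mm (NA for
#'   damaged specimens).
#' @export
draw_site_community <- function(config, system, landscape = 1L, seed = config$seed,
                                pools = NULL, site_id = NULL, coords = c(0, 0)) {
  if (!system %in% config$systems)
    stop(sprintf("unknown system label '%s'", system), call. = FALSE)
  landscape <- as.integer(landscape)
  if (landscape < 1 || landscape > config$n_landscapes)
    stop(sprintf("unknown landscape index %d", landscape), call. = FALSE)
  if (is.null(pools)) pools <- build_species_pools(config)
  if (is.null(site_id)) site_id <- sprintf("%s_L%d_s", system, landscape)

  dens_mult <- config$density_multiplier[[system]]
  keep_p <- config$richness_retention[[system]]
  len_mult <- config$body_mass_multiplier[[system]]^(1 / 3)

  inds <- with_rng_seed(seed, {
    per_guild <- lapply(GUILDS, function(g) {
      pool <- pools[[g]]
      retained <- pool[rbinom(nrow(pool), 1, keep_p) == 1, , drop = FALSE]
      lambda <- config$subplot_area_m2 * config$base_density_m2 *
        config$guild_fractions[[g]] * dens_mult
      counts <- rpois(config$subplots_per_site, lambda)
      if (sum(counts) == 0) return(NULL)
      if (nrow(retained) == 0) {
        # degenerate guard: retention wiped the pool but the guild still has
        # individuals to place; fall back to the most abundant pool species
        retained <- pool[which.max(pool$weight), , drop = FALSE]
      }
      w <- retained$weight
      turn <- config$abundance_model$turnover_sdlog %||% 0
      if (turn > 0)  # site-level compositional turnover
        w <- w * rlnorm(length(w), 0, turn)
      idx <- sample.int(nrow(retained), sum(counts), replace = TRUE, prob = w)
      bl <- config$body_length[[g]]
      lengths <- rlnorm(sum(counts), meanlog = bl[["meanlog"]] + log(len_mult),
                        sdlog = bl[["sdlog"]])
      damaged <- runif(sum(counts)) < config$prop_damaged
      lengths[damaged] <- NA_real_
      data.frame(
        subplot = rep(seq_len(config$subplots_per_site), counts),
        species_id = retained$species_id[idx],
        taxon_key = retained$taxon_key[idx],
        guild = g,
        body_length_mm = lengths,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_guild) %||% empty_individuals()
  })
  if (is.null(inds)) inds <- empty_individuals()
  rownames(inds) <- NULL

  site_community(
    site_id = site_id,
    landscape = paste0("L", landscape),
    system = system,
    temperature_C = config$temperature_C[system, landscape],
    n_subplots = config$subplots_per_site,
    subplot_area_m2 = config$subplot_area_m2,
    coords = coords,
    individuals = inds
  )
}

empty_individuals <- function() {
  data.frame(subplot = integer(), species_id = character(),
             taxon_key = character(), guild = character(),
             body_length_mm = numeric(), stringsAsFactors = FALSE)
}

#' Construct a site community object
#'
#' @param site_id,landscape,system Identifiers.
#' @param temperature_C Mean soil temperature at the site (degrees C).
#' @param n_subplots,subplot_area_m2 Sampling effort.
#' @param coords Numeric `c(x, y)` in metres (used for Moran's I).
#' @param individuals Data frame with columns subplot, species_id, taxon_key,
#'   guild, body_length_mm, and optionally fresh_mass_mg and mass_source.
#' @return An object of class `site_community`.
#' @export
site_community <- function(site_id, landscape, system, temperature_C,
                           n_subplots, subplot_area_m2, coords = c(0, 0),
                           individuals = empty_individuals()) {
  stopifnot(n_subplots >= 1, subplot_area_m2 > 0)
  bad <- setdiff(unique(individuals$guild), GUILDS)
  if (length(bad))
    stop("unknown guild label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    site_id = site_id, landscape = landscape, system = system,
    temperature_C = temperature_C, n_subplots = as.integer(n_subplots),
    subplot_area_m2 = subplot_area_m2, coords = coords,
    individuals = individuals
  ), class = "site_community")
}

#' @export
print.site_community <- function(x, ...) {
  cat(sprintf("<site_community> %s (%s, %s): %d individuals, %d species, %.1f m2\n",
              x$site_id, x$system, x$landscape, nrow(x$individuals),
              length(unique(x$individuals$species_id)),
              x$n_subplots * x$subplot_area_m2))
  invisible(x)
}

sampled_area <- function(site) site$n_subplots * site$subplot_area_m2

#' Generate a full synthetic study
#'
#' Generates one `site_community` per landscape x system x replicate cell
#' (32 sites under the default design), plus the ground truth needed for
#' parameter-recovery tests. A single root seed spawns independent per-site
#' substreams, so the same (config, seed) always yields an identical study
#' and individual sites can be re-drawn independently. Sites are placed on a
#' grid (landscapes offset by 5 km) so spatial statistics are computable.
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_study` with elements `sites` (list of
#'   `site_community`), `pools` (regional species pools), `truth`
#'   (ground-truth factors and expected per-site counts) and `config`.
#' @export
generate_study <- function(config) {
  config <- validate_synth_config(config)
  pools <- build_species_pools(config)
  grid <- expand.grid(
    replicate = seq_len(config$replicates_per_system_per_landscape),
    system = config$systems,
    landscape = seq_len(config$n_landscapes),
    stringsAsFactors = FALSE
  )
  n_per_land <- nrow(grid) / config$n_landscapes
  side <- ceiling(sqrt(n_per_land))
  sites <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    within <- (i - 1) %% n_per_land
    coords <- c(5000 * (g$landscape - 1) + 200 * (within %% side),
                200 * (within %/% side))
    sites[[i]] <- draw_site_community(
      config, g$system, g$landscape,
      seed = substream_seed(config$seed, i),
      pools = pools,
      site_id = sprintf("%s_L%d_r%d", g$system, g$landscape, g$replicate),
      coords = coords
    )
  }
  truth <- list(
    expected_site_count = config$subplots_per_site * config$subplot_area_m2 *
      config$base_density_m2 * config$density_multiplier[config$systems],
    density_multiplier = config$density_multiplier[config$systems],
    richness_retention = config$richness_retention[config$systems],
    body_mass_multiplier = config$body_mass_multiplier[config$systems],
    seed = config$seed
  )
  structure(list(sites = sites, pools = pools, truth = truth, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  n_ind <- sum(vapply(x$sites, function(s) nrow(s$individuals), 0L))
  cat(sprintf("<synthetic_study> %d sites (%s), %d individuals, seed %d\n",
              length(x$sites), paste(x$config$systems, collapse = "/"),
              n_ind, x$config$seed))
  invisible(x)
}

#' Ground-truth effect readback
#'
#' Returns the configured multiplicative effect of a transformation system on
#' a response, relative to the reference system, for parameter-recovery tests.
#'
#' @param config A [synth_config()].
#' @param system System label.
#' @param response One of "density", "richness_retention", "body_mass".
#' @return The configured factor (1 for the reference system).
#' @export
true_effect <- function(config, system, response) {
  if (!system %in% config$systems)
    stop(sprintf("unknown system label '%s'", system), call. = FALSE)
  tab <- switch(response,
    density = config$density_multiplier,
    richness_retention = config$richness_retention,
    body_mass = config$body_mass_multiplier,
    stop(sprintf("unknown response '%s'; expected density, richness_retention or body_mass",
                 response), call. = FALSE)
  )
  unname(tab[[system]])
}

#' Flatten a study into individual- and site-level tables
#'
#' @param study A `synthetic_study` or list of `site_community`.
#' @return `individuals_table()`: one row per individual (site_id, landscape,
#'   system, subplot, species_id, taxon_key, guild, body_length_mm, plus
#'   fresh_mass_mg/mass_source when present). `sites_table()`: one row per
#'   site with metadata and coordinates.
#' @export
individuals_table <- function(study) {
  sites <- study_sites(study)
  do.call(rbind, lapply(sites, function(s) {
    if (nrow(s$individuals) == 0) return(NULL)
    cbind(data.frame(site_id = s$site_id, landscape = s$landscape,
                     system = s$system, stringsAsFactors = FALSE),
          s$individuals, row.names = NULL)
  }))
}

#' @rdname individuals_table
#' @export
sites_table <- function(study) {
  sites <- study_sites(study)
  do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s$site_id, landscape = s$landscape, system = s$system,
               temperature_C = s$temperature_C, n_subplots = s$n_subplots,
               subplot_area_m2 = s$subplot_area_m2,
               x = s$coords[[1]], y = s$coords[[2]], stringsAsFactors = FALSE)
  }))
}

study_sites <- function(study) {
  if (inherits(study, "synthetic_study")) study$sites
  else if (inherits(study, "site_community")) list(study)
  else study
}

#' Write / read a study as plain-text files
#'
#' Writes `individuals.csv`, `sites.csv` and `config.yaml` to a directory;
#' `read_study()` reconstructs the site list from such a directory (ground
#' truth and species pools are regenerable from the config).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `write_study()` the directory, invisibly; `read_study()` a list of
#'   `site_community` objects.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(individuals_table(study), file.path(dir, "individuals.csv"),
            row.names = FALSE)
  write.csv(sites_table(study), file.path(dir, "sites.csv"), row.names = FALSE)
  if (inherits(study, "synthetic_study")) {
    cfg <- study$config
    cfg$temperature_C <- as.data.frame(cfg$temperature_C)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  ind <- read.csv(file.path(dir, "individuals.csv"), stringsAsFactors = FALSE)
  st <- read.csv(file.path(dir, "sites.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(st)), function(i) {
    s <- st[i, ]
    rows <- ind[ind$site_id == s$site_id, , drop = FALSE]
    keep <- setdiff(names(rows), c("site_id", "landscape", "system"))
    site_community(s$site_id, s$landscape, s$system, s$temperature_C,
                   s$n_subplots, s$subplot_area_m2, c(s$x, s$y),
                   rows[, keep, drop = FALSE])
  })
}
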