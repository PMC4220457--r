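# Small fixtures built in code for the unit tests.

# A fast, tiny study configuration: 2 landscapes x 4 systems x 1 replicate,
# small pools, low density. Effect sizes stay at package defaults.
tiny_config <- function(seed = 1, ...) {
  synth_config(
    replicates_per_system_per_landscape = 1,
    base_density_m2 = 12,
    species_pool_size = c(predator = 40, omnivore = 25,
                          detritivore = 60, herbivore = 30),
    seed = seed,
    ...
  )
}

# Hand-buildable site with known individuals.
manual_site <- function(guild, mass, species = NULL, subplot = NULL,
                        length_mm = NULL, taxon = "Insecta",
                        n_subplots = 3, area = 1, temp = 25) {
  n <- length(guild)
  ind <- data.frame(
    subplot = subplot %||% rep_len(seq_len(n_subplots), n),
    species_id = species %||% sprintf("sp%d", seq_len(n)),
    taxon_key = rep_len(taxon, n),
    guild = guild,
    body_length_mm = length_mm %||% rep(NA_real_, n),
    fresh_mass_mg = mass,
    mass_source = rep("measured_regression", n),
    stringsAsFactors = FALSE
  )
  site_community("manual", "L1", "forest", temp, n_subplots, area,
                 individuals = ind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-row allometry registry for closed-form checks.
toy_registry <- function(a = 1, b = 3, basis = "fresh", factor = NA,
                         lmin = 0.1, lmax = 100) {
  validate_toy <- data.frame(
    taxon_key = "Toy", a = a, b = b, mass_basis = basis,
    dry_to_fresh_factor = factor, len_min_mm = lmin, len_max_mm = lmax,
    fallback_key = NA_character_, stringsAsFactors = FALSE
  )
  trophicflux:::validate_registry(validate_toy)
}

# Random feasible flux-network instance: draws X and efficiencies, returns
# the inputs plus a fixed-point-iteration solution as an independent oracle.
random_flux_instance <- function(model = "null_model") {
  W <- build_diet_matrix(model)
  X <- setNames(runif(4, 0.1, 20), c("predator", "omnivore", "detritivore",
                                     "herbivore"))
  at <- assimilation_table(e_animal = runif(1, 0.7, 1),
                           e_plant = runif(1, 0.3, 0.7),
                           e_detritus = runif(1, 0.05, 0.3))
  e <- vapply(c("predator", "omnivore", "detritivore", "herbivore"),
              effective_assimilation, numeric(1), W = W, table = at)
  list(W = W, X = X, e = e)
}

# Fixed-point iteration oracle for the flux balance: F <- (X + L(F)) / e.
iterate_fluxes <- function(X, W, e, tol = 1e-13, max_iter = 10000) {
  guilds <- c("predator", "omnivore", "detritivore", "herbivore")
  Wcc <- W[guilds, guilds]
  f <- X / e
  for (i in seq_len(max_iter)) {
    f_new <- (X + as.vector(Wcc %*% f)) / e
    if (max(abs(f_new - f)) < tol * max(1, max(abs(f_new)))) return(f_new)
    f <- f_new
  }
  f
}

# Exact rarefaction expectation computed independently in log space.
rarefy_oracle <- function(abund, n) {
  N <- sum(abund)
  sum(1 - exp(lchoose(N - abund, n) - lchoose(N, n)))
}
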