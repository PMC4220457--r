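#' Guild-level diet proportion matrix
#'
#' Builds the resource-by-consumer diet matrix over the node set
#' {plant, detritus, predator, omnivore, detritivore, herbivore}. Entry
#' `W[r, c]` is the proportion of consumer c's ingoing energy flux drawn from
#' resource r; every consumer column sums to 1 and basal nodes consume
#' nothing.
#'
#' Under the `null_model` no active feeding preferences are assumed:
#' predators draw equally (1/3 each) from the three guilds below them;
#' detritivores feed only on detritus and herbivores only on plants;
#' omnivores draw 25% from each of the other three guilds and the remaining
#' 25% from plant plus detritus material (split per `omnivore_basal_split`,
#' equal by default). The `no_animal_omnivory` sensitivity variant instead
#' feeds omnivores on plant and detritus material only (50% each), leaving
#' all other columns unchanged.
#'
#' @param model "null_model" or "no_animal_omnivory".
#' @param omnivore_basal_split Length-2 proportions (plant, detritus) of the
#'   omnivore's 25% basal share under the null model; must sum to 1.
#' @return A 6 x 4 matrix of class `diet_matrix` (rows: all nodes; columns:
#'   consumer guilds).
#' @export
#' @examples
#' build_diet_matrix("null_model")
build_diet_matrix <- function(model = c("null_model", "no_animal_omnivory"),
                              omnivore_basal_split = c(plant = 0.5, detritus = 0.5)) {
  model <- match.arg(model)
  if (abs(sum(omnivore_basal_split) - 1) > 1e-12 || any(omnivore_basal_split < 0))
    stop("omnivore_basal_split must be nonnegative proportions summing to 1",
         call. = FALSE)
  W <- matrix(0, nrow = length(ALL_NODES), ncol = length(GUILDS),
              dimnames = list(ALL_NODES, GUILDS))
  W[c("omnivore", "detritivore", "herbivore"), "predator"] <- 1 / 3
  W["detritus", "detritivore"] <- 1
  W["plant", "herbivore"] <- 1
  if (model == "null_model") {
    W[c("predator", "detritivore", "herbivore"), "omnivore"] <- 0.25
    W["plant", "omnivore"] <- 0.25 * omnivore_basal_split[[1]]
    W["detritus", "omnivore"] <- 0.25 * omnivore_basal_split[[2]]
  } else {
    W["plant", "omnivore"] <- 0.5
    W["detritus", "omnivore"] <- 0.5
  }
  validate_diet_matrix(W)
}

validate_diet_matrix <- function(W) {
  stopifnot(identical(rownames(W), ALL_NODES), identical(colnames(W), GUILDS))
  if (any(W < 0)) stop("diet proportions must be nonnegative", call. = FALSE)
  csum <- colSums(W)
  if (any(abs(csum - 1) > 1e-12))
    stop("consumer columns must sum to 1: ",
         paste(colnames(W)[abs(csum - 1) > 1e-12], collapse = ", "),
         call. = FALSE)
  class(W) <- c("diet_matrix", "matrix")
  W
}

#' Diet-specific assimilation efficiencies
#'
#' Efficiency of converting ingested material into usable energy, by resource
#' class. Defaults are editable literature-typical stand-ins obeying
#' detritus <= plant <= animal.
#'
#' @param e_animal,e_plant,e_detritus Efficiencies in (0, 1].
#' @return Named list of class `assimilation_table`.
#' @export
assimilation_table <- function(e_animal = 0.9, e_plant = 0.45, e_detritus = 0.2) {
  vals <- c(e_animal = e_animal, e_plant = e_plant, e_detritus = e_detritus)
  if (any(vals <= 0) || any(vals > 1))
    stop("assimilation efficiencies must lie in (0, 1]", call. = FALSE)
  if (!(e_detritus <= e_plant && e_plant <= e_animal))
    warning("expected e_detritus <= e_plant <= e_animal; proceeding with given values")
  structure(as.list(vals), class = "assimilation_table")
}

#' Effective assimilation efficiency of a mixed diet
#'
#' Diet-weighted mean of resource-class efficiencies: animal-guild resources
#' contribute `e_animal`, plant contributes `e_plant`, detritus `e_detritus`.
#'
#' @param consumer Guild label (column of `W`).
#' @param W A [build_diet_matrix()].
#' @param table An [assimilation_table()].
#' @return Scalar efficiency in (0, 1].
#' @export
effective_assimilation <- function(consumer, W, table = assimilation_table()) {
  col <- W[, consumer]
  col[["plant"]] * table$e_plant + col[["detritus"]] * table$e_detritus +
    sum(col[GUILDS]) * table$e_animal
}

effective_assimilation_all <- function(W, table = assimilation_table()) {
  vapply(GUILDS, effective_assimilation, numeric(1), W = W, table = table)
}

#' Solve the network energy balance for ingoing fluxes
#'
#' At every consumer node the assimilated share of the ingoing flux must
#' cover the node's metabolic demand plus its loss to predation:
#' `e_c * F_c = X_c + L_c`, with `L_c = sum_k W[c, k] * F_k` the flux of node
#' c's biomass into its own consumers. Because predators and omnivores feed
#' on each other, the system is solved simultaneously as the linear system
#' `(diag(e) - W_cc) F = X` over the consumer block `W_cc`; the solution is
#' exact (no iteration) and is checked against the balance identity at every
#' node before returning.
#'
#' @param X Named numeric: metabolic demand per guild, J/h/m^2 (>= 0).
#' @param W A [build_diet_matrix()].
#' @param e_a Named numeric of per-guild effective assimilation efficiencies,
#'   or NULL to compute them from `assim`.
#' @param assim An [assimilation_table()] used when `e_a` is NULL.
#' @param energy_per_gram Energy content of fresh biomass (J/g) for the
#'   annual mass-flux conversion.
#' @return An `energy_network`: list with per-guild `X`, `e_a`, ingoing flux
#'   `F_J_h_m2` and `F_kg_ha_yr`, loss to predation `L`, the edge-flux matrix
#'   `edges` (rows: resources, cols: consumers, J/h/m^2) and per-basal-node
#'   outflow `basal_outflow`.
#' @export
#' @examples
#' W <- build_diet_matrix("null_model")
#' solve_fluxes(c(predator = 1, omnivore = 1, detritivore = 5, herbivore = 2), W)
solve_fluxes <- function(X, W, e_a = NULL, assim = assimilation_table(),
                         energy_per_gram = 7000) {
  W <- validate_diet_matrix(unclass(W))
  X <- X[GUILDS]
  if (anyNA(X) || any(X < 0))
    stop("metabolic demands X must be named, nonnegative and cover all guilds",
         call. = FALSE)
  if (is.null(e_a)) e_a <- effective_assimilation_all(W, assim)
  e_a <- e_a[GUILDS]
  if (anyNA(e_a) || any(e_a <= 0) || any(e_a > 1))
    stop("assimilation efficiencies must lie in (0, 1] for every guild",
         call. = FALSE)

  Wcc <- W[GUILDS, GUILDS]
  A <- diag(e_a, nrow = length(GUILDS)) - Wcc
  FF <- tryCatch(solve(A, X),
                 error = function(e) stop("flux balance system is singular: ",
                                          conditionMessage(e), call. = FALSE))
  names(FF) <- GUILDS
  tol <- 1e-9 * max(1, max(abs(FF)))
  if (any(FF < -tol))
    stop("negative flux at node(s): ",
         paste(GUILDS[FF < -tol], collapse = ", "),
         " (infeasible assimilation/diet combination)", call. = FALSE)
  FF <- pmax(FF, 0)
  L <- as.vector(Wcc %*% FF)
  names(L) <- GUILDS
  resid_bal <- e_a * FF - X - L
  if (any(abs(resid_bal) > 1e-9 * pmax(1, abs(X) + abs(L))))
    stop("flux balance violated after solve at node(s): ",
         paste(GUILDS[abs(resid_bal) > 1e-9 * pmax(1, abs(X) + abs(L))],
               collapse = ", "), call. = FALSE)
  edges <- sweep(W, 2, FF, `*`)
  structure(list(
    X = X, e_a = e_a,
    F_J_h_m2 = FF,
    F_kg_ha_yr = to_mass_flux(FF, energy_per_gram),
    L = L,
    edges = edges,
    basal_outflow = rowSums(edges)[BASAL_NODES],
    energy_per_gram = energy_per_gram
  ), class = "energy_network")
}

#' @export
print.energy_network <- function(x, ...) {
  cat("<energy_network>\n")
  print(round(data.frame(X_J_h_m2 = x$X, e_a = x$e_a, F_J_h_m2 = x$F_J_h_m2,
                         F_kg_ha_yr = x$F_kg_ha_yr, L = x$L), 4))
  invisible(x)
}

#' Convert energy flux to annual mass flux (and back)
#'
#' `to_mass_flux()` converts J/h/m^2 to kg fresh mass/ha/yr using the energy
#' content of fresh biomass: `F * 8760 h/yr * 1e4 m2/ha / (energy_per_gram *
#' 1e3 g/kg)`. `mass_to_energy_flux()` is the exact inverse.
#'
#' @param flux Energy flux (J/h/m^2) or mass flux (kg/ha/yr).
#' @param energy_per_gram Energy content of fresh biomass, J/g (> 0);
#'   default 7000, an editable literature-typical value.
#' @return Converted flux.
#' @export
to_mass_flux <- function(flux, energy_per_gram = 7000) {
  if (energy_per_gram <= 0) stop("energy_per_gram must be > 0", call. = FALSE)
  flux * HOURS_PER_YEAR * M2_PER_HA / (energy_per_gram * 1e3)
}

#' @rdname to_mass_flux
#' @export
mass_to_energy_flux <- function(flux, energy_per_gram = 7000) {
  if (energy_per_gram <= 0) stop("energy_per_gram must be > 0", call. = FALSE)
  flux * energy_per_gram * 1e3 / (HOURS_PER_YEAR * M2_PER_HA)
}

#' Energy network of one site
#'
#' Convenience wrapper chaining community metabolism and the flux solve for a
#' single site under a chosen diet model.
#'
#' @param site A `site_community` with fresh masses present.
#' @param model Diet model label passed to [build_diet_matrix()].
#' @param params,groups Metabolic parameter table and taxon-group mapping.
#' @param assim An [assimilation_table()].
#' @param energy_per_gram Energy content of fresh biomass (J/g).
#' @return An `energy_network` for the site.
#' @export
site_energy_network <- function(site, model = "null_model",
                                params = read_metabolic_params(),
                                groups = read_taxon_groups(),
                                assim = assimilation_table(),
                                energy_per_gram = 7000) {
  met <- community_metabolism(site, params, groups)
  X <- setNames(met$X_J_h_m2[match(GUILDS, met$guild)], GUILDS)
  W <- build_diet_matrix(model)
  solve_fluxes(X, W, assim = assim, energy_per_gram = energy_per_gram)
}

#' Compare relative flux losses between two diet models
#'
#' For each non-reference transformation system, computes the relative loss
#' of mean total flux versus the reference system under each model
#' (`1 - mean_flux_system / mean_flux_reference`) and the absolute disparity
#' between the two models' losses. Relative losses are invariant to any
#' global rescaling of fluxes, which is what makes the comparison a
#' meaningful robustness check of the diet assumptions.
#'
#' @param results_null,results_alt Data frames with columns `site_id`,
#'   `system` and `flux` (per-site total flux, any common unit), covering the
#'   same sites.
#' @param reference_system Label of the reference system.
#' @return Data frame: system, loss_null, loss_alt, disparity (absolute
#'   difference of the relative losses).
#' @export
sensitivity_compare <- function(results_null, results_alt,
                                reference_system = "forest") {
  for (d in list(results_null, results_alt))
    stopifnot(all(c("site_id", "system", "flux") %in% names(d)))
  if (!setequal(results_null$site_id, results_alt$site_id))
    stop("the two result sets must cover the same sites", call. = FALSE)
  if (!reference_system %in% results_null$system)
    stop(sprintf("reference system '%s' missing from results", reference_system),
         call. = FALSE)
  mean_by_system <- function(d) {
    agg <- aggregate(flux ~ system, data = d, FUN = mean)
    setNames(agg$flux, agg$system)
  }
  m0 <- mean_by_system(results_null)
  m1 <- mean_by_system(results_alt)
  systems <- setdiff(names(m0), reference_system)
  loss0 <- 1 - m0[systems] / m0[[reference_system]]
  loss1 <- 1 - m1[systems] / m1[[reference_system]]
  data.frame(system = systems, loss_null = unname(loss0),
             loss_alt = unname(loss1),
             disparity = unname(abs(loss0 - loss1)),
             stringsAsFactors = FALSE)
}
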